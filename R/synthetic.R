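# Synthetic mannequin fixtures. The mannequin is a union of capsules
# (thickened segments) plus a head disc, mimicking the acquisition
# protocol: a single subject standing barefoot before a uniform neutral
# wall. Its virtue is that every quantity the pipeline estimates — the
# silhouette, the 25 pose keypoints, the C7/L5/MA/FC landmarks and the
# three angles — has a closed form, so recovery can be checked exactly.
#
# Geometry conventions (fractions of stature): head radius 0.065, neck
# 0.05, trunk 0.30, thigh 0.26, shank 0.26 (sum of vertical chain = 1).
# On the sagittal view the trunk is a two-segment polyline bent anteriorly
# by the requested flexion angle at the fulcrum; a miter wedge fills the
# posterior corner so the back contour has a true vertex (the FC truth)
# instead of a capsule arc. On the frontal view the trunk leans rigidly by
# the requested angle; shoulders and ears sit symmetrically about the
# trunk axis, so the diagonal shoulder-ear intersection (the C7 truth)
# lies on the axis and the Pisa angle equals the lean by construction.

#' Mannequin specification
#'
#' @param view `"frontal"` or `"sagittal"`.
#' @param trunk_angle_deg Lateral lean (frontal) or anterior flexion
#'   (sagittal), degrees in `[0, 80]`.
#' @param fulcrum_height_frac Sagittal flexion apex as a fraction of trunk
#'   length above the hip, in (0, 1).
#' @param image_width,image_height Render size in pixels.
#' @param stature_frac Subject stature as a fraction of image height.
#' @param trunk_halfwidth_frac Trunk capsule radius as a fraction of
#'   stature (BMI proxy).
#' @param subject_rgb,background_rgb Colors, each `c(r, g, b)` in 0–255.
#' @param noise_sigma Gaussian channel noise, 0–255 units.
#' @param keypoint_jitter_sigma Isotropic keypoint noise, pixels (emulates
#'   pose-estimator error; 2 px is typical).
#' @param seed Integer seed; fixtures are bit-identical under a fixed seed.
#' @return Object of class `mannequin_spec`.
#' @export
mannequin_spec <- function(view = c("sagittal", "frontal"),
                           trunk_angle_deg = 0,
                           fulcrum_height_frac = 0.5,
                           image_width = 260, image_height = 360,
                           stature_frac = 0.88,
                           trunk_halfwidth_frac = 0.075,
                           subject_rgb = c(70, 70, 80),
                           background_rgb = c(235, 233, 228),
                           noise_sigma = 0,
                           keypoint_jitter_sigma = 0,
                           seed = 1L) {
  view <- match.arg(view)
  if (trunk_angle_deg < 0 || trunk_angle_deg > 80)
    stop_format("trunk_angle_deg must lie in [0, 80]")
  if (fulcrum_height_frac <= 0 || fulcrum_height_frac >= 1)
    stop_format("fulcrum_height_frac must lie in (0, 1)")
  if (any(c(subject_rgb, background_rgb) < 0 | c(subject_rgb, background_rgb) > 255))
    stop_format("colors must lie in [0, 255]")
  structure(list(view = view, trunk_angle_deg = trunk_angle_deg,
                 fulcrum_height_frac = fulcrum_height_frac,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 stature_frac = stature_frac,
                 trunk_halfwidth_frac = trunk_halfwidth_frac,
                 subject_rgb = subject_rgb, background_rgb = background_rgb,
                 noise_sigma = noise_sigma,
                 keypoint_jitter_sigma = keypoint_jitter_sigma,
                 seed = as.integer(seed)),
            class = "mannequin_spec")
}

#' @noRd
.proportions <- function(stature) {
  list(head_r = 0.065 * stature, neck = 0.05 * stature, trunk = 0.30 * stature,
       thigh = 0.26 * stature, shank = 0.26 * stature,
       r_thigh = 0.05 * stature, r_shank = 0.035 * stature,
       r_neck = 0.03 * stature)
}

#' Build the mannequin skeleton, keypoints and true landmarks
#'
#' Places the stick-figure joints, derives the 25-keypoint set (clean and
#' jittered), the true landmarks `C7`, `L5`, `MA` (and `FC` on sagittal
#' views, the miter-corner apex of the bent back) and the true angles,
#' which are recomputable from the true landmarks via [external_angle()].
#'
#' @param spec A [mannequin_spec()].
#' @return Object of class `mannequin_truth` (no raster yet; see
#'   [render_mannequin()]).
#' @export
build_skeleton <- function(spec) {
  W <- spec$image_width; H <- spec$image_height
  st <- spec$stature_frac * H
  pr <- .proportions(st)
  r_tr <- spec$trunk_halfwidth_frac * st
  th <- spec$trunk_angle_deg * pi / 180
  y0 <- (H + st) / 2 - 1                     # ankle height
  if (spec$view == "sagittal")
    tr <- .skeleton_sagittal(spec, W, H, st, pr, r_tr, th, y0)
  else
    tr <- .skeleton_frontal(spec, W, H, st, pr, r_tr, th, y0)
  set.seed(spec$seed)
  kj <- tr$keypoints
  pres <- kj$coords[, "confidence"] > 0
  if (spec$keypoint_jitter_sigma > 0) {
    kj$coords[pres, "x"] <- pmin(pmax(
      kj$coords[pres, "x"] + stats::rnorm(sum(pres), 0, spec$keypoint_jitter_sigma), 0), W - 1)
    kj$coords[pres, "y"] <- pmin(pmax(
      kj$coords[pres, "y"] + stats::rnorm(sum(pres), 0, spec$keypoint_jitter_sigma), 0), H - 1)
  }
  tr$keypoints_jittered <- kj
  tr$spec <- spec
  class(tr) <- "mannequin_truth"
  tr
}

#' @noRd
.kp_matrix <- function(pts, conf = 0.95) {
  m <- do.call(rbind, pts)
  cbind(x = m[, 1], y = m[, 2], confidence = rep(conf, nrow(m)))
}

#' @noRd
.skeleton_sagittal <- function(spec, W, H, st, pr, r_tr, th, y0) {
  f <- spec$fulcrum_height_frac
  x0 <- 0.38 * W
  d <- c(sin(th), -cos(th))              # upper-trunk axis, toward the head
  a_dir <- c(cos(th), sin(th))           # anterior normal of the upper trunk
  RA <- c(x0, y0)
  RK <- c(x0, y0 - pr$shank)
  RH <- c(x0, y0 - pr$shank - pr$thigh)
  V  <- RH + c(0, -f * pr$trunk)         # flexion fulcrum vertex
  C7n <- V + (1 - f) * pr$trunk * d      # neck base on the axis
  RSH <- C7n - 0.35 * (1 - f) * pr$trunk * d
  REar <- C7n + pr$neck * d
  head_c <- C7n + (pr$neck + pr$head_r) * d
  N <- head_c + 0.85 * pr$head_r * a_dir
  REye <- head_c + 0.6 * pr$head_r * a_dir + 0.3 * pr$head_r * d

  segs <- list(list(a = RA, b = RK, r = pr$r_shank),
               list(a = RK, b = RH, r = pr$r_thigh),
               list(a = RH, b = V, r = r_tr),
               list(a = V, b = C7n, r = r_tr),
               list(a = C7n, b = head_c, r = pr$r_neck))
  wedge <- NULL
  if (th > 0) {
    n2 <- -a_dir
    P1 <- V + r_tr * c(-1, 0)
    P2 <- V + r_tr * n2
    t <- (x0 - r_tr - P2[1]) / d[1]
    Vp <- P2 + t * d                     # miter corner: the true FC
    wedge <- rbind(P1, Vp, P2)
  }

  # true landmarks on the posterior contour
  A <- RSH + 0.4 * (REar - RSH)
  aA <- sum((A - C7n) * d)               # axial position of A past the neck base
  t_exit <- if (aA <= 0) r_tr else sqrt(max(r_tr^2 - aA^2, 0))
  t_exit <- max(t_exit, if (aA >= 0) pr$r_neck else 0)
  C7_true <- A - t_exit * a_dir
  L5p <- c(x0, RH[2] - 0.2 * pr$thigh)
  L5_true <- c(x0 - r_tr, L5p[2])
  FC_true <- if (th > 0) wedge[2, ] else c(x0 - r_tr, V[2])
  MA_true <- RA

  kp <- pose_keypoints(.kp_matrix(list(
    N = N, NECK = C7n, RSH = RSH, RH = RH, RK = RK, RA = RA,
    REye = REye, REar = REar, P = RH)),
    view = "sagittal", image_width = W, image_height = H)
  angles <- c(lCC = external_angle(L5_true, MA_true, C7_true),
              tCC = if (th > 0) external_angle(FC_true, L5_true, C7_true) else 0)
  list(keypoints = kp, segments = segs,
       head = list(center = head_c, r = pr$head_r), wedge = wedge,
       landmarks_true = list(C7 = C7_true, L5 = L5_true, FC = FC_true,
                             MA = MA_true, A = A, L5_prime = L5p),
       true_angles = angles, side = "right", posterior_dir = c(-1, 0))
}

#' @noRd
.skeleton_frontal <- function(spec, W, H, st, pr, r_tr, th, y0) {
  x0 <- W / 2
  hw <- 0.06 * st                         # hip / ankle half-separation
  u <- c(sin(th), -cos(th))               # trunk axis, toward the head
  w <- c(cos(th), sin(th))                # lateral unit vector
  LA <- c(x0 - hw, y0); RA <- c(x0 + hw, y0)
  LK <- LA - c(0, pr$shank); RK <- RA - c(0, pr$shank)
  LH <- LK - c(0, pr$thigh); RH <- RK - c(0, pr$thigh)
  MH <- (LH + RH) / 2
  L5_true <- MH - c(0, 0.2 * pr$thigh)
  Ttr <- pr$trunk - 0.2 * pr$thigh
  C7t <- L5_true + Ttr * u                # nominal neck base
  sd <- 0.05 * st; sw <- 0.13 * st        # shoulders below C7, lateral
  eu <- 0.07 * st; ew <- 0.055 * st       # ears above C7, lateral
  LSH <- C7t - sd * u + sw * w; RSH <- C7t - sd * u - sw * w
  LEar <- C7t + eu * u + ew * w; REar <- C7t + eu * u - ew * w
  head_c <- C7t + (pr$neck + pr$head_r) * u
  # symmetric placement puts the diagonal intersection on the trunk axis
  C7_true <- C7t + (eu * sw - sd * ew) / (sw + ew) * u
  MA_true <- (LA + RA) / 2

  segs <- list(list(a = LA, b = LK, r = pr$r_shank),
               list(a = RA, b = RK, r = pr$r_shank),
               list(a = LK, b = LH, r = pr$r_thigh),
               list(a = RK, b = RH, r = pr$r_thigh),
               list(a = LH, b = RH, r = 0.055 * st),
               list(a = MH, b = C7t, r = 0.10 * st),
               list(a = LSH, b = RSH, r = 0.045 * st),
               list(a = C7t, b = head_c, r = pr$r_neck))
  kp <- pose_keypoints(.kp_matrix(list(
    NECK = C7t, LSH = LSH, RSH = RSH, LEar = LEar, REar = REar,
    LH = LH, RH = RH, LK = LK, RK = RK, LA = LA, RA = RA, P = MH)),
    view = "frontal", image_width = W, image_height = H)
  angles <- c(PS = external_angle(L5_true, MA_true, C7_true))
  list(keypoints = kp, segments = segs,
       head = list(center = head_c, r = pr$head_r), wedge = NULL,
       landmarks_true = list(C7 = C7_true, L5 = L5_true, MA = MA_true, MH = MH),
       true_angles = angles)
}

#' Rasterize a mannequin to an image and its true mask
#'
#' The true mask is the union of the body capsules, the head disc and (on
#' bent sagittal views) the posterior miter wedge. The image paints the
#' subject color over the background color with optional Gaussian channel
#' noise, clipped to 0–255.
#'
#' @param truth A `mannequin_truth` from [build_skeleton()].
#' @return The same object with `mask` (logical matrix) and `image`
#'   (`[H, W, 3]` array) fields added.
#' @export
render_mannequin <- function(truth) {
  spec <- truth$spec
  W <- spec$image_width; H <- spec$image_height
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  inside <- rep(FALSE, W * H)
  for (s in truth$segments)
    inside <- inside | (.dist_to_segment(xs, ys, s$a, s$b) <= s$r)
  hc <- truth$head$center
  inside <- inside | ((xs - hc[1])^2 + (ys - hc[2])^2 <= truth$head$r^2)
  if (!is.null(truth$wedge))
    inside <- inside | .in_triangle(xs, ys, truth$wedge)
  mask <- matrix(inside, nrow = H, ncol = W)

  img <- array(0, dim = c(H, W, 3))
  set.seed(spec$seed + 1L)
  for (ch in 1:3) {
    plane <- matrix(spec$background_rgb[ch], H, W)
    plane[mask] <- spec$subject_rgb[ch]
    if (spec$noise_sigma > 0)
      plane <- plane + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
    img[, , ch] <- pmin(pmax(plane, 0), 255)
  }
  truth$mask <- mask
  truth$image <- img
  truth
}

#' @noRd
.in_triangle <- function(xs, ys, tri) {
  s <- function(p1, p2) (xs - p2[1]) * (p1[2] - p2[2]) - (p1[1] - p2[1]) * (ys - p2[2])
  d1 <- s(tri[1, ], tri[2, ]); d2 <- s(tri[2, ], tri[3, ]); d3 <- s(tri[3, ], tri[1, ])
  !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
}

#' Generate a complete mannequin fixture
#'
#' Convenience wrapper: [build_skeleton()] followed by
#' [render_mannequin()].
#'
#' @inheritParams build_skeleton
#' @return A `mannequin_truth` with rasters.
#' @export
generate_mannequin <- function(spec) render_mannequin(build_skeleton(spec))

#' Write a keypoint set in the 25-keypoint JSON dialect
#'
#' @param kps A [pose_keypoints()] object.
#' @param path Output path.
#' @export
write_pose_json <- function(kps, path) {
  flat <- as.vector(t(kps$coords[, c("x", "y", "confidence")]))
  payload <- list(version = 1.3,
                  canvas_width = kps$image_width,
                  canvas_height = kps$image_height,
                  people = list(list(person_id = list(-1L),
                                     pose_keypoints_2d = flat)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a factorial fixture battery
#'
#' Produces a full-factorial sweep of mannequin fixtures over the supplied
#' factor levels, writing images (PNG), true masks (PNG), keypoint files
#' (25-keypoint JSON dialect) and a manifest CSV with the true angles, the
#' BMI proxy and the mannequin parameters — the synthetic analogue of a clinical
#' photograph collection, consumable by [robustness_table()].
#'
#' @param design List with fields: `view` (`"frontal"`, `"sagittal"` or
#'   both), `image_height` (levels, px), `contrast` (levels: absolute gray
#'   distance subject-background, 0–255), `angle` (levels, degrees),
#'   optional `trunk_halfwidth_frac` and `background_hue_shift` levels,
#'   `n_per_cell` (replicates), `seed`, and optional
#'   `keypoint_jitter_sigma` / `noise_sigma`.
#' @param out_dir Output directory (created).
#' @return The manifest data frame, invisibly; also written as
#'   `manifest.csv`.
#' @export
synth_battery <- function(design, out_dir) {
  req <- c("view", "image_height", "contrast", "angle", "n_per_cell", "seed")
  if (length(design) == 0 || !all(req %in% names(design)))
    stop_format(paste("design must supply:", paste(req, collapse = ", ")))
  grid <- expand.grid(view = design$view,
                      image_height = design$image_height,
                      contrast = design$contrast,
                      angle = design$angle,
                      thw = design$trunk_halfwidth_frac %||% 0.075,
                      hue_shift = design$background_hue_shift %||% 0,
                      rep = seq_len(design$n_per_cell),
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop_format("empty design")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "keypoints"), showWarnings = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed_i <- design$seed + i
    set.seed(seed_i)
    bmi <- 25.07 + 300 * (g$thw - 0.075) + stats::rnorm(1, 0, 0.8)
    bg <- pmin(pmax(c(70 + g$contrast + g$hue_shift, 70 + g$contrast,
                      80 + g$contrast - g$hue_shift), 0), 255)
    spec <- mannequin_spec(
      view = as.character(g$view), trunk_angle_deg = g$angle,
      image_width = round(0.72 * g$image_height), image_height = g$image_height,
      trunk_halfwidth_frac = g$thw, background_rgb = bg,
      noise_sigma = design$noise_sigma %||% 0,
      keypoint_jitter_sigma = design$keypoint_jitter_sigma %||% 0,
      seed = seed_i)
    fx <- generate_mannequin(spec)
    id <- sprintf("fx%04d", i)
    img_p <- file.path(out_dir, "images", paste0(id, ".png"))
    msk_p <- file.path(out_dir, "masks", paste0(id, "_mask.png"))
    kp_p <- file.path(out_dir, "keypoints", paste0(id, "_keypoints.json"))
    write_png(fx$image, img_p)
    write_png(fx$mask, msk_p)
    write_pose_json(fx$keypoints_jittered, kp_p)
    ang <- fx$true_angles
    rows[[i]] <- data.frame(
      id = id, image = img_p, keypoints = kp_p, mask = msk_p,
      view = as.character(g$view), bmi = bmi,
      truth_PS = unname(ang["PS"])[1] %||% NA_real_,
      truth_lCC = if ("lCC" %in% names(ang)) unname(ang["lCC"]) else NA_real_,
      truth_tCC = if ("tCC" %in% names(ang)) unname(ang["tCC"]) else NA_real_,
      trunk_angle = g$angle, image_height = g$image_height,
      image_width = spec$image_width, contrast = g$contrast,
      trunk_halfwidth_frac = g$thw, seed = seed_i)
  }
  manifest <- do.call(rbind, rows)
  manifest$truth_PS[manifest$view != "frontal"] <- NA_real_
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
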