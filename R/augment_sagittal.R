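# Sagittal view landmark augmentation: C7, L5 and FC are spinous-process
# landmarks on the BACK contour, so they are found by marching from
# keypoint-derived anchor points posteriorly until the silhouette mask is
# left. MA is the visible lateral malleolus, proxied by the ankle keypoint.

#' @noRd
.px <- function(v) floor(v + 0.5)   # symmetric nearest-pixel rule

#' @noRd
.in_mask <- function(mask, p) {
  r <- .px(p[2]) + 1L; c <- .px(p[1]) + 1L
  r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c]
}

# March from `start` (inside the mask) along unit `dir` at sub-pixel steps,
# then bisect the bracketing interval to locate the mask-boundary crossing
# to ~0.02 px. Sub-pixel landmarks avoid the resolution-dependent inward
# bias that pixel-centre snapping would give the angles.
#' @noRd
.march_to_boundary <- function(mask, start, dir, step = 0.5) {
  if (!.in_mask(mask, start))
    stop_landmark(sprintf("march start (%.1f, %.1f) is outside the silhouette", start[1], start[2]))
  dir <- .unit(dir)
  diag_len <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  t_in <- 0
  for (t in seq(step, diag_len, by = step)) {
    p <- start + t * dir
    rc <- .px(p)             # pixel-centre sampling, same rounding as .in_mask
    if (rc[1] < 0 || rc[1] > ncol(mask) - 1 || rc[2] < 0 || rc[2] > nrow(mask) - 1)
      stop_boundary("boundary search exited the image while still inside the mask")
    if (!mask[rc[2] + 1, rc[1] + 1]) {
      t_out <- t
      for (i in 1:5) {       # bisect the crossing
        mid <- (t_in + t_out) / 2
        if (.in_mask(mask, start + mid * dir)) t_in <- mid else t_out <- mid
      }
      return(start + (t_in + t_out) / 2 * dir)
    }
    t_in <- t
  }
  stop_boundary("boundary search exhausted the image diagonal")
}

#' Detect the visible body side and the posterior direction
#'
#' On a sagittal photograph only one body side faces the camera. The side
#' whose ear–shoulder–hip–knee–ankle chain carries the highest summed
#' keypoint confidence is selected, and the posterior direction (toward the
#' subject's back) is the horizontal unit vector pointing from the face
#' points (nose/eyes) toward the ear.
#'
#' @param kps A [pose_keypoints()] object (sagittal view).
#' @return List with `side` (`"left"` or `"right"`) and `posterior_dir`
#'   (unit 2-vector).
#' @export
detect_side_and_posterior <- function(kps) {
  chain <- function(s) paste0(s, c("Ear", "SH", "H", "K", "A"))
  score <- function(s) sum(kps$coords[chain(s), "confidence"])
  sides <- c("right", "left")
  ok <- c(.side_complete(kps, "right") && kp_present(kps, "REar"),
          .side_complete(kps, "left") && kp_present(kps, "LEar"))
  if (!any(ok))
    stop_missing_keypoint("ear/shoulder/hip/knee/ankle chain",
                          "neither body side has a complete ear-shoulder-hip-knee-ankle chain")
  cand <- sides[ok]
  side <- cand[which.max(vapply(cand, function(s) score(toupper(substr(s, 1, 1))), numeric(1)))]
  s <- toupper(substr(side, 1, 1))
  ear <- kp_get(kps, paste0(s, "Ear"))
  face <- c("N", "REye", "LEye")
  face <- face[kp_present(kps, face)]
  if (length(face) == 0)
    stop_missing_keypoint("N/REye/LEye", "no face keypoint present; cannot orient the posterior direction")
  fx <- mean(kps$coords[face, "x"])
  if (ear[1] == fx) stop_geometry("face and ear horizontally coincident; posterior direction undefined")
  list(side = side, posterior_dir = c(sign(ear[1] - fx), 0))
}

#' Anchor point A on the ear–shoulder segment
#'
#' A lies on the segment from the shoulder to the ear of the visible side,
#' at a parametric percentage `K2` (default 40) of the distance from the
#' shoulder. The perpendicular through A locates C7 on the back contour.
#'
#' @inheritParams detect_side_and_posterior
#' @param K2 Percentage of the shoulder-to-ear distance, in (0, 100).
#' @param side Visible side, from [detect_side_and_posterior()].
#' @return Position `c(x, y)`.
#' @export
point_A <- function(kps, K2 = 40, side = "right") {
  stopifnot(K2 >= 0, K2 <= 100)
  s <- toupper(substr(side, 1, 1))
  sh <- kp_get(kps, paste0(s, "SH"))
  ear <- kp_get(kps, paste0(s, "Ear"))
  if (all(sh == ear)) stop_geometry("ear and shoulder keypoints coincide; A undefined")
  sh + K2 / 100 * (ear - sh)
}

#' C7 on a sagittal view
#'
#' C7 is the last point of the silhouette mask along the line through A
#' perpendicular to the ear–shoulder segment, marching toward the back.
#'
#' @param mask Logical silhouette matrix.
#' @inheritParams point_A
#' @param A Anchor from [point_A()]; must lie inside the mask.
#' @param posterior_dir Unit vector toward the subject's back.
#' @return Landmark position `c(x, y)` on the mask boundary.
#' @export
c7_sagittal <- function(mask, kps, A, posterior_dir, side = "right") {
  s <- toupper(substr(side, 1, 1))
  sh <- kp_get(kps, paste0(s, "SH"))
  ear <- kp_get(kps, paste0(s, "Ear"))
  perp <- .perp(.unit(ear - sh))
  if (sum(perp * posterior_dir) < 0) perp <- -perp
  if (sum(perp * posterior_dir) == 0)
    stop_geometry("ear-shoulder segment parallel to the posterior direction")
  .march_to_boundary(mask, A, perp)
}

#' L5 on a sagittal view
#'
#' L5 is found in two phases: first L5' is placed exactly as on the frontal
#' view (vertical offset of `K1`% of the leg length above the mid-hip
#' point, using the visible side alone when the far side is undetected),
#' then L5 is the last segmented pixel marching horizontally from L5'
#' toward the back.
#'
#' @inheritParams c7_sagittal
#' @param K1 Percentage of the leg (hip–knee) length, in (0, 100).
#' @return List with `L5` (on the mask boundary) and the intermediate
#'   `L5_prime`.
#' @export
l5_sagittal <- function(mask, kps, K1 = 20, posterior_dir = c(-1, 0)) {
  stopifnot(K1 > 0, K1 < 100)
  hips <- c("LH", "RH")[kp_present(kps, c("LH", "RH"))]
  if (length(hips) == 0) stop_missing_keypoint(c("LH", "RH"))
  legs <- numeric(0)
  for (s in c("L", "R")) {
    h <- paste0(s, "H"); k <- paste0(s, "K")
    if (all(kp_present(kps, c(h, k))))
      legs <- c(legs, .vec_norm(kp_get(kps, h) - kp_get(kps, k)))
  }
  if (length(legs) == 0) stop_missing_keypoint(c("LK", "RK"), "no hip-knee pair present to estimate leg length")
  leg <- mean(legs)
  if (leg == 0) stop_geometry("zero leg length; cannot place L5'")
  mh <- unname(colMeans(kps$coords[hips, c("x", "y"), drop = FALSE]))
  l5p <- c(mh[1], mh[2] - K1 / 100 * leg)
  list(L5 = .march_to_boundary(mask, l5p, posterior_dir), L5_prime = unname(l5p))
}

#' Fulcrum of the spine flexion (FC)
#'
#' FC is the point of the silhouette farthest from the line joining C7 and
#' L5, on the posterior side — geometrically, the apex of the bent back.
#' The default method takes the maximum perpendicular distance over all
#' posterior boundary pixels whose projection onto the chord falls between
#' C7 and L5 (the fulcrum is a trunk point; this excludes head and heel
#' pixels that happen to lie behind the line), with ties broken toward
#' smaller y, then smaller x. `method = "ray"` instead marches
#' perpendicularly backwards from each point of the C7–L5 segment, which
#' gives the same apex on convex backs.
#'
#' @param mask Logical silhouette matrix.
#' @param C7,L5 Landmarks from [c7_sagittal()] and [l5_sagittal()].
#' @param posterior_dir Unit vector toward the subject's back.
#' @param method `"boundary-max"` (default) or `"ray"`.
#' @param strict If `TRUE` (default), a silhouette with no boundary pixel
#'   strictly posterior to the C7–L5 line raises a
#'   `degenerate_silhouette_error`; if `FALSE` (a perfectly straight back)
#'   the posterior-most boundary pixel is returned with distance `<= 0`,
#'   which measures a thoracic angle of about zero.
#' @param refine If `TRUE` (default), the winning boundary pixel is refined
#'   to the sub-pixel mask-boundary crossing along the chord normal; the
#'   pixel centre sits up to a pixel inside the true contour, a bias that
#'   would otherwise grow the angle error at low resolutions.
#' @return Position `c(x, y)` with attribute `distance` (perpendicular
#'   distance to the C7–L5 line, pixels).
#' @export
fc_search <- function(mask, C7, L5, posterior_dir, method = c("boundary-max", "ray"),
                      strict = TRUE, refine = TRUE) {
  method <- match.arg(method)
  if (all(C7 == L5)) stop_geometry("C7 and L5 coincide; fulcrum line undefined")
  if (abs(sum(.perp(.unit(L5 - C7)) * posterior_dir)) < 1e-9)
    stop_geometry("C7-L5 line parallel to the posterior direction; posterior side undefined")
  if (!any(mask)) stop_segmentation("empty silhouette mask")
  if (method == "ray") return(.fc_ray(mask, C7, L5, posterior_dir))
  bd <- mask_boundary(mask)
  xs <- bd[, 1]; ys <- bd[, 2]
  # the fulcrum lies between C7 and L5: keep pixels projecting onto the chord
  u <- L5 - C7
  tproj <- ((xs - C7[1]) * u[1] + (ys - C7[2]) * u[2]) / sum(u^2)
  keep <- tproj > 0 & tproj < 1
  if (!any(keep)) {
    if (strict)
      .stop_typed("degenerate_silhouette_error", "no boundary pixel projects onto the C7-L5 chord")
  } else {
    xs <- xs[keep]; ys <- ys[keep]
  }
  d <- .signed_line_distance(xs, ys, C7, L5, posterior_dir)
  post <- d > 0
  if (!any(post)) {
    if (strict)
      .stop_typed("degenerate_silhouette_error", "no boundary pixel strictly posterior to the C7-L5 line")
    post <- d > max(d) - 1e-9
  }
  xs <- xs[post]; ys <- ys[post]; d <- d[post]
  # distances equal to within 1e-6 px are ties (keeps the smaller-y,
  # smaller-x rule independent of floating-point formula details)
  ord <- order(-round(d * 1e6), ys, xs)
  best <- ord[1]
  fc <- unname(c(xs[best], ys[best]))
  if (refine) {
    un <- .unit(L5 - C7); nrm <- .perp(un)
    if (sum(nrm * posterior_dir) < 0) nrm <- -nrm
    inside <- fc - nrm
    if (.in_mask(mask, inside)) {
      ref <- tryCatch(.march_to_boundary(mask, inside, nrm, step = 0.25),
                      error = function(e) NULL)
      if (!is.null(ref) && sum(abs(ref - fc)) < 2) fc <- ref
    }
  }
  structure(fc, distance = unname(.signed_line_distance(fc[1], fc[2], C7, L5,
                                                        posterior_dir)))
}

#' @noRd
.fc_ray <- function(mask, C7, L5, posterior_dir, step = 0.5) {
  u <- .unit(L5 - C7)
  perp <- .perp(u)
  if (sum(perp * posterior_dir) < 0) perp <- -perp
  len <- .vec_norm(L5 - C7)
  best <- NULL; best_d <- -Inf
  for (t in seq(0, len, by = step)) {
    p0 <- C7 + t * u
    if (!.in_mask(mask, p0)) next
    hit <- tryCatch(.march_to_boundary(mask, p0, perp), error = function(e) NULL)
    if (is.null(hit)) next
    d <- .signed_line_distance(hit[1], hit[2], C7, L5, posterior_dir)
    if (d > best_d + 1e-9) { best_d <- d; best <- hit }
  }
  if (is.null(best) || best_d <= 0)
    .stop_typed("degenerate_silhouette_error", "no posterior silhouette point found from the C7-L5 segment")
  structure(best, distance = best_d)
}

#' Boundary pixels of a binary mask
#'
#' A mask pixel is a boundary pixel if any of its 4-neighbors is outside
#' the mask or outside the image.
#'
#' @param mask Logical matrix.
#' @return Two-column matrix of pixel-centre coordinates `(x, y)`.
#' @export
mask_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
        pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  b <- core & !nb
  w <- which(b, arr.ind = TRUE)
  cbind(x = w[, 2] - 1, y = w[, 1] - 1)
}

#' MA on a sagittal view
#'
#' The visible lateral malleolus, proxied by the ankle keypoint of the
#' detected side.
#'
#' @inheritParams point_A
#' @return Position `c(x, y)`.
#' @export
ma_sagittal <- function(kps, side = "right") {
  s <- toupper(substr(side, 1, 1))
  kp_get(kps, paste0(s, "A"))
}

#' Full sagittal landmark set
#'
#' Composes side detection, the A anchor, the C7/L5 boundary searches, the
#' FC maximum-distance search and the MA proxy into the augmented landmark
#' set `{C7, FC, L5, MA}` (intermediates A and L5' retained for audit).
#'
#' @inheritParams c7_sagittal
#' @inheritParams l5_sagittal
#' @param K2 Percentage for [point_A()].
#' @param fc_method Passed to [fc_search()].
#' @return Object of class `sagittal_landmarks`.
#' @export
augment_sagittal <- function(kps, mask, K1 = 20, K2 = 40,
                             fc_method = "boundary-max") {
  if (kps$view != "sagittal") stop_format("augment_sagittal requires a sagittal-view keypoint set")
  if (inherits(mask, "silhouette_mask")) mask <- mask$mask
  sp <- detect_side_and_posterior(kps)
  A <- point_A(kps, K2, sp$side)
  C7 <- c7_sagittal(mask, kps, A, sp$posterior_dir, sp$side)
  l5 <- l5_sagittal(mask, kps, K1, sp$posterior_dir)
  FC <- fc_search(mask, C7, l5$L5, sp$posterior_dir, method = fc_method,
                  strict = FALSE)
  structure(list(view = "sagittal",
                 landmarks = list(C7 = C7, L5 = l5$L5,
                                  FC = c(FC[1], FC[2]),
                                  MA = ma_sagittal(kps, sp$side),
                                  A = A, L5_prime = l5$L5_prime),
                 fc_distance = attr(FC, "distance"),
                 side = sp$side, posterior_dir = sp$posterior_dir),
            class = c("sagittal_landmarks", "augmented_landmarks"))
}
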