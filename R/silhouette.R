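# Seeded silhouette extraction: a keypoint-driven trimap (certain foreground
# along limb bands, certain background outside the subject box, probable
# background elsewhere) feeds an iterative color-model graph-cut in the
# GrabCut style, with the min-cut solved by push-relabel max-flow.

#' Trimap label constants
#'
#' Integer raster labels for the three-class segmentation seed: certain
#' background (outside the subject box), probable background, and certain
#' foreground (inside the limb bands).
#' @export
TRIMAP_CERTAIN_BG <- 0L
#' @rdname TRIMAP_CERTAIN_BG
#' @export
TRIMAP_PROBABLE_BG <- 1L
#' @rdname TRIMAP_CERTAIN_BG
#' @export
TRIMAP_CERTAIN_FG <- 2L

# Adjacent-joint band pairs per body side, proximal to distal.
#' @noRd
.band_pairs_side <- function(side) {
  s <- if (side == "right") "R" else "L"
  list(c(paste0(s, "Ear"), paste0(s, "SH")),
       c(paste0(s, "SH"), paste0(s, "H")),
       c(paste0(s, "H"), paste0(s, "K")),
       c(paste0(s, "K"), paste0(s, "A")))
}

#' @noRd
.side_complete <- function(kps, side) {
  all(vapply(.band_pairs_side(side),
             function(p) all(kp_present(kps, p)), logical(1)))
}

#' Axis-aligned box around the subject
#'
#' The box height spans the vertical extent from ear to ankle, the width
#' the horizontal spread of the present keypoints; a single isotropic
#' pixel margin of `margin_frac` times that vertical extent is then added
#' on all four sides. The margin is proportional to the subject's height —
#' not to the keypoint spread — because on sagittal views the keypoints
#' are nearly collinear on the spine axis while the body still extends a
#' trunk radius to either side; head and feet are covered the same way.
#' Pixels outside the box are certain background.
#'
#' @param kps A [pose_keypoints()] object; an ear and an ankle keypoint
#'   (either side) must be present.
#' @param margin_frac Margin on all four sides, as a fraction of the
#'   ear-to-ankle vertical extent (default 0.15).
#' @return List with fields `x0`, `y0`, `x1`, `y1` (pixel coordinates,
#'   clipped to the image).
#' @export
subject_box <- function(kps, margin_frac = 0.15) {
  ear <- c("REar", "LEar")[kp_present(kps, c("REar", "LEar"))]
  ank <- c("RA", "LA")[kp_present(kps, c("RA", "LA"))]
  if (length(ear) == 0 || length(ank) == 0)
    stop_missing_keypoint(c("REar/LEar", "RA/LA")[c(length(ear) == 0, length(ank) == 0)])
  ey <- mean(kps$coords[ear, "y"])
  ay <- mean(kps$coords[ank, "y"])
  h <- abs(ey - ay)
  if (h == 0) stop_geometry("degenerate subject extent: ear and ankle at the same height")
  pres <- kps$coords[, "confidence"] > 0
  xs <- kps$coords[pres, "x"]
  m <- margin_frac * h
  box <- list(x0 = min(xs) - m, x1 = max(xs) + m,
              y0 = min(ey, ay) - m, y1 = max(ey, ay) + m)
  box$x0 <- max(box$x0, 0); box$y0 <- max(box$y0, 0)
  box$x1 <- min(box$x1, kps$image_width - 1)
  box$y1 <- min(box$y1, kps$image_height - 1)
  box
}

#' Band thickness for a joint-to-joint segment
#'
#' The certain-foreground band around the segment joining two adjacent
#' joints is expanded isotropically by a thickness proportional to the
#' segment length — a geometric stand-in for the body-segment radius — and
#' clamped to `[2 px, half the segment length]`.
#'
#' @inheritParams subject_box
#' @param pair Character vector of two keypoint names.
#' @param scale Thickness as a fraction of segment length (default 0.10,
#'   conservative so bands never overrun slim body segments).
#' @return Thickness in pixels.
#' @export
band_thickness <- function(kps, pair, scale = 0.10) {
  a <- kp_get(kps, pair[1]); b <- kp_get(kps, pair[2])
  len <- .vec_norm(b - a)
  if (len == 0) stop_geometry(sprintf("degenerate band segment %s-%s (length 0)", pair[1], pair[2]))
  min(max(scale * len, 2), 0.5 * len)
}

#' Build the three-class trimap
#'
#' Labels every pixel: outside the subject box is certain background; inside
#' any limb band (ear–shoulder, shoulder–hip, hip–knee, knee–ankle,
#' isotropically expanded segments between adjacent joints) is certain
#' foreground; all remaining pixels are probable background. On sagittal
#' views the bands of the visible side are used; on frontal views both
#' sides.
#'
#' @inheritParams subject_box
#' @param box Subject box from [subject_box()].
#' @param band_thickness_scale Passed to [band_thickness()].
#' @param pairs Optional list of keypoint-name pairs overriding the default
#'   adjacent-joint bands.
#' @return Integer matrix `[image_height, image_width]` of trimap labels.
#' @export
build_trimap <- function(kps, box, band_thickness_scale = 0.10, pairs = NULL) {
  H <- kps$image_height; W <- kps$image_width
  if (is.null(pairs)) {
    sides <- c("right", "left")[c(.side_complete(kps, "right"), .side_complete(kps, "left"))]
    if (kps$view == "sagittal" && length(sides) > 1)
      sides <- detect_side_and_posterior(kps)$side
    if (length(sides) == 0)
      stop_missing_keypoint("ear/shoulder/hip/knee/ankle chain",
                            "no complete ear-shoulder-hip-knee-ankle keypoint chain on either side")
    pairs <- unlist(lapply(sides, .band_pairs_side), recursive = FALSE)
  }
  tri <- matrix(TRIMAP_CERTAIN_BG, nrow = H, ncol = W)
  # integer pixel ranges covered by the box (pixel centres)
  c0 <- floor(box$x0) + 1L; c1 <- ceiling(box$x1) + 1L
  r0 <- floor(box$y0) + 1L; r1 <- ceiling(box$y1) + 1L
  c0 <- max(c0, 1L); r0 <- max(r0, 1L); c1 <- min(c1, W); r1 <- min(r1, H)
  tri[r0:r1, c0:c1] <- TRIMAP_PROBABLE_BG
  xs <- rep((c0:c1) - 1, each = r1 - r0 + 1)
  ys <- rep((r0:r1) - 1, times = c1 - c0 + 1)
  fg <- rep(FALSE, length(xs))
  for (p in pairs) {
    a <- kp_get(kps, p[1]); b <- kp_get(kps, p[2])
    tau <- band_thickness(kps, p, band_thickness_scale)
    fg <- fg | (.dist_to_segment(xs, ys, a, b) <= tau)
  }
  sub <- tri[r0:r1, c0:c1]
  sub[fg] <- TRIMAP_CERTAIN_FG
  tri[r0:r1, c0:c1] <- sub
  tri
}

# --- color models -----------------------------------------------------------

# Gaussian mixture fit by k-means hard assignment (full covariance per
# cluster, variance floor to survive flat-color regions).
#' @noRd
.fit_color_model <- function(X, k = 3L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- max(1L, min(k, n))
  cl <- if (k == 1L) rep(1L, n) else {
    # kmeans fails when fewer than k distinct colors exist; flat regions
    # then collapse to a single component
    km <- tryCatch(suppressWarnings(stats::kmeans(X, centers = k, iter.max = 30, nstart = 1)),
                   error = function(e) NULL)
    if (is.null(km)) { k <- 1L; rep(1L, n) } else km$cluster
  }
  comps <- lapply(seq_len(k), function(j) {
    Xi <- X[cl == j, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- if (nrow(Xi) > 3) stats::cov(Xi) else diag(3) * 0
    S <- S + diag(3) * 25  # variance floor, channel units^2
    R <- chol(S)
    list(mu = mu, Rinv = backsolve(R, diag(3)),
         logdet = 2 * sum(log(diag(R))), logw = log(nrow(Xi) / n))
  })
  comps
}

# Negative log-likelihood under the best-fitting mixture component
# (hard-assignment convention), clamped for numerical safety.
#' @noRd
.neg_loglik <- function(model, X) {
  X <- as.matrix(X)
  best <- rep(-Inf, nrow(X))
  for (cmp in model) {
    Z <- sweep(X, 2, cmp$mu) %*% cmp$Rinv
    ll <- cmp$logw - 0.5 * (rowSums(Z^2) + cmp$logdet + 3 * log(2 * pi))
    best <- pmax(best, ll)
  }
  pmin(pmax(-best, 0), 100)
}

# --- graph cut --------------------------------------------------------------

#' Extract the subject silhouette by iterative graph-cut segmentation
#'
#' Starting from the trimap seeds, foreground and background color mixtures
#' are estimated, every non-certain pixel gets data terms from the two
#' models, contrast-sensitive smoothness links join 4-neighbors, and the
#' labeling is solved as a minimum s-t cut; models and cut are re-estimated
#' until the labeling stabilizes or `n_iters` is reached. Certain-foreground
#' and certain-background seeds are hard constraints. The mask is
#' post-processed: the connected component with the largest seed overlap is
#' kept (plus any seed pixels the cut isolated) and interior holes are
#' filled.
#'
#' @param image Numeric array `[H, W, 3]`, channel units 0–255.
#' @param trimap Integer label matrix from [build_trimap()].
#' @param n_iters Maximum model/cut iterations (default 5).
#' @param gamma Smoothness weight (default 50).
#' @param n_components Mixture components per color model (default 3).
#' @return Object of class `silhouette_mask`: list with `mask` (logical
#'   matrix) and `connected` flag.
#' @export
segment_silhouette <- function(image, trimap, n_iters = 5L, gamma = 50,
                               n_components = 3L) {
  H <- nrow(trimap); W <- ncol(trimap)
  stopifnot(dim(image)[1] == H, dim(image)[2] == W)
  if (!any(trimap == TRIMAP_CERTAIN_FG))
    stop_segmentation("trimap has no certain-foreground pixels")
  if (!any(trimap == TRIMAP_CERTAIN_BG))
    stop_segmentation("trimap has no certain-background pixels")

  region <- which(trimap != TRIMAP_CERTAIN_BG)       # pixels in play
  cols_all <- cbind(as.vector(image[, , 1])[region],
                    as.vector(image[, , 2])[region],
                    as.vector(image[, , 3])[region])
  seed_fg <- trimap[region] == TRIMAP_CERTAIN_FG

  # graph nodes: the undecided (probable) pixels; certain-foreground seeds
  # are contracted into the source terminal, certain background is absent
  # (its hard label needs no node)
  free <- region[!seed_fg]
  n <- length(free)
  node_of <- integer(H * W)
  node_of[free] <- seq_len(n)
  src <- n + 1L
  node_of[region[seed_fg]] <- src
  cols <- cols_all[!seed_fg, , drop = FALSE]

  # 4-neighbor n-links; links touching a seed attach to the source
  idx <- matrix(seq_len(H * W), H, W)
  pair_ok <- function(a, b) {
    keep <- node_of[a] > 0 & node_of[b] > 0
    cbind(node_of[a[keep]], node_of[b[keep]], a[keep], b[keep])
  }
  e_v <- pair_ok(as.vector(idx[-H, ]), as.vector(idx[-1, ]))
  e_h <- pair_ok(as.vector(idx[, -W]), as.vector(idx[, -1]))
  nl <- rbind(e_v, e_h)
  nl <- nl[!(nl[, 1] == src & nl[, 2] == src), , drop = FALSE]
  px <- function(lin, ch) as.vector(image[, , ch])[lin]
  d2 <- (px(nl[, 3], 1) - px(nl[, 4], 1))^2 +
        (px(nl[, 3], 2) - px(nl[, 4], 2))^2 +
        (px(nl[, 3], 3) - px(nl[, 4], 3))^2
  beta <- if (mean(d2) > 0) 1 / (2 * mean(d2)) else 1
  w_n <- gamma * exp(-beta * d2)

  # background sample includes certain background outside the region
  bg_out <- which(trimap == TRIMAP_CERTAIN_BG)
  if (length(bg_out) > 20000) bg_out <- bg_out[round(seq(1, length(bg_out), length.out = 20000))]
  cols_bg_out <- cbind(as.vector(image[, , 1])[bg_out],
                       as.vector(image[, , 2])[bg_out],
                       as.vector(image[, , 3])[bg_out])

  snk <- n + 2L
  e_from <- c(nl[, 1], nl[, 2], rep(src, n), seq_len(n))
  e_to <- c(nl[, 2], nl[, 1], seq_len(n), rep(snk, n))
  t_src <- 2L * nrow(nl) + seq_len(n)      # capacity slots of the terminal links
  t_snk <- t_src + n
  caps <- c(w_n, w_n, numeric(2L * n))
  lab_fg <- rep(FALSE, n)                  # free pixels start as background
  for (it in seq_len(n_iters)) {
    fg_model <- .fit_color_model(rbind(cols[lab_fg, , drop = FALSE],
                                       cols_all[seed_fg, , drop = FALSE]),
                                 n_components)
    bg_model <- .fit_color_model(rbind(cols[!lab_fg, , drop = FALSE], cols_bg_out),
                                 n_components)
    caps[t_src] <- .neg_loglik(bg_model, cols)  # cost of labeling the pixel background
    caps[t_snk] <- .neg_loglik(fg_model, cols)  # cost of labeling the pixel foreground
    side <- .min_cut_source_side(e_from, e_to, caps, n + 2L, src, snk)
    new_fg <- side[seq_len(n)]
    if (identical(new_fg, lab_fg)) { lab_fg <- new_fg; break }
    lab_fg <- new_fg
  }
  free_fg <- lab_fg
  lab_fg <- rep(TRUE, length(region))      # seeds are foreground by construction
  lab_fg[!seed_fg] <- free_fg

  if (!any(lab_fg)) stop_segmentation("graph cut produced an empty foreground")
  mask <- matrix(FALSE, H, W)
  mask[region[lab_fg]] <- TRUE

  # keep the component with the largest certain-foreground overlap
  lab <- EBImage::bwlabel(mask)
  seeds <- region[seed_fg]
  ov <- table(lab[seeds][lab[seeds] > 0])
  if (length(ov) == 0) stop_segmentation("no mask component overlaps the foreground seeds")
  keep <- as.integer(names(ov)[which.max(ov)])
  mask <- lab == keep
  mask[seeds] <- TRUE                      # hard constraint survives post-processing
  mask <- EBImage::fillHull(mask * 1L) > 0
  connected <- max(EBImage::bwlabel(mask)) == 1
  structure(list(mask = mask, connected = connected), class = "silhouette_mask")
}

#' @export
print.silhouette_mask <- function(x, ...) {
  cat(sprintf("<silhouette_mask> %dx%d px, %d foreground pixels, %s\n",
              ncol(x$mask), nrow(x$mask), sum(x$mask),
              if (x$connected) "connected" else "fragmented"))
  invisible(x)
}

#' Write a trimap as a color PNG
#'
#' Red = certain background, yellow = probable background, green = certain
#' foreground.
#' @param trimap Label matrix.
#' @param path Output path.
#' @export
write_trimap_png <- function(trimap, path) {
  H <- nrow(trimap); W <- ncol(trimap)
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- ifelse(trimap == TRIMAP_CERTAIN_FG, 0, 255)
  img[, , 2] <- ifelse(trimap == TRIMAP_CERTAIN_BG, 0, 255)
  write_png(img, path)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Logical matrices of equal dimension.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
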