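# Shared fixture builders. Mannequins are generated in code (no stored
# rasters); expensive renders are cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached_mannequin <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_mannequin(mannequin_spec(...))
  .fixture_cache[[key]]
}

# Small renders keep the graph-cut tests fast
small_sagittal <- function(angle, seed = 11, ...) {
  cached_mannequin(view = "sagittal", trunk_angle_deg = angle,
                   image_width = 160, image_height = 220, seed = seed, ...)
}

small_frontal <- function(angle, seed = 12, ...) {
  cached_mannequin(view = "frontal", trunk_angle_deg = angle,
                   image_width = 160, image_height = 220, seed = seed, ...)
}

# Minimal keypoint set builder: named list of c(x, y) -> pose_keypoints
kps_from_list <- function(pts, view = "frontal", width = 1000, height = 1000,
                          conf = 0.9) {
  m <- do.call(rbind, pts)
  pose_keypoints(cbind(x = m[, 1], y = m[, 2], confidence = conf),
                 view = view, image_width = width, image_height = height)
}

# Independent brute-force oracle for the fulcrum search: double loop over
# every boundary pixel, |ax + by + c| / sqrt(a^2 + b^2) distance to the
# C7-L5 line, posterior side only, projection strictly within the chord,
# ties toward smaller y then smaller x.
fc_oracle <- function(mask, C7, L5, posterior_dir) {
  a <- L5[2] - C7[2]
  b <- C7[1] - L5[1]
  cc <- -(a * C7[1] + b * C7[2])
  nrm <- sqrt(a^2 + b^2)
  # orient the (a, b) normal toward the posterior
  if (a * posterior_dir[1] + b * posterior_dir[2] < 0) {
    a <- -a; b <- -b; cc <- -cc
  }
  u <- L5 - C7
  best <- NULL
  best_d <- 0
  for (r in seq_len(nrow(mask))) {
    for (cl in seq_len(ncol(mask))) {
      if (!mask[r, cl]) next
      on_bd <- r == 1 || r == nrow(mask) || cl == 1 || cl == ncol(mask) ||
        !(mask[r - 1, cl] && mask[r + 1, cl] && mask[r, cl - 1] && mask[r, cl + 1])
      if (!on_bd) next
      x <- cl - 1; y <- r - 1
      tp <- ((x - C7[1]) * u[1] + (y - C7[2]) * u[2]) / sum(u^2)
      if (tp <= 0 || tp >= 1) next
      d <- (a * x + b * y + cc) / nrm
      if (d <= 0) next
      dq <- round(d * 1e6)                 # same tie quantum as fc_search
      bq <- round(best_d * 1e6)
      if (dq > bq ||
          (dq == bq && !is.null(best) &&
           (y < best[2] || (y == best[2] && x < best[1])))) {
        best_d <- d
        best <- c(x, y)
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(unname(best), distance = unname(best_d))
}

# Random blob mask: union of random discs, guaranteed non-empty
random_blob_mask <- function(H = 60, W = 60, n_discs = 5) {
  mask <- matrix(FALSE, H, W)
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  inside <- rep(FALSE, H * W)
  for (i in seq_len(n_discs)) {
    cx <- runif(1, 10, W - 11); cy <- runif(1, 10, H - 11)
    r <- runif(1, 5, 14)
    inside <- inside | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  }
  matrix(inside, H, W)
}
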