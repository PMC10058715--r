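# Internal 2D geometry helpers. All coordinates are image pixels: origin at
# the top-left pixel centre, x to the right, y DOWNWARD, continuous
# (sub-pixel positions allowed).

#' @noRd
.vec_norm <- function(v) sqrt(sum(v^2))

#' @noRd
.unit <- function(v) {
  n <- .vec_norm(v)
  if (n == 0) stop_geometry("cannot normalize a zero-length vector")
  v / n
}

# Rotate a vector by 90 degrees (counter-clockwise in y-down raster coords).
#' @noRd
.perp <- function(v) c(-v[2], v[1])

# Intersection of the (infinite) lines through p1-p2 and p3-p4.
# Returns c(x, y, t, s) where t, s are the segment parameters, or NULL if
# the lines are (numerically) parallel.
#' @noRd
.line_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1
  d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  scale <- max(abs(c(d1, d2)), 1)
  if (abs(den) < 1e-12 * scale^2) return(NULL)
  w <- p3 - p1
  t <- (w[1] * d2[2] - w[2] * d2[1]) / den
  s <- (w[1] * d1[2] - w[2] * d1[1]) / den
  c(p1 + t * d1, t, s)
}

# Euclidean distance from points (x, y vectors) to segment a-b, vectorized.
#' @noRd
.dist_to_segment <- function(x, y, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt((x - a[1])^2 + (y - a[2])^2))
  t <- ((x - a[1]) * d[1] + (y - a[2]) * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (a[1] + t * d[1]))^2 + (y - (a[2] + t * d[2]))^2)
}

# Signed perpendicular distance of points to the infinite line through a-b,
# positive on the side pointed to by `positive_dir` (a unit vector).
#' @noRd
.signed_line_distance <- function(x, y, a, b, positive_dir) {
  u <- .unit(b - a)
  n <- .perp(u)
  if (sum(n * positive_dir) < 0) n <- -n
  (x - a[1]) * n[1] + (y - a[2]) * n[2]
}

# --- typed conditions -------------------------------------------------------

#' @noRd
.stop_typed <- function(class, msg, ...) {
  stop(structure(class = c(class, "axialposture_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

stop_geometry        <- function(msg, ...) .stop_typed("geometry_error", msg, ...)
stop_missing_keypoint <- function(kp, msg = NULL) {
  .stop_typed("missing_keypoint_error",
              msg %||% sprintf("required keypoint(s) missing: %s",
                               paste(kp, collapse = ", ")),
              keypoint = kp)
}
stop_format        <- function(msg, ...) .stop_typed("format_error", msg, ...)
stop_segmentation  <- function(msg, ...) .stop_typed("segmentation_failure_error", msg, ...)
stop_landmark      <- function(msg, ...) .stop_typed("landmark_failure_error", msg, ...)
stop_boundary      <- function(msg, ...) .stop_typed("boundary_error", msg, ...)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
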