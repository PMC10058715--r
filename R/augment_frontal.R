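# Frontal (posterior) view landmark augmentation: C7, L5 and MA are
# constructed geometrically from the canonical keypoints alone — no
# silhouette is needed because Pisa syndrome is measured in the coronal
# plane where the keypoints already constrain the trunk line.

#' C7 on a frontal view
#'
#' The seventh cervical vertebra is the most prominent point at the base of
#' the neck. On a frontal view it is located at the intersection of the two
#' contralateral shoulder–ear segments (left shoulder to right ear, right
#' shoulder to left ear), which physically cross at the neck base.
#'
#' @param kps A [pose_keypoints()] object with LSH, RSH, LEar, REar present.
#' @return Landmark position `c(x, y)`.
#' @export
c7_frontal <- function(kps) {
  need <- c("LSH", "RSH", "LEar", "REar")
  miss <- need[!kp_present(kps, need)]
  if (length(miss)) stop_missing_keypoint(miss)
  lsh <- kp_get(kps, "LSH"); rsh <- kp_get(kps, "RSH")
  lear <- kp_get(kps, "LEar"); rear <- kp_get(kps, "REar")
  hit <- .line_intersection(lsh, rear, rsh, lear)
  if (is.null(hit))
    stop_geometry("shoulder-ear diagonals are parallel; cannot locate C7")
  t <- hit[3]; s <- hit[4]
  if (t < 0 || t > 1 || s < 0 || s > 1)
    stop_geometry(sprintf(
      "shoulder-ear diagonals do not cross between the joints (t=%.2f, s=%.2f); check keypoint quality",
      t, s))
  hit[1:2]
}

#' L5 on a frontal view
#'
#' The fifth lumbar vertebra lies just under the line joining the iliac
#' crests. It is placed by starting from the mid-hip point MH (midpoint of
#' the left and right hip keypoints) and moving vertically toward the head
#' by a parametric percentage `K1` (default 20) of the average left and
#' right hip-to-knee distance.
#'
#' @inheritParams c7_frontal
#' @param K1 Percentage of the average leg (hip–knee) length, in (0, 100).
#' @return List with `L5` and the intermediate `MH`, each `c(x, y)`.
#' @export
l5_frontal <- function(kps, K1 = 20) {
  stopifnot(K1 >= 0, K1 < 100)   # K1 = 0 is the degenerate L5 = MH limit
  need <- c("LH", "RH", "LK", "RK")
  miss <- need[!kp_present(kps, need)]
  if (length(miss)) stop_missing_keypoint(miss)
  lh <- kp_get(kps, "LH"); rh <- kp_get(kps, "RH")
  lk <- kp_get(kps, "LK"); rk <- kp_get(kps, "RK")
  mh <- (lh + rh) / 2
  leg <- (.vec_norm(lh - lk) + .vec_norm(rh - rk)) / 2
  if (leg == 0) stop_geometry("zero leg length; cannot place L5")
  # image-vertical offset toward the head (decreasing y for an upright subject)
  list(L5 = c(mh[1], mh[2] - K1 / 100 * leg), MH = mh)
}

#' MA on a frontal view
#'
#' Midpoint between the two ankle keypoints.
#'
#' @inheritParams c7_frontal
#' @return Landmark position `c(x, y)`.
#' @export
ma_frontal <- function(kps) {
  need <- c("LA", "RA")
  miss <- need[!kp_present(kps, need)]
  if (length(miss)) stop_missing_keypoint(miss)
  (kp_get(kps, "LA") + kp_get(kps, "RA")) / 2
}

#' Full frontal landmark set
#'
#' Runs the three frontal constructions and returns the augmented landmark
#' set `{C7, L5, MA}` (with the intermediate MH retained for audit).
#'
#' @inheritParams l5_frontal
#' @return Object of class `frontal_landmarks`.
#' @export
augment_frontal <- function(kps, K1 = 20) {
  if (kps$view != "frontal") stop_format("augment_frontal requires a frontal-view keypoint set")
  l5 <- l5_frontal(kps, K1)
  structure(list(view = "frontal",
                 landmarks = list(C7 = c7_frontal(kps),
                                  L5 = l5$L5,
                                  MA = ma_frontal(kps),
                                  MH = l5$MH)),
            class = c("frontal_landmarks", "augmented_landmarks"))
}

#' @export
print.augmented_landmarks <- function(x, ...) {
  cat(sprintf("<%s landmarks>\n", x$view))
  for (nm in names(x$landmarks))
    cat(sprintf("  %-4s (%.1f, %.1f)\n", nm, x$landmarks[[nm]][1], x$landmarks[[nm]][2]))
  invisible(x)
}
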