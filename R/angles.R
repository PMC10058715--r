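# Trunk flexion angles. All three abnormality measures are EXTERNAL angles:
# 180 degrees minus the interior angle at the named apex landmark, so a
# straight upright posture measures 0 and larger values mean larger
# deviation. Cut-offs follow the movement-disorders consensus criteria:
# Pisa syndrome > 10, lumbar camptocormia > 30 (plus hip flexion, not
# assessable from a single photograph), thoracic camptocormia > 45.

#' External angle at an apex
#'
#' Computes `180 - arccos` of the normalized dot product of the apex-to-p
#' and apex-to-q directions: 0 degrees when p, apex, q are collinear with
#' the apex between them (straight posture), growing as the apex deviates.
#' If p and q lie on the same ray from the apex (anatomically impossible
#' for trunk landmarks) 180 is returned with a warning.
#'
#' @param apex,p,q Positions `c(x, y)`.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
external_angle <- function(apex, p, q) {
  v1 <- p - apex; v2 <- q - apex
  n1 <- .vec_norm(v1); n2 <- .vec_norm(v2)
  if (n1 == 0 || n2 == 0) stop_geometry("zero-length limb at the angle apex")
  cosang <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
  ang <- 180 - acos(cosang) * 180 / pi
  if (ang >= 180 - 1e-9)
    warning("p and q lie on the same ray from the apex (external angle 180): anatomically implausible landmarks")
  ang
}

#' Pisa syndrome angle (frontal view)
#'
#' Lateral trunk flexion: the external angle at L5 between the line joining
#' the mid-ankle point MA to L5 and the line from L5 to C7.
#'
#' @param lm A `frontal_landmarks` object from [augment_frontal()].
#' @return Degrees.
#' @export
measure_ps <- function(lm) {
  external_angle(lm$landmarks$L5, lm$landmarks$MA, lm$landmarks$C7)
}

#' Lumbar camptocormia angle (sagittal view)
#'
#' Anterior trunk flexion with lumbar fulcrum: the external angle at L5
#' between the line joining L5 to the visible lateral malleolus (MA) and
#' the line from L5 to C7. The clinical definition additionally requires
#' hip flexion, which a single photograph cannot assess; reports therefore
#' carry `hip_flexion_assessed = FALSE`.
#'
#' @param lm A `sagittal_landmarks` object from [augment_sagittal()].
#' @return Degrees.
#' @export
measure_lcc <- function(lm) {
  external_angle(lm$landmarks$L5, lm$landmarks$MA, lm$landmarks$C7)
}

#' Thoracic camptocormia angle (sagittal view)
#'
#' Anterior trunk flexion with thoracic fulcrum: the external angle at the
#' fulcrum FC between the line joining FC to L5 and the line joining FC to
#' C7.
#'
#' @inheritParams measure_lcc
#' @return Degrees.
#' @export
measure_tcc <- function(lm) {
  with(lm$landmarks, {
    if (all(FC == L5) || all(FC == C7))
      stop_geometry("fulcrum coincides with C7 or L5; thoracic angle undefined")
    external_angle(FC, L5, C7)
  })
}

#' Default classification cut-offs (degrees)
#' @export
default_thresholds <- function() c(PS = 10, lCC = 30, tCC = 45)

#' Classify angles against the consensus cut-offs
#'
#' Strict `>` comparison: an angle exactly at the cut-off does not flag.
#'
#' @param angles Named numeric vector with any of `PS`, `lCC`, `tCC`
#'   (degrees).
#' @param thresholds Named cut-offs (defaults `PS = 10`, `lCC = 30`,
#'   `tCC = 45`).
#' @return Named logical vector over the supplied angles.
#' @export
classify_angles <- function(angles, thresholds = default_thresholds()) {
  out <- vapply(names(angles),
                function(nm) unname(angles[nm] > thresholds[nm]),
                logical(1))
  names(out) <- names(angles)
  out
}

#' Build a per-image angle report
#'
#' Measures the angles applicable to the view (PS on frontal; lCC and tCC
#' on sagittal), classifies them, and snapshots the landmarks for
#' provenance. Angles are reported to 0.1 degree.
#'
#' @param lm An `augmented_landmarks` object.
#' @param thresholds Cut-offs for [classify_angles()].
#' @return Object of class `angle_report`: list with `view`, `angles`
#'   (named, degrees), `flags`, `hip_flexion_assessed` (always `FALSE`),
#'   and `landmarks`.
#' @export
angle_report <- function(lm, thresholds = default_thresholds()) {
  angles <- if (lm$view == "frontal") {
    c(PS = measure_ps(lm))
  } else {
    c(lCC = measure_lcc(lm), tCC = measure_tcc(lm))
  }
  angles <- round(angles, 1)
  structure(list(view = lm$view,
                 angles = angles,
                 flags = classify_angles(angles, thresholds),
                 hip_flexion_assessed = FALSE,
                 landmarks = lm$landmarks),
            class = "angle_report")
}

#' @export
print.angle_report <- function(x, ...) {
  cat(sprintf("<angle_report> %s view\n", x$view))
  for (nm in names(x$angles))
    cat(sprintf("  %-3s %6.1f deg  %s%s\n", nm, x$angles[nm],
                if (x$flags[nm]) "ABOVE cut-off" else "within cut-off",
                if (nm == "lCC") " (hip flexion unassessed)" else ""))
  invisible(x)
}
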