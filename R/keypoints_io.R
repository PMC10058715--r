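#' Canonical 25-keypoint skeleton names
#'
#' Names of the 25 keypoints of the BODY25 skeleton model, in the standard
#' slot order used by off-the-shelf pose estimators (flat
#' `people[].pose_keypoints_2d` triplet streams). The canonical subset used
#' by the posture pipeline: shoulders (`LSH`, `RSH`), elbows/wrists
#' (`LE`,`RE`,`LW`,`RW`), pelvis (`P`), hips (`LH`,`RH`), knees (`LK`,`RK`),
#' ankles (`LA`,`RA`), nose (`N`), eyes and ears.
#'
#' @return Character vector of length 25.
#' @export
body25_names <- function() {
  c("N", "NECK", "RSH", "RE", "RW", "LSH", "LE", "LW",
    "P", "RH", "RK", "RA", "LH", "LK", "LA",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel")
}

#' Construct a pose-keypoint set
#'
#' Builds the canonical keypoint container used throughout the package: 25
#' named slots, each an `(x, y, confidence)` triplet in pixel coordinates
#' (origin top-left, y increases downward, sub-pixel positions allowed).
#' A keypoint with confidence 0 is *missing* and its coordinates are
#' undefined.
#'
#' @param coords Numeric matrix with columns `x`, `y`, `confidence` and one
#'   row per named keypoint (rownames from [body25_names()]); keypoints not
#'   listed are missing.
#' @param view `"frontal"` or `"sagittal"`.
#' @param image_width,image_height Image dimensions in pixels.
#' @param clamp If `TRUE` (default) present keypoints outside the image are
#'   clamped to the image bounds with a warning; if `FALSE` they error.
#' @return An object of class `pose_keypoints`.
#' @export
pose_keypoints <- function(coords, view = c("frontal", "sagittal"),
                           image_width, image_height, clamp = TRUE) {
  view <- match.arg(view)
  nm <- body25_names()
  full <- matrix(0, nrow = 25, ncol = 3, dimnames = list(nm, c("x", "y", "confidence")))
  if (!is.null(coords) && nrow(coords) > 0) {
    bad <- setdiff(rownames(coords), nm)
    if (length(bad)) stop_format(paste("unknown keypoint name(s):", paste(bad, collapse = ", ")))
    full[rownames(coords), ] <- as.matrix(coords[, c("x", "y", "confidence"), drop = FALSE])
  }
  conf <- full[, "confidence"]
  if (any(conf < 0 | conf > 1)) stop_format("keypoint confidence outside [0, 1]")
  present <- conf > 0
  out_x <- present & (full[, "x"] < 0 | full[, "x"] > image_width - 1)
  out_y <- present & (full[, "y"] < 0 | full[, "y"] > image_height - 1)
  if (any(out_x | out_y)) {
    if (!clamp) stop_format("keypoint coordinates outside image bounds")
    warning(sprintf("clamped %d keypoint(s) outside image bounds: %s",
                    sum(out_x | out_y), paste(nm[out_x | out_y], collapse = ", ")))
    full[, "x"] <- ifelse(present, pmin(pmax(full[, "x"], 0), image_width - 1), full[, "x"])
    full[, "y"] <- ifelse(present, pmin(pmax(full[, "y"], 0), image_height - 1), full[, "y"])
  }
  structure(list(coords = full, view = view,
                 image_width = image_width, image_height = image_height),
            class = "pose_keypoints")
}

#' @export
print.pose_keypoints <- function(x, ...) {
  cat(sprintf("<pose_keypoints> %s view, %dx%d px, %d/25 keypoints present\n",
              x$view, x$image_width, x$image_height, sum(x$coords[, "confidence"] > 0)))
  invisible(x)
}

#' Test which keypoints are present
#'
#' @param kps A `pose_keypoints` object.
#' @param names Keypoint names to test.
#' @return Logical vector.
#' @export
kp_present <- function(kps, names) {
  kps$coords[names, "confidence"] > 0
}

#' Get keypoint coordinates
#'
#' Returns the `(x, y)` position of a named keypoint, failing with a typed
#' `missing_keypoint_error` if it is absent — coordinates of a missing
#' keypoint are never silently used.
#'
#' @inheritParams kp_present
#' @param name A single keypoint name.
#' @return Numeric `c(x, y)`.
#' @export
kp_get <- function(kps, name) {
  if (!kp_present(kps, name)) stop_missing_keypoint(name)
  unname(kps$coords[name, c("x", "y")])
}

#' Read pose keypoints from the standard 25-keypoint JSON dialect
#'
#' Parses the JSON produced by off-the-shelf 2D pose estimators:
#' `people[*].pose_keypoints_2d` as a flat stream of 75 floats
#' (25 x,y,confidence triplets). Triplets with confidence 0 are mapped to
#' missing keypoints.
#'
#' @param path Path to the keypoint JSON file.
#' @param person_index 1-based index of the person to extract.
#' @param view `"frontal"` or `"sagittal"`.
#' @param image_width,image_height Image dimensions in pixels. If `NULL`,
#'   taken from `canvas_width`/`canvas_height` fields in the file when
#'   present, else from the image file named by `image_path`.
#' @param image_path Optional path to the image the keypoints refer to, used
#'   to recover the dimensions.
#' @return A [pose_keypoints()] object.
#' @export
read_pose_json <- function(path, person_index = 1L,
                           view = c("frontal", "sagittal"),
                           image_width = NULL, image_height = NULL,
                           image_path = NULL) {
  view <- match.arg(view)
  if (!file.exists(path)) stop_format(paste("keypoint file not found:", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop_format(paste("malformed keypoint JSON:", conditionMessage(e))))
  people <- doc$people
  if (is.null(people) || length(people) == 0)
    .stop_typed("empty_detection_error", "no people detected in keypoint file")
  if (person_index < 1 || person_index > length(people))
    .stop_typed("index_error", sprintf("person_index %d out of range (1..%d)",
                                       person_index, length(people)))
  flat <- unlist(people[[person_index]]$pose_keypoints_2d)
  if (length(flat) != 75)
    stop_format(sprintf("pose_keypoints_2d has %d values, expected 75", length(flat)))
  m <- matrix(flat, ncol = 3, byrow = TRUE,
              dimnames = list(body25_names(), c("x", "y", "confidence")))
  if (is.null(image_width)) image_width <- doc$canvas_width
  if (is.null(image_height)) image_height <- doc$canvas_height
  if ((is.null(image_width) || is.null(image_height)) && !is.null(image_path)) {
    img <- read_rgb(image_path)
    image_height <- dim(img)[1]; image_width <- dim(img)[2]
  }
  if (is.null(image_width) || is.null(image_height))
    stop_format("image dimensions unavailable: supply image_width/image_height or image_path")
  pose_keypoints(m, view = view, image_width = image_width, image_height = image_height)
}

#' Select the subject among multiple detected people
#'
#' Acquisition protocols place a single subject in front of a neutral wall,
#' but pose estimators may still report bystanders. The subject is taken as
#' the person whose present keypoints span the largest bounding-box area;
#' ties break to the lowest index (deterministic).
#'
#' @param people List of `pose_keypoints` objects.
#' @return The selected `pose_keypoints` object.
#' @export
select_subject <- function(people) {
  if (length(people) == 0)
    .stop_typed("empty_detection_error", "no people to select from")
  areas <- vapply(people, function(p) {
    pres <- p$coords[, "confidence"] > 0
    if (sum(pres) < 2) return(0)
    xs <- p$coords[pres, "x"]; ys <- p$coords[pres, "y"]
    (max(xs) - min(xs)) * (max(ys) - min(ys))
  }, numeric(1))
  people[[which.max(areas)]]
}

#' Write augmented landmarks to JSON
#'
#' Serializes an augmented landmark set (`C7`, `L5`, `MA` and on sagittal
#' views `FC`, plus retained intermediates) to a documented JSON schema:
#' named landmarks with pixel coordinates and the view tag. Landmarks that
#' were not computed for the view are absent from the file, never
#' null-filled. Round-trips losslessly through [read_landmarks()].
#'
#' @param augmented A `frontal_landmarks` or `sagittal_landmarks` object.
#' @param path Output path.
#' @export
write_landmarks <- function(augmented, path) {
  pts <- augmented$landmarks
  if (any(!vapply(pts, function(p) all(is.finite(p)), logical(1))))
    stop_format("landmarks contain non-finite coordinates")
  payload <- list(view = augmented$view,
                  landmarks = lapply(pts, function(p) list(x = p[1], y = p[2])))
  if (!is.null(augmented$posterior_dir))
    payload$posterior_dir <- as.numeric(augmented$posterior_dir)
  if (!is.null(augmented$side)) payload$side <- augmented$side
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    .stop_typed("io_error", paste("cannot write landmark file:", path))
  invisible(path)
}

#' Read augmented landmarks from JSON
#'
#' @param path Path written by [write_landmarks()].
#' @return A list with `view`, `landmarks` (named list of `c(x, y)`), and,
#'   when present, `posterior_dir` and `side`.
#' @export
read_landmarks <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lm <- lapply(doc$landmarks, function(p) c(p$x, p$y))
  out <- list(view = doc$view, landmarks = lm)
  if (!is.null(doc$posterior_dir)) out$posterior_dir <- unlist(doc$posterior_dir)
  if (!is.null(doc$side)) out$side <- doc$side
  out
}

#' Read an RGB image as a height x width x 3 array
#'
#' PNG (and JPEG, when the jpeg package is installed) decoding to a numeric
#' array in channel units 0–255, rows indexed from the top of the image.
#' Grayscale images are expanded to three identical channels; alpha is
#' dropped.
#'
#' @param path Image path.
#' @return Numeric array `[height, width, 3]`, values in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop_format(paste("image not found:", path))
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop_format("jpeg package required to read JPEG images")
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Write an RGB or grayscale array as PNG
#'
#' @param img Array `[H, W, 3]` (0–255) or matrix (0–255 or logical).
#' @param path Output path.
#' @export
write_png <- function(img, path) {
  if (is.logical(img)) img <- img * 255
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
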