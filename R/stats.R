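# Robustness analysis: Pearson correlation (with t-based significance) of
# the measured angles — and of measurement errors against a ground truth —
# versus subject anthropometry (BMI) and picture characteristics (image
# size, subject cover factors, HSV color summaries). A method that is
# robust to acquisition conditions shows no significant correlations here.

#' Subject cover factors
#'
#' Ratio between the subject's tight bounding box and the whole image, per
#' dimension: `cover_w = bbox_width / image_width`, likewise for height and
#' area. Computed from the bounding box (not the pixel count) so the width
#' and height ratios are well-defined.
#'
#' @param mask Logical silhouette matrix (or `silhouette_mask`).
#' @return Named vector `cover_w`, `cover_h`, `cover_area`, each in
#'   `[0, 1]`.
#' @export
cover_factors <- function(mask) {
  if (inherits(mask, "silhouette_mask")) mask <- mask$mask
  if (!any(mask)) stop_segmentation("empty mask: cover factors undefined")
  w <- which(mask, arr.ind = TRUE)
  bw <- diff(range(w[, 2])) + 1
  bh <- diff(range(w[, 1])) + 1
  c(cover_w = bw / ncol(mask), cover_h = bh / nrow(mask),
    cover_area = (bw * bh) / (ncol(mask) * nrow(mask)))
}

#' HSV color summary of an image
#'
#' Converts to hue–saturation–value and summarizes each channel: circular
#' mean for hue (degrees in `[0, 360)`), arithmetic means for saturation
#' and value (unit scale). Saturation and value variances are also emitted.
#'
#' @param image Numeric array `[H, W, 3]`, channel units 0–255.
#' @return Named vector `hue_mean`, `sat_mean`, `val_mean`, `sat_var`,
#'   `val_var`.
#' @export
hsv_summary <- function(image) {
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  h <- hsv[1, ] * 2 * pi
  hue <- atan2(mean(sin(h)), mean(cos(h))) * 180 / pi
  if (hue < 0) hue <- hue + 360
  c(hue_mean = hue,
    sat_mean = mean(hsv[2, ]), val_mean = mean(hsv[3, ]),
    sat_var = stats::var(hsv[2, ]), val_var = stats::var(hsv[3, ]))
}

#' Image characteristics record
#'
#' Collects the covariates of the robustness analysis for one picture:
#' image size (width, height, area), subject cover factors, HSV color
#' summary and, when known, the subject's BMI.
#'
#' @param image Numeric array `[H, W, 3]`.
#' @param mask Silhouette mask for the cover factors.
#' @param bmi Body mass index in kg/m^2 (optional).
#' @return One-row data frame.
#' @export
image_characteristics <- function(image, mask, bmi = NA_real_) {
  if (!is.na(bmi) && bmi <= 0) stop_format("bmi must be positive")
  cf <- cover_factors(mask)
  hs <- hsv_summary(image)
  data.frame(width = dim(image)[2], height = dim(image)[1],
             area = dim(image)[2] * dim(image)[1],
             cover_w = cf["cover_w"], cover_h = cf["cover_h"],
             cover_area = cf["cover_area"],
             hue_mean = hs["hue_mean"], sat_mean = hs["sat_mean"],
             val_mean = hs["val_mean"], bmi = bmi, row.names = NULL)
}

#' Pearson correlation with significance
#'
#' Sample Pearson correlation coefficient and its two-sided p-value from
#' the t-distribution with `n - 2` degrees of freedom,
#' `t = R * sqrt((n - 2) / (1 - R^2))`.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`, neither
#'   constant.
#' @return List with `R`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_format("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_format("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_format("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stop_typed("undefined_correlation_error", "correlation undefined for a constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(R = r, p = p, n = n)
}

#' Default robustness covariates
#' @export
robustness_covariates <- function() {
  c("bmi", "width", "height", "area", "cover_w", "cover_h", "cover_area",
    "hue_mean", "sat_mean", "val_mean")
}

#' Robustness correlation table
#'
#' Correlates each measured abnormality angle (or, with `use_error`, the
#' measurement error `measured - ground truth`) against every covariate.
#' Records missing a covariate are excluded pairwise, with the exclusion
#' count reported in the `n_excluded` column. Raw per-correlation p-values
#' are reported (the protocol applies no multiple-testing correction); set
#' `bonferroni = TRUE` to adjust.
#'
#' @param records Data frame with one row per analyzed image: angle columns
#'   (`PS`, `lCC`, `tCC`, `NA` where not applicable), covariate columns
#'   (see [robustness_covariates()]) and, for `use_error`, truth columns
#'   `truth_PS`, `truth_lCC`, `truth_tCC`.
#' @param use_error Correlate measurement errors instead of measures.
#' @param covariates Covariate column names.
#' @param bonferroni Adjust p-values for the number of covariates.
#' @param plot_dir If non-`NULL`, write one scatter PNG per
#'   covariate x abnormality pair into this directory.
#' @return Data frame with columns `covariate`, `abnormality`, `R`, `p`,
#'   `n`, `n_excluded`, `significant` (`p < 0.05`).
#' @export
robustness_table <- function(records, use_error = FALSE,
                             covariates = robustness_covariates(),
                             bonferroni = FALSE, plot_dir = NULL) {
  covariates <- intersect(covariates, names(records))
  abns <- intersect(c("PS", "lCC", "tCC"), names(records))
  abns <- abns[vapply(abns, function(a) sum(!is.na(records[[a]])) > 0, logical(1))]
  if (length(abns) == 0) stop_format("no abnormality angle columns present in records")
  out <- list()
  for (ab in abns) {
    resp <- records[[ab]]
    if (use_error) {
      tc <- paste0("truth_", ab)
      if (!tc %in% names(records))
        stop_format(paste("use_error requires ground-truth column", tc))
      resp <- resp - records[[tc]]
    }
    if (sum(!is.na(resp)) < 3)
      stop_format(paste("fewer than 3 records with a measured angle for", ab))
    for (cv in covariates) {
      keep <- !is.na(resp) & !is.na(records[[cv]])
      n_exc <- sum(!is.na(resp)) - sum(keep)
      if (sum(keep) < 3)
        stop_format(sprintf("fewer than 3 complete pairs for %s vs %s", ab, cv))
      pc <- pearson_cor(records[[cv]][keep], resp[keep])
      if (bonferroni) pc$p <- min(1, pc$p * length(covariates))
      out[[length(out) + 1]] <- data.frame(
        covariate = cv, abnormality = ab, R = pc$R, p = pc$p, n = pc$n,
        n_excluded = n_exc, significant = pc$p < 0.05)
      if (!is.null(plot_dir))
        .scatter_png(records[[cv]][keep], resp[keep], cv,
                     paste0(ab, if (use_error) " error" else ""),
                     file.path(plot_dir, sprintf("%s_vs_%s%s.png", ab, cv,
                                                 if (use_error) "_error" else "")),
                     pc)
    }
  }
  do.call(rbind, out)
}

#' @noRd
.scatter_png <- function(x, y, xlab, ylab, path, pc) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    grDevices::png(path, width = 640, height = 480, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(x, y, xlab = xlab, ylab = paste(ylab, "(deg)"), pch = 19,
                   main = sprintf("R = %.2f, p = %.3g, n = %d", pc$R, pc$p, pc$n))
    graphics::abline(stats::lm(y ~ x), col = "red")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warning("could not write scatter plot (no PNG device available): ", path)
  invisible(ok)
}
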