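# Per-sample CD34+ quantification and method agreement against a reference
# (flow-cytometry-style) percentage: coefficient of determination, mean
# absolute difference and Bland-Altman bias with 95% limits of agreement.

#' Classify all cells of one sample and quantify the CD34+ percentage
#'
#' Runs the full chain over the sample's frames — detection, 30x30 cropping,
#' preprocessing, classifier — and reports the percentage of detections
#' called CD34_POS.
#'
#' @param model a trained [ShadowNet-class].
#' @param frames list of [ShadowFrame-class] (or matrices) for one sample.
#' @param sample_id sample identifier used in messages and the result.
#' @param k_sigma detection threshold multiplier.
#' @param classifier optional override taking the list of raw 30x30 crops
#'   and returning predicted labels; used for oracle/baseline studies.
#' @return a one-row data.frame: `sample_id`, `n_cells`, `n_positive`,
#'   `percent_positive`.
#' @export
classifySample <- function(model, frames, sample_id = "sample",
                           k_sigma = 3, classifier = NULL) {
  if (is(frames, "ShadowFrame") || is.matrix(frames)) frames <- list(frames)
  crops <- list()
  for (fr in frames) {
    det <- detectCells(fr, k_sigma = k_sigma)
    crops <- c(crops, det$crops)
  }
  n <- length(crops)
  if (n == 0) stop("no cells detected in sample '", sample_id, "'")
  if (is.null(classifier)) {
    bd <- if (is(frames[[1]], "ShadowFrame")) frames[[1]]@config@bit_depth
          else 8
    x <- stackInputs(crops, bit_depth = bd)
    labels <- predictModel(model, x)$label
  } else {
    labels <- classifier(crops)
  }
  npos <- sum(labels == "CD34_POS")
  data.frame(sample_id = sample_id, n_cells = n, n_positive = npos,
             percent_positive = 100 * npos / n, stringsAsFactors = FALSE)
}

#' Agreement analysis against a reference method
#'
#' For paired per-sample percentages, computes the coefficient of
#' determination of an ordinary least-squares fit of measured on reference,
#' the mean absolute difference, and the Bland-Altman bias (mean of
#' measured - reference) with 95% limits of agreement bias +/- 1.96 x the
#' sample (n-1) standard deviation of the differences.
#'
#' @param reference reference percentages in [0, 100].
#' @param measured measured percentages in [0, 100], same length.
#' @return an [AgreementReport-class].
#' @examples
#' rep <- compareToReference(c(10, 20, 30, 40), c(12, 18, 33, 37))
#' rep
#' @export
compareToReference <- function(reference, measured) {
  n <- length(reference)
  if (length(measured) != n) stop("paired vectors must have equal length")
  if (n < 2) stop("need at least 2 pairs")
  if (any(reference < 0 | reference > 100 | measured < 0 | measured > 100))
    stop("percentages must lie in [0, 100]")
  if (sd(reference) == 0) {
    warning("zero variance in the reference values: R^2 undefined")
    r2 <- NA_real_
  } else {
    fit <- lm(measured ~ reference)
    r2 <- withCallingHandlers(
      summary(fit)$r.squared,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  d <- measured - reference
  bias <- mean(d)
  s <- if (n > 1) sd(d) else 0
  new("AgreementReport", n_pairs = as.integer(n), r_squared = r2,
      mean_abs_diff = mean(abs(d)), bias = bias,
      loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
      differences = d)
}
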