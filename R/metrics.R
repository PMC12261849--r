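#' Prediction-error metrics
#'
#' Standard mean absolute error and root-mean-square error. For yield
#' tables these are conventionally reported in percentage points; the
#' functions themselves are unit-agnostic.
#'
#' @param preds,truths numeric vectors of equal positive length.
#' @return a scalar.
#' @export
yieldMAE <- function(preds, truths) {
  .checkPair(preds, truths)
  mean(abs(preds - truths))
}

#' @rdname yieldMAE
#' @export
yieldRMSE <- function(preds, truths) {
  .checkPair(preds, truths)
  sqrt(mean((preds - truths)^2))
}

.checkPair <- function(p, t) {
  if (!length(p) || length(p) != length(t))
    stop("preds and truths must have equal positive length")
}

#' Pearson correlation with a zero-variance guard
#'
#' @param preds,truths numeric vectors of equal length.
#' @return the sample correlation, or `NA` with a warning when either side
#'   has zero variance.
#' @export
pearsonR <- function(preds, truths) {
  .checkPair(preds, truths)
  if (stats::sd(preds) == 0 || stats::sd(truths) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(preds, truths)
}

#' Top-k retrieval score
#'
#' The size of the overlap between the k highest-predicted and the k
#' highest-true-yield indices (ties broken by smaller index on both
#' sides). An integer in `[0, k]`; k means the model's top-k picks are
#' exactly the true best-k conditions.
#'
#' @param preds,truths numeric vectors of equal length `>= k`.
#' @param k set size.
#' @return integer overlap count.
#' @export
topKScore <- function(preds, truths, k) {
  .checkPair(preds, truths)
  if (k > length(preds)) stop("k exceeds the number of observations")
  topP <- order(-preds, seq_along(preds))[seq_len(k)]
  topT <- order(-truths, seq_along(truths))[seq_len(k)]
  length(intersect(topP, topT))
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`; positive
#' values indicate a right-skewed distribution (mass at low yields, a long
#' high-yield tail).
#'
#' @param values numeric vector, `n >= 3`, positive variance.
#' @return the skewness, or `NA` with a warning on degenerate input.
#' @export
sampleSkewness <- function(values) {
  n <- length(values)
  if (n < 3 || stats::sd(values) == 0) {
    warning("skewness undefined for degenerate input", call. = FALSE)
    return(NA_real_)
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Evaluation report for yield predictions
#'
#' Bundles MAE, RMSE, Pearson r, top-k scores and the skewness of both
#' sides. Yields are converted to the 0-100 percent scale for the error
#' metrics, the convention of published yield-prediction tables.
#'
#' @param preds,truths yields on the fraction scale.
#' @param k top-k sizes to score.
#' @return a list (class `evaluationReport`).
#' @export
evaluatePredictions <- function(preds, truths, k = c(5, 10, 15, 20)) {
  k <- k[k <= length(preds)]
  structure(list(
    n = length(preds),
    mae = yieldMAE(100 * preds, 100 * truths),
    rmse = yieldRMSE(100 * preds, 100 * truths),
    pearson = pearsonR(preds, truths),
    topk = stats::setNames(vapply(k, function(kk)
      topKScore(preds, truths, kk), numeric(1)), paste0("top", k)),
    skewnessTruth = sampleSkewness(truths),
    skewnessPred = sampleSkewness(preds)),
    class = "evaluationReport")
}

#' @export
print.evaluationReport <- function(x, ...) {
  cat(sprintf("Yield evaluation on %d reactions\n", x$n))
  cat(sprintf("  MAE  %.2f %%    RMSE %.2f %%    Pearson r %.3f\n",
              x$mae, x$rmse, x$pearson))
  if (length(x$topk))
    cat("  top-k overlap:",
        paste(sprintf("%s=%d", names(x$topk), x$topk), collapse = "  "), "\n")
  cat(sprintf("  skewness: truth %.3f, predictions %.3f\n",
              x$skewnessTruth, x$skewnessPred))
  invisible(x)
}
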