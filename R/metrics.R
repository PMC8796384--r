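# Evaluation metrics: mean absolute error and Pearson correlation over the
# two reporting ranges of the clamped objective.

#' Evaluate %PPB predictions
#'
#' Computes MAE = mean |y - yhat| and the Pearson correlation R between
#' experimental and predicted %PPB. Two reporting ranges are supported:
#' \code{"50-95"} evaluates all records with predictions clamped to
#' [50, 95]; \code{"80-95"} keeps only records whose EXPERIMENTAL value is at
#' least 80 (predictions are never used for filtering) and applies the
#' ceiling of 95 to predictions.
#'
#' @param y Experimental %PPB values.
#' @param yhat Predicted %PPB values.
#' @param range \code{"50-95"} or \code{"80-95"}.
#' @return list with \code{range}, \code{mae}, \code{r} (NA with
#'   \code{r_defined = FALSE} when fewer than 2 records survive filtering)
#'   and \code{n_evaluated}.
#' @examples
#' evaluatePPB(c(62, 66), c(60, 70))$mae  # 3
#' @export
evaluatePPB <- function(y, yhat, range = c("50-95", "80-95")) {
  range <- match.arg(range)
  stopifnot(length(y) == length(yhat))
  if (range == "80-95") {
    keep <- y >= 80
    y <- y[keep]; yhat <- yhat[keep]
    yhat <- pmin(95, yhat)
  } else {
    yhat <- pmin(95, pmax(50, yhat))
  }
  n <- length(y)
  if (n == 0L) stop("no records left to evaluate in range ", range)
  mae <- mean(abs(y - yhat))
  if (n >= 2L && stats::sd(y) > 0 && stats::sd(yhat) > 0) {
    r <- stats::cor(y, yhat)
    rdef <- TRUE
  } else {
    r <- NA_real_
    rdef <- FALSE
  }
  list(range = range, mae = mae, r = r, r_defined = rdef, n_evaluated = n)
}
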