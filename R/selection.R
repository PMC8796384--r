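# Descriptor selection: two deterministic prefilters followed by
# bootstrap-Lasso (Bolasso-style) stable subset selection.

#' Remove constant descriptor columns
#'
#' Drops every column whose value is constant across all rows; the order of
#' the surviving columns is preserved.
#'
#' @param x Numeric matrix with named columns.
#' @return Matrix of surviving columns.
#' @export
prefilterConstant <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  keep <- apply(x, 2, function(col) any(col != col[1]))
  if (!any(keep)) stop("all descriptor columns are constant")
  x[, keep, drop = FALSE]
}

#' Remove highly correlated descriptor pairs
#'
#' For every descriptor pair with |Pearson r| at or above \code{threshold},
#' the member with the lower absolute correlation to the clamped %PPB target
#' is removed. Columns are visited in order of decreasing |corr(descriptor,
#' target)| and offending pairs resolved greedily, which makes the removal
#' deterministic; among mutually duplicate columns exactly the one most
#' correlated with the target survives.
#'
#' @param x Numeric matrix with named columns.
#' @param target Clamped %PPB vector aligned with the rows of \code{x}.
#' @param threshold Absolute pairwise correlation at which a pair offends.
#' @return Matrix of surviving columns (original column order).
#' @export
prefilterCorrelated <- function(x, target, threshold = 0.95) {
  stopifnot(is.matrix(x), length(target) == nrow(x))
  if (nrow(x) < 2L) stop("correlation prefilter needs at least 2 rows")
  ct <- abs(suppressWarnings(stats::cor(x, target)))[, 1]
  ct[is.na(ct)] <- 0
  cx <- abs(suppressWarnings(stats::cor(x)))
  cx[is.na(cx)] <- 0
  ord <- order(-ct, seq_len(ncol(x)))
  alive <- rep(TRUE, ncol(x))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!alive[i]) next
    for (b in seq_along(ord)) {
      if (b == a) next
      j <- ord[b]
      if (!alive[j] || !alive[i]) next
      if (cx[i, j] >= threshold) {
        # remove the member less correlated with the target
        if (ct[i] >= ct[j]) alive[j] <- FALSE else alive[i] <- FALSE
      }
    }
  }
  x[, alive, drop = FALSE]
}

#' Bootstrap-Lasso (Bolasso-style) descriptor selection
#'
#' For each penalty \code{alpha} and each of \code{nBootstrap} bootstrap
#' resamples (rows drawn with replacement), an L1-penalized linear regression
#' of the target on the descriptor matrix is fitted and the nonzero
#' coefficients recorded. A descriptor is selected when its nonzero frequency
#' reaches \code{threshold} at every alpha inside \code{stableWindow} (the
#' upper region of the penalty grid, where selection is most conservative).
#'
#' @param x Standardized descriptor matrix (at least two columns).
#' @param target Clamped %PPB vector.
#' @param alphaGrid Lasso penalty grid (default 0.5 to 4.9 in steps of 0.2).
#' @param nBootstrap Number of bootstrap resamples.
#' @param threshold Required selection fraction (1 = strict intersection).
#' @param stableWindow Numeric length-2 range of alphas that must all agree.
#' @param seed Integer seed for the bootstrap resampling.
#' @return list with \code{selected} (descriptor names), \code{frequency}
#'   (descriptor x alpha matrix of nonzero frequencies), \code{alphaGrid},
#'   \code{threshold}, \code{stableWindow} and \code{unstable} (descriptors
#'   that were picked in some but not enough fits inside the window).
#' @export
bolassoSelect <- function(x, target,
                          alphaGrid = seq(0.5, 4.9, by = 0.2),
                          nBootstrap = 100L,
                          threshold = 1.0,
                          stableWindow = c(4.3, 4.9),
                          seed = 1L) {
  stopifnot(is.matrix(x), ncol(x) >= 2L, length(target) == nrow(x),
            nBootstrap >= 1L)
  n <- nrow(x)
  lam <- sort(unique(alphaGrid), decreasing = TRUE)
  freq <- matrix(0, ncol(x), length(lam),
                 dimnames = list(colnames(x), as.character(lam)))
  set.seed(as.integer(seed))
  for (b in seq_len(nBootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- glmnet::glmnet(x[idx, , drop = FALSE], target[idx],
                          alpha = 1, lambda = lam, standardize = FALSE)
    beta <- as.matrix(fit$beta)
    # glmnet may stop early on degenerate resamples; align by lambda
    got <- match(signif(fit$lambda, 8), signif(lam, 8))
    nz <- matrix(0, ncol(x), length(lam))
    nz[, got[!is.na(got)]] <- (beta[, !is.na(got), drop = FALSE] != 0) * 1
    freq <- freq + nz
  }
  freq <- freq / nBootstrap
  inWin <- lam >= stableWindow[1] & lam <= stableWindow[2]
  if (!any(inWin)) stop("stableWindow contains no alpha from alphaGrid")
  winFreq <- freq[, inWin, drop = FALSE]
  selected <- rownames(freq)[apply(winFreq >= threshold, 1, all)]
  unstable <- setdiff(rownames(freq)[apply(winFreq, 1, max) > 0], selected)
  if (length(selected) == 0L)
    warning("bolassoSelect: no descriptor was stably selected ",
            "(empty selection)")
  list(selected = selected,
       frequency = freq,
       alphaGrid = lam,
       threshold = threshold,
       stableWindow = stableWindow,
       unstable = unstable)
}
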