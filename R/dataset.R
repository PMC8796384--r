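# Objective-variable clamping and the Kennard-Stone train/test split.

#' Clamp %PPB to the modeling range [50, 95]
#'
#' Experimental plasma protein binding rates below 50% are rounded up to 50
#' and values above 95% are rounded down to 95: peptides below 50% are not
#' drug-like and the assay loses resolution above 95%, so the model regresses
#' this clamped objective.
#'
#' @param y Numeric vector of %PPB values in [0, 100].
#' @return Numeric vector clamped to [50, 95].
#' @examples
#' clampPPB(c(12, 92, 97))  # 50 92 95
#' @export
clampPPB <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y > 100))
    stop("%PPB values must lie in [0, 100]")
  pmin(95, pmax(50, y))
}

#' Kennard-Stone train/test split
#'
#' Deterministic space-covering subset selection: the pair of points at
#' maximum Euclidean distance seeds the selection, then the point whose
#' minimum distance to the selected set is largest is added repeatedly until
#' \code{ceiling(testFraction * N)} points are chosen. The selected points
#' form the TEST set (the split extracts a uniformly covering test subset);
#' distance ties are broken by the smallest row index, so the split is a pure
#' function of the matrix.
#'
#' @param x Numeric matrix of (standardized) feature vectors, one row per
#'   sample; row names are used as ids when present.
#' @param testFraction Fraction of rows selected as test data, in (0, 1).
#' @return list with elements \code{train} and \code{test} (ids or row
#'   indices), partitioning the rows.
#' @examples
#' x <- matrix(c(0, 1, 10), ncol = 1)
#' kennardStoneSplit(x, 2/3)$test  # rows 1 and 3
#' @export
kennardStoneSplit <- function(x, testFraction) {
  stopifnot(is.matrix(x))
  N <- nrow(x)
  if (N < 2L) stop("Kennard-Stone split needs at least 2 rows")
  if (!is.numeric(testFraction) || testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  k <- as.integer(ceiling(testFraction * N))
  if (k < 1L || k >= N)
    stop("requested test size k = ", k, " must satisfy 1 <= k < N = ", N)
  D <- as.matrix(stats::dist(x))
  sel <- integer(k)
  # seed: the two mutually farthest points (ties: first in column-major order,
  # i.e. smallest indices)
  w <- which.max(D)
  i <- (w - 1L) %% N + 1L
  j <- (w - 1L) %/% N + 1L
  sel[1:2] <- sort(c(i, j))
  if (k > 2L) {
    minD <- pmin(D[, sel[1]], D[, sel[2]])
    for (m in 3:k) {
      minD[sel[1:(m - 1L)]] <- -Inf
      nxt <- which.max(minD)
      sel[m] <- nxt
      minD <- pmin(minD, D[, nxt])
    }
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- seq_len(N)
  test <- ids[sort(sel)]
  list(train = ids[-sort(sel)], test = test)
}

#' Read a peptide table
#'
#' @param path CSV file with columns \code{id}, \code{smiles} and optionally
#'   \code{ppb} (experimental %PPB in [0, 100]).
#' @return data.frame.
#' @export
readPeptideTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(df)))
    stop("peptide table must have columns 'id' and 'smiles'")
  if ("ppb" %in% names(df) && any(df$ppb < 0 | df$ppb > 100, na.rm = TRUE))
    stop("column 'ppb' must lie in [0, 100]")
  df
}
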