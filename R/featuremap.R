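# Fixed-length D x L input maps and their rotation/translation replicas.

.MAX_LENGTH <- 15L

#' Build the centered feature map of one peptide
#'
#' Places the ordered substructure descriptor vectors contiguously in the
#' center of a D x L array (zero padding elsewhere): start column =
#' floor((L - n)/2), rotation 0. L defaults to 15, the maximum substructure
#' count supported by the model.
#'
#' @param vectors Numeric D x n matrix: one column per substructure, in ring
#'   order.
#' @param peptideId Peptide identifier recorded in the provenance.
#' @param L Map length (number of columns).
#' @return A \linkS4class{PPBFeatureMap}.
#' @examples
#' m <- buildFeatureMap(matrix(1:14, 2, 7), "p1")
#' mapSpan(m)  # start 4, n 7
#' @export
buildFeatureMap <- function(vectors, peptideId = "peptide", L = 15L) {
  stopifnot(is.matrix(vectors))
  n <- ncol(vectors)
  if (n < 1L) stop("at least one substructure vector required")
  if (n > L) stop("peptide too long for Max_length: n = ", n, " > L = ", L)
  start <- as.integer(floor((L - n) / 2))
  vals <- matrix(0, nrow(vectors), L)
  rownames(vals) <- rownames(vectors)
  vals[, (start + 1L):(start + n)] <- vectors
  new("PPBFeatureMap", values = vals, start = start, n = as.integer(n),
      peptideId = peptideId, rotation = 0L, translation = start)
}

# Span block (D x n) of a map.
.spanBlock <- function(map) {
  s <- map@start; n <- map@n
  map@values[, (s + 1L):(s + n), drop = FALSE]
}

#' Enumerate all rotation/translation replicas of a feature map
#'
#' Returns the full augmentation set: every cyclic rotation r in 0..n-1 of
#' the substructure order at every translation t in 0..L-n of the occupied
#' span, n x (L - n + 1) replicas in total (the identity replica included).
#' Rotations/translations recorded in the provenance are relative to the
#' presented map.
#'
#' @param map A \linkS4class{PPBFeatureMap}.
#' @return list of \linkS4class{PPBFeatureMap} replicas.
#' @examples
#' m <- buildFeatureMap(matrix(1, 1, 5), "p")
#' length(augmentFeatureMap(m))  # 5 * 11 = 55
#' @export
augmentFeatureMap <- function(map) {
  stopifnot(is(map, "PPBFeatureMap"))
  n <- map@n
  L <- ncol(map@values)
  block <- .spanBlock(map)
  out <- vector("list", n * (L - n + 1L))
  k <- 0L
  for (r in 0:(n - 1L)) {
    rotIdx <- ((seq_len(n) - 1L + r) %% n) + 1L
    rotBlock <- block[, rotIdx, drop = FALSE]
    for (t in 0:(L - n)) {
      vals <- matrix(0, nrow(block), L)
      rownames(vals) <- rownames(block)
      vals[, (t + 1L):(t + n)] <- rotBlock
      k <- k + 1L
      out[[k]] <- new("PPBFeatureMap", values = vals, start = as.integer(t),
                      n = n, peptideId = map@peptideId,
                      rotation = as.integer(r), translation = as.integer(t))
    }
  }
  out
}
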