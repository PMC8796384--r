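# Gradient saliency attribution: |d yhat / d x| per input entry, averaged
# over augmentation replicas and mapped back to ring positions.

#' Saliency of one feature map
#'
#' The element-wise absolute gradient of the raw (unclamped) scalar output
#' with respect to the input map, evaluated in inference mode. The gradient
#' is taken before clamping because the clamp has zero gradient in its
#' saturated regions and would erase attribution for peptides predicted at
#' the range boundaries.
#'
#' @param model A trained \linkS4class{PPBModel}.
#' @param map A \linkS4class{PPBFeatureMap}.
#' @return Numeric D x L matrix of non-negative saliency scores.
#' @export
saliencyMatrix <- function(model, map) {
  cfg <- model@config
  if (nrow(map@values) != cfg$D)
    stop("shape mismatch: map has ", nrow(map@values),
         " descriptor rows but the model expects ", cfg$D)
  if (cfg$pooling == "flatten") {
    X3 <- array(map@values, c(cfg$D, cfg$L, 1L))
    fw <- .netForward(model@params, cfg, X3, training = FALSE)
    bw <- .netBackward(model@params, cfg, fw$cache, 1, training = FALSE,
                       needInputGrad = TRUE)
    return(abs(matrix(bw$dX, cfg$D, cfg$L)) * .labelScale(model))
  }
  n <- map@n
  X3 <- array(.spanBlock(map), c(cfg$D, n, 1L))
  fw <- .netForward(model@params, cfg, X3, training = FALSE)
  bw <- .netBackward(model@params, cfg, fw$cache, 1, training = FALSE,
                     needInputGrad = TRUE)
  out <- matrix(0, cfg$D, cfg$L)
  out[, (map@start + 1L):(map@start + n)] <-
    abs(matrix(bw$dX, cfg$D, n)) * .labelScale(model)
  rownames(out) <- rownames(map@values)
  out
}

# Scale from the network's internal z-scored output back to %PPB units.
.labelScale <- function(model) {
  ln <- model@params$labelNorm
  if (is.null(ln)) 1 else ln$sd
}

#' Replica-averaged saliency mapped back to ring positions
#'
#' Computes the saliency of every augmentation replica of a peptide's
#' feature map, maps each replica's span columns back to ring positions via
#' its (rotation, translation) provenance, discards the padding columns and
#' averages per (descriptor, ring position).
#'
#' @param model A trained \linkS4class{PPBModel}.
#' @param map The peptide's rotation-0 \linkS4class{PPBFeatureMap}.
#' @param augment Average over all replicas (default); otherwise use the
#'   presented map only.
#' @return A \linkS4class{SaliencyMap} with D x n scores and the length-n
#'   per-substructure totals (sum over descriptors).
#' @export
aggregateSaliency <- function(model, map, augment = TRUE) {
  cfg <- model@config
  n <- map@n
  reps <- if (augment) augmentFeatureMap(map) else list(map)
  acc <- matrix(0, cfg$D, n)
  if (cfg$pooling == "flatten") {
    for (rp in reps) {
      if (rp@peptideId != map@peptideId)
        stop("provenance mismatch: replica belongs to '", rp@peptideId, "'")
      s <- saliencyMatrix(model, rp)
      span <- s[, (rp@start + 1L):(rp@start + n), drop = FALSE]
      ringPos <- ((seq_len(n) - 1L + rp@rotation) %% n) + 1L
      acc[, ringPos] <- acc[, ringPos] + span
    }
  } else {
    # inference-mode passes are per-sample independent, so all replicas go
    # through one batched forward/backward
    B <- length(reps)
    X3 <- array(0, c(cfg$D, n, B))
    for (b in seq_len(B)) {
      if (reps[[b]]@peptideId != map@peptideId)
        stop("provenance mismatch: replica belongs to '",
             reps[[b]]@peptideId, "'")
      X3[, , b] <- .spanBlock(reps[[b]])
    }
    fw <- .netForward(model@params, cfg, X3, training = FALSE)
    bw <- .netBackward(model@params, cfg, fw$cache, rep(1, B),
                       training = FALSE, needInputGrad = TRUE)
    g <- abs(array(bw$dX, c(cfg$D, n, B))) * .labelScale(model)
    for (b in seq_len(B)) {
      ringPos <- ((seq_len(n) - 1L + reps[[b]]@rotation) %% n) + 1L
      acc[, ringPos] <- acc[, ringPos] + g[, , b]
    }
  }
  scores <- acc / length(reps)
  rownames(scores) <- rownames(map@values)
  new("SaliencyMap", peptideId = map@peptideId, scores = scores,
      perSubstructure = colSums(scores))
}

# Central finite-difference saliency (independent check used in tests).
.saliencyFiniteDiff <- function(model, map, h = 1e-3) {
  cfg <- model@config
  base <- map@values
  out <- matrix(0, nrow(base), ncol(base))
  evalMap <- function(vals) {
    m2 <- map
    m2@values <- vals
    if (cfg$pooling == "flatten") {
      X3 <- array(vals, c(cfg$D, cfg$L, 1L))
    } else {
      X3 <- array(vals[, (map@start + 1L):(map@start + map@n), drop = FALSE],
                  c(cfg$D, map@n, 1L))
    }
    .netForward(model@params, cfg, X3, training = FALSE)$yhat * .labelScale(model)
  }
  cols <- if (cfg$pooling == "flatten") seq_len(ncol(base)) else
    (map@start + 1L):(map@start + map@n)
  for (d in seq_len(nrow(base))) {
    for (j in cols) {
      up <- base; up[d, j] <- up[d, j] + h
      dn <- base; dn[d, j] <- dn[d, j] - h
      out[d, j] <- abs((evalMap(up) - evalMap(dn)) / (2 * h))
    }
  }
  out
}
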