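# End-to-end pipeline: decomposition -> descriptors -> standardization ->
# Kennard-Stone split -> feature maps -> training -> evaluation.

#' Build feature maps for a set of decomposed peptides
#'
#' Looks up each substructure's standardized (and frequency-weighted)
#' descriptor vector and arranges them in ring order into centered D x L
#' feature maps.
#'
#' @param decompositions Named list of \linkS4class{SubstructureSet}.
#' @param descMatrix Standardized substructure descriptor matrix with
#'   canonical capped SMILES as row names.
#' @param L Map length.
#' @return Named list of \linkS4class{PPBFeatureMap}.
#' @export
buildFeatureMaps <- function(decompositions, descMatrix, L = 15L) {
  lapply(decompositions, function(ss) {
    smi <- cappedSmiles(ss)
    missing <- setdiff(smi, rownames(descMatrix))
    if (length(missing))
      stop("no descriptor row for substructure(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
    buildFeatureMap(t(descMatrix[smi, , drop = FALSE]),
                    peptideId = peptideId(ss), L = L)
  })
}

#' Run the full residue-level %PPB pipeline
#'
#' Decomposes every peptide into capped substructures, computes whole-peptide
#' and substructure descriptors, standardizes both with the training-split
#' whole-peptide statistics, weights substructure rows by training appearance
#' frequency, splits train/test by Kennard-Stone on the standardized
#' whole-peptide matrix, trains the selected model variant on the clamped
#' labels and evaluates on the held-out test set over both reporting ranges.
#'
#' @param records data.frame with columns \code{id}, \code{smiles},
#'   \code{ppb} (raw experimental %PPB in [0, 100]).
#' @param descriptors Descriptor names used as model input.
#' @param variant Model variant (see \code{\link{ppbModelConfig}}).
#' @param testFraction Kennard-Stone test fraction.
#' @param weighting Frequency-weighting strategy for substructure rows.
#' @param config Optional \code{\link{ppbModelConfig}} overriding the default.
#' @param decompositions Optional precomputed list of
#'   \linkS4class{SubstructureSet} keyed by peptide id.
#' @param L Feature-map length.
#' @return list with the trained \code{model}, the \code{split}, test-set
#'   \code{predictions}, \code{metrics} for ranges 50-95 and 80-95,
#'   \code{maps}, \code{decompositions} and the substructure descriptor
#'   matrix.
#' @export
ppbPipeline <- function(records, descriptors = defaultDescriptors(),
                        variant = "augmented", testFraction = 0.1,
                        weighting = "linear", config = NULL,
                        decompositions = NULL, L = 15L) {
  stopifnot(all(c("id", "smiles", "ppb") %in% names(records)))
  ids <- as.character(records$id)

  if (is.null(decompositions))
    decompositions <- decomposeSet(records$smiles, ids)
  decompositions <- decompositions[ids]

  # whole-peptide descriptors; split on the all-data standardization (the
  # split must precede knowing which rows are training data), then refit the
  # modeling standardization on the training split only
  whole <- computeDescriptors(stats::setNames(records$smiles, ids), descriptors)
  splitStd <- standardizeDescriptors(whole)
  split <- kennardStoneSplit(splitStd, testFraction)
  trainIds <- split$train
  std <- fitStandardization(whole[trainIds, , drop = FALSE])

  # substructure descriptors standardized by training whole-peptide stats,
  # weighted by training appearance frequency
  allSmi <- unique(unlist(lapply(decompositions, cappedSmiles)))
  sub <- computeDescriptors(stats::setNames(allSmi, allSmi), descriptors)
  subStd <- standardizeDescriptors(sub, std)
  trainCounts <- table(unlist(lapply(decompositions[trainIds], cappedSmiles)))
  counts <- stats::setNames(as.integer(trainCounts), names(trainCounts))
  subW <- weightByFrequency(subStd, counts, weighting)

  maps <- buildFeatureMaps(decompositions, subW, L = L)
  labels <- stats::setNames(clampPPB(records$ppb), ids)

  if (is.null(config))
    config <- ppbModelConfig(variant = variant, D = length(descriptors), L = L)
  if (config$D != length(descriptors))
    stop("config$D (", config$D, ") does not match the number of descriptors (",
         length(descriptors), ")")
  model <- trainPPBModel(maps[trainIds], labels[trainIds], config)
  model@standardization <- std
  model@descriptors <- descriptors

  testIds <- split$test
  preds <- predictPPB(model, maps[testIds])
  yTest <- records$ppb[match(testIds, ids)]
  metrics <- list(
    `50-95` = evaluatePPB(clampPPB(yTest), preds$y_hat, "50-95"),
    `80-95` = if (sum(yTest >= 80) >= 1L)
      evaluatePPB(clampPPB(yTest), preds$y_hat, "80-95") else NULL
  )
  list(model = model, split = split, predictions = preds, metrics = metrics,
       maps = maps, decompositions = decompositions,
       substructureDescriptors = subW, wholeDescriptors = whole,
       standardization = std, labels = labels)
}
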