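#' @rdname CyclicPeptide-class
#' @param object,x An object.
#' @export
setGeneric("peptideId", function(x) standardGeneric("peptideId"))

#' @rdname CyclicPeptide-class
#' @export
setGeneric("macrocycleAtoms", function(x) standardGeneric("macrocycleAtoms"))

#' @rdname CyclicPeptide-class
#' @export
setGeneric("cleavableBonds", function(x) standardGeneric("cleavableBonds"))

#' @rdname SubstructureSet-class
#' @export
setGeneric("cappedSmiles", function(x) standardGeneric("cappedSmiles"))

#' @rdname SubstructureSet-class
#' @export
setGeneric("nSubstructures", function(x) standardGeneric("nSubstructures"))

#' @rdname SubstructureSet-class
#' @export
setGeneric("parentAtoms", function(x) standardGeneric("parentAtoms"))

#' @rdname PPBFeatureMap-class
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname PPBFeatureMap-class
#' @export
setGeneric("mapSpan", function(x) standardGeneric("mapSpan"))

#' @rdname PPBFeatureMap-class
#' @export
setGeneric("mapProvenance", function(x) standardGeneric("mapProvenance"))

#' @rdname PPBModel-class
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname PPBModel-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname SaliencyMap-class
#' @export
setGeneric("saliencyScores", function(x) standardGeneric("saliencyScores"))

#' @rdname SaliencyMap-class
#' @export
setGeneric("substructureSaliency", function(x) standardGeneric("substructureSaliency"))

setMethod("peptideId", "CyclicPeptide", function(x) x@id)
setMethod("peptideId", "SubstructureSet", function(x) x@peptideId)
setMethod("peptideId", "PPBFeatureMap", function(x) x@peptideId)
setMethod("peptideId", "SaliencyMap", function(x) x@peptideId)

setMethod("macrocycleAtoms", "CyclicPeptide", function(x) x@macrocycleAtoms)
setMethod("cleavableBonds", "CyclicPeptide", function(x) x@cleavableBonds)

setMethod("cappedSmiles", "SubstructureSet", function(x) x@table$capped_smiles)
setMethod("nSubstructures", "SubstructureSet", function(x) nrow(x@table))
setMethod("parentAtoms", "SubstructureSet", function(x) x@parentAtoms)

setMethod("mapValues", "PPBFeatureMap", function(x) x@values)
setMethod("mapSpan", "PPBFeatureMap", function(x) c(start = x@start, n = x@n))
setMethod("mapProvenance", "PPBFeatureMap", function(x)
  list(peptide_id = x@peptideId, rotation = x@rotation, translation = x@translation))

setMethod("modelConfig", "PPBModel", function(x) x@config)
setMethod("trainingHistory", "PPBModel", function(x) x@history)

setMethod("saliencyScores", "SaliencyMap", function(x) x@scores)
setMethod("substructureSaliency", "SaliencyMap", function(x) x@perSubstructure)

setMethod("show", "CyclicPeptide", function(object) {
  cat("CyclicPeptide '", object@id, "'\n", sep = "")
  cat("  heavy atoms: ", length(object@elem),
      ", macrocycle size: ", length(object@macrocycleAtoms), "\n", sep = "")
  tb <- table(object@cleavableBonds$class)
  cat("  cleavable bonds: ", nrow(object@cleavableBonds),
      " (", paste(names(tb), tb, sep = ": ", collapse = ", "), ")\n", sep = "")
})

setMethod("show", "SubstructureSet", function(object) {
  cat("SubstructureSet for '", object@peptideId, "': ",
      nrow(object@table), " substructures\n", sep = "")
  print(utils::head(object@table, 8))
  if (nrow(object@table) > 8) cat("  ...\n")
})

setMethod("show", "PPBFeatureMap", function(object) {
  cat("PPBFeatureMap '", object@peptideId, "': ",
      nrow(object@values), " x ", ncol(object@values),
      ", span [", object@start, ", ", object@start + object@n - 1L, "]",
      ", rotation ", object@rotation,
      ", translation ", object@translation, "\n", sep = "")
})

setMethod("show", "PPBModel", function(object) {
  cfg <- object@config
  cat("PPBModel (variant '", cfg$variant, "')\n", sep = "")
  cat("  descriptors:", paste(object@descriptors, collapse = ", "), "\n")
  cat("  conv layers:", length(cfg$convLayers),
      " fc widths:", paste(c(cfg$fcLayers, 1), collapse = " -> "), "\n")
  if (nrow(object@history))
    cat("  trained ", max(object@history$epoch), " epochs, best val loss ",
        signif(min(object@history$val_loss, na.rm = TRUE), 4), "\n", sep = "")
  else cat("  untrained\n")
})

setMethod("show", "SaliencyMap", function(object) {
  cat("SaliencyMap '", object@peptideId, "': ",
      nrow(object@scores), " descriptors x ",
      ncol(object@scores), " ring positions\n", sep = "")
  cat("  per-substructure:", paste(signif(object@perSubstructure, 3), collapse = " "), "\n")
})
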