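#' @import methods
NULL

#' CyclicPeptide: a parsed cyclic peptide with its macrocycle
#'
#' Holds the molecular graph of one cyclic peptide together with the
#' identified macrocycle (the division target) and the bonds that will be
#' cleaved during residue decomposition: backbone amide bonds and disulfide
#' bonds lying on the macrocycle.
#'
#' @slot id Peptide identifier.
#' @slot smiles Canonical SMILES of the whole peptide.
#' @slot elem Element symbol per heavy atom.
#' @slot coords Numeric matrix of 2D coordinates (one row per atom).
#' @slot bonds data.frame with columns \code{from}, \code{to}, \code{order}.
#' @slot macrocycleAtoms Integer vector of atom indices in ring order.
#' @slot cleavableBonds data.frame with columns \code{from}, \code{to},
#'   \code{class} (\code{"backbone_amide"} or \code{"disulfide"}).
#'
#' @exportClass CyclicPeptide
setClass("CyclicPeptide",
  representation(
    id = "character",
    smiles = "character",
    elem = "character",
    coords = "matrix",
    bonds = "data.frame",
    macrocycleAtoms = "integer",
    cleavableBonds = "data.frame"
  )
)

setValidity("CyclicPeptide", function(object) {
  msg <- character(0)
  ring <- object@macrocycleAtoms
  cb <- object@cleavableBonds
  if (length(ring) < 12L)
    msg <- c(msg, "macrocycle must span at least 12 heavy atoms")
  if (nrow(cb) < 5L)
    msg <- c(msg, "fewer than 5 cleavable bonds (peptides of < 5 residues are rejected)")
  if (nrow(cb) > 0L && !all(cb$from %in% ring & cb$to %in% ring))
    msg <- c(msg, "every cleavable bond must lie on the macrocycle")
  if (length(msg)) msg else TRUE
})

#' SubstructureSet: residue-level fragments of one cyclic peptide
#'
#' The ordered result of cleaving all macrocycle backbone bonds of one
#' peptide and capping the cut ends (methyl on the amide nitrogen, aldehyde
#' at the carbonyl carbon, hydrogen on disulfide sulfurs). Positions are
#' consecutive ring positions \code{0..n-1}; position i and (i+1) mod n were
#' joined by a cleaved bond in the parent.
#'
#' @slot peptideId Parent peptide identifier.
#' @slot table data.frame with columns \code{position}, \code{capped_smiles},
#'   \code{n_total}.
#' @slot parentAtoms List of integer vectors: parent heavy-atom indices
#'   belonging to each fragment (capping atoms excluded).
#'
#' @exportClass SubstructureSet
setClass("SubstructureSet",
  representation(
    peptideId = "character",
    table = "data.frame",
    parentAtoms = "list"
  )
)

setValidity("SubstructureSet", function(object) {
  tab <- object@table
  n <- nrow(tab)
  if (n == 0L) return("empty substructure set")
  if (!identical(tab$position, 0:(n - 1L)))
    return("positions must be consecutive 0..n-1")
  if (length(object@parentAtoms) != n)
    return("parentAtoms must have one entry per substructure")
  atoms <- unlist(object@parentAtoms)
  if (anyDuplicated(atoms))
    return("parent atoms must partition the parent (duplicate membership)")
  TRUE
})

#' PPBFeatureMap: one D x L input map for the convolutional model
#'
#' Substructure descriptor vectors arranged contiguously inside a fixed
#' D x L array (L = 15), zero elsewhere. Provenance records which
#' rotation/translation replica of the parent peptide this map is.
#'
#' @slot values Numeric D x L matrix.
#' @slot start 0-based start column of the occupied span.
#' @slot n Number of substructures (span length).
#' @slot peptideId Parent peptide identifier.
#' @slot rotation Cyclic rotation r in 0..n-1 applied to the substructure order.
#' @slot translation Translation t in 0..L-n (equals \code{start}).
#'
#' @exportClass PPBFeatureMap
setClass("PPBFeatureMap",
  representation(
    values = "matrix",
    start = "integer",
    n = "integer",
    peptideId = "character",
    rotation = "integer",
    translation = "integer"
  )
)

setValidity("PPBFeatureMap", function(object) {
  L <- ncol(object@values)
  n <- object@n
  s <- object@start
  if (n < 1L || n > L) return("span length must satisfy 1 <= n <= L")
  if (s < 0L || s > L - n) return("span start out of range")
  outside <- setdiff(seq_len(L), (s + 1L):(s + n))
  if (length(outside) && any(object@values[, outside, drop = FALSE] != 0))
    return("entries outside the occupied span must be exactly 0")
  TRUE
})

#' PPBModel: a trained (or freshly built) %PPB regression network
#'
#' @slot config Validated model configuration (see \code{\link{ppbModelConfig}}).
#' @slot params Network parameters (conv / batch-norm / fully connected).
#' @slot history data.frame of per-epoch training and validation loss.
#' @slot standardization Per-descriptor mean/sd used at featurization time.
#' @slot descriptors Descriptor names the model was trained on.
#'
#' @exportClass PPBModel
setClass("PPBModel",
  representation(
    config = "list",
    params = "list",
    history = "data.frame",
    standardization = "list",
    descriptors = "character"
  )
)

#' SaliencyMap: residue-level gradient attribution for one peptide
#'
#' Saliency scores |d yhat / d x| per (descriptor, ring position), averaged
#' over all augmentation replicas and mapped back from map columns to ring
#' positions; \code{perSubstructure} sums over descriptors.
#'
#' @slot peptideId Peptide identifier.
#' @slot scores Numeric D x n matrix (descriptor x ring position).
#' @slot perSubstructure Length-n numeric vector.
#'
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  representation(
    peptideId = "character",
    scores = "matrix",
    perSubstructure = "numeric"
  )
)

setValidity("SaliencyMap", function(object) {
  if (any(object@scores < 0)) return("saliency scores must be non-negative")
  if (length(object@perSubstructure) != ncol(object@scores))
    return("perSubstructure length must equal the number of ring positions")
  TRUE
})
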