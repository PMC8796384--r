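# 2D physicochemical descriptor engine.
#
# Open-source surrogate descriptors stand in for a commercial engine: logP
# comes from OpenBabel's atomic-contribution model, logS is an ESOL-type
# estimate, and the PEOE_VSA surrogates bin an approximate per-atom van der
# Waals surface area by Gasteiger partial charge. Roughly 50 graph- and
# charge-based 2D descriptors form the search space for descriptor selection.
# The engine name is recorded on every matrix so models trained with
# different engines are never mixed.

.DESCRIPTOR_ENGINE <- "openbabel-surrogate-v1"

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, H = 1.20)

# Approximate per-atom VdW surface area: sphere area shrunk by coordination.
.atomVSA <- function(elem, degree) {
  r <- .VDW_RADII[elem]
  r[is.na(r)] <- 1.70
  pmax(4 * pi * r^2 * (1 - 0.12 * degree), 1.0)
}

# Per-molecule context: graph features + OpenBabel properties + charges.
.molContext <- function(mol, prop, charges) {
  b <- mol$bonds
  nat <- length(mol$elem)
  deg <- tabulate(c(b$from, b$to), nbins = nat)
  nC <- sum(mol$elem == "C")
  dblAtoms <- unique(c(b$from[b$order >= 2L], b$to[b$order >= 2L]))
  # ring atoms = endpoints of non-bridge edges
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("from", "to")]), directed = FALSE)
  if (nat > igraph::vcount(g)) g <- igraph::add_vertices(g, nat - igraph::vcount(g))
  br <- igraph::bridges(g)
  ringEdge <- rep(TRUE, nrow(b)); ringEdge[as.integer(br)] <- FALSE
  ringAtoms <- unique(c(b$from[ringEdge], b$to[ringEdge]))
  amide <- .amideBonds(mol)
  carbonylC <- unique(b$from[b$order == 2L &
    ((mol$elem[b$from] == "C" & mol$elem[b$to] == "O"))])
  carbonylC <- unique(c(carbonylC, b$to[b$order == 2L &
    (mol$elem[b$to] == "C" & mol$elem[b$from] == "O")]))
  # rotatable: single, non-ring, both ends degree >= 2, not an amide C-N
  amideKey <- paste(pmin(amide$from, amide$to), pmax(amide$from, amide$to))
  rot <- sum(b$order == 1L & !ringEdge &
             deg[b$from] >= 2L & deg[b$to] >= 2L &
             !(paste(pmin(b$from, b$to), pmax(b$from, b$to)) %in% amideKey))
  dmat <- igraph::distances(g)
  finite <- dmat[is.finite(dmat)]
  ecc <- apply(dmat, 1, function(r) max(r[is.finite(r)]))
  vsa <- .atomVSA(mol$elem, deg)
  if (length(charges) != nat) charges <- rep(0, nat)
  list(mol = mol, prop = prop, charges = charges, deg = deg, nat = nat,
       nC = nC, dblAtoms = dblAtoms, ringAtoms = ringAtoms,
       ringEdge = ringEdge, amide = amide, carbonylC = carbonylC,
       rot = rot, wiener = sum(finite) / 2, diam = max(ecc), rad = min(ecc),
       vsa = vsa,
       aromAtoms = intersect(ringAtoms, dblAtoms))
}

# Charge-bin edges chosen for the Gasteiger implementation at hand: its
# most negative charges (carbonyl and hydroxyl oxygens) sit near -0.29, so
# the most-negative bin starts at -0.25.
.chargeBins <- list(
  PEOE_VSA1 = c(-Inf, -0.25), PEOE_VSA2 = c(-0.25, -0.20),
  PEOE_VSA3 = c(-0.20, -0.15), PEOE_VSA4 = c(-0.15, -0.10),
  PEOE_VSA5 = c(-0.10, -0.05), PEOE_VSA6 = c(-0.05, 0.00),
  PEOE_VSA7 = c(0.00, 0.05), PEOE_VSA8 = c(0.05, 0.10),
  PEOE_VSA9 = c(0.10, 0.15), PEOE_VSA10 = c(0.15, 0.20),
  PEOE_VSA11 = c(0.20, 0.25), PEOE_VSA12 = c(0.25, 0.30),
  PEOE_VSA13 = c(0.30, Inf)
)

.descriptorFuns <- local({
  funs <- list(
    MolLogP = function(cx) cx$prop[["logP"]],
    MolWt = function(cx) cx$prop[["MW"]],
    MolMR = function(cx) cx$prop[["MR"]],
    TPSA = function(cx) cx$prop[["TPSA"]],
    NumHBA = function(cx) cx$prop[["HBA2"]],
    NumHBD = function(cx) cx$prop[["HBD"]],
    ESOL_LogS = function(cx) {
      ap <- length(cx$aromAtoms) / cx$nat
      0.16 - 0.63 * cx$prop[["logP"]] - 0.0062 * cx$prop[["MW"]] +
        0.066 * cx$rot - 0.74 * ap
    },
    HeavyAtomCount = function(cx) cx$nat,
    NumBonds = function(cx) nrow(cx$mol$bonds),
    NumC = function(cx) cx$nC,
    NumN = function(cx) sum(cx$mol$elem == "N"),
    NumO = function(cx) sum(cx$mol$elem == "O"),
    NumS = function(cx) sum(cx$mol$elem == "S"),
    NumHalogen = function(cx) sum(cx$mol$elem %in% c("F", "Cl", "Br", "I")),
    HeteroatomFraction = function(cx) 1 - cx$nC / cx$nat,
    NumRings = function(cx) nrow(cx$mol$bonds) - cx$nat +
      max(.components(cx$nat, cx$mol$bonds)),
    NumRingAtoms = function(cx) length(cx$ringAtoms),
    NumRingBonds = function(cx) sum(cx$ringEdge),
    NumAromaticAtoms = function(cx) length(cx$aromAtoms),
    AromaticProportion = function(cx) length(cx$aromAtoms) / cx$nat,
    NumRotatableBonds = function(cx) cx$rot,
    FractionCsp3 = function(cx) {
      if (cx$nC == 0) return(0)
      sp3 <- setdiff(which(cx$mol$elem == "C"), cx$dblAtoms)
      length(sp3) / cx$nC
    },
    NumAmideBonds = function(cx) nrow(cx$amide),
    NumCarbonyl = function(cx) length(cx$carbonylC),
    NumHydroxyl = function(cx) {
      b <- cx$mol$bonds
      o1 <- which(cx$mol$elem == "O" & cx$deg == 1L)
      sum(o1 %in% c(b$from[b$order == 1L], b$to[b$order == 1L]))
    },
    NumEtherO = function(cx) sum(cx$mol$elem == "O" & cx$deg == 2L),
    NumAmineN = function(cx) {
      amideN <- unique(cx$amide$to)
      sum(cx$mol$elem == "N" & !(seq_len(cx$nat) %in% amideN))
    },
    NumDoubleBonds = function(cx) sum(cx$mol$bonds$order == 2L),
    NumTripleBonds = function(cx) sum(cx$mol$bonds$order == 3L),
    MaxDegree = function(cx) max(cx$deg),
    MeanDegree = function(cx) mean(cx$deg),
    ZagrebM1 = function(cx) sum(cx$deg^2),
    ZagrebM2 = function(cx) sum(cx$deg[cx$mol$bonds$from] * cx$deg[cx$mol$bonds$to]),
    WienerIndex = function(cx) cx$wiener,
    GraphDiameter = function(cx) cx$diam,
    GraphRadius = function(cx) cx$rad,
    PetitjeanIndex = function(cx) if (cx$rad > 0) (cx$diam - cx$rad) / cx$rad else 0,
    TotalVSA = function(cx) sum(cx$vsa),
    GasteigerMax = function(cx) if (length(cx$charges)) max(cx$charges) else 0,
    GasteigerMin = function(cx) if (length(cx$charges)) min(cx$charges) else 0,
    SumNegCharge = function(cx) sum(cx$charges[cx$charges < 0]),
    SumPosCharge = function(cx) sum(cx$charges[cx$charges > 0]),
    PEOE_VSA_FPNEG = function(cx)
      sum(cx$vsa[cx$charges < 0]) / max(sum(cx$vsa), 1e-12)
  )
  for (nm in names(.chargeBins)) {
    funs[[nm]] <- local({
      bin <- .chargeBins[[nm]]
      function(cx) sum(cx$vsa[cx$charges > bin[1] & cx$charges <= bin[2]])
    })
  }
  funs
})

#' Names of all available 2D descriptors
#' @return Character vector of descriptor names.
#' @export
availableDescriptors <- function() names(.descriptorFuns)

#' Default descriptor trio
#'
#' The lipophilicity / partial-charge / solubility trio used as model input:
#' \code{MolLogP} (octanol-water partition, atomic-contribution surrogate),
#' \code{PEOE_VSA1} (approximate VdW surface area in the most negative
#' Gasteiger-charge bin) and \code{ESOL_LogS} (estimated aqueous solubility).
#' @return Character vector of three descriptor names.
#' @export
defaultDescriptors <- function() c("MolLogP", "PEOE_VSA1", "ESOL_LogS")

#' Compute 2D descriptors for a set of molecules
#'
#' @param smiles Character vector of SMILES (names become row names; unnamed
#'   input is named by the SMILES themselves).
#' @param descriptors Descriptor names; see \code{\link{availableDescriptors}}.
#' @return Numeric matrix, one row per molecule, with attribute
#'   \code{"engine"} recording the surrogate engine identity.
#' @examples
#' computeDescriptors(c(benzene = "c1ccccc1", ethanol = "CCO"))[, "MolLogP"]
#' @export
computeDescriptors <- function(smiles, descriptors = availableDescriptors()) {
  stopifnot(is.character(smiles))
  unknown <- setdiff(descriptors, availableDescriptors())
  if (length(unknown))
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "))
  ids <- names(smiles)
  if (is.null(ids)) ids <- smiles
  out <- matrix(numeric(0), nrow = length(smiles), ncol = length(descriptors),
                dimnames = list(ids, descriptors))
  if (length(smiles) == 0L || length(descriptors) == 0L) {
    attr(out, "engine") <- .DESCRIPTOR_ENGINE
    return(out)
  }
  mols <- .parseMols(smiles, paste0("m", seq_along(smiles)))
  blocks <- vapply(seq_along(mols), function(i)
    .molBlock(mols[[i]]$elem, mols[[i]]$coords, mols[[i]]$bonds,
              paste0("m", i)), character(1))
  sdfs <- ChemmineR::read.SDFset(unlist(strsplit(blocks, "\n", fixed = TRUE)))
  ChemmineR::cid(sdfs) <- paste0("m", seq_along(mols))
  props <- ChemmineR::propOB(sdfs)
  charges <- .gasteigerCharges(blocks)
  for (i in seq_along(smiles)) {
    cx <- .molContext(mols[[i]], as.list(props[i, ]), charges[[i]])
    out[i, ] <- vapply(descriptors, function(d) .descriptorFuns[[d]](cx),
                       numeric(1))
  }
  attr(out, "engine") <- .DESCRIPTOR_ENGINE
  out
}

#' Fit Z-score standardization parameters on a reference matrix
#'
#' The reference is the whole-peptide descriptor matrix of the training set;
#' the same column means and standard deviations are applied to whole-peptide
#' and substructure matrices alike.
#'
#' @param reference Numeric matrix with named columns.
#' @return list with numeric vectors \code{mu} and \code{sigma}.
#' @export
fitStandardization <- function(reference) {
  stopifnot(is.matrix(reference))
  if (is.null(colnames(reference)))
    colnames(reference) <- paste0("V", seq_len(ncol(reference)))
  mu <- colMeans(reference)
  # population standard deviation: sigma = sqrt(mean((x - mu)^2))
  sigma <- sqrt(colMeans(sweep(reference, 2, mu)^2))
  bad <- names(sigma)[sigma == 0 | !is.finite(sigma)]
  if (length(bad))
    stop("zero-variance column(s) in standardization reference: ",
         paste(bad, collapse = ", "))
  list(mu = mu, sigma = sigma)
}

#' Apply Z-score standardization
#'
#' Computes \code{z = (x - mu) / sigma} column-wise with parameters fitted by
#' \code{\link{fitStandardization}} (or fitted on \code{reference}).
#'
#' @param x Numeric matrix to standardize.
#' @param reference Reference matrix, or a parameter list from
#'   \code{\link{fitStandardization}}. Defaults to \code{x} itself.
#' @return Standardized matrix with attribute \code{"standardization"}.
#' @export
standardizeDescriptors <- function(x, reference = x) {
  params <- if (is.list(reference) && all(c("mu", "sigma") %in% names(reference)))
    reference else fitStandardization(reference)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  stopifnot(all(colnames(x) %in% names(params$mu)))
  z <- sweep(x, 2, params$mu[colnames(x)], "-")
  z <- sweep(z, 2, params$sigma[colnames(x)], "/")
  attr(z, "standardization") <- params
  attr(z, "engine") <- attr(x, "engine", exact = TRUE)
  z
}

#' Weight substructure descriptor rows by appearance frequency
#'
#' Each row is scaled by a monotone function of how often its substructure
#' occurs in the training data: \code{"linear"} uses count/max(count),
#' \code{"sqrt"} its square root, \code{"none"} leaves the matrix unchanged.
#' Substructures unseen in training receive count 1.
#'
#' @param x Numeric substructure descriptor matrix.
#' @param counts Named integer vector of training occurrence counts; names
#'   are matched against \code{rownames(x)} (canonical capped SMILES).
#' @param strategy One of \code{"linear"}, \code{"sqrt"}, \code{"none"}.
#' @return Weighted matrix with attribute \code{"weights"}.
#' @export
weightByFrequency <- function(x, counts, strategy = c("linear", "sqrt", "none")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") {
    attr(x, "weights") <- rep(1, nrow(x))
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (any(counts <= 0)) stop("substructure occurrence counts must be >= 1")
  cnt <- counts[rownames(x)]
  cnt[is.na(cnt)] <- 1
  w <- cnt / max(counts)
  if (strategy == "sqrt") w <- sqrt(w)
  out <- x * w
  attr(out, "weights") <- unname(w)
  attr(out, "engine") <- attr(x, "engine", exact = TRUE)
  out
}
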