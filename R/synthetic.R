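# Synthetic cyclic-peptide generator.
#
# Emits head-to-tail amide-cyclized (or terminal-cysteine disulfide-cyclized)
# peptide SMILES with %PPB labels driven by substructure lipophilicity:
# %PPB = clamp(a + b * mean(substructure logP) + c * max(substructure logP)
# + Gaussian noise). The max term plants a single "important residue" per
# peptide so saliency attribution has a known target; the mean term carries
# the bulk lipophilicity signal. Label mass accumulates at both clamp
# boundaries, as real assay panels of optimized peptides do.

.RESIDUES <- list(
  Ala = "C",          Gly = "",            Val = "C(C)C",
  Leu = "CC(C)C",     Ile = "C(C)CC",      Phe = "Cc1ccccc1",
  Trp = "Cc1c[nH]c2ccccc12",               Met = "CCSC",
  Ser = "CO",         Thr = "C(C)O",       Tyr = "Cc1ccc(O)cc1",
  Asn = "CC(N)=O",    Gln = "CCC(N)=O",    Asp = "CC(O)=O",
  Glu = "CCC(O)=O",   Lys = "CCCCN",       Arg = "CCCNC(=N)N",
  His = "Cc1c[nH]cn1", Pro = "PROLINE",    Cys = "CS"
)

#' Residue alphabet of the synthetic generator
#' @return Character vector of supported residue names.
#' @export
availableResidues <- function() names(.RESIDUES)

#' Default residue alphabet
#'
#' All proteinogenic residues except cysteine (reserved for disulfide
#' cyclization termini), giving a realistic mix of lipophilic and
#' hydrophilic substructures.
#' @return Character vector of residue names.
#' @export
defaultResidueAlphabet <- function() setdiff(availableResidues(), "Cys")

# --- direct graph construction -------------------------------------------
# Reading macrocyclic SMILES through the chemistry toolkit is by far the
# most expensive step of the synthetic pipeline (ring perception in the
# reader). Because the generator assembles peptides from known residue
# templates, it can also assemble the molecular graph directly and seed the
# parse cache, so downstream decomposition never re-reads the SMILES. A
# consistency test asserts graph/SMILES identity via canonical forms.

# Graph of one residue unit. Returns list(elem, coords, bonds, N, Cp, S).
.residueGraph <- function(name, nMethyl = FALSE, disulfideEnd = FALSE,
                          cTerminal = FALSE) {
  if (identical(.RESIDUES[[name]], "PROLINE")) {
    elem <- c("N", "C", "C", "C", "C", "C", "O")  # N CD CG CB CA C' O
    bonds <- data.frame(from = c(1, 2, 3, 4, 5, 5, 6),
                        to   = c(2, 3, 4, 5, 1, 6, 7),
                        order = c(1, 1, 1, 1, 1, 1, 2))
    Ca <- 5L; Cp <- 6L; S <- NA_integer_
  } else {
    side <- if (disulfideEnd) "CS" else .RESIDUES[[name]]
    elem <- c("N", "C", "C", "O")  # N CA C' O
    bonds <- data.frame(from = c(1, 2, 3), to = c(2, 3, 4),
                        order = c(1, 1, 2))
    Ca <- 2L; Cp <- 3L; S <- NA_integer_
    if (nzchar(side)) {
      # single-atom side chains are built directly (single-atom SDF blocks
      # round-trip poorly through the toolkit)
      sm <- if (nchar(side) == 1L)
        list(elem = side,
             bonds = data.frame(from = integer(0), to = integer(0),
                                order = integer(0)))
      else .parseMol(side, paste0("side_", name))
      off <- length(elem)
      elem <- c(elem, sm$elem)
      bonds <- rbind(bonds,
                     data.frame(from = sm$bonds$from + off,
                                to = sm$bonds$to + off,
                                order = sm$bonds$order),
                     data.frame(from = Ca, to = off + 1L, order = 1L))
      if (disulfideEnd) S <- off + which(sm$elem == "S")[1]
    }
    if (nMethyl) {
      elem <- c(elem, "C")
      bonds <- rbind(bonds, data.frame(from = 1L, to = length(elem), order = 1L))
    }
  }
  if (cTerminal) {  # carboxyl OH on the C-terminal carbonyl
    elem <- c(elem, "O")
    bonds <- rbind(bonds, data.frame(from = Cp, to = length(elem), order = 1L))
  }
  list(elem = elem, bonds = bonds, N = 1L, Cp = Cp, S = S)
}

# Assemble the peptide graph matching the generated SMILES and register it
# in the parse cache under that SMILES.
.stitchPeptideGraph <- function(smiles, res, meth, disulfide) {
  n <- length(res)
  elem <- character(0)
  bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  Ns <- Cps <- Ss <- integer(n)
  for (i in seq_len(n)) {
    term <- disulfide && (i == 1L || i == n)
    g <- .residueGraph(res[i],
                       nMethyl = meth[i] && !(disulfide && term) &&
                         !(i == 1L && !disulfide),
                       disulfideEnd = term,
                       cTerminal = disulfide && i == n)
    off <- length(elem)
    elem <- c(elem, g$elem)
    bonds <- rbind(bonds, data.frame(from = g$bonds$from + off,
                                     to = g$bonds$to + off,
                                     order = g$bonds$order))
    Ns[i] <- g$N + off; Cps[i] <- g$Cp + off
    Ss[i] <- if (is.na(g$S)) NA_integer_ else g$S + off
  }
  for (i in seq_len(n - 1L))
    bonds <- rbind(bonds, data.frame(from = Cps[i], to = Ns[i + 1L], order = 1L))
  if (disulfide) {
    bonds <- rbind(bonds, data.frame(from = Ss[1L], to = Ss[n], order = 1L))
  } else {
    bonds <- rbind(bonds, data.frame(from = Cps[n], to = Ns[1L], order = 1L))
  }
  mol <- list(elem = elem,
              coords = matrix(0, length(elem), 3L),
              bonds = bonds)
  assign(smiles, mol, envir = .molCache)
  mol
}

# One backbone unit of the growing SMILES string.
.residueUnit <- function(name, nMethyl = FALSE, first = FALSE, last = FALSE,
                         disulfideEnd = FALSE) {
  side <- .RESIDUES[[name]]
  ringOpen <- if (first) "%99" else ""
  carbonyl <- if (last) "C%99=O" else "C(=O)"
  if (identical(side, "PROLINE"))
    return(paste0("N", ringOpen, "%97CCCC%97", carbonyl))
  nm <- if (nMethyl) "(C)" else ""
  if (disulfideEnd) side <- "CS%98"
  mid <- if (side == "") "C" else paste0("C(", side, ")")
  paste0("N", ringOpen, nm, mid, carbonyl)
}

#' Generate one cyclic-peptide SMILES
#'
#' Head-to-tail amide-cyclized by default; with \code{disulfide = TRUE} the
#' peptide is linear with terminal cysteines joined by an S-S bond (free
#' N-terminal amine and C-terminal carboxyl stay exocyclic). The SMILES
#' round-trips through \code{\link{decomposePeptide}} yielding exactly
#' \code{nResidues} substructures.
#'
#' @param nResidues Number of residues, 5 to 15.
#' @param alphabet Residue names sampled for (interior) positions.
#' @param seed Optional integer seed.
#' @param nMethylProb Probability that an interior backbone amide nitrogen is
#'   N-methylated.
#' @param disulfide Cyclize via terminal-cysteine disulfide instead of
#'   head-to-tail amide.
#' @return list with \code{smiles} and \code{residues} (sampled names).
#' @examples
#' generatePeptide(6, "Ala", seed = 1)$smiles
#' @export
generatePeptide <- function(nResidues, alphabet = defaultResidueAlphabet(),
                            seed = NULL, nMethylProb = 0, disulfide = FALSE) {
  if (nResidues < 5L || nResidues > 15L)
    stop("nResidues must be between 5 and 15")
  bad <- setdiff(alphabet, availableResidues())
  if (length(bad))
    stop("unknown residue(s) in alphabet: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- sample(alphabet, nResidues, replace = TRUE)
  if (disulfide) res[c(1L, nResidues)] <- "Cys"
  meth <- stats::runif(nResidues) < nMethylProb
  meth[res == "Pro"] <- FALSE
  units <- character(nResidues)
  for (i in seq_len(nResidues)) {
    if (disulfide) {
      term <- i == 1L || i == nResidues
      units[i] <- .residueUnit(res[i], nMethyl = meth[i] && !term,
                               disulfideEnd = term)
      if (i == nResidues) units[i] <- sub("C\\(=O\\)$", "C(=O)O", units[i])
    } else {
      units[i] <- .residueUnit(res[i], nMethyl = meth[i] && i != 1L,
                               first = i == 1L, last = i == nResidues)
    }
  }
  smiles <- paste(units, collapse = "")
  .stitchPeptideGraph(smiles, res, meth, disulfide)
  list(smiles = smiles, residues = res, nMethylated = meth)
}

#' Specification of a synthetic %PPB dataset
#'
#' The defaults emulate the shape of real cyclic-peptide PPB panels: 5-15
#' residues with the mode near 7-10, labels concentrated between 50 and 95
#' with mass at both clamp boundaries, and a label driven monotonically by
#' substructure lipophilicity with assay-scale noise (sd 3 %PPB).
#'
#' @param nPeptides Number of peptides.
#' @param residueCountProbs Sampling weights over 5..15 residues.
#' @param alphabet Residue alphabet for the optimized (lipophilic) population.
#' @param nMethylProb Interior N-methylation probability (optimized
#'   population; the natural population is never N-methylated).
#' @param disulfideProb Extra probability that an optimized peptide is
#'   disulfide-cyclized (the natural population always is).
#' @param hydrophilicFraction Fraction of peptides drawn from a
#'   natural-amino-acid, hydrophilic-biased, disulfide-cyclized population
#'   (the low-%PPB tail of real panels).
#' @param a,b,c Label model intercept, mean-logP and max-logP coefficients
#'   (%PPB per logP unit).
#' @param sigma Gaussian label noise sd in %PPB.
#' @param seed Integer seed.
#' @return list of generator settings.
#' @export
syntheticSpec <- function(nPeptides = 300L,
                          residueCountProbs = c(0.06, 0.10, 0.16, 0.18, 0.16,
                                                0.12, 0.08, 0.05, 0.04, 0.03,
                                                0.02),
                          alphabet = defaultResidueAlphabet(),
                          nMethylProb = 0.2,
                          disulfideProb = 0.1,
                          hydrophilicFraction = 0.15,
                          a = 48, b = 40, c = 10, sigma = 3,
                          seed = 1L) {
  stopifnot(length(residueCountProbs) == 11L, nPeptides >= 1L)
  list(nPeptides = as.integer(nPeptides),
       residueCountProbs = residueCountProbs / sum(residueCountProbs),
       alphabet = alphabet, nMethylProb = nMethylProb,
       disulfideProb = disulfideProb,
       hydrophilicFraction = hydrophilicFraction,
       a = a, b = b, c = c, sigma = sigma,
       seed = as.integer(seed))
}

# Hydrophilic-biased natural alphabet for the low-%PPB population.
.HYDROPHILIC_ALPHABET <- c("Ser", "Thr", "Asn", "Gln", "Asp", "Glu", "Gly",
                           "His", "Lys", "Arg", "Ala")

#' Generate a synthetic %PPB dataset
#'
#' Samples peptides from the spec, decomposes each into capped substructures
#' (guaranteeing generator/decomposer consistency), computes the logP of each
#' substructure and assembles labels as
#' \code{clamp(a + b * mean(logP) + c * max(logP) + noise)} clamped to
#' [0, 100]. The decompositions are returned so downstream featurization can
#' reuse them.
#'
#' @param spec Settings from \code{\link{syntheticSpec}}.
#' @return list with \code{records} (data.frame id, smiles, ppb),
#'   \code{truth} (label-model coefficients and per-peptide mean/max
#'   substructure logP and the planted max-logP position) and
#'   \code{decompositions} (list of \linkS4class{SubstructureSet}).
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  set.seed(spec$seed)
  n <- spec$nPeptides
  sizes <- sample(5:15, n, replace = TRUE, prob = spec$residueCountProbs)
  hydrophilic <- stats::runif(n) < spec$hydrophilicFraction
  disulf <- hydrophilic | stats::runif(n) < spec$disulfideProb
  peps <- vector("list", n)
  for (i in seq_len(n))
    peps[[i]] <- generatePeptide(
      sizes[i],
      if (hydrophilic[i]) .HYDROPHILIC_ALPHABET else spec$alphabet,
      seed = NULL,
      nMethylProb = if (hydrophilic[i]) 0 else spec$nMethylProb,
      disulfide = disulf[i])
  noise <- stats::rnorm(n, 0, spec$sigma)
  ids <- sprintf("synth%03d", seq_len(n))
  decomp <- decomposeSet(vapply(peps, `[[`, character(1), "smiles"), ids)
  allSmi <- unique(unlist(lapply(decomp, cappedSmiles)))
  logP <- computeDescriptors(stats::setNames(allSmi, allSmi), "MolLogP")[, 1]
  meanLP <- maxLP <- numeric(n)
  planted <- integer(n)
  for (i in seq_len(n)) {
    lp <- logP[cappedSmiles(decomp[[i]])]
    meanLP[i] <- mean(lp)
    maxLP[i] <- max(lp)
    planted[i] <- which.max(lp) - 1L  # ring position, 0-based
  }
  raw <- spec$a + spec$b * meanLP + spec$c * maxLP + noise
  raw <- pmin(100, pmax(0, raw))
  list(records = data.frame(id = ids,
                            smiles = vapply(peps, `[[`, character(1), "smiles"),
                            ppb = raw),
       truth = list(a = spec$a, b = spec$b, c = spec$c, sigma = spec$sigma,
                    mean_logp = meanLP, max_logp = maxLP,
                    planted_position = planted, n_residues = sizes,
                    disulfide = disulf),
       decompositions = decomp)
}
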