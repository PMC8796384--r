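# Macrocycle identification and residue-level decomposition.
#
# A cyclic peptide is divided at every backbone amide bond and disulfide bond
# lying on its macrocycle. Cut ends are capped 2D-style: the amide nitrogen
# is methylated, the carbonyl carbon becomes an aldehyde, and each disulfide
# sulfur receives a hydrogen. Amide bonds outside the macrocycle (side-chain
# amides such as glutamine's) are never divided.

# Amide C-N single bonds: carbon carries a double-bonded oxygen.
.amideBonds <- function(mol) {
  b <- mol$bonds
  nat <- length(mol$elem)
  hasCarbonylO <- logical(nat)
  dbl <- b[b$order == 2L, , drop = FALSE]
  for (i in seq_len(nrow(dbl))) {
    f <- dbl$from[i]; t <- dbl$to[i]
    if (mol$elem[f] == "C" && mol$elem[t] == "O") hasCarbonylO[f] <- TRUE
    if (mol$elem[t] == "C" && mol$elem[f] == "O") hasCarbonylO[t] <- TRUE
  }
  sel <- b$order == 1L &
    ((mol$elem[b$from] == "C" & mol$elem[b$to] == "N" & hasCarbonylO[b$from]) |
     (mol$elem[b$from] == "N" & mol$elem[b$to] == "C" & hasCarbonylO[b$to]))
  idx <- which(sel)
  data.frame(
    from = ifelse(mol$elem[b$from[idx]] == "C", b$from[idx], b$to[idx]),  # carbonyl C
    to   = ifelse(mol$elem[b$from[idx]] == "C", b$to[idx],   b$from[idx]), # amide N
    class = rep("backbone_amide", length(idx))
  )
}

.disulfideBonds <- function(mol) {
  b <- mol$bonds
  idx <- which(b$order == 1L & mol$elem[b$from] == "S" & mol$elem[b$to] == "S")
  data.frame(from = b$from[idx], to = b$to[idx],
             class = rep("disulfide", length(idx)))
}

# Smallest cycle through a given bond: shortest path between its endpoints
# with the bond removed. Returns atom indices in ring order, or NULL.
.cycleThroughBond <- function(g, from, to) {
  eid <- igraph::get_edge_ids(g, c(from, to))
  if (eid == 0) return(NULL)
  g2 <- igraph::delete_edges(g, eid)
  sp <- suppressWarnings(
    igraph::shortest_paths(g2, from = from, to = to, output = "vpath")
  )$vpath[[1]]
  if (length(sp) == 0L) return(NULL)
  as.integer(sp)
}

# Select the macrocycle: the largest smallest-cycle through any candidate
# cleavable bond that is >= 12 atoms and carries >= 2 backbone amide bonds;
# ties broken by amide-bond count, then by first discovery.
.findMacrocycle <- function(mol, candidates) {
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("from", "to")]),
                                   directed = FALSE)
  nmiss <- length(mol$elem) - igraph::vcount(g)
  if (nmiss > 0) g <- igraph::add_vertices(g, nmiss)
  amide <- candidates[candidates$class == "backbone_amide", , drop = FALSE]
  best <- NULL; bestAmides <- -1L
  seen <- character(0)
  for (i in seq_len(nrow(candidates))) {
    ring <- .cycleThroughBond(g, candidates$from[i], candidates$to[i])
    if (is.null(ring) || length(ring) < 12L) next
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    nAm <- .countBondsOnRing(ring, amide)
    if (nAm < 2L) next
    if (is.null(best) || length(ring) > length(best) ||
        (length(ring) == length(best) && nAm > bestAmides)) {
      best <- ring; bestAmides <- nAm
    }
  }
  best
}

# Count candidate bonds joining ring-adjacent atom pairs.
.countBondsOnRing <- function(ring, bonds) {
  if (nrow(bonds) == 0L) return(0L)
  n <- length(ring)
  pos <- match(seq_len(max(c(ring, bonds$from, bonds$to))), ring)
  cnt <- 0L
  for (i in seq_len(nrow(bonds))) {
    pf <- pos[bonds$from[i]]; pt <- pos[bonds$to[i]]
    if (is.na(pf) || is.na(pt)) next
    d <- abs(pf - pt)
    if (d == 1L || d == n - 1L) cnt <- cnt + 1L
  }
  cnt
}

#' Parse a cyclic-peptide SMILES and identify its macrocycle
#'
#' Parses the molecule, locates the macrocycle (the largest ring carrying at
#' least two backbone amide bonds) and collects the cleavable bonds on it:
#' every amide C(=O)-N bond and every S-S bond whose two atoms are adjacent
#' on the ring. Side-chain amides are excluded by construction.
#'
#' @param smiles SMILES string containing exactly one macrocycle closed by
#'   backbone amide bonds and/or one disulfide bond.
#' @param id Peptide identifier carried through downstream tables.
#' @return A \linkS4class{CyclicPeptide}.
#' @examples
#' cp <- parseCyclicPeptide(cycloAlaSmiles(6), "cA6")
#' nrow(cleavableBonds(cp))  # 6 backbone amides
#' @export
parseCyclicPeptide <- function(smiles, id = "peptide") {
  mol <- .parseMol(smiles, id)
  .peptideFromMol(mol, id, canonicalSmiles(smiles))
}

.peptideFromMol <- function(mol, id, canSmiles) {
  cand <- rbind(.amideBonds(mol), .disulfideBonds(mol))
  if (nrow(cand) == 0L)
    stop("not a cyclic peptide: '", id, "' has no amide or disulfide bonds")
  ring <- .findMacrocycle(mol, cand)
  if (is.null(ring))
    stop("not a cyclic peptide: no macrocycle (ring of >= 12 atoms with >= 2 ",
         "backbone amide bonds) found in '", id, "'")
  n <- length(ring)
  pos <- match(seq_len(length(mol$elem)), ring)
  onRing <- vapply(seq_len(nrow(cand)), function(i) {
    pf <- pos[cand$from[i]]; pt <- pos[cand$to[i]]
    !is.na(pf) && !is.na(pt) && (abs(pf - pt) == 1L || abs(pf - pt) == n - 1L)
  }, logical(1))
  cb <- cand[onRing, , drop = FALSE]
  rownames(cb) <- NULL
  if (nrow(cb) < 5L)
    stop("too few residues: '", id, "' has ", nrow(cb),
         " cleavable bonds on the macrocycle; at least 5 required")
  new("CyclicPeptide",
      id = id,
      smiles = canSmiles,
      elem = mol$elem,
      coords = mol$coords,
      bonds = mol$bonds,
      macrocycleAtoms = as.integer(ring),
      cleavableBonds = cb)
}

#' Identify the cleavable bonds of a cyclic peptide
#'
#' Convenience wrapper returning the cleavable-bond table (backbone amide and
#' disulfide bonds on the macrocycle) for a SMILES or a parsed peptide.
#'
#' @param x SMILES string or \linkS4class{CyclicPeptide}.
#' @param id Identifier used when \code{x} is a SMILES string.
#' @return data.frame with columns \code{from}, \code{to}, \code{class}.
#' @export
identifyCleavableBonds <- function(x, id = "peptide") {
  if (is.character(x)) x <- parseCyclicPeptide(x, id)
  cleavableBonds(x)
}

#' Decompose a cyclic peptide into capped residue substructures
#'
#' Cleaves all cleavable bonds simultaneously and caps the cut ends: for each
#' amide cleavage the nitrogen receives a methyl group and the carbonyl side
#' becomes an aldehyde; each disulfide sulfur receives a hydrogen. Fragments
#' are returned in ring-adjacency order (N-to-C along the backbone), starting
#' from a canonical anchor: the fragment whose capped canonical SMILES is
#' lexicographically smallest (full rotated sequence used to break ties), so
#' the result is deterministic.
#'
#' @param x SMILES string or \linkS4class{CyclicPeptide}.
#' @param id Identifier used when \code{x} is a SMILES string.
#' @return A \linkS4class{SubstructureSet}.
#' @examples
#' ss <- decomposePeptide(cycloAlaSmiles(6), "cA6")
#' cappedSmiles(ss)  # six identical capped alanine units
#' @export
decomposePeptide <- function(x, id = "peptide") {
  cp <- if (is.character(x)) parseCyclicPeptide(x, id) else x
  plan <- .fragmentBlocks(cp)
  smis <- .molBlocksToSmiles(plan$blocks)
  .assembleSubstructures(cp, plan, smis)
}

# Cleave all cleavable bonds, cap, and emit per-fragment mol blocks in
# pre-anchor ring order. Returns list(blocks, fragAtoms, nFrag).
.fragmentBlocks <- function(cp) {
  cb <- cp@cleavableBonds
  bonds <- cp@bonds
  elem <- cp@elem
  coords <- cp@coords
  nOrig <- length(elem)

  # drop the cleavable bonds
  key <- function(f, t) paste(pmin(f, t), pmax(f, t))
  drop <- key(cb$from, cb$to)
  keep <- !(key(bonds$from, bonds$to) %in% drop)
  newBonds <- bonds[keep, , drop = FALSE]

  # methyl-cap each amide nitrogen; aldehyde and thiol caps are implicit H
  amide <- cb[cb$class == "backbone_amide", , drop = FALSE]
  for (i in seq_len(nrow(amide))) {
    nAtom <- amide$to[i]
    elem <- c(elem, "C")
    coords <- rbind(coords, coords[nAtom, , drop = FALSE] + c(0.6, 0.6, 0))
    newBonds <- rbind(newBonds,
                      data.frame(from = nAtom, to = length(elem), order = 1L))
  }

  memb <- .components(length(elem), newBonds)
  nFrag <- max(memb)
  if (nFrag != nrow(cb))
    stop("capping failure: cleaving ", nrow(cb), " bonds of '", cp@id,
         "' produced ", nFrag, " fragments")

  # ring-adjacency order: fragments in order of first appearance on the ring,
  # oriented N -> C (the successor of a fragment holding a cleaved carbonyl C
  # is the fragment holding the matching amide N)
  ringMemb <- memb[cp@macrocycleAtoms]
  fragOrder <- unique(ringMemb)
  succ <- rep(NA_integer_, nFrag)
  for (i in seq_len(nrow(amide)))
    succ[memb[amide$from[i]]] <- memb[amide$to[i]]
  ss <- cb[cb$class == "disulfide", , drop = FALSE]
  for (i in seq_len(nrow(ss))) {
    a <- memb[ss$from[i]]; b <- memb[ss$to[i]]
    if (is.na(succ[a]) && a != b) succ[a] <- b
    else if (is.na(succ[b])) succ[b] <- a
  }
  ordered <- integer(nFrag)
  ordered[1] <- fragOrder[1]
  for (i in seq_len(nFrag - 1L)) {
    nxt <- succ[ordered[i]]
    if (is.na(nxt) || nxt %in% ordered[seq_len(i)])
      nxt <- setdiff(fragOrder, ordered[seq_len(i)])[1]
    ordered[i + 1L] <- nxt
  }

  # canonical SMILES per fragment (single batched conversion)
  blocks <- vapply(ordered, function(fr) {
    atoms <- which(memb == fr)
    remap <- integer(length(elem)); remap[atoms] <- seq_along(atoms)
    fb <- newBonds[memb[newBonds$from] == fr, , drop = FALSE]
    .molBlock(elem[atoms], coords[atoms, , drop = FALSE],
              data.frame(from = remap[fb$from], to = remap[fb$to],
                         order = fb$order),
              name = paste0(cp@id, "_frag"))
  }, character(1))
  fragAtoms <- lapply(ordered, function(fr) {
    a <- which(memb == fr)
    sort(a[a <= nOrig])
  })
  list(blocks = blocks, fragAtoms = fragAtoms, nFrag = nFrag)
}

# Anchor the fragment order at the canonical rotation and build the set.
.assembleSubstructures <- function(cp, plan, smis) {
  nFrag <- plan$nFrag
  if (length(smis) != nFrag || anyNA(smis) || any(!nzchar(smis)))
    stop("capping failure: a fragment of '", cp@id,
         "' did not yield a valid molecule")
  # canonical anchor: rotation whose SMILES sequence is lexicographically
  # smallest, anchored at the smallest capped SMILES
  rot <- .anchorRotation(smis)
  idxRot <- ((seq_len(nFrag) - 1L + rot) %% nFrag) + 1L
  new("SubstructureSet",
      peptideId = cp@id,
      table = data.frame(position = 0:(nFrag - 1L),
                         capped_smiles = smis[idxRot],
                         n_total = nFrag),
      parentAtoms = plan$fragAtoms[idxRot])
}

# Rotation offset (0-based) minimizing the rotated SMILES sequence
# lexicographically; ties resolved by earliest rotation index.
.anchorRotation <- function(smis) {
  n <- length(smis)
  starts <- which(smis == min(smis))
  if (length(starts) == 1L) return(starts - 1L)
  seqs <- vapply(starts, function(s) {
    paste(smis[((seq_len(n) - 1L + s - 1L) %% n) + 1L], collapse = "\r")
  }, character(1))
  starts[order(seqs)[1]] - 1L
}

#' Decompose a set of peptides
#'
#' Batch version of \code{\link{decomposePeptide}}: parses, cleaves and
#' canonicalizes all peptides with a constant number of conversion calls,
#' which is substantially faster than looping over peptides.
#'
#' @param smiles Character vector of peptide SMILES.
#' @param ids Peptide identifiers (defaults to names of \code{smiles}).
#' @return Named list of \linkS4class{SubstructureSet}.
#' @export
decomposeSet <- function(smiles, ids = names(smiles)) {
  if (is.null(ids)) ids <- paste0("peptide", seq_along(smiles))
  mols <- .parseMols(smiles, ids)
  # the batch path stores the input SMILES on the peptide objects; per-SMILES
  # canonicalization of whole macrocycles is costly and only cosmetic here
  cps <- lapply(seq_along(mols), function(i)
    .peptideFromMol(mols[[i]], ids[i], smiles[i]))
  plans <- lapply(cps, .fragmentBlocks)
  allBlocks <- unlist(lapply(plans, `[[`, "blocks"))
  allSmis <- .molBlocksToSmiles(allBlocks)
  counts <- vapply(plans, function(p) as.integer(p$nFrag), integer(1))
  if (length(allSmis) != sum(counts))
    stop("capping failure: ", sum(counts) - length(allSmis),
         " fragment(s) did not yield a valid molecule")
  ends <- cumsum(counts)
  out <- lapply(seq_along(cps), function(i) {
    smis <- allSmis[(ends[i] - counts[i] + 1L):ends[i]]
    .assembleSubstructures(cps[[i]], plans[[i]], smis)
  })
  names(out) <- ids
  out
}

#' Decompose a table of peptides
#'
#' Applies the decomposition to each row of a peptide table and returns the
#' stacked substructure table.
#'
#' @param records data.frame with columns \code{id} and \code{smiles}.
#' @return data.frame with columns \code{peptide_id}, \code{position},
#'   \code{capped_smiles}, \code{n_total}.
#' @export
decomposeTable <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  sets <- decomposeSet(records$smiles, records$id)
  out <- lapply(sets, function(ss)
    cbind(peptide_id = ss@peptideId, ss@table))
  ret <- do.call(rbind, out)
  rownames(ret) <- NULL
  ret
}

#' Head-to-tail cyclo-oligoalanine SMILES
#'
#' Convenience constructor for \code{cyclo(Ala)n}, the canonical small test
#' peptide of the decomposition rules.
#'
#' @param n Number of alanine residues (>= 3).
#' @return SMILES string.
#' @export
cycloAlaSmiles <- function(n = 6L) {
  stopifnot(n >= 3L)
  paste0("N%99C(C)C(=O)", strrep("NC(C)C(=O)", n - 2L), "NC(C)C%99=O")
}
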