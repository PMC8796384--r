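# Internal chemistry helpers built on ChemmineR/ChemmineOB (OpenBabel).
# Molecules are held as plain atom/bond tables; ChemmineR has no graph-edit
# API, so edited fragments are re-emitted as V2000 mol blocks and pushed back
# through OpenBabel for canonicalization.

# Parse SMILES into an atom/bond table representation.
# Returns list(elem = character, coords = n x 3 matrix, bonds = data.frame(from, to, order)).
.parseMol <- function(smiles, id = "mol") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("invalid SMILES input: empty or not a string")
  if (exists(smiles, envir = .molCache))
    return(get(smiles, envir = .molCache))
  names(smiles) <- id
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]],
    error = function(e) stop("unparseable SMILES for '", id, "': ", conditionMessage(e))
  )
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L)
    stop("unparseable SMILES for '", id, "': no atoms")
  elem <- sub("_.*$", "", rownames(ab))
  bonds <- .bondTable(ChemmineR::bondblock(sdf))
  coords <- .coordTable(ab)
  mol <- list(elem = elem, coords = coords, bonds = bonds)
  assign(unname(smiles), mol, envir = .molCache)
  mol
}

# Coordinate matrix from a ChemmineR atom block (pads to 3 columns).
.coordTable <- function(ab) {
  k <- min(3L, ncol(ab))
  out <- matrix(0, nrow(ab), 3L)
  out[, seq_len(k)] <- ab[, seq_len(k)]
  out
}

# Bond table from a ChemmineR bond block (may be empty for single atoms).
.bondTable <- function(bb) {
  if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L)
    return(data.frame(from = integer(0), to = integer(0), order = integer(0)))
  data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
}

# Assemble a V2000 mol block from atom/bond tables.
.molBlock <- function(elem, coords, bonds, name = "frag") {
  nat <- length(elem)
  nbd <- nrow(bonds)
  out <- character(4L + nat + nbd + 2L)
  out[1] <- name
  out[2] <- " MacrocyclePPB"
  out[3] <- ""
  out[4] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nat, nbd)
  out[4L + seq_len(nat)] <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    coords[, 1], coords[, 2], coords[, 3], elem
  )
  if (nbd > 0L)
    out[4L + nat + seq_len(nbd)] <- sprintf(
      "%3d%3d%3d  0  0  0  0", bonds$from, bonds$to, bonds$order
    )
  out[4L + nat + nbd + 1L] <- "M  END"
  out[4L + nat + nbd + 2L] <- "$$$$"
  paste(out, collapse = "\n")
}

#' Canonical SMILES
#'
#' Canonicalizes a vector of SMILES strings in a single OpenBabel call;
#' unparseable entries come back as NA. Two SMILES denote the same molecule
#' exactly when their canonical forms are equal.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES.
#' @export
canonicalSmiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  tags <- paste0("q", seq_along(smiles))
  input <- paste0(paste(smiles, tags, sep = "\t", collapse = "\n"), "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", input),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(smiles))
  for (p in parts) {
    if (length(p) >= 2L) {
      i <- match(trimws(p[2]), tags)
      if (!is.na(i)) res[i] <- p[1]
    }
  }
  res
}

# Canonical SMILES for a set of mol blocks (joined, one conversion call).
.molBlocksToSmiles <- function(blocks) {
  if (length(blocks) == 0L) return(character(0))
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
}

# Gasteiger (PEOE) partial charges per heavy atom, via OpenBabel mol2 output
# computed from SDF blocks (fast; no SMILES re-read).
# Returns a list of numeric vectors aligned with .parseMol atom order.
.gasteigerCharges <- function(blocks) {
  if (length(blocks) == 0L) return(list())
  input <- paste0(paste(blocks, collapse = "\n"), "\n")
  out <- ChemmineOB::convertFormat("SDF", "MOL2", input)
  mols <- strsplit(out, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  mols <- mols[-1]
  if (length(mols) != length(blocks))
    stop("partial charge computation failed: ", length(mols), " of ",
         length(blocks), " molecules converted")
  lapply(mols, function(m) {
    seg <- strsplit(m, "@<TRIPOS>", fixed = TRUE)[[1]]
    atomseg <- seg[startsWith(seg, "ATOM")]
    if (length(atomseg) == 0L) return(numeric(0))
    lines <- strsplit(sub("^ATOM\n?", "", atomseg[1]), "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    vapply(strsplit(trimws(lines), "\\s+"), function(f) as.numeric(f[length(f)]),
           numeric(1))
  })
}

# SMILES reading dominates run time for macrocycles (ring/stereo perception
# in the reader), so parsed molecules are memoized by their SMILES string;
# all later operations run off the parsed tables or SDF blocks.
.molCache <- new.env(parent = emptyenv())

# Batch-parse SMILES in one OpenBabel call; falls back to per-molecule
# parsing when the batch drops entries. Returns a list of mol tables.
.parseMols <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  out <- vector("list", length(smiles))
  cached <- vapply(smiles, exists, logical(1), envir = .molCache)
  out[cached] <- mget(smiles[cached], envir = .molCache)
  todo <- which(!cached)
  if (length(todo) == 0L) return(out)
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(smiles[todo], ids[todo]))),
    error = function(e) NULL
  )
  if (is.null(sdfs) || length(sdfs) != length(todo)) {
    out[todo] <- lapply(todo, function(i) .parseMol(smiles[i], ids[i]))
    return(out)
  }
  for (j in seq_along(todo)) {
    i <- todo[j]
    ab <- ChemmineR::atomblock(sdfs[[j]])
    if (is.null(ab) || nrow(ab) == 0L)
      stop("unparseable SMILES for '", ids[i], "'")
    mol <- list(elem = sub("_.*$", "", rownames(ab)),
                coords = .coordTable(ab),
                bonds = .bondTable(ChemmineR::bondblock(sdfs[[j]])))
    assign(smiles[i], mol, envir = .molCache)
    out[[i]] <- mol
  }
  out
}

# Adjacency list from a bond table.
.adjacency <- function(nat, bonds) {
  adj <- vector("list", nat)
  for (i in seq_len(nrow(bonds))) {
    f <- bonds$from[i]; t <- bonds$to[i]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  adj
}

# Connected components over atoms; returns integer membership vector.
.components <- function(nat, bonds) {
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("from", "to")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nat - igraph::vcount(g)))
  igraph::components(g)$membership
}
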