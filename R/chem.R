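# Chemical-graph plumbing: OpenBabel glue (via ChemmineOB), a minimal
# SYBYL-MOL2 reader/writer used as the exchange format with OpenBabel, and
# distance-based bond perception for het groups.

.OB_NOOPT <- data.frame(names = character(0), args = character(0))

ob_convert <- function(from, to, text, options = .OB_NOOPT) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text, options = options),
                  error = function(e) "")
  if (!nzchar(out)) return(NA_character_)
  out
}

# ---- MOL2 ------------------------------------------------------------------

sybyl_type <- function(element, aromatic) {
  ifelse(element == "*", "Du",
    ifelse(aromatic, paste0(element, ".ar"),
      ifelse(element %in% c("C", "N", "O", "S", "P"), paste0(element, ".3"),
             element)))
}

# atoms: data.frame(element, x, y, z); aromatic: logical; bonds: (i, j, order)
# with order in {"1","2","3","ar","am"}. charges optional.
mol2_from_graph <- function(atoms, bonds, aromatic = NULL, charges = NULL,
                            name = "frag") {
  n <- nrow(atoms)
  if (is.null(aromatic)) aromatic <- rep(FALSE, n)
  q <- if (is.null(charges)) rep(0, n) else charges
  at <- sprintf("%7d %-4s %9.4f %9.4f %9.4f %-6s %3d UNL %9.4f",
                seq_len(n),
                ifelse(atoms$element == "*", "Du",
                       paste0(atoms$element, seq_len(n))),
                atoms$x, atoms$y, atoms$z,
                sybyl_type(atoms$element, aromatic), 1L, q)
  m <- nrow(bonds)
  bd <- if (m) sprintf("%6d %5d %5d %4s", seq_len(m), bonds$i, bonds$j,
                       bonds$order) else character(0)
  paste(c("@<TRIPOS>MOLECULE", name, sprintf(" %d %d 0 0 0", n, m), "SMALL",
          if (is.null(charges)) "NO_CHARGES" else "USER_CHARGES", "",
          "@<TRIPOS>ATOM", at, "@<TRIPOS>BOND", bd, ""), collapse = "\n")
}

parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sec <- which(startsWith(lines, "@<TRIPOS>"))
  take <- function(tag) {
    i <- which(lines == paste0("@<TRIPOS>", tag))[1]
    if (is.na(i)) return(character(0))
    nxt <- sec[sec > i]
    j <- if (length(nxt)) min(nxt) - 1L else length(lines)
    ln <- lines[seq(i + 1L, j)]
    ln[nzchar(trimws(ln))]
  }
  al <- take("ATOM")
  if (!length(al)) return(NULL)
  f <- strsplit(trimws(al), "[[:space:]]+")
  type <- vapply(f, `[`, "", 6)
  atoms <- data.frame(
    element = normalize_element(sub("\\..*$", "", type)),
    x = as.numeric(vapply(f, `[`, "", 3)),
    y = as.numeric(vapply(f, `[`, "", 4)),
    z = as.numeric(vapply(f, `[`, "", 5)),
    stringsAsFactors = FALSE)
  atoms$element[atoms$element %in% c("Du", "Xx", "Any")] <- "*"
  aromatic <- grepl("\\.ar$", type)
  charges <- vapply(f, function(v) if (length(v) >= 9)
    suppressWarnings(as.numeric(v[9])) else NA_real_, 0)
  bl <- take("BOND")
  bonds <- if (length(bl)) {
    g <- strsplit(trimws(bl), "[[:space:]]+")
    data.frame(i = as.integer(vapply(g, `[`, "", 2)),
               j = as.integer(vapply(g, `[`, "", 3)),
               order = vapply(g, `[`, "", 4), stringsAsFactors = FALSE)
  } else data.frame(i = integer(0), j = integer(0), order = character(0),
                    stringsAsFactors = FALSE)
  list(atoms = atoms, aromatic = aromatic, charges = charges, bonds = bonds)
}

# ---- bond perception -------------------------------------------------------

#' Perceive the chemical graph of a ligand from its coordinates
#'
#' Connectivity is the union of any deposited \code{CONECT} bonds with
#' distance-perceived bonds: two heavy atoms are bonded iff their distance is
#' at most the sum of their covalent radii plus a fudge factor (default
#' 0.4 Angstrom). Bond orders and aromaticity are then completed by
#' OpenBabel's valence/ring perception on the same coordinates and
#' connectivity.
#'
#' @param ligand an \code{lsr_ligand} (from \code{\link{parse_structure}}).
#' @param fudge tolerance added to the covalent-radius sum, Angstrom.
#' @return The ligand with \code{bonds} (orders in \code{"1","2","3","ar"}),
#'   per-atom \code{aromatic} flags and \code{perceived = TRUE}.
#' @export
perceive_ligand_graph <- function(ligand, fudge = 0.4) {
  stopifnot(inherits(ligand, "lsr_ligand"))
  a <- ligand$atoms
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (n > 1) {
    D <- as.matrix(dist(xyz))
    diag(D) <- Inf
    if (any(D < 0.5))
      stop(sprintf("perceive_ligand_graph: atom clash (< 0.5 A) in %s/%s/%d",
                   ligand$het_code, ligand$chain, ligand$resno))
    rc <- covalent_radius(a$element)
    thr <- outer(rc, rc, "+") + fudge
    hit <- which(D <= thr & upper.tri(D), arr.ind = TRUE)
    bonds <- data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
                        order = rep("1", nrow(hit)), stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                        stringsAsFactors = FALSE)
  }
  if (nrow(ligand$bonds)) {
    bonds <- rbind(bonds, ligand$bonds[, c("i", "j", "order")])
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    bonds <- bonds[!duplicated(key), , drop = FALSE]
    bonds[, c("i", "j")] <- cbind(pmin(bonds$i, bonds$j),
                                  pmax(bonds$i, bonds$j))
  }
  rownames(bonds) <- NULL
  ligand$bonds <- bonds
  ligand$aromatic <- rep(FALSE, n)

  # bond orders / aromaticity: OpenBabel on the same coordinates + CONECT
  if (n > 1 && nrow(bonds)) {
    pdb <- c(pdb_atom_line("HETATM", seq_len(n), paste0(a$element, seq_len(n)),
                           rep(substr(ligand$het_code, 1, 3), n),
                           rep("A", n), rep(1L, n), a$x, a$y, a$z,
                           rep(1, n), a$element),
             sprintf("CONECT%5d%5d", bonds$i, bonds$j),
             sprintf("CONECT%5d%5d", bonds$j, bonds$i), "END")
    m2 <- ob_convert("PDB", "MOL2", paste(pdb, collapse = "\n"))
    p <- if (!is.na(m2)) parse_mol2(m2) else NULL
    if (!is.null(p) && nrow(p$atoms) == n) {
      ligand$aromatic <- p$aromatic
      if (nrow(p$bonds)) {
        ok <- paste(pmin(p$bonds$i, p$bonds$j), pmax(p$bonds$i, p$bonds$j))
        mk <- match(paste(bonds$i, bonds$j), ok)
        ord <- p$bonds$order[mk]
        ord[is.na(ord) | !(ord %in% c("1", "2", "3", "ar"))] <- "1"
        ord[ord == "am"] <- "1"
        ligand$bonds$order <- ord
      }
    } else {
      warning(sprintf(
        "perceive_ligand_graph: order perception unavailable for %s/%s/%d; all bonds kept single",
        ligand$het_code, ligand$chain, ligand$resno))
    }
    resc <- aromatic_ring_rescue(ligand$atoms, ligand$bonds, ligand$aromatic)
    ligand$aromatic <- resc$aromatic
    ligand$bonds <- resc$bonds
  }
  ligand$perceived <- TRUE
  ligand
}

# all simple cycles of length 5 or 6 (unique atom sets) -- small molecules
ring_cycles <- function(n, bonds, sizes = c(5L, 6L)) {
  adj <- bond_adjacency(n, bonds)
  found <- list()
  seen <- character(0)
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1] && length(path) %in% sizes) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) { seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- path }
      } else if (!(w %in% path) && length(path) < max(sizes) && w > path[1]) {
        dfs(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  found
}

# geometric ring-aromaticity rescue: a 5/6-ring of C/N/O/S atoms that is
# near-planar with aromatic-range bond lengths is flagged aromatic even when
# the toolkit's order perception balked (coordinate noise makes that step
# brittle). Tolerances: max out-of-plane deviation 0.25 A (roughly 2.5x a
# typical coordinate uncertainty), mean ring bond length in [1.25, 1.47] A
# (excludes saturated rings at ~1.54 A).
aromatic_ring_rescue <- function(atoms, bonds, aromatic,
                                 plane_tol = 0.25, len_range = c(1.25, 1.47)) {
  n <- nrow(atoms)
  if (n < 5 || !nrow(bonds)) return(list(aromatic = aromatic, bonds = bonds))
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  bkey <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  for (ring in ring_cycles(n, bonds)) {
    el <- atoms$element[ring]
    if (!all(el %in% c("C", "N", "O", "S"))) next
    if (any(deg[ring] > 3)) next
    P <- sweep(xyz[ring, , drop = FALSE], 2,
               colMeans(xyz[ring, , drop = FALSE]))
    sv <- svd(P)
    dev <- abs(P %*% sv$v[, 3])
    if (max(dev) > plane_tol) next
    pairs <- cbind(ring, c(ring[-1], ring[1]))
    blen <- sqrt(rowSums((xyz[pairs[, 1], ] - xyz[pairs[, 2], ])^2))
    mlen <- mean(blen)
    if (mlen < len_range[1] || mlen > len_range[2]) next
    aromatic[ring] <- TRUE
    rkey <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    bonds$order[bkey %in% rkey] <- "ar"
  }
  list(aromatic = aromatic, bonds = bonds)
}

# adjacency list of a bond table over n atoms
bond_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# connected components of an atom subset (indices into the ligand) under the
# induced bonds; returns list of integer vectors
graph_components <- function(n, bonds, subset = seq_len(n)) {
  if (!length(subset)) return(list())
  sub <- sort(subset)
  b <- bonds[bonds$i %in% sub & bonds$j %in% sub, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(b$i), to = as.character(b$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(sub)))
  cm <- igraph::components(g)$membership
  split(as.integer(names(cm)), cm)
}

# logical per bond row: is this bond part of a cycle (i.e. not a bridge)?
bond_in_cycle <- function(n, bonds) {
  if (!nrow(bonds)) return(logical(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$i, to = bonds$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(bonds))
  res[as.integer(br)] <- FALSE
  res
}

has_cycle <- function(n_atoms, bonds, n_components) {
  nrow(bonds) >= n_atoms - n_components + 1
}

# ---- canonical SMILES ------------------------------------------------------

# canonical SMILES of an atom/bond graph via OpenBabel; wildcard atoms ("*")
# survive as "*" in the output.
graph_to_canonical_smiles <- function(atoms, bonds, aromatic) {
  deg <- tabulate(c(bonds$i, bonds$j), nbins = nrow(atoms))
  maxd <- .MAX_DEGREE[atoms$element]
  maxd[is.na(maxd)] <- 8
  over <- which(atoms$element != "*" & deg > maxd)
  if (length(over))
    stop(sprintf("impossible valence: %s with %d bonds",
                 atoms$element[over[1]], deg[over[1]]))
  m2 <- mol2_from_graph(atoms, bonds, aromatic)
  smi <- ob_convert("MOL2", "CAN", m2)
  if (is.na(smi)) stop("canonical SMILES generation failed")
  trimws(strsplit(smi, "[\t\n]")[[1]][1])
}

#' Canonicalize a SMILES string
#'
#' Canonical SMILES via OpenBabel; isomorphic inputs give identical output.
#'
#' @param smiles a SMILES string.
#' @return The canonical SMILES.
#' @examples
#' canonical_smiles("c1ccncc1") == canonical_smiles("n1ccccc1")  # TRUE
#' @export
canonical_smiles <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  if (is.na(out))
    stop(sprintf("canonical_smiles: unparseable SMILES \"%s\"", smiles))
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}

# parse a SMILES string into a graph (atoms/aromatic/bonds) via OpenBabel;
# explicit hydrogens are dropped. Returns NULL on failure.
smiles_to_graph <- function(smiles) {
  m2 <- ob_convert("SMI", "MOL2", smiles)
  if (is.na(m2)) return(NULL)
  p <- parse_mol2(m2)
  if (is.null(p)) return(NULL)
  keep <- p$atoms$element != "H"
  if (!all(keep)) {
    idx <- which(keep)
    remap <- match(seq_along(keep), idx)
    b <- p$bonds[p$bonds$i %in% idx & p$bonds$j %in% idx, , drop = FALSE]
    b$i <- remap[b$i]; b$j <- remap[b$j]
    p <- list(atoms = p$atoms[keep, , drop = FALSE],
              aromatic = p$aromatic[keep], charges = p$charges[keep],
              bonds = b)
    rownames(p$atoms) <- NULL
  }
  p
}
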