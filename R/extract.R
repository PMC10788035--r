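# Probe-sphere fragment extraction: spheres centred on the matched
# reference-fragment atoms capture superposed target-ligand atoms, which are
# induced into chemically complete replacement fragments.

#' Construct a probe set
#'
#' A probe set is a collection of spheres of common radius (default
#' 2.5 Angstrom) centred on the coordinates of the matched
#' reference-fragment atoms.
#'
#' @param centers n x 3 matrix of sphere centres (Angstrom).
#' @param radius sphere radius, Angstrom (> 0).
#' @return Object of class \code{lsr_probes}.
#' @export
probe_set <- function(centers, radius = 2.5) {
  centers <- as.matrix(centers)
  if (!nrow(centers) || ncol(centers) != 3)
    stop("probe_set: centers must be a non-empty n x 3 matrix")
  if (!is.numeric(radius) || radius <= 0) stop("probe_set: radius must be > 0")
  if (!all(is.finite(centers))) stop("probe_set: non-finite center coordinates")
  structure(list(centers = centers, radius = radius), class = "lsr_probes")
}

#' Capture ligand atoms inside the probe spheres
#'
#' An atom index is captured iff its minimum distance to any probe centre is
#' at most the probe radius (closed ball: an atom exactly on the boundary is
#' included). Heavy atoms only; the ligand must already sit in the
#' reference frame (superposed).
#'
#' @param probes an \code{lsr_probes}.
#' @param ligand an \code{lsr_ligand}.
#' @return Sorted integer vector of captured ligand atom indices (possibly
#'   empty).
#' @export
capture_atoms <- function(probes, ligand) {
  stopifnot(inherits(probes, "lsr_probes"), inherits(ligand, "lsr_ligand"))
  xyz <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  if (!nrow(xyz)) return(integer(0))
  C <- probes$centers
  d2 <- outer(rowSums(xyz^2), rowSums(C^2), "+") - 2 * xyz %*% t(C)
  d2[d2 < 0] <- 0
  which(sqrt(apply(d2, 1, min)) <= probes$radius)
}

#' Induce replacement fragments from captured atoms
#'
#' The subgraph induced on the captured atoms is split into connected
#' components; each component becomes one fragment. Every bond from a
#' captured atom to an uncaptured neighbour is cut and counted as one
#' attachment. Organic components smaller than \code{min_atoms} are
#' discarded; single-atom metal ions are exempt (ions can act as local
#' structural replacements).
#'
#' @param ligand a perceived \code{lsr_ligand}.
#' @param captured integer vector of captured atom indices.
#' @param min_atoms minimum heavy-atom count for organic fragments
#'   (default 3).
#' @return List of \code{lsr_fragment} objects: atom table (with
#'   coordinates), induced bonds, per-atom aromatic flags,
#'   \code{attachment_count}, \code{cut_positions} (coordinates of the lost
#'   neighbours, used to place attachment caps), and empty provenance.
#' @export
induce_fragments <- function(ligand, captured, min_atoms = 3) {
  stopifnot(inherits(ligand, "lsr_ligand"))
  captured <- sort(unique(as.integer(captured)))
  if (!length(captured)) return(list())
  if (any(captured < 1 | captured > nrow(ligand$atoms)))
    stop("induce_fragments: captured indices out of range")
  comps <- graph_components(nrow(ligand$atoms), ligand$bonds, captured)
  out <- list()
  for (comp in comps) {
    comp <- sort(comp)
    single_metal <- length(comp) == 1L && is_metal(ligand$atoms$element[comp])
    if (length(comp) < min_atoms && !single_metal) next
    b <- ligand$bonds
    inside <- b$i %in% comp & b$j %in% comp
    cut <- xor(b$i %in% comp, b$j %in% comp)
    remap <- match(seq_len(nrow(ligand$atoms)), comp)
    bonds <- data.frame(i = remap[b$i[inside]], j = remap[b$j[inside]],
                        order = b$order[inside], stringsAsFactors = FALSE)
    lost <- ifelse(b$i[cut] %in% comp, b$j[cut], b$i[cut])
    anchor <- ifelse(b$i[cut] %in% comp, b$i[cut], b$j[cut])
    cuts <- if (any(cut)) data.frame(
      anchor = remap[anchor],
      x = ligand$atoms$x[lost], y = ligand$atoms$y[lost],
      z = ligand$atoms$z[lost]) else
      data.frame(anchor = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0))
    frag <- structure(list(
      atoms = ligand$atoms[comp, c("serial", "name", "element", "x", "y", "z"),
                           drop = FALSE],
      bonds = bonds,
      aromatic = ligand$aromatic[comp],
      attachment_count = sum(cut),
      cut_positions = cuts,
      smiles = NA_character_,
      fitness = NULL,
      provenance = data.frame(ref_entry = character(0), ref_het = character(0),
                              target_entry = character(0),
                              target_het = character(0),
                              stringsAsFactors = FALSE)),
      class = "lsr_fragment")
    rownames(frag$atoms) <- NULL
    out[[length(out) + 1L]] <- frag
  }
  out
}

#' @export
print.lsr_fragment <- function(x, ...) {
  cat(sprintf("<lsr_fragment> %d atoms, %d bonds, %d attachment(s)%s%s\n",
              nrow(x$atoms), nrow(x$bonds), x$attachment_count,
              if (!is.na(x$smiles)) paste0(", SMILES ", x$smiles) else "",
              if (!is.null(x$fitness))
                sprintf(", fitness %.3f", x$fitness$combined) else ""))
  invisible(x)
}

#' Canonical SMILES of an extracted fragment
#'
#' Cut bonds are capped with wildcard attachment atoms placed at the
#' coordinates of the lost neighbours; remaining valence is filled with
#' implicit hydrogens by the SMILES writer. Aromatic flags are kept only for
#' bonds that still lie in a ring of the fragment (a broken aromatic ring is
#' emitted as a plain chain). Output is canonical: isomorphic fragments give
#' identical strings.
#'
#' @param fragment an \code{lsr_fragment}.
#' @return The fragment with \code{smiles} set.
#' @export
fragment_to_smiles <- function(fragment) {
  stopifnot(inherits(fragment, "lsr_fragment"))
  atoms <- fragment$atoms[, c("element", "x", "y", "z")]
  bonds <- fragment$bonds
  aromatic <- fragment$aromatic
  # demote aromaticity on bonds no longer inside a ring
  if (nrow(bonds)) {
    inring <- bond_in_cycle(nrow(atoms), bonds)
    demote <- bonds$order == "ar" & !inring
    bonds$order[demote] <- "1"
    ar_atoms <- unique(c(bonds$i[bonds$order == "ar"],
                         bonds$j[bonds$order == "ar"]))
    aromatic <- seq_len(nrow(atoms)) %in% ar_atoms
  } else aromatic <- rep(FALSE, nrow(atoms))
  # cap each cut bond with a wildcard at the lost neighbour's position
  cp <- fragment$cut_positions
  if (nrow(cp)) {
    base <- nrow(atoms)
    atoms <- rbind(atoms, data.frame(element = rep("*", nrow(cp)),
                                     x = cp$x, y = cp$y, z = cp$z))
    bonds <- rbind(bonds, data.frame(i = cp$anchor,
                                     j = base + seq_len(nrow(cp)),
                                     order = "1", stringsAsFactors = FALSE))
    aromatic <- c(aromatic, rep(FALSE, nrow(cp)))
  }
  smi <- tryCatch(graph_to_canonical_smiles(atoms, bonds, aromatic),
                  error = function(e) stop(sprintf(
                    "fragment_to_smiles [%s]: %s",
                    paste(fragment$provenance$target_entry, collapse = ","),
                    conditionMessage(e)), call. = FALSE))
  fragment$smiles <- smi
  fragment
}

#' Deduplicate fragments by canonical SMILES
#'
#' Keeps one representative per canonical SMILES -- the highest-fitness
#' instance -- and accumulates all provenances onto the representative.
#'
#' @param fragments list of \code{lsr_fragment} with \code{smiles} set.
#' @return Deduplicated list, input order of first occurrence preserved.
#' @export
deduplicate <- function(fragments) {
  if (!length(fragments)) return(list())
  smi <- vapply(fragments, function(f) f$smiles, "")
  if (anyNA(smi)) stop("deduplicate: fragments must have SMILES set")
  fit <- vapply(fragments, function(f)
    if (is.null(f$fitness)) -Inf else f$fitness$combined, 0)
  out <- list()
  for (s in unique(smi)) {
    idx <- which(smi == s)
    best <- idx[which.max(fit[idx])]
    rep_frag <- fragments[[best]]
    rep_frag$provenance <- unique(do.call(
      rbind, lapply(fragments[idx], function(f) f$provenance)))
    rownames(rep_frag$provenance) <- NULL
    out[[length(out) + 1L]] <- rep_frag
  }
  out
}

#' Write fragments as an SDF file
#'
#' V2000 blocks with 3D coordinates; aromatic bonds use bond type 4;
#' wildcard caps are written as \code{"*"} atoms. SMILES, fitness and
#' provenance are attached as data fields.
#'
#' @param fragments list of \code{lsr_fragment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fragments_sdf <- function(fragments, path) {
  blocks <- vapply(seq_along(fragments), function(k) {
    f <- fragments[[k]]
    atoms <- f$atoms[, c("element", "x", "y", "z")]
    bonds <- f$bonds
    cp <- f$cut_positions
    aromatic <- f$aromatic
    if (nrow(cp)) {
      base <- nrow(atoms)
      atoms <- rbind(atoms, data.frame(element = rep("*", nrow(cp)),
                                       x = cp$x, y = cp$y, z = cp$z))
      bonds <- rbind(bonds, data.frame(i = cp$anchor,
                                       j = base + seq_len(nrow(cp)),
                                       order = "1"))
      aromatic <- c(aromatic, rep(FALSE, nrow(cp)))
    }
    otype <- ifelse(bonds$order == "ar", 4L,
                    ifelse(bonds$order %in% c("2", "3"),
                           as.integer(bonds$order), 1L))
    paste(c(
      sprintf("fragment_%d", k), "  lsrsearch          3D", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              nrow(atoms), nrow(bonds)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              atoms$x, atoms$y, atoms$z,
              ifelse(atoms$element == "*", "*", atoms$element)),
      if (nrow(bonds)) sprintf("%3d%3d%3d  0", bonds$i, bonds$j, otype),
      "M  END",
      "> <SMILES>", f$smiles, "",
      "> <FITNESS>",
      if (is.null(f$fitness)) "NA" else sprintf("%.4f", f$fitness$combined), "",
      "> <PROVENANCE>",
      if (nrow(f$provenance)) paste(f$provenance$ref_entry, f$provenance$ref_het,
                                    f$provenance$target_entry,
                                    f$provenance$target_het, sep = "/",
                                    collapse = "; ") else "NA", "",
      "$$$$"), collapse = "\n")
  }, "")
  writeLines(blocks, path)
  invisible(path)
}
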