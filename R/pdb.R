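# PDB-format structure I/O: fixed-column ATOM/HETATM/CONECT records.
# Heavy-atom pipeline: hydrogens/deuteriums are discarded on input. Only the
# first NMR model is read. Waters (HOH/WAT/DOD) are never ligands. Atom and
# residue numbering is kept exactly as printed in the file so provenance can
# echo PDB numbering.

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")
# HETATM residues that are really polymer residues (selenomethionine).
.POLYMER_HET <- c("MSE")

substr_trim <- function(x, a, b) trimws(substring(x, a, b))

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Parse a PDB-format structure
#'
#' Reads fixed-column \code{ATOM}/\code{HETATM}/\code{CONECT} records into a
#' protein-ligand complex: polymer residues grouped into chains, het groups
#' (except water) collected as ligand instances, \code{CONECT} records kept
#' as bonds. Hydrogens are dropped; of alternate locations the
#' highest-occupancy conformer is kept (ties broken in favour of altloc
#' \code{"A"}); only the first model of a multi-model file is read.
#'
#' @param text PDB-format text (single string or character vector of lines).
#' @param entry_id identifier stored on the result; defaults to the
#'   \code{HEADER} id if present, else \code{"XXXX"}.
#' @return An object of class \code{lsr_complex}: a list with
#'   \code{entry_id}, \code{atoms} (polymer-atom data frame), and
#'   \code{ligands} (list of \code{lsr_ligand}, each with het code, chain,
#'   residue number, atom table and bond table).
#' @examples
#' pdb <- paste(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
#'   "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
#'   sep = "\n")
#' cx <- parse_structure(pdb)
#' length(cx$ligands)  # 0
#' @export
parse_structure <- function(text, entry_id = NULL) {
  if (length(text) == 0L || !any(nzchar(text)))
    stop("parse_structure: empty input")
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text

  if (is.null(entry_id)) {
    hdr <- grep("^HEADER", lines, value = TRUE)
    entry_id <- if (length(hdr) && nchar(hdr[1]) >= 66)
      substr_trim(hdr[1], 63, 66) else "XXXX"
    if (!nzchar(entry_id)) entry_id <- "XXXX"
  }

  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("parse_structure: no ATOM or HETATM records")

  idx <- which(is_atom)
  al <- lines[idx]
  serial <- num_or_na(substring(al, 7, 11))
  name <- substr_trim(al, 13, 16)
  altloc <- substring(al, 17, 17)
  resname <- substr_trim(al, 18, 20)
  chain <- substring(al, 22, 22)
  resno <- num_or_na(substring(al, 23, 26))
  icode <- substring(al, 27, 27)
  x <- num_or_na(substring(al, 31, 38))
  y <- num_or_na(substring(al, 39, 46))
  z <- num_or_na(substring(al, 47, 54))
  occ <- num_or_na(substring(al, 55, 60))
  occ[is.na(occ)] <- 1
  element <- substr_trim(al, 77, 78)
  # fall back on the atom-name column when the element field is blank
  blank <- !nzchar(element)
  element[blank] <- sub("^[0-9']*", "", name[blank])
  element[blank] <- sub("[0-9'].*$", "", element[blank])
  element <- normalize_element(element)

  bad <- which(is.na(serial) | is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("parse_structure: malformed record at line %d: %s",
                 idx[bad[1]], lines[idx[bad[1]]]))

  atoms <- data.frame(
    serial = serial, name = name, altloc = altloc, resname = resname,
    chain = chain, resno = resno, icode = icode,
    x = x, y = y, z = z, occupancy = occ, element = element,
    is_het = rec[idx] == "HETATM", stringsAsFactors = FALSE)

  # heavy atoms only
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per atom site; ties -> 'A'
  # (blank altloc sorts ahead so unique sites are untouched).
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname, atoms$name)
  if (anyDuplicated(key)) {
    pref <- order(key, -atoms$occupancy, atoms$altloc != " " & atoms$altloc != "A")
    atoms <- atoms[pref, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                     atoms$resname, atoms$name)), , drop = FALSE]
    atoms <- atoms[order(match(atoms$serial, serial)), , drop = FALSE]
  }

  # MSE and friends are polymer residues even though deposited as HETATM
  atoms$is_het[atoms$resname %in% .POLYMER_HET] <- FALSE
  # drop waters entirely
  atoms <- atoms[!(atoms$resname %in% .WATER_CODES), , drop = FALSE]
  rownames(atoms) <- NULL

  poly <- atoms[!atoms$is_het, , drop = FALSE]
  het <- atoms[atoms$is_het, , drop = FALSE]

  # CONECT records: pairs of serial numbers (col 7-11 plus up to 4 partners)
  conect <- matrix(numeric(0), ncol = 2)
  cl <- lines[rec == "CONECT"]
  if (length(cl)) {
    pairs <- lapply(cl, function(s) {
      f <- num_or_na(c(substring(s, 7, 11), substring(s, 12, 16),
                       substring(s, 17, 21), substring(s, 22, 26),
                       substring(s, 27, 31)))
      f <- f[!is.na(f)]
      if (length(f) >= 2) cbind(f[1], f[-1]) else NULL
    })
    conect <- do.call(rbind, pairs)
    if (is.null(conect)) conect <- matrix(numeric(0), ncol = 2)
  }

  ligands <- list()
  if (nrow(het)) {
    grp <- split(seq_len(nrow(het)),
                 paste(het$resname, het$chain, het$resno, het$icode, sep = "\r"))
    ligands <- lapply(grp, function(ii) {
      a <- het[ii, c("serial", "name", "element", "x", "y", "z", "occupancy"),
               drop = FALSE]
      rownames(a) <- NULL
      bonds <- data.frame(i = integer(0), j = integer(0),
                          order = character(0), stringsAsFactors = FALSE)
      if (nrow(conect)) {
        mi <- match(conect[, 1], a$serial)
        mj <- match(conect[, 2], a$serial)
        keep <- !is.na(mi) & !is.na(mj)
        if (any(keep)) {
          b <- cbind(pmin(mi[keep], mj[keep]), pmax(mi[keep], mj[keep]))
          b <- unique(b[b[, 1] != b[, 2], , drop = FALSE])
          if (nrow(b))
            bonds <- data.frame(i = b[, 1], j = b[, 2], order = "1",
                                stringsAsFactors = FALSE)
        }
      }
      structure(list(
        het_code = het$resname[ii[1]], chain = het$chain[ii[1]],
        resno = het$resno[ii[1]], atoms = a, bonds = bonds,
        aromatic = rep(FALSE, nrow(a)), perceived = FALSE, charges = NULL),
        class = "lsr_ligand")
    })
    names(ligands) <- vapply(ligands, function(l)
      paste(l$het_code, l$chain, l$resno, sep = "_"), "")
    # stable order: by chain then residue number
    ligands <- ligands[order(vapply(ligands, function(l) l$chain, ""),
                             vapply(ligands, function(l) l$resno, 0))]
  }

  if (nrow(poly) == 0 && length(ligands) == 0)
    stop("parse_structure: no usable atoms after filtering")

  structure(list(entry_id = entry_id, atoms = poly, ligands = ligands),
            class = "lsr_complex")
}

#' @export
print.lsr_complex <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<lsr_complex %s> %d chain(s) [%s], %d polymer atoms, %d ligand(s)\n",
              x$entry_id, length(ch), paste(ch, collapse = ","),
              nrow(x$atoms), length(x$ligands)))
  for (l in x$ligands)
    cat(sprintf("  ligand %s chain %s resno %d: %d atoms, %d bonds\n",
                l$het_code, l$chain, l$resno, nrow(l$atoms), nrow(l$bonds)))
  invisible(x)
}

#' @export
print.lsr_ligand <- function(x, ...) {
  cat(sprintf("<lsr_ligand %s/%s/%d> %d atoms, %d bonds%s\n", x$het_code,
              x$chain, x$resno, nrow(x$atoms), nrow(x$bonds),
              if (x$perceived) " (perceived)" else ""))
  invisible(x)
}

pdb_atom_line <- function(rec, serial, name, resname, chain, resno, x, y, z,
                          occ, element) {
  nm <- ifelse(nchar(name) <= 3, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, resname, chain, resno, x, y, z, occ, 0,
          toupper(element))
}

#' Write a complex back to PDB format
#'
#' Inverse of \code{\link{parse_structure}}: emits fixed-column
#' \code{ATOM}/\code{TER}/\code{HETATM}/\code{CONECT} records. Ligand bonds
#' are written as \code{CONECT} pairs so a round trip preserves
#' connectivity.
#'
#' @param complex an \code{lsr_complex}.
#' @param path optional file path; when \code{NULL} the text is returned.
#' @return The PDB text, invisibly when written to a file.
#' @export
write_structure <- function(complex, path = NULL) {
  stopifnot(inherits(complex, "lsr_complex"))
  out <- character(0)
  a <- complex$atoms
  if (nrow(a)) {
    for (ch in unique(a$chain)) {
      ca <- a[a$chain == ch, , drop = FALSE]
      out <- c(out, pdb_atom_line("ATOM", ca$serial, ca$name, ca$resname,
                                  ca$chain, ca$resno, ca$x, ca$y, ca$z,
                                  ca$occupancy, ca$element), "TER")
    }
  }
  conect <- character(0)
  for (l in complex$ligands) {
    la <- l$atoms
    out <- c(out, pdb_atom_line("HETATM", la$serial, la$name,
                                rep(l$het_code, nrow(la)),
                                rep(l$chain, nrow(la)), rep(l$resno, nrow(la)),
                                la$x, la$y, la$z, la$occupancy, la$element))
    if (nrow(l$bonds))
      conect <- c(conect, sprintf("CONECT%5d%5d",
                                  la$serial[l$bonds$i], la$serial[l$bonds$j]),
                  sprintf("CONECT%5d%5d",
                          la$serial[l$bonds$j], la$serial[l$bonds$i]))
  }
  txt <- paste(c(out, conect, "END", ""), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' Extract the one-letter amino-acid sequence of a chain
#'
#' Residues are ordered by (residue number, insertion code); the standard
#' 3-to-1 letter mapping is used and any nonstandard residue (e.g.
#' selenomethionine MSE) becomes \code{"X"}.
#'
#' @param complex an \code{lsr_complex}.
#' @param chain_id single chain identifier.
#' @return One-letter sequence string (possibly \code{""} for an empty chain).
#' @export
extract_sequence <- function(complex, chain_id) {
  stopifnot(inherits(complex, "lsr_complex"))
  a <- complex$atoms[complex$atoms$chain == chain_id, , drop = FALSE]
  if (!nrow(a)) {
    if (!(chain_id %in% complex$atoms$chain))
      stop(sprintf("extract_sequence: unknown chain '%s'", chain_id))
    return("")
  }
  res <- unique(a[, c("resno", "icode", "resname")])
  res <- res[order(res$resno, res$icode), , drop = FALSE]
  paste(aa_three_to_one(res$resname), collapse = "")
}

# residue table of a chain: resno + one CA row index per residue (NA if none)
chain_residues <- function(complex, chain_id) {
  a <- complex$atoms[complex$atoms$chain == chain_id, , drop = FALSE]
  if (!nrow(a)) return(data.frame(resno = integer(0)))
  res <- unique(a[, c("resno", "icode")])
  res <- res[order(res$resno, res$icode), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# n x 3 matrix of CA coordinates for given residue numbers (NA rows dropped
# jointly by the caller)
ca_coords <- function(complex, chain_id, resnos) {
  a <- complex$atoms
  a <- a[a$chain == chain_id & a$name == "CA", , drop = FALSE]
  m <- match(resnos, a$resno)
  cbind(a$x[m], a$y[m], a$z[m])
}

#' Write chain sequences as FASTA
#'
#' @param complex an \code{lsr_complex}.
#' @param path optional output file; when \code{NULL} the text is returned.
#' @return FASTA text, invisibly when written to a file.
#' @export
write_fasta <- function(complex, path = NULL) {
  stopifnot(inherits(complex, "lsr_complex"))
  chains <- unique(complex$atoms$chain)
  txt <- unlist(lapply(chains, function(ch)
    c(sprintf(">%s_%s", complex$entry_id, ch), extract_sequence(complex, ch))))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}
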