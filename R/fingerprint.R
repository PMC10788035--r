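# Circular (Morgan-type) fingerprints and the Tanimoto distance matrix.
# Fingerprints are OpenBabel ECFC/ECFP circular environments of radius 2
# (ECFP4), folded by OR to the requested bit length (2048 by default).

#' Fingerprint configuration
#'
#' @param n_bits fingerprint length; a power of two not exceeding 4096
#'   (default 2048).
#' @param radius circular-environment radius (default 2, i.e. ECFP4).
#' @return Object of class \code{fingerprint_config}.
#' @export
fingerprint_config <- function(n_bits = 2048, radius = 2) {
  stopifnot(n_bits >= 2, bitwAnd(n_bits, n_bits - 1L) == 0,
            n_bits <= 4096, radius %in% 0:5)
  structure(list(n_bits = as.integer(n_bits), radius = as.integer(radius)),
            class = "fingerprint_config")
}

fold_bits <- function(v, n_bits) {
  if (length(v) <= n_bits) return(as.integer(v))
  m <- matrix(v, nrow = n_bits)
  as.integer(rowSums(m) > 0)
}

#' Compute a binary fingerprint matrix for a SMILES set
#'
#' The list is cleaned first: empty/NA entries and duplicates are removed
#' (with a message), matching the usual post-search data hygiene. Rows that
#' fail to parse are dropped with a warning.
#'
#' @param smiles_list character vector of SMILES.
#' @param config a \code{\link{fingerprint_config}}.
#' @return Integer 0/1 matrix, one row per surviving SMILES (rownames =
#'   SMILES), \code{n_bits} columns.
#' @export
fingerprint_set <- function(smiles_list, config = fingerprint_config()) {
  smiles_list <- as.character(smiles_list)
  keep <- !is.na(smiles_list) & nzchar(trimws(smiles_list))
  if (!all(keep)) message(sprintf("fingerprint_set: dropped %d empty entries",
                                  sum(!keep)))
  smiles_list <- smiles_list[keep]
  dup <- duplicated(smiles_list)
  if (any(dup)) message(sprintf("fingerprint_set: removed %d duplicates",
                                sum(dup)))
  smiles_list <- smiles_list[!dup]
  if (!length(smiles_list)) stop("fingerprint_set: no usable SMILES")
  fpname <- paste0("ECFP", 2 * config$radius)
  rows <- lapply(smiles_list, function(s) {
    fp <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      v <- ChemmineOB::fingerprint_OB(mol, fpname)
      fold_bits(as.integer(v), config$n_bits)
    }, error = function(e) NULL)
    fp
  })
  ok <- !vapply(rows, is.null, TRUE)
  if (!all(ok))
    warning(sprintf("fingerprint_set: %d SMILES failed to parse and were dropped: %s",
                    sum(!ok), paste(smiles_list[!ok], collapse = ", ")))
  if (!any(ok)) stop("fingerprint_set: all SMILES failed to parse")
  m <- do.call(rbind, rows[ok])
  rownames(m) <- smiles_list[ok]
  m
}

#' Tanimoto distance matrix of binary fingerprints
#'
#' \eqn{D_{ij} = 1 - |fp_i \wedge fp_j| / |fp_i \vee fp_j|}; the diagonal is
#' 0 and the distance between two all-zero rows is 0 by convention.
#'
#' @param fps 0/1 matrix (rows = molecules).
#' @return Symmetric n x n distance matrix in [0,1].
#' @export
tanimoto_distance_matrix <- function(fps) {
  fps <- as.matrix(fps)
  if (nrow(fps) < 2) stop("tanimoto_distance_matrix: need at least 2 rows")
  common <- tcrossprod(fps)
  sums <- rowSums(fps)
  un <- outer(sums, sums, "+") - common
  D <- 1 - common / un
  D[un == 0] <- 0
  diag(D) <- 0
  D
}
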