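# Rigid-body superposition: least-squares (Kabsch) fit on mapped CA atoms,
# applied to whole complexes to bring binding sites into a common frame.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing the
#' RMSD of \code{Q} onto \code{P} (i.e. \code{R \%*\% q + t} approximates
#' \code{p}). Reflections are forbidden.
#'
#' @param P,Q numeric n x 3 matrices of paired coordinates, n >= 3, not all
#'   collinear.
#' @return Object of class \code{rigid_transform}: \code{rotation} (3 x 3,
#'   determinant +1), \code{translation} (length 3), \code{rmsd}
#'   (Angstrom), \code{n_mapped}.
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' tf <- kabsch_fit(P, P)
#' tf$rmsd   # 0
#' @export
kabsch_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop("kabsch_fit: P and Q must be equal-length n x 3 matrices")
  n <- nrow(P)
  if (n < 3) stop("kabsch_fit: need at least 3 point pairs")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  sv_p <- svd(Pc)$d; sv_q <- svd(Qc)$d
  if (sv_p[2] < 1e-8 * max(sv_p, 1e-12) || sv_q[2] < 1e-8 * max(sv_q, 1e-12))
    stop("kabsch_fit: degenerate (collinear) point set")
  H <- crossprod(Qc, Pc)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cP - R %*% cQ)
  Qfit <- t(R %*% t(Q)) + rep(t, each = n)
  rmsd <- sqrt(mean(rowSums((Qfit - P)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_mapped = n),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rmsd %.4f A over %d points\n",
              x$rmsd, x$n_mapped))
  print(round(x$rotation, 4))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

apply_transform_xyz <- function(xyz, tf) {
  xyz <- as.matrix(xyz)
  t(tf$rotation %*% t(xyz)) + rep(tf$translation, each = nrow(xyz))
}

#' Apply a rigid transform to a whole complex
#'
#' @param complex an \code{lsr_complex}.
#' @param tf a \code{rigid_transform}.
#' @return The transformed complex (all chain and ligand atoms moved).
#' @export
transform_complex <- function(complex, tf) {
  stopifnot(inherits(complex, "lsr_complex"), inherits(tf, "rigid_transform"))
  if (nrow(complex$atoms)) {
    new <- apply_transform_xyz(complex$atoms[, c("x", "y", "z")], tf)
    complex$atoms[, c("x", "y", "z")] <- new
  }
  complex$ligands <- lapply(complex$ligands, function(l) {
    l$atoms[, c("x", "y", "z")] <-
      apply_transform_xyz(l$atoms[, c("x", "y", "z")], tf)
    l
  })
  complex
}

#' Superpose a target complex onto a reference via a residue mapping
#'
#' Fits the mapped CA atoms of the target onto those of the reference by
#' least squares and applies the resulting rigid transform to every atom of
#' the target (chains and ligands). With \code{site_radius} set, the fit is
#' refined using only mapped residues whose CA lies within that distance of
#' any \code{site_coords} point (binding-site-weighted fit; off by default).
#'
#' @param target,reference \code{lsr_complex} objects.
#' @param pair an \code{lsr_homologue} linking them.
#' @param site_coords optional m x 3 matrix (e.g. reference-fragment atoms)
#'   used with \code{site_radius}.
#' @param site_radius optional radius (Angstrom) for the local refit.
#' @return The transformed copy of \code{target}, with attributes
#'   \code{transform} (the \code{rigid_transform}) and \code{rmsd}.
#' @export
superpose_by_mapping <- function(target, reference, pair,
                                 site_coords = NULL, site_radius = NULL) {
  stopifnot(inherits(pair, "lsr_homologue"))
  map <- pair$residue_map
  Pref <- ca_coords(reference, pair$reference["chain"], map$ref_resno)
  Ptgt <- ca_coords(target, pair$target["chain"], map$target_resno)
  ok <- stats::complete.cases(Pref) & stats::complete.cases(Ptgt)
  if (sum(ok) < 3)
    stop("superpose_by_mapping: fewer than 3 mapped residue pairs with CA atoms")
  Pref <- Pref[ok, , drop = FALSE]; Ptgt <- Ptgt[ok, , drop = FALSE]
  tf <- kabsch_fit(Pref, Ptgt)
  if (!is.null(site_coords) && !is.null(site_radius)) {
    d <- sqrt(outer(rowSums(Pref^2), rowSums(as.matrix(site_coords)^2), "+") -
                2 * Pref %*% t(as.matrix(site_coords)))
    near <- apply(d, 1, min) <= site_radius
    if (sum(near) >= 3)
      tf <- kabsch_fit(Pref[near, , drop = FALSE], Ptgt[near, , drop = FALSE])
  }
  out <- transform_complex(target, tf)
  attr(out, "transform") <- tf
  attr(out, "rmsd") <- tf$rmsd
  out
}
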