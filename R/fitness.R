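# Shape + electrostatics fitness of an extracted fragment against the
# reference moiety: a [0,1] surrogate for a shape/ESP overlay index with the
# contract range [0,1], 1 = perfect match, default acceptance threshold 0.2.
# No re-alignment takes place: fragments are compared in the superposed
# frame.

#' Fitness scoring configuration
#'
#' @param threshold acceptance threshold on the combined score (default 0.2;
#'   fragments scoring below it are discarded).
#' @param shape_sigma scale factor from van der Waals radius to Gaussian
#'   width; the default \code{1/sqrt(2)} gives a carbon Gaussian a 1/e
#'   radius of about 1.7 Angstrom.
#' @param esp_sigma width (Angstrom) of the charge-smearing Gaussians in the
#'   electrostatic term.
#' @param esp_weight weight of the electrostatic term in the combined score
#'   (default 0.5: arithmetic mean of shape and ESP).
#' @return Object of class \code{fitness_config}.
#' @export
fitness_config <- function(threshold = 0.2, shape_sigma = 1 / sqrt(2),
                           esp_sigma = 1.0, esp_weight = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1, shape_sigma > 0, esp_sigma > 0,
            esp_weight >= 0, esp_weight <= 1)
  structure(list(threshold = threshold, shape_sigma = shape_sigma,
                 esp_sigma = esp_sigma, esp_weight = esp_weight),
            class = "fitness_config")
}

frag_xyz <- function(frag) {
  if (inherits(frag, "lsr_fragment"))
    as.matrix(frag$atoms[, c("x", "y", "z")])
  else as.matrix(frag[, c("x", "y", "z")])
}

frag_elements <- function(frag) {
  if (inherits(frag, "lsr_fragment")) frag$atoms$element else frag$element
}

# sum_{i,j} w_i w_j (2 pi s_i^2 s_j^2 / (s_i^2+s_j^2))^{3/2}
#                    exp(-d_ij^2 / (2 (s_i^2+s_j^2)))
gaussian_overlap <- function(A, B, sa, sb, wa = NULL, wb = NULL) {
  if (is.null(wa)) wa <- rep(1, nrow(A))
  if (is.null(wb)) wb <- rep(1, nrow(B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  s2 <- outer(sa^2, sb^2, "+")
  pref <- (2 * pi * outer(sa^2, sb^2) / s2)^1.5
  sum(outer(wa, wb) * pref * exp(-d2 / (2 * s2)))
}

#' Gaussian-volume shape overlap of two fragments
#'
#' Each heavy atom carries an isotropic Gaussian whose width scales with its
#' van der Waals radius; the score is the volume Tanimoto
#' \eqn{V_{AB} / (V_{AA} + V_{BB} - V_{AB})}. It is 1 iff the two atom sets
#' are identical in elements and positions, symmetric, and invariant under a
#' rigid motion applied jointly to both fragments.
#'
#' @param frag_a,frag_b \code{lsr_fragment} objects or data frames with
#'   \code{element}, \code{x}, \code{y}, \code{z} columns (same coordinate
#'   frame; no re-alignment is performed).
#' @param config a \code{\link{fitness_config}}.
#' @return Shape similarity in [0,1].
#' @export
shape_overlap <- function(frag_a, frag_b, config = fitness_config()) {
  A <- frag_xyz(frag_a); B <- frag_xyz(frag_b)
  if (!nrow(A) || !nrow(B)) stop("shape_overlap: empty fragment")
  sa <- config$shape_sigma * vdw_radius(frag_elements(frag_a))
  sb <- config$shape_sigma * vdw_radius(frag_elements(frag_b))
  vab <- gaussian_overlap(A, B, sa, sb)
  vaa <- gaussian_overlap(A, A, sa, sa)
  vbb <- gaussian_overlap(B, B, sb, sb)
  max(0, min(1, vab / (vaa + vbb - vab)))
}

#' Electronegativity-equalization partial charges
#'
#' Solves the electronegativity-equalization (EEM) stationarity system for
#' heavy-atom partial charges: all atomic chemical potentials equal, total
#' charge zero. Element electronegativity/hardness parameters are on the
#' Mulliken scale; the Coulomb off-diagonal is screened at short range with
#' the Louwen-Vogt interpolation \eqn{J_{ij} = k / (r^3 +
#' (k/\sqrt{4\eta_i\eta_j})^3)^{1/3}} (k = 14.4 eV Angstrom), which keeps
#' the system diagonally dominant at bonding distances.
#'
#' @param frag an \code{lsr_fragment} or atom data frame.
#' @return Numeric vector of partial charges (sums to ~0).
#' @export
assign_charges <- function(frag) {
  el <- frag_elements(frag)
  xyz <- frag_xyz(frag)
  n <- length(el)
  if (!n) stop("assign_charges: empty fragment")
  if (n == 1L) return(0)
  chi <- .EEM_CHI[el]; chi[is.na(chi)] <- 6.0
  eta <- .EEM_ETA[el]; eta[is.na(eta)] <- 5.0
  D <- as.matrix(dist(xyz))
  gam <- (14.4 / sqrt(4 * outer(eta, eta)))^3
  A <- 14.4 / (D^3 + gam)^(1 / 3)
  diag(A) <- 2 * eta
  M <- rbind(cbind(A, 1), c(rep(1, n), 0))
  rhs <- c(-chi, 0)
  q <- tryCatch(solve(M, rhs)[seq_len(n)],
                error = function(e) stop("assign_charges: singular EEM system"))
  unname(q)
}

hodgkin_index <- function(A, B, qa, qb, sigma) {
  sa <- rep(sigma, nrow(A)); sb <- rep(sigma, nrow(B))
  vab <- gaussian_overlap(A, B, sa, sb, qa, qb)
  vaa <- gaussian_overlap(A, A, sa, sa, qa, qa)
  vbb <- gaussian_overlap(B, B, sb, sb, qb, qb)
  if (vaa < 1e-12 && vbb < 1e-12) return(1)     # both fields identically zero
  if (vaa < 1e-12 || vbb < 1e-12) return(0)
  max(-1, min(1, 2 * vab / (vaa + vbb)))
}

#' Electrostatic similarity of two fragments
#'
#' Hodgkin index \eqn{H = 2\langle\psi_A\psi_B\rangle /
#' (\langle\psi_A^2\rangle + \langle\psi_B^2\rangle)} of charge-weighted
#' Gaussian fields (EEM charges unless supplied), mapped from [-1,1] to
#' [0,1] as \eqn{(H+1)/2}. Two fragments with identically zero fields (pure
#' nonpolar) score 1; a fragment against its charge-negated copy scores 0.
#'
#' @param frag_a,frag_b fragments (as in \code{\link{shape_overlap}}).
#' @param config a \code{\link{fitness_config}}.
#' @param charges_a,charges_b optional explicit charge vectors.
#' @return ESP similarity in [0,1].
#' @export
esp_similarity <- function(frag_a, frag_b, config = fitness_config(),
                           charges_a = NULL, charges_b = NULL) {
  A <- frag_xyz(frag_a); B <- frag_xyz(frag_b)
  if (!nrow(A) || !nrow(B)) stop("esp_similarity: empty fragment")
  qa <- charges_a %||% assign_charges(frag_a)
  qb <- charges_b %||% assign_charges(frag_b)
  h <- hodgkin_index(A, B, qa, qb, config$esp_sigma)
  (h + 1) / 2
}

#' Combined fitness of a fragment against the reference moiety
#'
#' @param frag,reference fragments in the same (superposed) frame.
#' @param config a \code{\link{fitness_config}}.
#' @return List of class \code{fitness_score} with \code{shape}, \code{esp}
#'   and \code{combined} (all in [0,1];
#'   \code{combined = (1-esp_weight)*shape + esp_weight*esp}).
#' @export
score_fragment <- function(frag, reference, config = fitness_config()) {
  shape <- shape_overlap(frag, reference, config)
  esp <- esp_similarity(frag, reference, config)
  structure(list(shape = shape, esp = esp,
                 combined = (1 - config$esp_weight) * shape +
                   config$esp_weight * esp),
            class = "fitness_score")
}

#' @export
print.fitness_score <- function(x, ...) {
  cat(sprintf("<fitness> shape %.3f  esp %.3f  combined %.3f\n",
              x$shape, x$esp, x$combined))
  invisible(x)
}

#' Filter and rank scored fragments
#'
#' Fragments with combined score below the threshold are removed (the
#' boundary is kept: score == threshold survives); survivors are sorted by
#' descending combined score, ties broken by smaller heavy-atom count then
#' lexicographic SMILES.
#'
#' @param fragments list of \code{lsr_fragment} with \code{fitness} set.
#' @param config a \code{\link{fitness_config}}.
#' @return Ordered, filtered list.
#' @export
filter_rank <- function(fragments, config = fitness_config()) {
  if (!length(fragments)) return(list())
  comb <- vapply(fragments, function(f) {
    if (is.null(f$fitness)) stop("filter_rank: fragment without fitness")
    f$fitness$combined
  }, 0)
  keep <- comb >= config$threshold
  fragments <- fragments[keep]; comb <- comb[keep]
  if (!length(fragments)) return(list())
  natoms <- vapply(fragments, function(f) nrow(f$atoms), 0L)
  smi <- vapply(fragments, function(f)
    if (is.na(f$smiles)) "" else f$smiles, "")
  fragments[order(-comb, natoms, smi, method = "radix")]
}
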