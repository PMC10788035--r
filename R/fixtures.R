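# Synthetic fixture corpus: toy protein-ligand complexes with a planted
# replacement, so the full search pipeline runs with no downloads. One
# reference complex carries a 3-methylcatechol-like ligand containing the
# query moiety; the homologous targets are rigid-motion + noise copies of
# the same CA-trace chain, each carrying a planted ligand whose ring
# occupies the reference moiety's location.

#' Fixture corpus specification
#'
#' @param n_complexes total complexes (1 reference + n-1 homologous
#'   targets), >= 2.
#' @param planted_smiles SMILES of the planted replacement ligand (default
#'   pyridine \code{"c1ccncc1"}).
#' @param chain_length residues in the CA-trace chain (default 60, so the
#'   homology step's 50-aligned-residue floor is met).
#' @param noise_sd per-coordinate Gaussian noise applied to target
#'   complexes, Angstrom (default 0.1).
#' @param seed integer seed; the whole corpus is deterministic given it.
#' @param ligand_offset distance from the helix axis at which ligands are
#'   placed, Angstrom.
#' @return Object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_complexes = 4, planted_smiles = "c1ccncc1",
                         chain_length = 60, noise_sd = 0.1, seed = 1,
                         ligand_offset = 10) {
  stopifnot(n_complexes >= 2, noise_sd >= 0, chain_length >= 4)
  structure(list(n_complexes = as.integer(n_complexes),
                 planted_smiles = planted_smiles,
                 chain_length = as.integer(chain_length),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 ligand_offset = ligand_offset),
            class = "fixture_spec")
}

# ideal alpha-helix CA trace: rise 1.5 A, 100 degrees per residue, r 2.3 A
helix_ca <- function(n) {
  t <- (seq_len(n) - 1) * 100 * pi / 180
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n) - 1))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr_d <- qr(m)
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# planar 3-methylcatechol: benzene hexagon (1.39 A), two hydroxyl O on
# adjacent carbons, one methyl C on the carbon next to an O (the "R"
# substituent position of the 3-substituted catechol query).
catechol_geometry <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  subst <- function(k, bond) {
    dir <- ring[k, ] / sqrt(sum(ring[k, ]^2))
    ring[k, ] + bond * dir
  }
  xyz <- rbind(ring, subst(1, 1.36), subst(2, 1.36), subst(3, 1.50))
  list(xyz = xyz,
       element = c(rep("C", 6), "O", "O", "C"),
       bonds = data.frame(i = c(1:6, 1, 2, 3), j = c(2:6, 1, 7, 8, 9),
                          order = "1", stringsAsFactors = FALSE))
}

# 3D geometry of an arbitrary planted SMILES via OpenBabel, heavy atoms
# only, rotated into a canonical frame (principal plane -> xy, centroid 0).
planted_geometry <- function(smiles) {
  m2 <- ob_convert("SMI", "MOL2", smiles,
                   options = data.frame(names = "gen3D", args = ""))
  if (is.na(m2)) stop(sprintf("fixture: cannot build 3D for \"%s\"", smiles))
  p <- parse_mol2(m2)
  keep <- p$atoms$element != "H"
  idx <- which(keep)
  xyz <- as.matrix(p$atoms[idx, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(xyz)
  xyz <- xyz %*% sv$v        # principal axes -> x, y, z (plane into xy)
  remap <- match(seq_along(keep), idx)
  b <- p$bonds[p$bonds$i %in% idx & p$bonds$j %in% idx, , drop = FALSE]
  list(xyz = xyz, element = p$atoms$element[idx],
       bonds = data.frame(i = remap[b$i], j = remap[b$j], order = b$order,
                          stringsAsFactors = FALSE))
}

make_complex <- function(entry_id, seq_letters, ca, lig_xyz, lig_el,
                         lig_bonds, het_code) {
  n <- nrow(ca)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", altloc = " ",
    resname = names(.AA_3TO1)[match(seq_letters, .AA_3TO1)],
    chain = "A", resno = seq_len(n), icode = " ",
    x = ca[, 1], y = ca[, 2], z = ca[, 3],
    occupancy = 1, element = "C", is_het = FALSE, stringsAsFactors = FALSE)
  la <- data.frame(
    serial = n + seq_len(nrow(lig_xyz)),
    name = paste0(lig_el, seq_len(nrow(lig_xyz))),
    element = lig_el, x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    occupancy = 1, stringsAsFactors = FALSE)
  lig <- structure(list(het_code = het_code, chain = "A", resno = n + 1,
                        atoms = la, bonds = lig_bonds,
                        aromatic = rep(FALSE, nrow(la)),
                        perceived = FALSE, charges = NULL),
                   class = "lsr_ligand")
  structure(list(entry_id = entry_id, atoms = atoms,
                 ligands = stats::setNames(list(lig),
                   paste(het_code, "A", n + 1, sep = "_"))),
            class = "lsr_complex")
}

#' Generate a synthetic fixture corpus with a planted replacement
#'
#' Builds one reference complex whose ligand (het \code{MCT},
#' 3-methylcatechol geometry) contains the 3-substituted-catechol query
#' moiety, plus \code{n_complexes - 1} homologous targets: the same
#' CA-trace chain under a random rigid motion with \code{noise_sd}
#' coordinate noise, each carrying the planted ligand (het \code{PLT})
#' whose ring centre coincides with the reference catechol ring before the
#' motion. Deterministic under a fixed seed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir optional directory; when given, PDB files are written there
#'   and their paths returned as attribute \code{paths}.
#' @return List of \code{lsr_complex} (reference first).
#' @export
generate_fixture_corpus <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n_res <- spec$chain_length
  seq_letters <- sample(unname(.AA_3TO1), n_res, replace = TRUE)
  ca <- helix_ca(n_res)

  cat_geo <- catechol_geometry()
  # place the ligand plane next to the helix, centred mid-chain
  place <- function(xyz) {
    out <- xyz
    out[, 1] <- out[, 1] + spec$ligand_offset
    out[, 3] <- out[, 3] + 1.5 * (n_res / 2)
    out
  }
  ref_lig <- place(cat_geo$xyz)
  plt <- planted_geometry(spec$planted_smiles)
  # ring centroid of the catechol = centroid of its 6 ring carbons
  ring_ctr <- colMeans(ref_lig[1:6, ])
  plt_xyz <- sweep(plt$xyz, 2, ring_ctr, "+")

  check_clash <- function(lig_xyz) {
    d2 <- outer(rowSums(lig_xyz^2), rowSums(ca^2), "+") -
      2 * lig_xyz %*% t(ca)
    min(sqrt(pmax(d2, 0)))
  }
  if (check_clash(ref_lig) < 1.5 || check_clash(plt_xyz) < 1.5)
    stop("generate_fixture_corpus: planted ligand clashes with the chain; increase ligand_offset")

  ids <- sprintf("FX%02d", seq_len(spec$n_complexes))
  out <- vector("list", spec$n_complexes)
  out[[1]] <- make_complex(ids[1], seq_letters, ca, ref_lig,
                           cat_geo$element, cat_geo$bonds, "MCT")
  for (i in seq_len(spec$n_complexes)[-1]) {
    R <- random_rotation()
    tvec <- runif(3, -20, 20)
    move <- function(xyz) t(R %*% t(xyz)) + rep(tvec, each = nrow(xyz))
    ca_i <- move(ca) + matrix(rnorm(length(ca), 0, spec$noise_sd), nrow(ca))
    lig_i <- move(plt_xyz) +
      matrix(rnorm(length(plt_xyz), 0, spec$noise_sd), nrow(plt_xyz))
    out[[i]] <- make_complex(ids[i], seq_letters, ca_i, lig_i,
                             plt$element, plt$bonds, "PLT")
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(tolower(ids), ".pdb"))
    for (i in seq_along(out)) write_structure(out[[i]], paths[i])
    attr(out, "paths") <- paths
  }
  out
}
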