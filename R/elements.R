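# Element property tables used across the pipeline. All lengths in Angstrom,
# energies in eV. Heavy-atom pipeline: hydrogens are dropped at parse time.

# Covalent radii (Cordero et al. consensus values, rounded to 2 dp).
.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20, Br = 1.20, I = 1.39,
  Li = 1.28, Na = 1.66, K = 2.03, Rb = 2.20, Cs = 2.44,
  Be = 0.96, Mg = 1.41, Ca = 1.76, Sr = 1.95, Ba = 2.15,
  Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Cd = 1.44, Hg = 1.32, Al = 1.21, As = 1.19
)

# van der Waals radii (Bondi), used to size the shape Gaussians.
.VDW_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Se = 1.90, Br = 1.85, I = 1.98,
  Li = 1.82, Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31,
  Mn = 2.05, Fe = 2.05, Co = 2.00, Ni = 1.97, Cu = 1.96, Zn = 2.01,
  Cd = 2.18, Hg = 2.05, Al = 1.84, As = 1.85
)

# Mulliken-scale electronegativity chi and hardness eta for the EEM charge
# solve. Unlisted elements fall back to (6.0, 5.0).
.EEM_CHI <- c(
  H = 7.18, C = 6.27, N = 7.27, O = 7.54, F = 10.41, P = 5.62, S = 6.22,
  Cl = 8.29, Br = 7.60, I = 6.76, B = 4.29, Si = 4.77, Se = 5.89,
  Li = 3.01, Na = 2.84, K = 2.42, Mg = 3.75, Ca = 2.20,
  Mn = 3.72, Fe = 4.06, Co = 4.26, Ni = 4.40, Cu = 4.48, Zn = 4.45
)
.EEM_ETA <- c(
  H = 6.42, C = 5.00, N = 7.23, O = 6.08, F = 7.01, P = 4.88, S = 4.14,
  Cl = 4.68, Br = 4.22, I = 3.69, B = 4.01, Si = 3.38, Se = 3.87,
  Li = 2.39, Na = 2.30, K = 1.92, Mg = 3.90, Ca = 4.00,
  Mn = 3.72, Fe = 3.81, Co = 3.60, Ni = 3.25, Cu = 3.25, Zn = 4.94
)

# Elements treated as metals: single-atom ligands of these are kept (ions can
# take part in local structural replacements) and are exempt from the
# min_atoms fragment-size filter.
.METALS <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
             "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Cd", "Hg", "Al")

# Maximum usual heavy-atom connectivity, used as a cheap valence sanity check
# before handing a fragment to the SMILES writer.
.MAX_DEGREE <- c(H = 1, B = 4, C = 4, N = 4, O = 3, F = 1, P = 6, S = 6,
                 Cl = 1, Br = 1, I = 3, Si = 6, Se = 6)

covalent_radius <- function(element) {
  r <- .COVALENT_RADII[element]
  r[is.na(r)] <- 1.5   # generous default keeps odd elements connectable
  unname(r)
}

vdw_radius <- function(element) {
  r <- .VDW_RADII[element]
  r[is.na(r)] <- 1.8
  unname(r)
}

is_metal <- function(element) element %in% .METALS

# Standard 3 -> 1 letter amino-acid code; anything else maps to 'X'.
.AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa_three_to_one <- function(resname) {
  out <- .AA_3TO1[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Normalise element capitalisation ("ZN" -> "Zn", "c" -> "C").
normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}
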