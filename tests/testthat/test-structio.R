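# Structure I/O: PDB parsing, sequence extraction, bond perception.

test_that("polymer-only files give chains without ligands", {
  cx <- parse_structure(gly_chain_pdb())
  expect_s3_class(cx, "lsr_complex")
  expect_equal(unique(cx$atoms$chain), "A")
  expect_equal(nrow(unique(cx$atoms[, c("resno", "icode")])), 1)
  expect_length(cx$ligands, 0)
})

test_that("het groups with CONECT become ligands with bonds", {
  pdb <- paste(gly_chain_pdb(), hexagon_het_pdb("BNZ"), sep = "\n")
  cx <- parse_structure(pdb)
  expect_length(cx$ligands, 1)
  lig <- cx$ligands[[1]]
  expect_equal(lig$het_code, "BNZ")
  expect_equal(nrow(lig$atoms), 6)
  expect_equal(nrow(lig$bonds), 6)
})

test_that("waters are excluded from ligands", {
  pdb <- paste(
    gly_chain_pdb(),
    atom_rec("HETATM", 10, "O", "HOH", "A", 501, 5, 5, 5, element = "O"),
    sep = "\n")
  cx <- parse_structure(pdb)
  expect_length(cx$ligands, 0)
  expect_error(parse_structure(atom_rec("HETATM", 1, "O", "HOH", "A", 1,
                                        0, 0, 0, element = "O")),
               "no usable atoms")
})

test_that("malformed fixed-column records raise an error naming the line", {
  bad <- paste(gly_chain_pdb(),
               "ATOM      4  CB  GLY A   1      xx.xxx   0.000   0.000  1.00  0.00           C",
               sep = "\n")
  expect_error(parse_structure(bad), "line 4")
  expect_error(parse_structure(""), "empty")
})

test_that("altloc keeps the highest-occupancy conformer, ties prefer A", {
  pdb <- paste(
    atom_rec("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4,
             altloc = "A", element = "C"),
    atom_rec("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6,
             altloc = "B", element = "C"),
    atom_rec("ATOM", 3, "CA", "ALA", "A", 2, 1, 0, 0, occ = 0.5,
             altloc = "A", element = "C"),
    atom_rec("ATOM", 4, "CA", "ALA", "A", 2, 8, 8, 8, occ = 0.5,
             altloc = "B", element = "C"),
    sep = "\n")
  cx <- parse_structure(pdb)
  expect_equal(nrow(cx$atoms), 2)
  expect_equal(cx$atoms$x, c(9, 1))   # occupancy winner, then tie -> A
})

test_that("hydrogens are dropped and first model only is read", {
  pdb <- paste(
    "MODEL        1",
    gly_chain_pdb(),
    atom_rec("ATOM", 9, "H", "GLY", "A", 1, 0.5, 0.5, 0, element = "H"),
    "ENDMDL",
    "MODEL        2",
    atom_rec("ATOM", 11, "CA", "ALA", "B", 1, 7, 7, 7, element = "C"),
    "ENDMDL", sep = "\n")
  cx <- parse_structure(pdb)
  expect_equal(nrow(cx$atoms), 3)
  expect_false("B" %in% cx$atoms$chain)
  expect_false(any(cx$atoms$element == "H"))
})

test_that("sequence extraction uses the 3-to-1 table with X for nonstandard", {
  pdb <- paste(
    atom_rec("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    atom_rec("ATOM", 2, "CA", "ALA", "A", 2, 3, 0, 0, element = "C"),
    atom_rec("ATOM", 3, "CA", "SER", "A", 3, 6, 0, 0, element = "C"),
    atom_rec("ATOM", 4, "CA", "MSE", "A", 4, 9, 0, 0, element = "C"),
    sep = "\n")
  cx <- parse_structure(pdb)
  expect_equal(extract_sequence(cx, "A"), "GASX")
  expect_error(extract_sequence(cx, "Z"), "unknown chain")
})

test_that("write -> parse round trip preserves atoms, coordinates, het codes", {
  corpus <- generate_fixture_corpus(fixture_spec(n_complexes = 2, seed = 3))
  cx <- corpus[[1]]
  cx2 <- parse_structure(write_structure(cx), entry_id = cx$entry_id)
  expect_equal(nrow(cx2$atoms), nrow(cx$atoms))
  expect_equal(cx2$atoms$x, cx$atoms$x, tolerance = 1e-3)
  expect_equal(vapply(cx2$ligands, `[[`, "", "het_code"),
               vapply(cx$ligands, `[[`, "", "het_code"))
  l1 <- cx$ligands[[1]]; l2 <- cx2$ligands[[1]]
  expect_equal(as.matrix(l2$atoms[, c("x", "y", "z")]),
               as.matrix(l1$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # CONECT round trip: same bond set
  key <- function(b) sort(paste(pmin(b$i, b$j), pmax(b$i, b$j)))
  expect_equal(key(l2$bonds), key(l1$bonds))
})

test_that("distance-based bond perception follows the covalent-radius rule", {
  two_c <- function(d) make_ligand(c("C", "C"),
                                   cbind(c(0, d), c(0, 0), c(0, 0)))
  lig <- perceive_ligand_graph(two_c(1.5))
  expect_equal(nrow(lig$bonds), 1)   # 1.5 <= 0.76 + 0.76 + 0.4
  lig2 <- perceive_ligand_graph(two_c(3.0))
  expect_equal(nrow(lig2$bonds), 0)
  expect_error(perceive_ligand_graph(two_c(0.3)), "clash")
})

test_that("benzene geometry is perceived aromatic, matching the toolkit", {
  lig <- perceive_ligand_graph(make_ligand(rep("C", 6), hexagon_xyz()))
  expect_equal(nrow(lig$bonds), 6)
  expect_true(all(lig$aromatic))
  expect_true(all(lig$bonds$order == "ar"))
  frag <- induce_fragments(lig, 1:6)[[1]]
  smi <- fragment_to_smiles(frag)$smiles
  # independent oracle: direct toolkit perception of the same coordinates
  oracle <- lsrsearch:::ob_convert("PDB", "CAN", hexagon_het_pdb(conect = FALSE))
  expect_equal(smi, trimws(strsplit(oracle, "[\t\n]")[[1]][1]))
  expect_equal(smi, "c1ccccc1")
})

test_that("bond perception is invariant under atom reordering", {
  set.seed(42)
  lig <- methylcatechol_ligand()
  lig$bonds <- lig$bonds[0, ]   # force pure distance perception
  p1 <- perceive_ligand_graph(lig)
  perm <- sample(nrow(lig$atoms))
  lig2 <- lig
  lig2$atoms <- lig$atoms[perm, ]
  rownames(lig2$atoms) <- NULL
  p2 <- perceive_ligand_graph(lig2)
  key <- function(l, map) sort(paste(pmin(map[l$bonds$i], map[l$bonds$j]),
                                     pmax(map[l$bonds$i], map[l$bonds$j])))
  expect_equal(key(p2, perm), key(p1, seq_len(9)))
})

test_that("metal ions survive as single-atom ligands", {
  pdb <- paste(gly_chain_pdb(),
               atom_rec("HETATM", 20, "ZN", "ZN", "A", 600, 4, 4, 4,
                        element = "Zn"),
               sep = "\n")
  cx <- parse_structure(pdb)
  expect_length(cx$ligands, 1)
  expect_equal(cx$ligands[[1]]$atoms$element, "Zn")
})
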