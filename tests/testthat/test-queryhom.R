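# Fragment-query parsing, substructure matching, sequence homology.

test_that("query parsing recognises attachment markers", {
  q <- parse_fragment_query("Oc1cccc([R])c1O")
  expect_length(q$core, 8)                       # 6 ring C + 2 O
  expect_equal(q$attachment_count, 1)
  expect_equal(sort(table(q$atoms$element[q$core]), decreasing = TRUE),
               sort(table(c(rep("C", 6), rep("O", 2))), decreasing = TRUE),
               ignore_attr = TRUE)
  q2 <- parse_fragment_query("O")
  expect_length(q2$core, 1)
  expect_equal(q2$attachment_count, 0)
  # "*" is equivalent to "[R]"
  q3 <- parse_fragment_query("Oc1cccc(*)c1O")
  expect_equal(q3$attachment_count, 1)
})

test_that("malformed query SMILES raise parse errors", {
  expect_error(parse_fragment_query("Oc1cccc("), "unbalanced")
  expect_error(parse_fragment_query(""), "empty")
  expect_error(parse_fragment_query("Xx%%"), "unparseable")
})

test_that("3-methylcatechol matches the 3-substituted catechol query once", {
  q <- parse_fragment_query("Oc1cccc([R])c1O")
  lig <- perceive_ligand_graph(methylcatechol_ligand())
  m <- match_substructure(lig, q)
  expect_length(m, 1)
  expect_setequal(m[[1]], 1:8)    # catechol core: ring + both oxygens
  expect_equal(match_oracle_count(lig, q), 1)
})

test_that("benzene does not match an oxygenated query", {
  q <- parse_fragment_query("Oc1cccc([R])c1O")
  lig <- perceive_ligand_graph(make_ligand(rep("C", 6), hexagon_xyz()))
  expect_length(match_substructure(lig, q), 0)
})

test_that("an attachment point requires a real substituent atom", {
  # plain catechol: no atom available at the R position
  ring <- hexagon_xyz()
  sub <- function(k, bond) ring[k, ] * (1 + bond / 1.39)
  xyz <- rbind(ring, sub(1, 1.36), sub(2, 1.36))
  catechol <- make_ligand(c(rep("C", 6), "O", "O"), xyz,
                          data.frame(i = c(1:6, 1, 2), j = c(2:6, 1, 7, 8),
                                     order = "1"))
  lig <- perceive_ligand_graph(catechol)
  q <- parse_fragment_query("Oc1cccc([R])c1O")
  expect_length(match_substructure(lig, q), 0)
  expect_equal(match_oracle_count(lig, q), 0)
  # without the attachment requirement it does match
  q0 <- parse_fragment_query("Oc1ccccc1O")
  expect_length(match_substructure(lig, q0), 1)
})

test_that("match count agrees with exhaustive enumeration and is order-invariant", {
  set.seed(11)
  q <- parse_fragment_query("Oc1cccc([R])c1O")
  lig <- perceive_ligand_graph(methylcatechol_ligand())
  n0 <- length(match_substructure(lig, q))
  for (rep in 1:3) {
    perm <- sample(nrow(lig$atoms))
    lig2 <- lig
    lig2$atoms <- lig$atoms[perm, ]
    rownames(lig2$atoms) <- NULL
    lig2$bonds <- lig$bonds[0, ]
    lig2 <- perceive_ligand_graph(lig2)
    expect_length(match_substructure(lig2, q), n0)
  }
  # symmetric query on a symmetric ligand: duplicates collapsed to one set
  qb <- parse_fragment_query("c1ccccc1")
  benzene <- perceive_ligand_graph(make_ligand(rep("C", 6), hexagon_xyz()))
  expect_length(match_substructure(benzene, qb), 1)
  expect_equal(match_oracle_count(benzene, qb), 1)
})

test_that("alignment identity follows the column definition", {
  s <- paste(rep("ACDEFGHIKL", 2), collapse = "")
  expect_equal(align_pair(s, s)$identity, 100)
  a <- "ACDEFGHIKW"
  b <- "ACDEFGHIKY"                       # one mismatch in ten
  expect_equal(align_pair(a, b)$identity, 90)
  expect_error(align_pair("", "ACD"), "empty")
})

test_that("tiny-gap alignment matches the exhaustive oracle", {
  # brute force over all global alignments of "ACD" vs "AD" with affine
  # gaps (open 11, extend 1, BLOSUM62): scores of the 3 column layouts
  bl <- lsrsearch:::blosum62()
  sc <- function(cols) {
    s <- 0; open <- FALSE
    for (c in cols) {
      if (c[1] == "-" || c[2] == "-") { s <- s - 11 - 1 }
      else s <- s + bl[c[1], c[2]]
    }
    s
  }
  cand <- list(
    list(c("A","A"), c("C","-"), c("D","D")),
    list(c("A","A"), c("C","D"), c("D","-")),
    list(c("A","-"), c("C","A"), c("D","D")))
  best <- cand[[which.max(vapply(cand, sc, 0))]]
  al <- align_pair("ACD", "AD")
  ident_oracle <- {
    both <- Filter(function(c) c[1] != "-" && c[2] != "-", best)
    100 * mean(vapply(both, function(c) c[1] == c[2], TRUE))
  }
  expect_equal(al$identity, ident_oracle)
  expect_equal(nrow(al$map), 2)       # A-A and D-D aligned
})

test_that("identity is symmetric and residue maps increase monotonically", {
  set.seed(5)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  for (i in 1:5) {
    a <- paste(sample(aa, 30, TRUE), collapse = "")
    b <- paste(sample(aa, 25, TRUE), collapse = "")
    expect_equal(align_pair(a, b)$identity, align_pair(b, a)$identity,
                 tolerance = 1e-9)
    m <- align_pair(a, b)$map
    expect_true(all(diff(m[, 1]) > 0))
    expect_true(all(diff(m[, 2]) > 0))
  }
})

test_that("homologue selection respects threshold and excludes the reference", {
  corpus <- generate_fixture_corpus(fixture_spec(n_complexes = 3, seed = 9))
  ref <- corpus[[1]]
  homs <- select_homologues(ref, "A", corpus, min_identity = 90)
  expect_length(homs, 2)
  expect_true(all(vapply(homs, function(h) h$identity, 0) == 100))
  expect_false(ref$entry_id %in%
                 vapply(homs, function(h) h$target[["entry"]], ""))
  for (h in homs) {
    expect_true(all(diff(h$residue_map$ref_resno) > 0))
    expect_true(all(diff(h$residue_map$target_resno) > 0))
  }
  # an unrelated sequence falls below the threshold
  stranger <- corpus[[2]]
  stranger$entry_id <- "ZZ99"
  set.seed(1)
  stranger$atoms$resname <- sample(c("GLY", "ALA", "SER", "THR", "VAL",
                                     "LEU", "LYS", "ASP"),
                                   nrow(stranger$atoms), TRUE)
  homs2 <- select_homologues(corpus[[1]], "A", list(corpus[[1]], stranger),
                             min_identity = 90)
  expect_length(homs2, 0)
})
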