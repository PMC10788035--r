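Package: lsrsearch
Title: Local Structural Replacement Search for Bioisostere Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate bioisosteric replacements of a ligand
    moiety by mining protein-ligand complexes. Given a fragment query
    (SMILES with an attachment point) and a corpus of PDB-format
    complexes, the package locates reference ligands containing the
    moiety, selects sequence homologues, superposes them by least squares
    onto the reference frame, captures target-ligand atoms inside probe
    spheres centred on the reference-fragment atoms, induces the captured
    atoms into chemically complete fragments with canonical SMILES, scores
    their fit to the reference moiety on a combined Gaussian-shape and
    electrostatic-potential scale, and post-processes accepted fragments
    with composition categories, 2048-bit circular-fingerprint Tanimoto
    clustering (elbow and silhouette tuning) and PCA embedding. A
    synthetic-fixture generator builds toy complexes with planted
    replacements so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Biostrings,
    igraph,
    kernlab,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    cluster,
    bio3d
Config/testthat/edition: 3
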