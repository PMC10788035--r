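# Composition categories, fingerprints, Tanimoto distances, clustering,
# tuning and PCA.

test_that("categories follow the ring / element-set rules", {
  expect_equal(assign_category("c1ccncc1"), "cycle C+N")
  expect_equal(assign_category("c1ccoc1"), "cycle C+O")
  expect_equal(assign_category("c1ccc2ncccc2c1"), "cycle C+N")
  expect_equal(assign_category("[F]"), "F")
  expect_equal(assign_category("[Zn]"), "Zn")
  # cyclic with C,N,O,S is not in the predefined list
  expect_equal(assign_category("C1OC1NCS1CC1"), "cycle other")
  expect_equal(assign_category("CCO"), "C+O")
  expect_equal(assign_category("CC(N)O"), "C+O+N")
  expect_equal(assign_category("ClCCl"), "acyclic other")
  # attachment wildcards are ignored
  expect_equal(assign_category("*c1ccncc1"), "cycle C+N")
  expect_error(assign_category("notsmiles%%"), "unparseable")
})

test_that("category labels partition any fragment set", {
  smi <- c("c1ccncc1", "CCO", "c1ccccc1", "[F]", "CCN", "C1CC1",
           "c1ccsc1", "OCC(N)S")
  tb <- category_table(smi)
  expect_equal(sum(tb$count), length(smi))
  labs <- vapply(smi, assign_category, "")
  expect_length(labs, length(smi))          # exactly one label each
})

test_that("fingerprints are deterministic, cleaned, and non-empty", {
  fps <- suppressMessages(fingerprint_set(c("C", "C", "CCO", "")))
  expect_equal(nrow(fps), 2)                # duplicate + empty removed
  expect_equal(ncol(fps), 2048)
  expect_gte(sum(fps["C", ]), 1)
  fps2 <- suppressMessages(fingerprint_set(c("C", "CCO")))
  expect_identical(fps, fps2)
  expect_warning(suppressMessages(fingerprint_set(c("CCO", "xx%%yy"))),
                 "failed to parse")
})

test_that("tanimoto distances follow the bit-set definition", {
  m <- rbind(a = c(1, 1, 1, 0, 0), b = c(0, 1, 1, 1, 0))
  D <- tanimoto_distance_matrix(m)
  expect_equal(D["a", "b"], 0.5)            # intersection 2, union 4
  m2 <- rbind(x = c(1, 1, 0), y = c(1, 1, 0), z = c(0, 0, 1))
  D2 <- tanimoto_distance_matrix(m2)
  expect_equal(D2["x", "y"], 0)
  expect_equal(D2["x", "z"], 1)             # disjoint non-empty
  zz <- rbind(p = c(0, 0), q = c(0, 0))
  expect_equal(tanimoto_distance_matrix(zz)["p", "q"], 0)  # convention
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("kmeans recovers planted blobs and k = n gives zero SSE", {
  pb <- planted_blobs(2, seed = 41)
  rep2 <- run_clustering(pb$x, "kmeans", params = list(k = 2), seed = 1)
  expect_equal(length(unique(paste(rep2$labels, pb$labels))), 2)  # label-permutation match
  repn <- run_clustering(pb$x[1:8, ], "kmeans", params = list(k = 8), seed = 1)
  expect_equal(repn$sse, 0)
  expect_error(run_clustering(pb$x, "kmeans", params = list(k = 1000)),
               "exceeds")
  expect_error(run_clustering(pb$x, "nosuch"), "arg")
})

test_that("all eight algorithms run and most recover two planted blobs", {
  pb <- planted_blobs(2, per = 10, seed = 42)
  for (alg in c("kmeans", "agglomerative", "spectral", "birch", "meanshift",
                "dbscan", "optics", "affinity_propagation")) {
    params <- if (alg %in% c("kmeans", "agglomerative", "spectral"))
      list(k = 2) else list()
    rep_ <- run_clustering(pb$x, alg, params = params, seed = 3)
    expect_s3_class(rep_, "lsr_clustering")
    expect_length(rep_$labels, 20)
    if (alg %in% c("kmeans", "agglomerative", "spectral", "dbscan"))
      expect_equal(length(unique(paste(rep_$labels, pb$labels))), 2,
                   info = alg)
  }
})

test_that("meanshift with a huge bandwidth collapses to one cluster", {
  pb <- planted_blobs(1, per = 15, seed = 43)
  rep_ <- run_clustering(pb$x, "meanshift",
                         params = list(bandwidth = 1e4), seed = 1)
  expect_equal(rep_$k, 1)
})

test_that("silhouette matches hand evaluation and brute force", {
  # 1-D points {0, 0.1, 10, 10.1} in two pairs
  D <- as.matrix(dist(c(0, 0.1, 10, 10.1)))
  lab <- c(1, 1, 2, 2)
  s <- silhouette_mean(D, lab)
  # hand: a = 0.1, b = mean(10,10.1)=10.05 (point 1) -> (10.05-0.1)/10.05
  hand <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                 (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(s, hand, tolerance = 1e-12)
  expect_equal(round(s, 3), 0.990)
  # duplicated points per cluster: a = 0 -> s = 1 exactly
  D2 <- as.matrix(dist(c(0, 0, 5, 5)))
  expect_equal(silhouette_mean(D2, c(1, 1, 2, 2)), 1)
  expect_error(silhouette_mean(D2, rep(1, 4)), "at least 2")
  # random labels on one blob: near zero
  set.seed(44)
  x <- matrix(rnorm(60), 20, 3)
  Dx <- as.matrix(dist(x))
  expect_lt(abs(silhouette_mean(Dx, sample(1:2, 20, TRUE))), 0.25)
})

test_that("silhouette agrees with brute force on random small datasets", {
  set.seed(45)
  for (rep_ in 1:25) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(x))
    k <- sample(2:3, 1)
    lab <- sample(rep(seq_len(k), length.out = n))
    expect_equal(silhouette_mean(D, lab), silhouette_oracle(D, lab),
                 tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package on Tanimoto distances", {
  skip_if_not_installed("cluster")
  pb <- planted_blobs(3, per = 8, seed = 46)
  D <- tanimoto_distance_matrix(pb$x)
  sil <- cluster::silhouette(pb$labels, dmatrix = D)
  expect_equal(silhouette_mean(D, pb$labels),
               mean(sil[, "sil_width"]), tolerance = 1e-12)
})

test_that("tune_clusters recovers the planted cluster number", {
  pb <- planted_blobs(5, per = 10, seed = 47)
  tn <- tune_clusters(pb$x, "kmeans", seed = 2)
  expect_equal(tn$best$k, 5)
  expect_equal(unname(tn$best_param), 5)
  expect_true(all(c("k", "sse", "silhouette") %in% names(tn$curves)))
  # SSE decreases with k on the curve (elbow shape)
  expect_true(all(diff(tn$curves$sse) <= 1e-8))
  pb2 <- planted_blobs(2, per = 10, seed = 48)
  tn2 <- tune_clusters(pb2$x, "kmeans", seed = 2)
  expect_equal(tn2$best$k, 2)   # well-separated: degeneracy rule must not fire
})

test_that("the k = 2 degeneracy guard retreats to the next silhouette", {
  pb <- planted_blobs(5, per = 10, seed = 49)
  # force the guard: declare any k = 2 SSE 'still large'
  tn <- tune_clusters(pb$x, "kmeans", seed = 2, sse_ratio = 0)
  expect_gt(tn$best$k, 2)
})

test_that("bandwidth-style tuning emits a silhouette curve with an argmax", {
  pb <- planted_blobs(3, per = 8, seed = 50)
  tn <- tune_clusters(pb$x, "meanshift", seed = 1)
  expect_s3_class(tn, "lsr_tuning")
  expect_equal(names(tn$curves)[1], "bandwidth")
  best_sil <- tn$curves$silhouette[match(unname(tn$best_param),
                                         tn$curves$bandwidth)]
  expect_equal(max(tn$curves$silhouette, na.rm = TRUE), best_sil)
  expect_equal(tn$best$k, 3)
})

test_that("pca embedding preserves exact low-rank geometry", {
  set.seed(51)
  # points on a 2-D plane embedded in high dimension
  basis <- qr.Q(qr(matrix(rnorm(128 * 2), 128, 2)))
  coords <- matrix(rnorm(40), 20, 2)
  x <- coords %*% t(basis)
  emb <- pca_embed(x, 2)
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(coords)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # duplicated rows embed identically
  x2 <- rbind(x, x[1, ])
  emb2 <- pca_embed(x2, 2)
  expect_equal(emb2[21, ], emb2[1, ], tolerance = 1e-9)
  # component variances are ordered
  y <- matrix(rnorm(300), 50, 6)
  e3 <- pca_embed(y, 3)
  v <- apply(e3, 2, var)
  expect_true(v[1] >= v[2] && v[2] >= v[3])
  expect_error(pca_embed(x[1:2, ], 2), "at least")
  # deterministic including sign
  expect_identical(pca_embed(x, 2), pca_embed(x, 2))
})
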