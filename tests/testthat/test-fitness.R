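# Shape + electrostatics fitness: contracts and numerical oracles.

frag_df <- function(elements, xyz) {
  data.frame(element = elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

test_that("self shape overlap is exactly 1 and empty input errors", {
  set.seed(31)
  f <- frag_df(c("C", "N", "O"), matrix(rnorm(9), 3, 3))
  expect_equal(shape_overlap(f, f), 1)
  expect_error(shape_overlap(f[0, ], f), "empty")
})

test_that("distant fragments have vanishing overlap", {
  f1 <- frag_df("C", matrix(0, 1, 3))
  f2 <- frag_df("C", matrix(c(100, 0, 0), 1, 3))
  expect_lt(shape_overlap(f1, f2), 1e-6)
})

test_that("two-carbon overlap matches dense-grid numerical integration", {
  cfg <- fitness_config()
  f1 <- frag_df("C", matrix(0, 1, 3))
  f2 <- frag_df("C", matrix(c(1, 0, 0), 1, 3))
  got <- shape_overlap(f1, f2, cfg)
  # oracle: integrate the two Gaussians on a dense grid
  sigma <- cfg$shape_sigma * 1.7          # carbon vdW radius
  h <- 0.12
  g <- seq(-6, 7, by = h)
  gx <- rep(g, times = length(g) * length(g))
  gy <- rep(rep(g, each = length(g)), times = length(g))
  gz <- rep(g, each = length(g)^2)
  ga <- exp(-(gx^2 + gy^2 + gz^2) / (2 * sigma^2))
  gb <- exp(-((gx - 1)^2 + gy^2 + gz^2) / (2 * sigma^2))
  vab <- sum(ga * gb) * h^3
  vaa <- sum(ga * ga) * h^3
  oracle <- vab / (2 * vaa - vab)
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("shape and esp are symmetric and rigid-motion invariant", {
  set.seed(32)
  a <- frag_df(c("C", "O", "N", "C"), matrix(rnorm(12), 4, 3))
  b <- frag_df(c("C", "C", "O"), matrix(rnorm(9, 0.5), 3, 3))
  expect_equal(shape_overlap(a, b), shape_overlap(b, a), tolerance = 1e-9)
  expect_equal(esp_similarity(a, b), esp_similarity(b, a), tolerance = 1e-9)
  R <- random_rotation_matrix()
  tv <- runif(3, -5, 5)
  mv <- function(f) {
    xyz <- t(R %*% t(as.matrix(f[, c("x", "y", "z")]))) +
      rep(tv, each = nrow(f))
    frag_df(f$element, xyz)
  }
  expect_equal(shape_overlap(mv(a), mv(b)), shape_overlap(a, b),
               tolerance = 1e-9)
  expect_equal(esp_similarity(mv(a), mv(b)), esp_similarity(a, b),
               tolerance = 1e-6)
})

test_that("EEM charges are deterministic, neutral in total, and polarity-sensible", {
  set.seed(33)
  xyz <- rbind(c(0, 0, 0), c(1.23, 0, 0), c(-1.4, 0.4, 0))
  f <- frag_df(c("C", "O", "C"), xyz)
  q1 <- assign_charges(f); q2 <- assign_charges(f)
  expect_identical(q1, q2)
  expect_equal(sum(q1), 0, tolerance = 1e-9)
  expect_lt(q1[2], 0)            # oxygen pulls negative charge
  expect_equal(assign_charges(frag_df("C", matrix(0, 1, 3))), 0)
})

test_that("esp contract: self 1, negated copy 0, nonpolar pair 1", {
  set.seed(34)
  f <- frag_df(c("C", "O", "N"), matrix(rnorm(9), 3, 3))
  expect_equal(esp_similarity(f, f), 1, tolerance = 1e-12)
  q <- assign_charges(f)
  expect_equal(esp_similarity(f, f, charges_a = q, charges_b = -q), 0,
               tolerance = 1e-12)
  # all-carbon fragments carry zero EEM charge: fields identical
  c1 <- frag_df(rep("C", 3), matrix(rnorm(9), 3, 3))
  c2 <- frag_df(rep("C", 4), matrix(rnorm(12), 4, 3))
  expect_equal(esp_similarity(c1, c2), 1)
})

test_that("hodgkin similarity matches dense-grid integration for a polar pair", {
  cfg <- fitness_config()
  a <- frag_df(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  b <- frag_df(c("C", "N"), rbind(c(0.3, 0.2, 0), c(1.4, 0.3, 0)))
  qa <- assign_charges(a); qb <- assign_charges(b)
  got <- esp_similarity(a, b, cfg, qa, qb)
  s <- cfg$esp_sigma
  h <- 0.15
  g <- seq(-5, 6.5, by = h)
  gx <- rep(g, times = length(g) * length(g))
  gy <- rep(rep(g, each = length(g)), times = length(g))
  gz <- rep(g, each = length(g)^2)
  field <- function(f, q) {
    ps <- 0
    for (i in seq_len(nrow(f)))
      ps <- ps + q[i] * exp(-((gx - f$x[i])^2 + (gy - f$y[i])^2 +
                                (gz - f$z[i])^2) / (2 * s^2))
    ps
  }
  pa <- field(a, qa); pb <- field(b, qb)
  H <- 2 * sum(pa * pb) / (sum(pa^2) + sum(pb^2))
  expect_equal(got, (H + 1) / 2, tolerance = 1e-3)
})

test_that("combined score respects the weight and stays in [0,1]", {
  set.seed(35)
  for (rep in 1:5) {
    a <- frag_df(sample(c("C", "N", "O", "S"), 4, TRUE),
                 matrix(rnorm(12, sd = 2), 4, 3))
    b <- frag_df(sample(c("C", "N", "O"), 3, TRUE),
                 matrix(rnorm(9, sd = 2), 3, 3))
    sc <- score_fragment(a, b)
    expect_gte(sc$shape, 0); expect_lte(sc$shape, 1)
    expect_gte(sc$esp, 0); expect_lte(sc$esp, 1)
    expect_equal(sc$combined, 0.5 * sc$shape + 0.5 * sc$esp)
  }
  a <- frag_df(c("C", "O"), rbind(c(0, 0, 0), c(1.3, 0, 0)))
  expect_equal(score_fragment(a, a)$combined, 1)
})

test_that("threshold filtering keeps the boundary and breaks ties as declared", {
  mk <- function(score, smiles, natoms) {
    structure(list(atoms = data.frame(element = rep("C", natoms)),
                   smiles = smiles, attachment_count = 0L,
                   fitness = list(combined = score)),
              class = "lsr_fragment")
  }
  out <- filter_rank(list(mk(0.6, "CCO", 3), mk(0.19, "CC", 2),
                          mk(0.2, "CO", 2)))
  expect_equal(vapply(out, function(f) f$fitness$combined, 0), c(0.6, 0.2))
  # ties: smaller fragment first, then lexicographic SMILES
  out2 <- filter_rank(list(mk(0.5, "CCO", 3), mk(0.5, "CO", 2),
                           mk(0.5, "CN", 2)))
  expect_equal(vapply(out2, function(f) f$smiles, ""),
               c("CN", "CO", "CCO"))
  expect_length(filter_rank(list()), 0)
  expect_length(filter_rank(list(mk(0.1, "C", 1))), 0)
})
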