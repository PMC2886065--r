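test_that("expected_la matches an independent numerical-integration oracle", {
  # E[Z c(Z)] with c = tanh: oracle by adaptive quadrature over z phi(z)
  oracle <- function(cf)
    integrate(function(z) z * cf(z) * dnorm(z), -Inf, Inf,
              rel.tol = 1e-12)$value
  m1 <- mediation_fn("tanh", rho_max = 0.999999, kappa = 1)
  expect_equal(expected_la(m1), oracle(m1$c), tolerance = 1e-8)
  expect_equal(expected_la(m1), 0.605, tolerance = 2e-3)
  m2 <- mediation_fn("linear_clipped", rho_max = 0.8, kappa = 0.5)
  expect_equal(expected_la(m2), oracle(m2$c), tolerance = 1e-8)
  # constant mediation carries no three-way signal
  expect_equal(expected_la(mediation_fn("constant", 0.7)), 0,
               tolerance = 1e-12)
  # linear in rho_max
  m9 <- mediation_fn("tanh", rho_max = 0.9, kappa = 1)
  expect_equal(expected_la(m9), 0.9 * expected_la(m1), tolerance = 1e-5)
  expect_error(mediation_fn("tanh", rho_max = 1), "rho_max")
  expect_error(mediation_fn("tanh", kappa = -1), "kappa")
  expect_error(expected_la(m1, nodes = 16), "64")
})

test_that("generation is deterministic and honors the spec layout", {
  spec <- planted_spec(50, c(20, 60, 8), missing_rate = 0.1, seed = 51L)
  g1 <- generate_dataset(spec)
  g2 <- generate_dataset(spec)
  expect_identical(g1$dataset$values, g2$dataset$values)
  expect_equal(dim(g1$dataset$values), c(50L, 88L))
  expect_equal(as.vector(table(g1$dataset$batch_labels)[
    unique(g1$dataset$batch_labels)]), c(20L, 60L, 8L))
  expect_equal(mean(is.na(g1$dataset$values)), 0.1, tolerance = 0.1)
  expect_equal(g1$truth$expected_la,
               expected_la(mediation_fn("tanh", 0.9, 1)))
  # different seed, different draw
  spec2 <- planted_spec(50, c(20, 60, 8), missing_rate = 0.1, seed = 52L)
  expect_false(identical(generate_dataset(spec2)$dataset$values,
                         g1$dataset$values))
})

test_that("spec validation rejects overlapping planted roles", {
  med <- mediation_fn("tanh", 0.9, 1)
  expect_error(synthetic_spec(10, c(4, 4), list(
    list(x = 1L, y = 2L, z = 3L, mediation = med),
    list(x = 3L, y = 4L, z = 5L, mediation = med))), "more than one")
  expect_error(synthetic_spec(10, c(4, 4), list(
    list(x = 1L, y = 1L, z = 2L, mediation = med))), "distinct")
  expect_error(synthetic_spec(10, c(4, 4), list(
    list(x = 1L, y = 2L, z = 99L, mediation = med))), "range")
  expect_error(synthetic_spec(5, c(1, 4)), "2 samples")
  expect_error(synthetic_spec(5, c(4, 4), missing_rate = 1), "missing_rate")
})

test_that("background genes are independent: pairwise correlations stay small", {
  spec <- synthetic_spec(40, 200, seed = 53L)
  gen <- generate_dataset(spec)
  cors <- cor(t(gen$dataset$values))
  off <- cors[upper.tri(cors)]
  # |r| bounded at ~4/sqrt(n) for all 780 background pairs
  expect_lt(max(abs(off)), 4 / sqrt(200))
})

test_that("planted subgroup correlation matches the Monte-Carlo prediction", {
  # strong steep mediation: in the top half of z, corr(x, y) approaches
  # rho_max * E[tanh(kappa Z) | Z in upper half]
  spec <- synthetic_spec(3, 10000, planted_triplets = list(
    list(x = 1L, y = 2L, z = 3L,
         mediation = mediation_fn("tanh", 0.9, 25))),
    seed = 54L)
  gen <- generate_dataset(spec)
  v <- gen$dataset$values
  hi <- v[3, ] > median(v[3, ])
  # E[tanh(25 Z) | Z > 0] by quadrature
  pred <- 0.9 * 2 * integrate(function(z) tanh(25 * z) * dnorm(z),
                              0, Inf, rel.tol = 1e-10)$value
  expect_equal(cor(v[1, hi], v[2, hi]), pred, tolerance = 0.05)
})

test_that("sample LA on transformed planted data converges to expected_la", {
  med <- mediation_fn("tanh", 0.9, 1)
  target <- expected_la(med)
  scores <- vapply(1:30, function(r) {
    spec <- synthetic_spec(3, 5000, planted_triplets = list(
      list(x = 1L, y = 2L, z = 3L, mediation = med)), seed = 54000L + r)
    gen <- generate_dataset(spec)
    tds <- transform_dataset(gen$dataset)
    la_score(tds$values[1, ], tds$values[2, ], tds$values[3, ])$la_score
  }, numeric(1))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - target), 3 * se + 0.01)
})

test_that("background LA scores scatter around zero at scale 1/sqrt(n)", {
  spec <- synthetic_spec(30, 100, seed = 55L)
  tds <- transform_dataset(generate_dataset(spec)$dataset)
  st <- scout_z(tds, "g0001", "g0002", top_k = 28)
  expect_lt(abs(mean(st$scores)), 0.05)
  expect_equal(sd(st$scores), 1 / sqrt(100), tolerance = 0.5)
})

test_that("recovery_experiment with one replicate equals the single run", {
  spec <- planted_spec(30, c(10, 10), seed = 56L)
  rs <- recovery_experiment(spec, n_replicates = 1, seed = 7L)
  spec1 <- spec
  spec1$seed <- spec$seed + 7L + 1L
  gen <- generate_dataset(spec1)
  tds <- transform_dataset(gen$dataset)
  st <- scout_z(tds, "g0001", "g0002", top_k = 30)
  expect_equal(rs$places, st$top$place[st$top$z == "g0003"])
  expect_equal(rs$place1_rate, as.numeric(rs$places == 1L))
})

test_that("null mediation leaves the planted gene's rank uninformative", {
  spec <- synthetic_spec(20, c(10, 10), planted_triplets = list(
    list(x = 1L, y = 2L, z = 3L, mediation = mediation_fn("constant", 0.5))),
    seed = 57L)
  rs <- recovery_experiment(spec, n_replicates = 25, seed = 11L)
  # place roughly uniform over 18 candidates: mean near 9.5, not pinned at 1
  expect_gt(mean(rs$places), 3)
  expect_lt(rs$place1_rate, 0.5)
})

test_that("synthetic files round-trip through the plain-text writers", {
  gen <- generate_dataset(planted_spec(8, c(4, 4), missing_rate = 0.1,
                                       seed = 58L))
  dir <- withr::local_tempdir()
  paths <- write_synthetic(gen, dir)
  st <- read_expression_table(paths[["expression"]], "tsv")
  bm <- read_batch_map(paths[["batches"]])
  expect_identical(is.na(st$values), is.na(gen$dataset$values))
  expect_identical(st$values[!is.na(st$values)],
                   gen$dataset$values[!is.na(gen$dataset$values)])
  expect_equal(unname(bm[st$sample_ids]), gen$dataset$batch_labels)
  truth <- read.delim(paths[["truth"]])
  expect_equal(truth$z, "g0003")
})
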