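test_that("asymptotic p-values match the normal-CDF oracle", {
  # sqrt(88) * 0.3755 ~ 3.52 -> upper tail ~ 2.1e-4
  p <- asymptotic_pvalue(0.3755, 88)
  expect_equal(p$p, pnorm(sqrt(88) * 0.3755, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(p$p, 2.1e-4, tolerance = 0.05)
  expect_equal(asymptotic_pvalue(0, 88)$p, 0.5)
  # two-sided p is sign-symmetric
  expect_equal(asymptotic_pvalue(-0.2, 50, "two_sided")$p,
               asymptotic_pvalue(0.2, 50, "two_sided")$p)
  expect_error(asymptotic_pvalue(0.1, 5), "n_used")
})

test_that("permutation p-values are seeded, bounded, and honest at the null center", {
  withr::with_seed(31L, {
    x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
  })
  p1 <- permutation_pvalue(x, y, z, B = 500, seed = 9L, scope = "global")
  p2 <- permutation_pvalue(x, y, z, B = 500, seed = 9L, scope = "global")
  expect_identical(p1$p, p2$p)  # determinism under a fixed seed
  expect_gte(p1$p, 1 / 501)
  expect_lte(p1$p, 1)
  # observed score ~0: at the center of a symmetric null
  x0 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  y0 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  z0 <- c(1, 1, 1, 1, -1, -1, -1, -1)  # exact LA = 0
  p0 <- permutation_pvalue(x0, y0, z0, B = 400, seed = 2L,
                           scope = "global")
  expect_gte(p0$p, 0.5)
  expect_error(permutation_pvalue(x, y, z, B = 0), "B")
  expect_error(permutation_pvalue(x, y, z, B = 10, scope = "within_batch"),
               "batch_labels")
})

test_that("the null distribution is exchange-invariant across which profile is shuffled", {
  withr::with_seed(32L, {
    x <- rnorm(60); y <- rnorm(60); z <- rnorm(60)
  })
  pz <- permutation_pvalue(x, y, z, B = 3000, seed = 5L, scope = "global")
  px <- permutation_pvalue(y, z, x, B = 3000, seed = 5L, scope = "global")
  # same statistic, same seed, shuffled argument swapped: p within MC error
  expect_lt(abs(pz$p - px$p), 3 * sqrt(0.25 / 3000) * 2)
})

test_that("within-batch permutation only shuffles inside batches", {
  batches <- rep(c("a", "b"), each = 4)
  # z constant within each batch: within-batch shuffles leave z unchanged,
  # so every permuted score equals the observed one and p = 1
  z <- c(rep(2, 4), rep(-1, 4))
  withr::with_seed(33L, { x <- rnorm(8); y <- rnorm(8) })
  p <- permutation_pvalue(x, y, z, B = 200, seed = 4L,
                          scope = "within_batch", batch_labels = batches)
  expect_equal(p$p, 1)
})

test_that("asymptotic and permutation p agree on a Gaussian null at n = 88", {
  withr::with_seed(34L, {
    x <- rnorm(88); y <- rnorm(88); z <- rnorm(88)
  })
  x <- normal_score_transform(x); y <- normal_score_transform(y)
  z <- normal_score_transform(z)
  pp <- permutation_pvalue(x, y, z, B = 20000, seed = 6L,
                           scope = "global")
  pa <- asymptotic_pvalue(pp$observed, 88)
  expect_lt(abs(pp$p - pa$p),
            0.02 + 3 * sqrt(pa$p * (1 - pa$p) / 20000))
})

test_that("null-pool draws are distinct pool pairs and counts add up", {
  ds <- make_dataset(40, c(10, 10), seed = 35L)
  tds <- transform_dataset(ds)
  pool <- tds$gene_ids[1:20]
  res <- null_pool_experiment(tds, pool, c("g021", "g001"), n_pairs = 50,
                              seed = 3L)
  expect_equal(nrow(res$sampled_pairs), 50L)
  keys <- paste(res$sampled_pairs$x, res$sampled_pairs$y)
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(res$sampled_pairs$x %in% pool))
  expect_true(all(res$sampled_pairs$y %in% pool))
  expect_true(all(res$sampled_pairs$x < res$sampled_pairs$y))
  expect_true(all(res$counts <= 50))
  expect_equal(res$counts[["g001"]], 0L)  # leads excluded as own scout
  # audited leaders match an independent recount
  recount <- sum(res$sampled_pairs$leading_scout == "g021")
  expect_equal(res$counts[["g021"]], recount)
  # reproducible draw
  res2 <- null_pool_experiment(tds, pool, "g021", n_pairs = 50, seed = 3L)
  expect_identical(res2$sampled_pairs[c("x", "y")],
                   res$sampled_pairs[c("x", "y")])
  expect_error(null_pool_experiment(tds, pool, "g021", n_pairs = 1000),
               "exceeds")
  expect_equal(null_pool_experiment(tds, pool, "g021", 0)$counts[["g021"]],
               0L)
})

test_that("a dominant planted mediator is detected for every random pair", {
  # one strong global mediator: a shared factor whose loading rises with
  # z gives EVERY pool pair conditional correlation c(z), monotone in z
  n <- 200
  withr::with_seed(36L, {
    z <- rnorm(n)
    cc <- 0.9 * (1 + tanh(2 * z)) / 2
    f <- rnorm(n)
    v <- matrix(rnorm(12 * n), 12, n)
    for (i in 1:12) v[i, ] <- sqrt(cc) * f + sqrt(1 - cc) * v[i, ]
  })
  v <- rbind(v, z)
  rownames(v) <- sprintf("g%03d", 1:13)
  colnames(v) <- sprintf("s%03d", 1:n)
  tds <- transform_dataset(expression_dataset(v, rep("b1", n)))
  res <- null_pool_experiment(tds, sprintf("g%03d", 1:12), "g013",
                              n_pairs = 20, seed = 8L)
  expect_equal(res$counts[["g013"]], 20L)
  expect_equal(res$fractions[["g013"]], 1)
})

test_that("null-pool counts across seeds behave like a binomial draw", {
  ds <- make_dataset(30, 20, seed = 37L)
  tds <- transform_dataset(ds)
  pool <- tds$gene_ids[1:15]
  target <- "g016"
  counts <- vapply(1:12, function(s)
    null_pool_experiment(tds, pool, target, n_pairs = 30,
                         seed = s)$counts[[target]], integer(1))
  # dispersion sanity: variance within an order of magnitude of binomial
  phat <- mean(counts) / 30
  if (phat > 0)
    expect_lt(var(counts), 10 * 30 * phat * (1 - phat) + 1)
})
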