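# Shared fixtures and independent oracles for the test suite.

# Small random series with optional missingness.
make_series <- function(series_id, n_genes, n_samples, missing = 0,
                        gene_ids = sprintf("SO%04d", seq_len(n_genes)),
                        seed = 1L) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(gene_ids,
                                sprintf("%s_s%d", series_id,
                                        seq_len(n_samples))))
    if (missing > 0) v[runif(length(v)) < missing] <- NA_real_
    series_table(series_id, v)
  })
}

# Random already-on-LA-scale dataset (values i.i.d. normal), one batch
# unless batch sizes given.
make_dataset <- function(n_genes, batch_sizes, missing = 0, seed = 1L) {
  withr::with_seed(seed, {
    n <- sum(batch_sizes)
    v <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n))))
    if (missing > 0) v[runif(length(v)) < missing] <- NA_real_
    expression_dataset(v, rep(sprintf("b%d", seq_along(batch_sizes)),
                              batch_sizes))
  })
}

# Write a GEO series-matrix-style fixture around a value matrix.
write_geo_fixture <- function(values, path) {
  lines <- c(
    "!Series_title\t\"synthetic fixture\"",
    "!Series_platform_id\t\"GPL0000\"",
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"",
            sprintf("\"%s\"", colnames(values))), collapse = "\t"),
    vapply(seq_len(nrow(values)), function(i)
      paste(c(sprintf("\"%s\"", rownames(values)[i]),
              ifelse(is.na(values[i, ]), "",
                     format(values[i, ], digits = 10))),
            collapse = "\t"), ""),
    "!series_matrix_table_end",
    "!extra_trailing_metadata\t\"ignored\"")
  writeLines(lines, path)
  path
}

# Brute-force LA score over complete triples: the oracle for la_score
# and the vectorized searches.
naive_la <- function(x, y, z, policy = "complete_triples") {
  s <- 0; n_used <- 0
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && !is.na(y[i]) && !is.na(z[i])) {
      s <- s + x[i] * y[i] * z[i]
      n_used <- n_used + 1
    }
  }
  s / if (policy == "complete_triples") n_used else length(x)
}

# Naive triple loop behind scout_z.
naive_scout_scores <- function(ds, xg, yg) {
  cand <- setdiff(ds$gene_ids, c(xg, yg))
  vapply(cand, function(zg)
    naive_la(ds$values[xg, ], ds$values[yg, ], ds$values[zg, ]),
    numeric(1))
}

# Naive double loop behind search_pairs; returns a named vector keyed
# "y|z" with y < z.
naive_pair_scores <- function(ds, xg) {
  cand <- setdiff(ds$gene_ids, xg)
  out <- c()
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (i < j) {
      s <- naive_la(ds$values[xg, ], ds$values[cand[i], ],
                    ds$values[cand[j], ])
      out[paste(cand[i], cand[j], sep = "|")] <- s
    }
  }
  out
}

# Spec for one planted tanh triplet in front of background noise.
planted_spec <- function(n_genes = 200, batch_sizes = c(20, 60, 8),
                         rho_max = 0.9, kappa = 1, missing_rate = 0,
                         seed = 1L) {
  synthetic_spec(n_genes, batch_sizes, planted_triplets = list(
    list(x = 1L, y = 2L, z = 3L,
         mediation = mediation_fn("tanh", rho_max, kappa))),
    missing_rate = missing_rate, seed = seed)
}
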