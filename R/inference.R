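# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Permutation p-value for an LA score
#'
#' Destroys the three-way association by permuting the mediator profile
#' z across samples B times and compares the observed LA score with the
#' permuted ones: p = (1 + #extreme) / (B + 1). Under
#' `scope = "within_batch"` the permutation shuffles samples only within
#' each batch, respecting the per-series normal-score transform; under
#' `"global"` the whole profile is shuffled. Because the statistic is
#' symmetric in (x, y, z), permuting z is equivalent to permuting any of
#' the three under the global scope.
#'
#' @param x,y,z Equal-length transformed profiles (`NA` = missing).
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed; the computation is reproducible and leaves
#'   the caller's RNG state untouched.
#' @param scope `"within_batch"` (default; requires `batch_labels`) or
#'   `"global"`.
#' @param batch_labels Batch label per sample, required for
#'   `within_batch`.
#' @param sidedness `"one_sided_signed"` (extreme = at least as far in
#'   the direction of the observed sign; default) or `"two_sided"`
#'   (extreme = |permuted| >= |observed|).
#' @param denominator_policy See [la_score()].
#' @return List of class `pvalue_result`: `p`, `observed`, `B`,
#'   `method = "permutation"`, `sidedness`, `n_used`.
#' @export
permutation_pvalue <- function(x, y, z, B = 10000L, seed = 1L,
                               scope = c("within_batch", "global"),
                               batch_labels = NULL,
                               sidedness = c("one_sided_signed",
                                             "two_sided"),
                               denominator_policy = c("complete_triples",
                                                      "total_n")) {
  scope <- match.arg(scope)
  sidedness <- match.arg(sidedness)
  denominator_policy <- match.arg(denominator_policy)
  if (B < 1L) stop("B must be >= 1")
  if (scope == "within_batch" && is.null(batch_labels))
    stop("within_batch scope requires batch_labels")
  obs <- la_score(x, y, z, denominator_policy)
  n <- length(z)
  w <- x * y
  perm_idx <- .with_seed(seed, {
    if (scope == "global") {
      t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
    } else {
      groups <- split(seq_len(n), batch_labels)
      t(vapply(seq_len(B), function(b) {
        idx <- integer(n)
        for (g in groups) idx[g] <- g[sample.int(length(g))]
        idx
      }, integer(n)))
    }
  })
  Zp <- matrix(z[perm_idx], nrow = B)
  P <- Zp * rep(w, each = B)
  n_used <- rowSums(!is.na(P))
  denom <- if (denominator_policy == "complete_triples") n_used else n
  perm_scores <- rowSums(P, na.rm = TRUE) / denom
  extreme <- switch(sidedness,
    one_sided_signed = if (obs$la_score >= 0)
      perm_scores >= obs$la_score else perm_scores <= obs$la_score,
    two_sided = abs(perm_scores) >= abs(obs$la_score))
  structure(list(p = (1 + sum(extreme)) / (B + 1),
                 observed = obs$la_score, B = B,
                 method = "permutation", sidedness = sidedness,
                 scope = scope, n_used = obs$n_used),
            class = "pvalue_result")
}

#' Large-sample normal p-value for an LA score
#'
#' The LA score is a mean of n bounded products; for independent
#' normal-scored profiles each product has mean 0 and variance close to
#' 1, so sqrt(n) * LA is approximately standard normal under the null.
#' The one-sided, sign-matched p-value is the normal tail probability
#' beyond sqrt(n_used) * |observed|; the two-sided p doubles it.
#'
#' @param observed Observed LA score.
#' @param n_used Number of complete triples behind it (>= 10 for the
#'   approximation to be meaningful).
#' @param sidedness `"one_sided_signed"` (default) or `"two_sided"`.
#' @return List of class `pvalue_result`.
#' @examples
#' asymptotic_pvalue(0.3755, 88)$p  # ~2.1e-4
#' @export
asymptotic_pvalue <- function(observed, n_used,
                              sidedness = c("one_sided_signed",
                                            "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (n_used < 10L)
    stop("asymptotic p-value needs n_used >= 10; got ", n_used)
  tail <- stats::pnorm(sqrt(n_used) * abs(observed), lower.tail = FALSE)
  p <- if (sidedness == "two_sided") min(1, 2 * tail) else tail
  structure(list(p = p, observed = observed, B = NA_integer_,
                 method = "asymptotic", sidedness = sidedness,
                 n_used = n_used),
            class = "pvalue_result")
}

#' @export
print.pvalue_result <- function(x, ...) {
  cat(sprintf("<pvalue_result> %s %s: p = %.4g (observed LA %.4f, n = %d%s)\n",
              x$method, x$sidedness, x$p, x$observed, x$n_used,
              if (!is.na(x$B)) sprintf(", B = %d", x$B) else ""))
  invisible(x)
}

# Unrank 1-based linear indices over unordered pairs (i < j) of n items,
# lexicographic order. f(i) = i*(2n - i - 1)/2 counts pairs with first
# element <= i.
.unrank_pairs <- function(m, n) {
  f <- function(i) i * (2 * n - i - 1) / 2
  i <- floor(n - 0.5 - sqrt((n - 0.5)^2 - 2 * m))  # initial guess
  i <- pmax(pmin(i, n - 1), 0)
  # fix rounding: want smallest i with f(i) >= m, then first = i
  repeat {
    lo <- f(i) < m
    hi <- f(pmax(i - 1, 0)) >= m & i > 1
    if (!any(lo | hi)) break
    i <- i + lo - hi
  }
  first <- i
  second <- first + (m - f(first - 1))
  cbind(first, second)
}

# Place-1 positive scouting gene for a lead pair, lexicographic tie-break.
.leading_scout <- function(values, gene_ids, xg, yg, denominator_policy) {
  w <- values[xg, ] * values[yg, ]
  cand <- setdiff(gene_ids, c(xg, yg))
  sc <- .la_against_weight(values[cand, , drop = FALSE], w,
                           denominator_policy, ncol(values))
  s <- sc$score
  ok <- !is.na(s)
  if (!any(ok)) return(NA_character_)
  best <- max(s[ok])
  min(cand[ok][s[ok] == best])
}

#' Random-pair null-pool experiment
#'
#' Estimates how often given target genes emerge as the leading
#' (place-1 positive) scouting gene purely by chance: draws `n_pairs`
#' distinct unordered lead pairs uniformly from a pool of genes presumed
#' irrelevant to the process under study, scouts every pair over all
#' candidate genes, and counts per target how many pairs it leads. The
#' count divided by `n_pairs` estimates the chance detection rate.
#'
#' @param ds A transformed [expression_dataset()].
#' @param pool_ids Gene ids forming the pool lead pairs are drawn from
#'   (>= 2 genes). Targets need not be in the pool.
#' @param target_ids Gene ids whose detections are counted.
#' @param n_pairs Number of distinct pairs to draw (0 allowed).
#' @param seed Integer seed for the draw.
#' @param index Alias index for query resolution.
#' @param denominator_policy See [la_score()].
#' @return List of class `null_pool_result`: `counts` (named integer
#'   vector per target), `fractions`, `n_pairs`, `seed`,
#'   `sampled_pairs` (data frame `x`, `y`, `leading_scout` for audit).
#' @export
null_pool_experiment <- function(ds, pool_ids, target_ids, n_pairs,
                                 seed = 1L, index = so_gene_index(),
                                 denominator_policy = c("complete_triples",
                                                        "total_n")) {
  stopifnot(inherits(ds, "expression_dataset"))
  denominator_policy <- match.arg(denominator_policy)
  pool <- vapply(pool_ids, resolve_gene, "", index = index,
                 gene_ids = ds$gene_ids)
  targets <- vapply(target_ids, resolve_gene, "", index = index,
                    gene_ids = ds$gene_ids)
  if (length(pool) < 2L) stop("pool needs >= 2 genes")
  pool <- sort(unique(unname(pool)))
  total <- choose(length(pool), 2)
  if (n_pairs > total)
    stop("n_pairs (", n_pairs, ") exceeds the ", total,
         " distinct pairs in the pool")
  if (n_pairs == 0L) {
    return(structure(list(
      counts = stats::setNames(integer(length(targets)), targets),
      fractions = stats::setNames(numeric(length(targets)), targets),
      n_pairs = 0L, seed = seed,
      sampled_pairs = data.frame(x = character(), y = character(),
                                 leading_scout = character())),
      class = "null_pool_result"))
  }
  draw <- .with_seed(seed, sample(total, n_pairs))
  ij <- .unrank_pairs(draw, length(pool))
  xs <- pool[ij[, 1L]]
  ys <- pool[ij[, 2L]]
  leaders <- vapply(seq_len(n_pairs), function(k)
    .leading_scout(ds$values, ds$gene_ids, xs[k], ys[k],
                   denominator_policy), "")
  counts <- vapply(targets, function(t) sum(leaders == t, na.rm = TRUE),
                   integer(1))
  structure(list(counts = counts, fractions = counts / n_pairs,
                 n_pairs = as.integer(n_pairs), seed = seed,
                 sampled_pairs = data.frame(x = xs, y = ys,
                                            leading_scout = leaders,
                                            stringsAsFactors = FALSE)),
            class = "null_pool_result")
}

#' @export
print.null_pool_result <- function(x, ...) {
  cat(sprintf("<null_pool_result> %d random lead pairs (seed %d)\n",
              x$n_pairs, x$seed))
  for (t in names(x$counts))
    cat(sprintf("  %s: leading scout in %d/%d pairs (%.2f%%)\n",
                t, x$counts[[t]], x$n_pairs, 100 * x$fractions[[t]]))
  invisible(x)
}
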