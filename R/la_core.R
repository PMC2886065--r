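#' The liquid-association score of a gene triple
#'
#' For normal-scored profiles x, y, z the LA score is the mean of the
#' elementwise triple products, LA(X,Y|Z) = sum(x_i * y_i * z_i) / n.
#' It is symmetric in all three arguments; a positive score means higher
#' Z accompanies a stronger positive (X, Y) correlation. Samples where
#' any of the three values is missing are dropped from the sum; by
#' default the denominator is the number of complete triples actually
#' used (`"complete_triples"`), keeping the statistic a mean, while
#' `"total_n"` divides by the full profile length.
#'
#' @param x,y,z Numeric profiles of equal length (normal-scored).
#' @param denominator_policy `"complete_triples"` (default) or
#'   `"total_n"`.
#' @return List of class `la_result`: `la_score`, `n_used`, and the
#'   policy.
#' @examples
#' la_score(c(1, -1), c(1, -1), c(1, 1))$la_score  # 1
#' @export
la_score <- function(x, y, z,
                     denominator_policy = c("complete_triples",
                                            "total_n")) {
  denominator_policy <- match.arg(denominator_policy)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("profiles must have equal length")
  p <- x * y * z
  used <- !is.na(p)
  n_used <- sum(used)
  if (n_used < 3L)
    stop("need >= 3 complete (x, y, z) triples; got ", n_used)
  denom <- if (denominator_policy == "complete_triples") n_used else n
  structure(list(la_score = sum(p[used]) / denom,
                 n_used = n_used,
                 denominator_policy = denominator_policy),
            class = "la_result")
}

# Resolve a query to a row of the dataset and return its profile.
.profile <- function(ds, id, index = so_gene_index()) {
  gid <- resolve_gene(id, index, ds$gene_ids)
  ds$values[gid, ]
}

# Signed ranking of a score vector: top = descending, bot = ascending,
# ties broken lexicographically by gene id for reproducible places.
.rank_ends <- function(scores, ids, top_k) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  ids <- ids[ok]
  k <- min(top_k, length(ids))
  o_top <- order(-scores, ids)
  o_bot <- order(scores, ids)
  list(
    top = data.frame(z = ids[o_top[seq_len(k)]],
                     la_score = scores[o_top[seq_len(k)]],
                     place = seq_len(k), stringsAsFactors = FALSE),
    bot = data.frame(z = ids[o_bot[seq_len(k)]],
                     la_score = scores[o_bot[seq_len(k)]],
                     place = seq_len(k), stringsAsFactors = FALSE),
    candidate_count = length(ids))
}

# Vectorized LA scores of every gene against a fixed sample weight w
# (w = x*y with NA where either is missing). Handles missing data by
# zero-filling and counting complete triples per gene.
.la_against_weight <- function(values, w, denominator_policy, total_n) {
  wc <- ifelse(is.na(w), 0, w)
  zf <- values
  zf[is.na(zf)] <- 0
  num <- as.vector(zf %*% wc)
  n_used <- as.vector((!is.na(values)) %*% (!is.na(w)))
  denom <- if (denominator_policy == "complete_triples") n_used
           else rep(total_n, length(num))
  score <- num / denom
  score[n_used < 3L] <- NA_real_
  list(score = score, n_used = n_used)
}

#' Genome-wide scouting of mediator genes for a lead pair
#'
#' Computes LA(X,Y|Z) for every candidate gene Z in the dataset (all
#' genes except X and Y) and returns the two signed ends of the ranking:
#' the TOP list of positive LA-scouting genes and the BOT list of
#' negative ones, each with 1-based places. Equal scores are ordered
#' lexicographically by gene id, so places are deterministic.
#'
#' The scan is a single matrix-vector product of the gene matrix with
#' the elementwise product x*y, so a full genome (~5,000 genes x 88
#' samples) takes milliseconds.
#'
#' @param ds A [transform_dataset()] result (or any expression_dataset
#'   whose values are already on the LA scale).
#' @param x_id,y_id Lead gene queries (locus tags or known aliases).
#' @param top_k List length per end (default 20).
#' @param denominator_policy See [la_score()].
#' @param index Alias index for query resolution.
#' @return List of class `scout_table`: `x_id`, `y_id`, `top` and `bot`
#'   data frames (columns `z`, `la_score`, `place`), `candidate_count`,
#'   and `scores` (the full named score vector for downstream use).
#' @export
scout_z <- function(ds, x_id, y_id, top_k = 20,
                    denominator_policy = c("complete_triples", "total_n"),
                    index = so_gene_index()) {
  stopifnot(inherits(ds, "expression_dataset"))
  denominator_policy <- match.arg(denominator_policy)
  if (top_k < 1L) stop("top_k must be >= 1")
  xg <- resolve_gene(x_id, index, ds$gene_ids)
  yg <- resolve_gene(y_id, index, ds$gene_ids)
  if (xg == yg) stop("x and y must be distinct genes")
  w <- ds$values[xg, ] * ds$values[yg, ]
  cand <- setdiff(ds$gene_ids, c(xg, yg))
  if (!length(cand)) stop("no candidate genes besides x and y")
  sc <- .la_against_weight(ds$values[cand, , drop = FALSE], w,
                           denominator_policy, ncol(ds$values))
  scores <- stats::setNames(sc$score, cand)
  ends <- .rank_ends(scores, cand, top_k)
  structure(list(x_id = xg, y_id = yg,
                 top = ends$top, bot = ends$bot,
                 candidate_count = ends$candidate_count,
                 scores = scores,
                 n_used = stats::setNames(sc$n_used, cand)),
            class = "scout_table")
}

#' @export
print.scout_table <- function(x, ...) {
  cat(sprintf("<scout_table> lead pair (%s, %s), %d candidates\n",
              x$x_id, x$y_id, x$candidate_count))
  cat("TOP (positive LA-scouting genes):\n")
  print(utils::head(x$top, 5), row.names = FALSE)
  cat("BOT (negative LA-scouting genes):\n")
  print(utils::head(x$bot, 5), row.names = FALSE)
  invisible(x)
}

#' Single-lead search over all (Y, Z) gene pairs
#'
#' Fixes one query gene X and scores every unordered pair {Y, Z} of the
#' remaining genes by LA(X,Y|Z). Implemented as a weighted cross-product
#' of the gene matrix with itself (columns weighted by X), so the full
#' genome is a single dense matrix multiplication. Because the score is
#' symmetric in Y and Z, each pair is reported once, with its members
#' labelled in gene-id order.
#'
#' @inheritParams scout_z
#' @param x_id The single lead gene query.
#' @return List of class `pair_search`: `x_id`, `top` and `bot` data
#'   frames (columns `y`, `z`, `la_score`, `place`), `pair_count`.
#' @export
search_pairs <- function(ds, x_id, top_k = 20,
                         denominator_policy = c("complete_triples",
                                                "total_n"),
                         index = so_gene_index()) {
  stopifnot(inherits(ds, "expression_dataset"))
  denominator_policy <- match.arg(denominator_policy)
  if (top_k < 1L) stop("top_k must be >= 1")
  xg <- resolve_gene(x_id, index, ds$gene_ids)
  cand <- setdiff(ds$gene_ids, xg)
  if (length(cand) < 2L) stop("need at least 2 candidate genes besides x")
  G <- ds$values[cand, , drop = FALSE]
  xw <- ds$values[xg, ]
  xo <- !is.na(xw)
  xw0 <- ifelse(xo, xw, 0)
  B <- G
  B[is.na(B)] <- 0
  num <- (B * rep(xw0, each = nrow(B))) %*% t(B)
  M <- (!is.na(G)) * 1
  n_used <- (M * rep(xo * 1, each = nrow(M))) %*% t(M)
  denom <- if (denominator_policy == "complete_triples") n_used
           else ncol(ds$values)
  S <- num / denom
  S[n_used < 3L] <- NA_real_
  ut <- upper.tri(S)
  scores <- S[ut]
  ij <- which(ut, arr.ind = TRUE)
  pair_ids <- paste(cand[ij[, 1L]], cand[ij[, 2L]], sep = "\r")
  ok <- !is.na(scores)
  scores <- scores[ok]; pair_ids <- pair_ids[ok]
  k <- min(top_k, length(scores))
  o_top <- order(-scores, pair_ids)[seq_len(k)]
  o_bot <- order(scores, pair_ids)[seq_len(k)]
  unpack <- function(o) {
    parts <- strsplit(pair_ids[o], "\r", fixed = TRUE)
    data.frame(y = vapply(parts, `[[`, "", 1L),
               z = vapply(parts, `[[`, "", 2L),
               la_score = scores[o], place = seq_along(o),
               stringsAsFactors = FALSE)
  }
  structure(list(x_id = xg, top = unpack(o_top), bot = unpack(o_bot),
                 pair_count = length(scores)),
            class = "pair_search")
}

#' @export
print.pair_search <- function(x, ...) {
  cat(sprintf("<pair_search> lead gene %s, %d candidate pairs\n",
              x$x_id, x$pair_count))
  cat("TOP of positive end:\n")
  print(utils::head(x$top, 5), row.names = FALSE)
  invisible(x)
}

#' Scouting report for a set of lead genes
#'
#' Runs [scout_z()] for every unordered pair of lead genes and emits one
#' row per reported scouting gene Z in the standard report schema:
#' X, Y, Z, LA score, the (X, Y) Pearson correlation within the high-Z
#' and low-Z sample subgroups (from [lap_split()]), a p-value, and the
#' place of Z within its signed end of the ranking.
#'
#' @inheritParams scout_z
#' @param lead_ids Character vector of >= 2 lead gene queries.
#' @param z_ids Optional character vector restricting rows to particular
#'   scouting genes (e.g. one mediator of interest across all pairs);
#'   `NULL` reports the full top-k list per pair.
#' @param end `"positive"` (TOP list, default), `"negative"`, or
#'   `"both"`.
#' @param pvalue_cfg List: `method` (`"asymptotic"`, `"permutation"` or
#'   `"none"`), and for permutation `B`, `seed`, `scope` (see
#'   [permutation_pvalue()]). Sign-matched one-sided p-values are
#'   reported, matching the signed ranking ends.
#' @param split_cfg List: `split_fraction` (default 0.5) for the
#'   high/low correlation columns.
#' @return Data frame of class `lead_set_report` with columns
#'   `x`, `y`, `z`, `la_score`, `corr_high`, `corr_low`, `p_value`,
#'   `place`, `end`.
#' @export
lead_set_report <- function(ds, lead_ids, top_k = 20, z_ids = NULL,
                            end = c("positive", "negative", "both"),
                            pvalue_cfg = list(method = "asymptotic"),
                            split_cfg = list(split_fraction = 0.5),
                            index = so_gene_index()) {
  stopifnot(inherits(ds, "expression_dataset"))
  end <- match.arg(end)
  if (length(lead_ids) < 2L) stop("need >= 2 lead genes")
  leads <- vapply(lead_ids, resolve_gene, "", index = index,
                  gene_ids = ds$gene_ids)
  if (!is.null(z_ids))
    z_ids <- vapply(z_ids, resolve_gene, "", index = index,
                    gene_ids = ds$gene_ids)
  frac <- split_cfg$split_fraction %||% 0.5
  method <- pvalue_cfg$method %||% "asymptotic"
  rows <- list()
  pairs <- utils::combn(leads, 2L)
  for (j in seq_len(ncol(pairs))) {
    xg <- pairs[1L, j]; yg <- pairs[2L, j]
    st <- scout_z(ds, xg, yg, top_k = top_k, index = index)
    ends <- switch(end, positive = list(positive = st$top),
                   negative = list(negative = st$bot),
                   both = list(positive = st$top, negative = st$bot))
    for (e in names(ends)) {
      tab <- ends[[e]]
      if (!is.null(z_ids)) tab <- tab[tab$z %in% z_ids, , drop = FALSE]
      if (!nrow(tab)) next
      for (i in seq_len(nrow(tab))) {
        zg <- tab$z[i]
        sp <- tryCatch(
          lap_split(ds$values[xg, ], ds$values[yg, ], ds$values[zg, ],
                    split_fraction = frac),
          error = function(err) list(corr_high = NA_real_,
                                     corr_low = NA_real_))
        pv <- switch(
          method,
          none = NA_real_,
          asymptotic = asymptotic_pvalue(tab$la_score[i],
                                         st$n_used[[zg]],
                                         sidedness = "one_sided_signed")$p,
          permutation = permutation_pvalue(
            ds$values[xg, ], ds$values[yg, ], ds$values[zg, ],
            B = pvalue_cfg$B %||% 10000L,
            seed = pvalue_cfg$seed %||% 1L,
            scope = pvalue_cfg$scope %||% "within_batch",
            batch_labels = ds$batch_labels,
            sidedness = "one_sided_signed")$p)
        rows[[length(rows) + 1L]] <- data.frame(
          x = xg, y = yg, z = zg, la_score = tab$la_score[i],
          corr_high = sp$corr_high, corr_low = sp$corr_low,
          p_value = pv, place = tab$place[i], end = e,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(x = character(), y = character(), z = character(),
                  la_score = numeric(), corr_high = numeric(),
                  corr_low = numeric(), p_value = numeric(),
                  place = integer(), end = character())
  class(out) <- c("lead_set_report", class(out))
  out
}

#' Recurring scouting genes across lead pairs
#'
#' Answers "which Z genes appear in the reported list of several lead
#' pairs": counts, per scouting gene, the number of distinct lead pairs
#' whose report contains it.
#'
#' @param report A [lead_set_report()] result.
#' @return Data frame with columns `z`, `n_pairs`, `best_place`, sorted
#'   by decreasing `n_pairs`.
#' @export
common_scouts <- function(report) {
  stopifnot(inherits(report, "lead_set_report"))
  if (!nrow(report))
    return(data.frame(z = character(), n_pairs = integer(),
                      best_place = integer()))
  agg <- stats::aggregate(
    cbind(n_pairs = paste(report$x, report$y)) ~ z, data = report,
    FUN = function(p) length(unique(p)))
  bp <- stats::aggregate(place ~ z, data = report, FUN = min)
  out <- merge(agg, bp, by = "z")
  names(out)[names(out) == "place"] <- "best_place"
  out$n_pairs <- as.integer(out$n_pairs)
  out[order(-out$n_pairs, out$best_place, out$z), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
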