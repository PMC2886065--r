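#' Normal-score transform of one profile
#'
#' Replaces the observed values of a profile by standard-normal quantiles
#' of their ranks: the entry with rank r among m observed values becomes
#' Phi^-1(r/(m+1)) (van der Waerden scores, the liquid-association
#' convention) or Phi^-1((r - 3/8)/(m + 1/4)) (Blom). Ranks are computed
#' with average ties by default, so the transform is deterministic and
#' invariant under any strictly increasing relabeling of the data.
#' Missing entries stay missing; output order matches input order.
#'
#' @param x Numeric vector, `NA` = missing.
#' @param tie_policy `"average_rank"` (ties share the mean rank before
#'   quantile mapping) or `"stable_order"` (ties broken by position).
#' @param convention `"vdw"` (default) or `"blom"` quantile convention.
#' @return Numeric vector, same length and missingness as `x`.
#' @examples
#' normal_score_transform(c(0.5, 2.0, 1.1))  # -0.6745 0.6745 0
#' @export
normal_score_transform <- function(x,
                                   tie_policy = c("average_rank",
                                                  "stable_order"),
                                   convention = c("vdw", "blom")) {
  tie_policy <- match.arg(tie_policy)
  convention <- match.arg(convention)
  obs <- !is.na(x)
  m <- sum(obs)
  if (m < 2L)
    stop("normal_score_transform needs >= 2 non-missing values (got ",
         m, ")")
  r <- rank(x[obs], ties.method = if (tie_policy == "average_rank")
    "average" else "first")
  q <- if (convention == "vdw") r / (m + 1) else (r - 3 / 8) / (m + 1 / 4)
  out <- rep(NA_real_, length(x))
  out[obs] <- stats::qnorm(q)
  out
}

#' Per-batch normal-score transform of a dataset
#'
#' Applies [normal_score_transform()] independently to each (gene, batch)
#' slice, so every series is Gaussianized on its own scale before
#' profiles are concatenated back in the original sample order. This
#' per-series transform is the batch handling of the LA pipeline: no
#' further cross-batch normalization is applied, and by default the
#' concatenated profile is not re-standardized (the LA score divides the
#' raw triple sum by the sample count).
#'
#' A gene with fewer than 2 observed values in some batch cannot be
#' scored there; it is retained but masked to missing for that batch and
#' recorded in the `flags` attribute.
#'
#' @param ds An [expression_dataset()].
#' @param tie_policy,convention Passed to [normal_score_transform()].
#' @param recenter_global If `TRUE`, re-center each full concatenated
#'   profile to mean 0 afterwards (sensitivity analysis only; default
#'   `FALSE`).
#' @return A `transformed_dataset` (subclass of `expression_dataset`)
#'   with attributes `transform` (metadata list) and `flags` (data frame
#'   of masked gene/batch slices).
#' @export
transform_dataset <- function(ds,
                              tie_policy = c("average_rank",
                                             "stable_order"),
                              convention = c("vdw", "blom"),
                              recenter_global = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  tie_policy <- match.arg(tie_policy)
  convention <- match.arg(convention)
  v <- ds$values
  out <- v
  flags <- list()
  for (b in unique(ds$batch_labels)) {
    cols <- which(ds$batch_labels == b)
    slice <- v[, cols, drop = FALSE]
    m <- rowSums(!is.na(slice))
    usable <- m >= 2L
    if (any(!usable))
      flags[[b]] <- data.frame(gene_id = ds$gene_ids[!usable],
                               batch = b, observed = m[!usable])
    tr <- slice
    tr[!usable, ] <- NA_real_
    if (any(usable))
      tr[usable, ] <- t(apply(slice[usable, , drop = FALSE], 1L,
                              normal_score_transform,
                              tie_policy = tie_policy,
                              convention = convention))
    out[, cols] <- tr
  }
  if (recenter_global)
    out <- out - rowMeans(out, na.rm = TRUE)
  res <- expression_dataset(out, ds$batch_labels, name = ds$name)
  class(res) <- c("transformed_dataset", class(res))
  attr(res, "transform") <- list(tie_policy = tie_policy,
                                 convention = convention,
                                 per_batch = TRUE,
                                 recenter_global = recenter_global)
  attr(res, "flags") <- if (length(flags))
    do.call(rbind, unname(flags))
  else data.frame(gene_id = character(), batch = character(),
                  observed = integer())
  res
}

#' Filter genes by observed fraction
#'
#' Keeps genes whose overall non-missing fraction is at least
#' `min_observed_fraction`; gene order is preserved.
#'
#' @param ds An `expression_dataset`.
#' @param min_observed_fraction Threshold in \[0, 1\].
#' @return The filtered dataset, with an attribute `filter` holding kept
#'   and dropped counts.
#' @export
filter_genes <- function(ds, min_observed_fraction = 0) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.numeric(min_observed_fraction) ||
      min_observed_fraction < 0 || min_observed_fraction > 1)
    stop("min_observed_fraction must lie in [0, 1]")
  frac <- rowMeans(!is.na(ds$values))
  keep <- frac >= min_observed_fraction
  out <- expression_dataset(ds$values[keep, , drop = FALSE],
                            ds$batch_labels, name = ds$name)
  if (inherits(ds, "transformed_dataset")) {
    class(out) <- class(ds)
    attr(out, "transform") <- attr(ds, "transform")
  }
  attr(out, "filter") <- list(kept = sum(keep), dropped = sum(!keep),
                              threshold = min_observed_fraction)
  out
}
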