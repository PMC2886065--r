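#' Split samples by mediator level and compute subgroup correlations
#'
#' The LAP (liquid-association pair) view sorts samples by the mediator
#' profile z and contrasts the Pearson correlation of (x, y) within the
#' high-z and low-z subgroups. With `split_fraction = 0.5` (median
#' split, the default) all z-observed samples are partitioned into two
#' halves whose sizes differ by at most one; with a smaller fraction the
#' top and bottom `split_fraction` of samples form the groups and the
#' middle samples are excluded. Ties at a cut are resolved by sample
#' order, so the split is deterministic.
#'
#' @param x,y,z Equal-length numeric profiles (`NA` = missing). Pass
#'   transformed profiles to work in the LA space (the default
#'   convention) or raw ones to inspect the original scale.
#' @param split_fraction Fraction in (0, 0.5] of samples per subgroup.
#' @param ids Optional character vector `c(x, y, z)` of gene labels used
#'   in printing and plotting.
#' @return List of class `lap_split`: `high`, `low`, `excluded` (integer
#'   sample indices), `corr_high`, `corr_low` (Pearson, `NA` with a flag
#'   when a profile is constant within a subgroup), `la_score`,
#'   `n_used`, `split_fraction`, plus the input profiles for plotting.
#' @examples
#' z <- c(-2, -1, -0.5, 0.5, 1, 2)
#' x <- c(1, 2, 3, 1, 2, 3)
#' y <- c(3, 2, 1, 1, 2, 3)
#' lap_split(x, y, z)$corr_high  # +1 within the high-z half
#' @export
lap_split <- function(x, y, z, split_fraction = 0.5, ids = NULL) {
  n <- length(z)
  if (length(x) != n || length(y) != n)
    stop("profiles must have equal length")
  if (!is.numeric(split_fraction) || split_fraction <= 0 ||
      split_fraction > 0.5)
    stop("split_fraction must lie in (0, 0.5]")
  obs <- which(!is.na(z))
  m <- length(obs)
  ord <- obs[order(z[obs])]  # stable: ties resolved by sample order
  if (split_fraction == 0.5) {
    n_low <- floor(m / 2)
    n_high <- m - n_low
  } else {
    n_low <- n_high <- floor(m * split_fraction)
  }
  low <- ord[seq_len(n_low)]
  high <- ord[seq.int(m - n_high + 1L, m)]
  excluded <- sort(c(setdiff(ord, c(low, high)), setdiff(seq_len(n), obs)))
  sub_cor <- function(idx, grp) {
    ok <- idx[!is.na(x[idx]) & !is.na(y[idx])]
    if (length(ok) < 3L)
      stop(grp, " subgroup has ", length(ok),
           " complete (x, y) pairs; need >= 3")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(structure(NA_real_, flag = "constant profile in subgroup"))
    stats::cor(x[ok], y[ok])
  }
  ch <- sub_cor(high, "high")
  cl <- sub_cor(low, "low")
  la <- la_score(x, y, z)
  structure(list(high = sort(high), low = sort(low), excluded = excluded,
                 corr_high = as.numeric(ch), corr_low = as.numeric(cl),
                 corr_flags = c(high = attr(ch, "flag"),
                                low = attr(cl, "flag")),
                 la_score = la$la_score, n_used = la$n_used,
                 split_fraction = split_fraction,
                 ids = ids, x = x, y = y, z = z),
            class = "lap_split")
}

#' @export
print.lap_split <- function(x, ...) {
  lab <- if (!is.null(x$ids))
    sprintf(" (%s, %s | %s)", x$ids[1], x$ids[2], x$ids[3]) else ""
  cat(sprintf(
    "<lap_split>%s LA = %.4f; r(high, n=%d) = %.4f; r(low, n=%d) = %.4f\n",
    lab, x$la_score, length(x$high), x$corr_high, length(x$low),
    x$corr_low))
  invisible(x)
}

#' Split a dataset triple by gene queries
#'
#' Convenience wrapper building a [lap_split()] from a dataset and three
#' gene names.
#'
#' @param ds An [expression_dataset()] (normally transformed).
#' @param x_id,y_id,z_id Gene queries.
#' @inheritParams lap_split
#' @param index Alias index for resolution.
#' @return A `lap_split`.
#' @export
lap_split_genes <- function(ds, x_id, y_id, z_id, split_fraction = 0.5,
                            index = so_gene_index()) {
  xg <- resolve_gene(x_id, index, ds$gene_ids)
  yg <- resolve_gene(y_id, index, ds$gene_ids)
  zg <- resolve_gene(z_id, index, ds$gene_ids)
  lap_split(ds$values[xg, ], ds$values[yg, ], ds$values[zg, ],
            split_fraction = split_fraction, ids = c(xg, yg, zg))
}

#' Render a LAP plot
#'
#' Scatter of x versus y with the high-mediator subgroup drawn as red
#' triangles, the low subgroup as blue dots, and any excluded middle
#' samples as hollow grey points; the subtitle reports both subgroup
#' correlations and the LA score.
#'
#' @param split A [lap_split()].
#' @param out_path Optional output file; when given the plot is written
#'   there in `format`.
#' @param format `"png"` or `"svg"`.
#' @param width,height,dpi Device size in inches and resolution.
#' @return The ggplot object, invisibly.
#' @export
render_lap_plot <- function(split, out_path = NULL,
                            format = c("png", "svg"),
                            width = 6, height = 5, dpi = 150) {
  stopifnot(inherits(split, "lap_split"))
  format <- match.arg(format)
  grp <- rep(NA_character_, length(split$x))
  grp[split$high] <- "high"
  grp[split$low] <- "low"
  grp[split$excluded] <- "excluded"
  df <- data.frame(x = split$x, y = split$y, group = grp)
  df <- df[!is.na(df$x) & !is.na(df$y) & !is.na(df$group), , drop = FALSE]
  labs <- split$ids %||% c("X", "Y", "Z")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = group,
                                        shape = group)) +
    ggplot2::geom_point(size = 2.4) +
    ggplot2::scale_colour_manual(
      values = c(high = "#C62828", low = "#1565C0",
                 excluded = "grey60"),
      breaks = c("high", "low", "excluded"),
      labels = c(high = paste0("high ", labs[3]),
                 low = paste0("low ", labs[3]),
                 excluded = "excluded")) +
    ggplot2::scale_shape_manual(
      values = c(high = 17, low = 16, excluded = 1),
      breaks = c("high", "low", "excluded"),
      labels = c(high = paste0("high ", labs[3]),
                 low = paste0("low ", labs[3]),
                 excluded = "excluded")) +
    ggplot2::labs(
      x = labs[1], y = labs[2],
      title = sprintf("LAP plot: (%s, %s) mediated by %s",
                      labs[1], labs[2], labs[3]),
      subtitle = sprintf(
        "LA = %.4f;  r(high) = %.4f (n = %d);  r(low) = %.4f (n = %d)",
        split$la_score, split$corr_high, length(split$high),
        split$corr_low, length(split$low)),
      colour = NULL, shape = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
  if (!is.null(out_path)) {
    dev <- if (format == "png") grDevices::png else grDevices::svg
    if (format == "png")
      grDevices::png(out_path, width = width, height = height,
                     units = "in", res = dpi)
    else grDevices::svg(out_path, width = width, height = height)
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
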