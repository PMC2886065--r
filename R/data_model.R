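#' Construct a single-series expression table
#'
#' A `series_table` holds the expression matrix of one experimental series
#' (one GEO-style batch of hybridizations): genes in rows, samples in
#' columns, with `NA` marking missing measurements.
#'
#' @param series_id Accession-like label for the series (e.g. `"GSE3876"`).
#' @param values Numeric matrix, genes x samples. Row names are taken as
#'   gene ids and column names as sample ids unless overridden.
#' @param gene_ids,sample_ids Optional character vectors overriding
#'   `dimnames(values)`.
#' @return An object of class `series_table` with elements `series_id`,
#'   `gene_ids`, `sample_ids`, `values`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("SO0001", "SO0002", "SO0003"), c("s1", "s2")))
#' series_table("demo", m)
#' @export
series_table <- function(series_id, values, gene_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("values must have row (gene) and column (sample) names, ",
         "or gene_ids/sample_ids must be given")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids in series '", series_id, "': ",
         paste(dup, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in series '", series_id, "'")
  if (ncol(values) < 2L)
    stop("a series needs at least 2 samples")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(series_id = as.character(series_id),
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 values = values),
            class = "series_table")
}

#' @export
print.series_table <- function(x, ...) {
  cat(sprintf("<series_table> %s: %d genes x %d samples (%.1f%% missing)\n",
              x$series_id, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Construct a multi-batch expression dataset
#'
#' An `expression_dataset` is a gene x sample matrix together with one
#' batch (source-series) label per sample. The per-batch structure drives
#' the normal-score transform ([transform_dataset()]): each series is
#' Gaussianized independently before profiles are analysed jointly.
#'
#' @param values Numeric matrix, genes x samples, `NA` = missing.
#' @param batch_labels Character vector, one label per sample (column).
#' @param name Dataset label, e.g. `"gpl3253_cia"`.
#' @param gene_ids,sample_ids Optional overrides for `dimnames(values)`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, batch_labels, name = "dataset",
                               gene_ids = rownames(values),
                               sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (length(batch_labels) != ncol(values))
    stop("need one batch label per sample")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  sizes <- table(batch_labels)
  if (any(sizes < 2L))
    stop("each batch needs at least 2 samples; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 batch_labels = as.character(batch_labels),
                 values = values,
                 name = as.character(name)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> '%s': %d genes x %d samples, %d batches\n",
              x$name, nrow(x$values), ncol(x$values),
              length(unique(x$batch_labels))))
  b <- table(factor(x$batch_labels, levels = unique(x$batch_labels)))
  cat("  batches:", paste(sprintf("%s (%d)", names(b), b), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression table from disk
#'
#' Two dialects are supported. `"tsv"`: a plain tab-delimited table whose
#' first row holds sample ids and first column gene ids; empty or
#' non-numeric cells become missing. `"geo_series_matrix"`: the value
#' table between the standard `!series_matrix_table_begin` /
#' `!series_matrix_table_end` markers of a GEO series-matrix file
#' (metadata lines outside the markers are ignored; quoted ids allowed).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @param series_id Series label; defaults to the file name without
#'   extension.
#' @return A [series_table()].
#' @export
read_expression_table <- function(path,
                                  dialect = c("tsv", "geo_series_matrix"),
                                  series_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(series_id))
    series_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "geo_series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("no series-matrix table markers found in ", path)
    lines <- lines[(beg + 1L):(end - 1L)]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("empty expression table in ", path)
  # sentinel keeps trailing empty cells that strsplit would drop
  cells <- lapply(strsplit(paste0(lines, "\t\x03"), "\t", fixed = TRUE),
                  function(r) r[-length(r)])
  ncol_exp <- length(cells[[1L]])
  if (ncol_exp < 2L)
    stop("malformed header (line 1): expected tab-separated sample ids")
  strip <- function(x) gsub('^"|"$', "", trimws(x))
  sample_ids <- strip(cells[[1L]][-1L])
  body <- cells[-1L]
  bad <- which(vapply(body, length, 1L) != ncol_exp)
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, ": expected ",
         ncol_exp, " fields")
  gene_ids <- strip(vapply(body, `[[`, "", 1L))
  vals <- vapply(body, function(r) {
    suppressWarnings(as.numeric(strip(r[-1L])))
  }, numeric(length(sample_ids)))
  vals <- matrix(vals, nrow = length(gene_ids), ncol = length(sample_ids),
                 byrow = TRUE, dimnames = list(gene_ids, sample_ids))
  series_table(series_id, vals)
}

#' Write an expression table as TSV
#'
#' Inverse of [read_expression_table()] (TSV dialect): first row sample
#' ids, first column gene ids, missing entries written as empty cells.
#'
#' @param x A `series_table` or `expression_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  v <- x$values
  fmt <- function(z) ifelse(is.na(z), "", formatC(z, digits = 17,
                                                  format = "g"))
  hdr <- paste(c("gene_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a sample-to-batch map
#'
#' A two-column TSV (`sample_id`, `batch_label`), with or without a
#' header row, used to attach batch structure to a generic TSV input.
#'
#' @param path Path to the TSV.
#' @return Named character vector of batch labels, names = sample ids.
#' @export
read_batch_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("batch map needs two columns")
  if (identical(tolower(tab[1L, 1L]), "sample_id")) tab <- tab[-1L, ]
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Merge several series into one batched dataset
#'
#' Concatenates series along the sample axis, recording each sample's
#' source series as its batch label. Gene sets are reconciled by
#' `gene_policy`: `"intersect"` keeps genes common to all series (in
#' first-series order), `"union_with_missing"` keeps every gene and
#' fills values absent from a series with `NA`. Sample ids that collide
#' across series are disambiguated by prefixing `"<series_id>:"`.
#'
#' @param series List of [series_table()] objects.
#' @param gene_policy `"intersect"` (default) or `"union_with_missing"`.
#' @param name Label for the merged dataset.
#' @return An [expression_dataset()] whose sample count is the sum of the
#'   series sample counts and whose batch labels are the series ids.
#' @export
merge_series <- function(series, gene_policy = c("intersect",
                                                 "union_with_missing"),
                         name = "merged") {
  gene_policy <- match.arg(gene_policy)
  if (!length(series)) stop("need at least one series")
  if (!all(vapply(series, inherits, TRUE, "series_table")))
    stop("all inputs must be series_table objects")
  sids <- vapply(series, `[[`, "", "series_id")
  all_samples <- unlist(lapply(series, `[[`, "sample_ids"))
  if (anyDuplicated(all_samples)) {
    series <- lapply(series, function(s) {
      s$sample_ids <- paste0(s$series_id, ":", s$sample_ids)
      colnames(s$values) <- s$sample_ids
      s
    })
    all_samples <- unlist(lapply(series, `[[`, "sample_ids"))
    if (anyDuplicated(all_samples))
      stop("sample id collisions persist after series-id prefixing")
  }
  if (gene_policy == "intersect") {
    genes <- Reduce(intersect, lapply(series, `[[`, "gene_ids"))
    genes <- series[[1L]]$gene_ids[series[[1L]]$gene_ids %in% genes]
    if (!length(genes))
      stop("no genes common to all series under gene_policy = 'intersect'")
  } else {
    genes <- unique(unlist(lapply(series, `[[`, "gene_ids")))
  }
  blocks <- lapply(series, function(s) {
    m <- matrix(NA_real_, length(genes), length(s$sample_ids),
                dimnames = list(genes, s$sample_ids))
    hit <- intersect(genes, s$gene_ids)
    m[hit, ] <- s$values[hit, , drop = FALSE]
    m
  })
  vals <- do.call(cbind, blocks)
  batches <- rep(sids, vapply(series, function(s) length(s$sample_ids), 1L))
  expression_dataset(vals, batches, name = name)
}

#' Split a merged dataset back into per-batch series
#'
#' @param ds An `expression_dataset`.
#' @return Named list of [series_table()] objects, one per batch, in
#'   order of first appearance.
#' @export
split_by_batch <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  labs <- unique(ds$batch_labels)
  out <- lapply(labs, function(b) {
    keep <- ds$batch_labels == b
    series_table(b, ds$values[, keep, drop = FALSE])
  })
  stats::setNames(out, labs)
}

#' Average replicate rows mapping to one gene
#'
#' Optional probe-collapse step for platforms carrying replicate spots
#' per locus tag: rows sharing a tag are averaged (NA-aware) before any
#' transformation. Off by default in all pipelines, because collapsing
#' changes the statistic's inputs.
#'
#' @param ds An `expression_dataset` (or `series_table`).
#' @param tag_of Named character vector mapping row id -> locus tag;
#'   rows without an entry keep their own id.
#' @return Object of the same class with one row per tag.
#' @export
collapse_probes <- function(ds, tag_of) {
  ids <- ds$gene_ids
  tags <- ifelse(ids %in% names(tag_of), tag_of[ids], ids)
  grp <- factor(tags, levels = unique(tags))
  v <- rowsum(ifelse(is.na(ds$values), 0, ds$values), grp, reorder = FALSE)
  n <- rowsum((!is.na(ds$values)) * 1, grp, reorder = FALSE)
  out <- v / n  # 0/0 -> NaN -> NA
  out[n == 0] <- NA_real_
  rownames(out) <- levels(grp)
  if (inherits(ds, "expression_dataset"))
    expression_dataset(out, ds$batch_labels, name = ds$name)
  else series_table(ds$series_id, out)
}
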