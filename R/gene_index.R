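#' Build a gene alias index
#'
#' Maps common gene names (e.g. `cheA-1`) to locus tags (e.g. `SO2121`)
#' and back. Lookups are case-insensitive on common names and exact on
#' locus tags.
#'
#' @param aliases Data frame with columns `alias` and `locus_tag`.
#' @return An object of class `gene_index`.
#' @seealso [resolve_gene()], [so_gene_index()]
#' @export
build_gene_index <- function(aliases) {
  stopifnot(is.data.frame(aliases),
            all(c("alias", "locus_tag") %in% names(aliases)))
  aliases$alias <- as.character(aliases$alias)
  aliases$locus_tag <- as.character(aliases$locus_tag)
  key <- tolower(aliases$alias)
  if (anyDuplicated(key)) {
    dup <- unique(aliases$alias[duplicated(key)])
    stop("ambiguous aliases: ", paste(dup, collapse = ", "))
  }
  structure(list(table = aliases, key = key), class = "gene_index")
}

#' Alias index for the Shewanella oneidensis MR-1 genes used in examples
#'
#' Common-name to locus-tag pairs for the anaerobic-respiratory-plasticity
#' (ARP) genes, the two chemotaxis histidine-kinase genes, and other named
#' genes that recur in liquid-association analyses of this organism.
#'
#' @return A `gene_index`.
#' @export
so_gene_index <- function() {
  build_gene_index(data.frame(
    alias = c("cymA", "mtrA", "mtrB", "omcB", "mtrC", "omcA",
              "gspF", "gspD", "gspE", "cheA-1", "cheA-3", "crp",
              "petC"),
    locus_tag = c("SO4591", "SO1777", "SO1776", "SO1778", "SO1778",
                  "SO1779", "SO0168", "SO0166", "SO0167", "SO2121",
                  "SO3207", "SO0624", "SO0610"),
    stringsAsFactors = FALSE))
}

#' Resolve a gene query to a dataset gene id
#'
#' Accepts either a locus tag present in the dataset or a common name
#' known to the index (case-insensitive). Fails with near matches listed
#' rather than guessing.
#'
#' @param query Single character string.
#' @param index A `gene_index` (default [so_gene_index()]).
#' @param gene_ids Optional character vector of ids present in the
#'   dataset; when given, the resolved id must be among them.
#' @return The resolved gene id (locus tag / row id), length 1.
#' @export
resolve_gene <- function(query, index = so_gene_index(), gene_ids = NULL) {
  stopifnot(is.character(query), length(query) == 1L)
  hit <- index$table$locus_tag[index$key == tolower(query)]
  if (!length(hit)) {
    # treat as a literal id (locus tag or row id)
    hit <- query
    known <- !is.null(gene_ids) && query %in% gene_ids
    if (!known && !grepl("^SO", query) && is.null(gene_ids)) {
      near <- index$table$alias[agrepl(query, index$table$alias,
                                       ignore.case = TRUE)]
      stop("unknown gene '", query, "'",
           if (length(near)) paste0("; near matches: ",
                                    paste(near, collapse = ", ")) else "")
    }
  }
  hit <- unique(hit)
  if (length(hit) != 1L)
    stop("ambiguous gene query '", query, "': ",
         paste(hit, collapse = ", "))
  if (!is.null(gene_ids) && !hit %in% gene_ids) {
    near <- gene_ids[agrepl(hit, gene_ids, ignore.case = TRUE,
                            max.distance = 0.2)]
    stop("gene '", query, "' (", hit, ") not in dataset",
         if (length(near)) paste0("; near matches: ",
                                  paste(utils::head(near, 5),
                                        collapse = ", ")) else "")
  }
  hit
}
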