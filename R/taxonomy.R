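CANONICAL_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' Taxonomy map
#'
#' Stores OTU lineages as one column per canonical rank
#' (kingdom ... species), possibly truncated; unassigned ranks are `NA`.
#'
#' @param df A data.frame with an `otu_id` column and a subset of the
#'   canonical rank columns in canonical order.
#' @return The validated data.frame with class `taxonomy_map` prepended.
#' @export
taxonomy_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"otu_id" %in% names(df)) abort("taxonomy is missing column 'otu_id'")
  if (nrow(df) == 0L) abort("taxonomy map is empty")
  ranks <- intersect(names(df), CANONICAL_RANKS)
  if (length(ranks) == 0L) {
    abort("taxonomy has no recognised rank columns (expected among: %s)",
          paste(CANONICAL_RANKS, collapse = ", "))
  }
  pos <- match(ranks, CANONICAL_RANKS)
  if (is.unsorted(pos)) abort("rank columns are not in canonical order")
  df$otu_id <- as.character(df$otu_id)
  if (anyDuplicated(df$otu_id)) abort("duplicated otu_id in taxonomy map")
  for (r in ranks) {
    v <- as.character(df[[r]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[r]] <- v
  }
  attr(df, "ranks") <- ranks
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read an OTU-to-taxonomy map from TSV
#' @param path TSV with header `otu_id` plus rank columns.
#' @return A `taxonomy_map`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  taxonomy_map(utils::read.table(path, sep = "\t", header = TRUE,
                                 check.names = FALSE, quote = "",
                                 comment.char = "",
                                 stringsAsFactors = FALSE))
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Sums counts over OTUs sharing a label at the requested rank; column sums
#' (and hence library sizes) are conserved.  OTUs unassigned at the rank are
#' pooled under `"<nearest assigned parent>_norank"`; OTUs absent from the
#' map are pooled under `"unclassified_norank"`.
#'
#' @param table An `otu_table`.
#' @param tax A `taxonomy_map`.
#' @param rank One of the canonical rank names present in `tax`.
#' @return An `otu_table` whose features are rank labels.
#' @export
aggregate_taxa <- function(table, tax, rank) {
  stopifnot(inherits(table, "otu_table"))
  tax <- taxonomy_map(tax)
  ranks <- attr(tax, "ranks")
  if (!rank %in% ranks) {
    abort("rank '%s' not present in taxonomy (has: %s)", rank,
          paste(ranks, collapse = ", "))
  }
  idx <- match(table$otu_ids, tax$otu_id)
  above <- ranks[seq_len(match(rank, ranks))]
  labels <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    if (is.na(i)) return("unclassified_norank")
    v <- as.character(tax[i, above])
    if (!is.na(v[length(v)])) return(v[length(v)])
    parent <- rev(v[!is.na(v)])[1]
    if (is.na(parent) || length(parent) == 0L) "unclassified_norank"
    else paste0(parent, "_norank")
  }, character(1L))
  agg <- t(rowsum(t(table$counts), group = labels))
  otu_table(agg)
}
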