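#' Sample metadata table
#'
#' Validates a per-sample metadata table: a `sample_id` column, a two-level
#' `group` label (case/control), an optional `cohort` tag (discovery,
#' validation, independent, ...) and any number of numeric clinical
#' indicator columns (e.g. SCr in umol/L, BUN in mmol/L, eGFR in
#' mL/min/1.73m2, ALB and Hb in g/L, phosphate in mmol/L).  Missing clinical
#' values are allowed and handled pairwise downstream.
#'
#' @param df A data.frame with at least columns `sample_id` and `group`.
#' @return The validated data.frame with class `sample_metadata` prepended.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(df)) abort("metadata is missing column '%s'", col)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort("duplicated sample ids in metadata: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (anyNA(df$group)) abort("metadata group column contains missing values")
  df$group <- as.character(df$group)
  if (!"cohort" %in% names(df)) df$cohort <- "discovery"
  clin <- setdiff(names(df), c("sample_id", "group", "cohort"))
  for (col in clin) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      if (all(is.na(v) == (is.na(df[[col]]) | df[[col]] %in% c("", "NA")))) {
        df[[col]] <- v
      } else {
        abort("clinical indicator column '%s' is not numeric", col)
      }
    }
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' Expects a header `sample_id  group  cohort  <indicator...>` (tab
#' separated); `cohort` and indicator columns are optional.
#'
#' @param path Path to the TSV file.
#' @return A `sample_metadata` data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param meta A `sample_metadata` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(meta, path) {
  write_tsv_file(as.data.frame(meta), path)
}

#' Align metadata to the samples of an OTU table
#'
#' Reorders the metadata rows to the table's sample order and errors if any
#' table sample lacks a group label.
#'
#' @param table An `otu_table`.
#' @param meta A `sample_metadata` data.frame.
#' @return The metadata subset, in table order.
#' @export
align_metadata <- function(table, meta) {
  stopifnot(inherits(table, "otu_table"))
  meta <- sample_metadata(meta)
  idx <- match(table$sample_ids, meta$sample_id)
  if (anyNA(idx)) {
    abort("samples missing from metadata (no group label): %s",
          paste(table$sample_ids[is.na(idx)], collapse = ", "))
  }
  out <- meta[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
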