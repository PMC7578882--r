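#' OTU count table
#'
#' The universal currency of the package: a samples x OTUs matrix of
#' non-negative integer read counts with unique sample and OTU identifiers.
#'
#' @param counts Numeric matrix of non-negative integers, rows = samples,
#'   columns = OTUs.
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: `rownames(counts)`).
#' @param otu_ids Character vector of unique OTU identifiers
#'   (default: `colnames(counts)`).
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix with dimnames), `sample_ids` and `otu_ids`.
#' @examples
#' tab <- otu_table(matrix(c(5L, 0L, 2L, 9L), 2, 2,
#'                  dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2"))))
#' tab
#' @export
otu_table <- function(counts,
                      sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(nrow(counts)), recycle0 = TRUE)
  }
  if (is.null(otu_ids)) {
    otu_ids <- paste0("OTU_", seq_len(ncol(counts)), recycle0 = TRUE)
  }
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts)) {
    abort("length of sample_ids (%d) does not match number of rows (%d)",
          length(sample_ids), nrow(counts))
  }
  if (length(otu_ids) != ncol(counts)) {
    abort("length of otu_ids (%d) does not match number of columns (%d)",
          length(otu_ids), ncol(counts))
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicated sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(otu_ids)) {
    abort("duplicated OTU ids: %s",
          paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  }
  if (!is.numeric(counts)) abort("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    abort(paste0("counts must be non-negative integers; offending cell: ",
                 "sample '%s', OTU '%s' (value %s)"),
          sample_ids[i], otu_ids[j], format(counts[i, j]))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(list(counts = counts, sample_ids = sample_ids, otu_ids = otu_ids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, total reads %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.double(x$counts)), big.mark = ",")))
  cat(sprintf("  sample totals: min %d, median %s, max %d\n",
              min(sample_totals(x)), format(stats::median(sample_totals(x))),
              max(sample_totals(x))))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Per-sample read totals
#' @param table An `otu_table`.
#' @return Named integer vector of library sizes.
#' @export
sample_totals <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  rowSums(table$counts)
}

#' Subset an OTU table
#'
#' @param x An `otu_table`.
#' @param i Sample index (integer, logical or character).
#' @param j OTU index (integer, logical or character).
#' @param ... Ignored.
#' @return An `otu_table` restricted to the requested samples/OTUs.
#' @export
`[.otu_table` <- function(x, i, j, ...) {
  m <- x$counts
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  otu_table(m)
}

#' Read an OTU count table
#'
#' Reads a tab-separated or BIOM-JSON (v1.0) OTU table.  The TSV dialect is
#' a header line of ids and a first column of ids for the other axis; the
#' orientation is declared, never guessed: with `samples_in = "columns"`
#' (default, the common amplicon convention) rows are OTUs and columns are
#' samples, and the table is transposed internally to samples x OTUs.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom-json"`.
#' @param samples_in For TSV input: `"columns"` (OTUs in rows, default) or
#'   `"rows"` (samples in rows).
#' @return An `otu_table`.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json"),
                           samples_in = c("columns", "rows")) {
  format <- match.arg(format)
  samples_in <- match.arg(samples_in)
  if (!file.exists(path)) abort("file not found: %s", path)
  if (format == "biom-json") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    return(otu_table(check_integer_counts(t(m), path)))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           comment.char = "", colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 1L) abort("malformed header in %s: no columns", path)
  if (anyDuplicated(colnames(raw))) {
    abort("malformed header in %s: duplicated column ids", path)
  }
  row_ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = list(row_ids, colnames(raw)[-1L])))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort("non-numeric count in %s at row '%s', column '%s': '%s'",
          path, row_ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]],
          cells[bad[1L, 1L], bad[1L, 2L]])
  }
  if (samples_in == "columns") num <- t(num)
  otu_table(check_integer_counts(num, path))
}

# shared count validation with file-oriented error messages
check_integer_counts <- function(m, path) {
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort("invalid count in %s at row '%s', column '%s': %s (must be a non-negative integer)",
          path, rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
          format(m[bad[1L, 1L], bad[1L, 2L]]))
  }
  m
}

#' Write an OTU count table
#'
#' Writes TSV (lossless round trip with [read_otu_table()]) or BIOM-JSON.
#'
#' @param table An `otu_table`.
#' @param path Output path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param samples_in TSV orientation, as in [read_otu_table()].
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(table, path, format = c("tsv", "biom-json"),
                            samples_in = c("columns", "rows")) {
  stopifnot(inherits(table, "otu_table"))
  format <- match.arg(format)
  samples_in <- match.arg(samples_in)
  if (format == "biom-json") {
    b <- biomformat::make_biom(data = t(table$counts))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  m <- if (samples_in == "columns") t(table$counts) else table$counts
  id_col <- if (samples_in == "columns") "#OTU ID" else "#Sample ID"
  lines <- paste(c(id_col, colnames(m)), collapse = "\t")
  if (nrow(m) > 0L) {
    body <- paste(rownames(m),
                  apply(m, 1L, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, body)
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort("cannot write OTU table to %s: %s", path,
                         conditionMessage(ok))
  invisible(path)
}

#' Convert counts to relative abundance
#'
#' Divides each sample's counts by its library size.  No pseudocount is
#' added; each row of the result sums to exactly 1.
#'
#' @param table An `otu_table` (or samples x OTUs count matrix).
#' @return Numeric matrix of per-sample proportions.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort("cannot normalise samples with zero total counts: %s",
          paste(rownames(m)[tot <= 0], collapse = ", "))
  }
  m / tot
}

#' Rarefy counts to an even depth
#'
#' Randomly subsamples each sample's reads without replacement
#' (hypergeometric) to a common depth.  Samples whose library size is below
#' the depth are dropped with a warning listing their ids.
#'
#' @param table An `otu_table`.
#' @param depth Target reads per sample; default is the minimum library size.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A rarefied `otu_table` in which every retained sample has total
#'   `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  tot <- sample_totals(table)
  if (is.null(depth)) depth <- min(tot)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0 ||
      depth != round(depth)) {
    abort("rarefaction depth must be a positive integer")
  }
  keep <- tot >= depth
  if (!any(keep)) abort("no sample has at least %d reads", depth)
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(table$sample_ids[!keep], collapse = ", ")),
            call. = FALSE)
  }
  m <- table$counts[keep, , drop = FALSE]
  sub <- with_seed(seed, quiet_rrarefy(m, depth))
  otu_table(sub)
}

# vegan::rrarefy warns when every count is large (suspecting non-count
# input); our inputs are validated integer counts, so silence only that
quiet_rrarefy <- function(m, depth) {
  withCallingHandlers(vegan::rrarefy(m, depth),
                      warning = function(w) {
                        if (grepl("observed counts", conditionMessage(w))) {
                          invokeRestart("muffleWarning")
                        }
                      })
}
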