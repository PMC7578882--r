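# Internal helpers shared across the package.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, and restores the state so
#' seeded package functions never clobber the user's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream unchanged.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a sub-stream seed from a master seed
#'
#' Stream-splitting rule used everywhere a pipeline stage needs its own
#' reproducible stream: `(seed + 999983 * stream) mod (2^31 - 1)`, kept
#' strictly positive.  Documented so stage-level results can be reproduced
#' in isolation from a single master seed.
#'
#' @param seed Master integer seed.
#' @param stream Small non-negative integer identifying the sub-stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  s <- (as.double(seed) + 999983 * as.double(stream)) %% 2147483647
  as.integer(s) + 1L
}

# stop() with sprintf-style formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic TSV writer used by all pipeline outputs
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# coerce an otu_table or plain matrix to a samples x features relative
# abundance matrix; plain matrices are assumed to already be abundances
# and are row-normalised only when `normalise` is TRUE
as_abundance <- function(x, normalise = TRUE) {
  if (inherits(x, "otu_table")) {
    return(relative_abundance(x))
  }
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("abundance input must be numeric")
  if (normalise) {
    tot <- rowSums(m)
    if (any(tot <= 0)) {
      abort("samples with non-positive totals: %s",
            paste(rownames(m)[tot <= 0], collapse = ", "))
    }
    m <- m / tot
  }
  m
}

# resolve the case level of a two-level grouping factor; default convention:
# a level literally named "case" wins, otherwise the first factor level
resolve_case_level <- function(groups, case_level = NULL) {
  lev <- levels(groups)
  if (is.null(case_level)) {
    case_level <- if ("case" %in% lev) "case" else lev[1L]
  }
  if (!case_level %in% lev) {
    abort("case_level '%s' is not a level of the grouping factor", case_level)
  }
  case_level
}

as_group_factor <- function(groups, n = NULL, two_level = TRUE) {
  g <- factor(groups)
  if (!is.null(n) && length(g) != n) {
    abort("group labels have length %d but %d samples were given",
          length(g), n)
  }
  if (anyNA(g)) abort("group labels contain missing values")
  if (two_level && nlevels(g) != 2L) {
    abort("exactly 2 groups are required, got %d (%s)",
          nlevels(g), paste(levels(g), collapse = ", "))
  }
  droplevels(g)
}
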