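# Spearman correlation of marker abundances with clinical indicators,
# with pairwise-complete handling of missing clinical values.

# midrank Spearman correlation of two complete vectors, with an optional
# covariate set for the partial variant (rank-regress both variables on
# the covariate ranks, correlate the residuals)
spearman_one <- function(x, y, z = NULL) {
  n <- length(x)
  if (is.null(z)) {
    ct <- tryCatch(
      suppressWarnings(stats::cor.test(x, y, method = "spearman")),
      error = function(e) NULL)
    if (is.null(ct) || is.na(ct$estimate)) return(c(rho = NA_real_, p = NA_real_))
    return(c(rho = unname(ct$estimate), p = ct$p.value))
  }
  zr <- apply(as.matrix(z), 2L, rank)
  rx <- stats::resid(stats::lm.fit(cbind(1, zr), rank(x)))
  ry <- stats::resid(stats::lm.fit(cbind(1, zr), rank(y)))
  r <- suppressWarnings(stats::cor(rx, ry))
  if (is.na(r)) return(c(rho = NA_real_, p = NA_real_))
  df <- n - 2L - ncol(zr)
  if (df < 1L) return(c(rho = r, p = NA_real_))
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  c(rho = r, p = 2 * stats::pt(-abs(tstat), df))
}

#' Spearman correlation matrix of features vs clinical indicators
#'
#' Midrank (tie-corrected) Spearman correlation of every feature against
#' every clinical indicator.  Missing clinical values are excluded pairwise
#' and the number of complete pairs is recorded; a cell with fewer than
#' `min_pairs` complete pairs is flagged not-computable (`NA`) rather than
#' raising an error.  An optional covariate set turns each cell into a
#' partial Spearman correlation (both variables are rank-regressed on the
#' covariate ranks and the residuals correlated).
#'
#' @param abund Samples x features abundance matrix or `otu_table`.
#' @param clinical Data.frame of numeric indicators with a `sample_id`
#'   column (a `sample_metadata` works directly; its `group`/`cohort`
#'   columns are ignored), or a numeric matrix with sample rownames.
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @param covariates Optional character vector naming indicator columns to
#'   adjust for (partial Spearman); these columns are excluded from the
#'   indicator axis.
#' @return Object of class `correlation_matrix`: list of matrices `rho`,
#'   `p`, `n_used` (features x indicators).  Use [as.data.frame()] for the
#'   long form.
#' @export
spearman_matrix <- function(abund, clinical, min_pairs = 3,
                            covariates = NULL) {
  m <- as_abundance(abund, normalise = inherits(abund, "otu_table"))
  if (is.data.frame(clinical)) {
    ids <- if ("sample_id" %in% names(clinical)) clinical$sample_id
           else rownames(clinical)
    keep <- setdiff(names(clinical), c("sample_id", "group", "cohort"))
    clin <- as.matrix(as.data.frame(clinical, stringsAsFactors = FALSE)[, keep,
                                                                        drop = FALSE])
    rownames(clin) <- ids
  } else {
    clin <- as.matrix(clinical)
  }
  if (!is.numeric(clin)) abort("clinical indicators must be numeric")
  common <- intersect(rownames(m), rownames(clin))
  if (length(common) < min_pairs) {
    abort("only %d samples shared between abundances and clinical data",
          length(common))
  }
  m <- m[common, , drop = FALSE]
  clin <- clin[common, , drop = FALSE]
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, colnames(clin))
    if (length(miss) > 0L) {
      abort("covariates not found among indicators: %s",
            paste(miss, collapse = ", "))
    }
    zmat <- clin[, covariates, drop = FALSE]
    clin <- clin[, setdiff(colnames(clin), covariates), drop = FALSE]
  } else {
    zmat <- NULL
  }
  feats <- colnames(m)
  inds <- colnames(clin)
  rho <- p <- matrix(NA_real_, length(feats), length(inds),
                     dimnames = list(feats, inds))
  n_used <- matrix(0L, length(feats), length(inds),
                   dimnames = list(feats, inds))
  for (j in seq_along(inds)) {
    for (i in seq_along(feats)) {
      ok <- !is.na(m[, i]) & !is.na(clin[, j])
      if (!is.null(zmat)) ok <- ok & stats::complete.cases(zmat)
      n_used[i, j] <- sum(ok)
      if (sum(ok) < min_pairs) next
      res <- spearman_one(m[ok, i], clin[ok, j],
                          if (is.null(zmat)) NULL
                          else zmat[ok, , drop = FALSE])
      rho[i, j] <- res[["rho"]]
      p[i, j] <- res[["p"]]
    }
  }
  structure(list(rho = rho, p = p, n_used = n_used,
                 covariates = covariates),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Spearman correlation matrix: %d features x %d indicators%s\n",
              nrow(x$rho), ncol(x$rho),
              if (is.null(x$covariates)) ""
              else sprintf(" (partial, adjusting for %s)",
                           paste(x$covariates, collapse = ", "))))
  print(round(x$rho, 3))
  invisible(x)
}

#' @export
as.data.frame.correlation_matrix <- function(x, ...) {
  grid <- expand.grid(feature_id = rownames(x$rho),
                      indicator = colnames(x$rho),
                      stringsAsFactors = FALSE)
  grid$rho <- x$rho[cbind(grid$feature_id, grid$indicator)]
  grid$p <- x$p[cbind(grid$feature_id, grid$indicator)]
  grid$n_used <- x$n_used[cbind(grid$feature_id, grid$indicator)]
  grid
}
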