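# Beta diversity: Bray-Curtis dissimilarity, PCoA/PCA ordination, and
# group-overlap (Venn) accounting.

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y), computed on
#' relative abundances.  An `otu_table` is converted to relative abundance
#' first; a plain matrix is used as given.
#'
#' @param x An `otu_table` or a samples x features abundance matrix.
#' @return A `dist` object with sample labels (values in [0, 1] for
#'   non-negative input).
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) relative_abundance(x) else as.matrix(x)
  if (nrow(m) < 2L) abort("at least 2 samples are required")
  if (any(rowSums(m) <= 0)) {
    abort("samples with zero total abundance: %s",
          paste(rownames(m)[rowSums(m) <= 0], collapse = ", "))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers the squared distance matrix (Gower transformation) and
#' eigendecomposes it.  Axes are ordered by non-increasing eigenvalue;
#' negative eigenvalues are reported but their axes are dropped.  The
#' proportion explained is relative to the sum of positive eigenvalues.
#'
#' @param d A `dist` object or symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return An object of class `ordination`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending), and
#'   `proportion_explained` (for the returned axes).
#' @export
pcoa <- function(d, n_axes = 2) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8) || any(abs(diag(d)) > 1e-8)) {
      abort("distance input must be symmetric with a zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (n < 2L) abort("at least 2 samples are required")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1))
  k <- min(n_axes, max(npos, 1L))
  coords <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos_sum <- sum(eig[eig > 0])
  prop <- if (pos_sum > 0) pmax(eig[seq_len(ncol(coords))], 0) / pos_sum
          else rep(0, ncol(coords))
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop, method = "pcoa"),
            class = "ordination")
}

#' Principal component analysis of relative abundances
#'
#' Covariance-based PCA (centered, unscaled) on the relative abundance
#' matrix, returned in the same shape as [pcoa()].
#'
#' @param x An `otu_table` or samples x features abundance matrix.
#' @param n_axes Number of components to return.
#' @return An `ordination` object.
#' @export
pca_ordination <- function(x, n_axes = 2) {
  m <- if (inherits(x, "otu_table")) relative_abundance(x) else as.matrix(x)
  if (nrow(m) < 2L) abort("at least 2 samples are required")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- fit$sdev^2
  k <- min(n_axes, ncol(fit$x))
  coords <- fit$x[, seq_len(k), drop = FALSE]
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = eig[seq_len(k)] / sum(eig),
                 method = "pca"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes returned\n",
              toupper(x$method), nrow(x$coordinates), ncol(x$coordinates)))
  cat("proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.ordination <- function(x, groups = NULL, axes = c(1, 2), ...) {
  co <- x$coordinates
  if (ncol(co) < max(axes)) abort("ordination has fewer axes than requested")
  col <- if (is.null(groups)) 1L else as.integer(factor(groups)) + 1L
  graphics::plot(co[, axes[1]], co[, axes[2]], col = col, pch = 19,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1],
                                100 * x$proportion_explained[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2],
                                100 * x$proportion_explained[axes[2]]),
                 ...)
  invisible(x)
}

#' Group overlap (Venn) accounting of OTUs
#'
#' An OTU is "present" in a group when its summed count there is at least
#' `presence_min`.  Returns the number of OTUs present in every group
#' (shared), the number unique to each group, per-group totals, and the
#' number present anywhere.
#'
#' @param table An `otu_table`.
#' @param groups Per-sample group labels (>= 2 groups).
#' @param presence_min Minimum summed count for presence (default 1).
#' @return List with `shared`, `unique_per_group` (named), `per_group`
#'   (named presence totals) and `total`.
#' @export
group_overlap <- function(table, groups, presence_min = 1) {
  stopifnot(inherits(table, "otu_table"))
  groups <- as_group_factor(groups, n = nrow(table$counts), two_level = FALSE)
  if (nlevels(groups) < 2L) abort("at least 2 groups are required")
  pres <- vapply(levels(groups), function(g) {
    colSums(table$counts[groups == g, , drop = FALSE]) >= presence_min
  }, logical(ncol(table$counts)))
  n_groups_present <- rowSums(pres)
  uniq <- vapply(seq_len(ncol(pres)), function(j) {
    sum(pres[, j] & n_groups_present == 1L)
  }, integer(1))
  list(shared = sum(n_groups_present == nlevels(groups)),
       unique_per_group = stats::setNames(uniq, levels(groups)),
       per_group = colSums(pres),
       total = sum(n_groups_present > 0L))
}
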