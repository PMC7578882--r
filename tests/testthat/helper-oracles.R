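# Independent brute-force oracles used to check the package's estimators
# against direct evaluations of their defining formulas, plus small fixture
# builders.  Everything here is deliberately written from the formulas,
# not by calling the package.

shannon_bf <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

chao1_bf <- function(x) {
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

ace_bf <- function(x, thr = 10) {
  x <- x[x > 0]
  n_abund <- sum(x > thr)
  ra <- x[x <= thr]
  if (length(ra) == 0) return(n_abund)
  n_rare <- sum(ra)
  f1 <- sum(ra == 1)
  cov <- 1 - f1 / n_rare
  if (cov == 0) return(chao1_bf(c(x)))
  fi <- tabulate(ra, nbins = thr)
  i <- seq_len(thr)
  g2 <- 0
  if (n_rare > 1) {
    g2 <- max(length(ra) / cov * sum(i * (i - 1) * fi) /
                (n_rare * (n_rare - 1)) - 1, 0)
  }
  n_abund + length(ra) / cov + f1 / cov * g2
}

bray_bf <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# tie-corrected Kruskal-Wallis p-value from the textbook formula
kruskal_bf <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  rsum <- tapply(r, groups, sum)
  ni <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  stats::pchisq(h, df = nlevels(groups) - 1, lower.tail = FALSE)
}

# midrank Spearman rho from the explicit product-moment formula on ranks
spearman_bf <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# AUC by exhaustive case-control pair counting (ties count one half)
auc_pairs_bf <- function(scores, is_case) {
  sc <- scores[is_case]
  sn <- scores[!is_case]
  tot <- 0
  for (a in sc) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sc) * length(sn))
}

# expected observed richness after rarefying one sample to depth d
expected_richness_bf <- function(counts, d) {
  n <- sum(counts)
  sum(1 - exp(lchoose(n - counts, d) - lchoose(n, d)))
}

# sparse random count vector
random_counts <- function(m = 40, lambda = 3, zero_frac = 0.5) {
  x <- stats::rpois(m, lambda)
  x[stats::runif(m) < zero_frac] <- 0L
  x
}

# small deterministic two-group abundance matrix with one shifted feature
toy_abund <- function(n_per = 6, n_feat = 4, shift = 1, seed = 11) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(2 * n_per * n_feat), 2 * n_per, n_feat)
  m[seq_len(n_per), 1] <- m[seq_len(n_per), 1] * exp(shift)
  rownames(m) <- paste0("s", seq_len(2 * n_per))
  colnames(m) <- paste0("f", seq_len(n_feat))
  list(abund = m / rowSums(m),
       groups = rep(c("case", "control"), each = n_per))
}
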