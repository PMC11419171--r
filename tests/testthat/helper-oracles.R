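# Independent oracles used across tests; deliberately naive implementations.

# Adjusted Rand index from the contingency table (Hubert & Arabie).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Textbook silhouette: per point, a = mean distance to own cluster,
# b = min over other clusters of mean distance.
silhouette_oracle <- function(D, labels) {
  mean(vapply(seq_along(labels), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- if (length(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1)))
}

# Pearson chi-square of a 2x2 table, no continuity correction.
chisq_oracle <- function(x1, n1, x2, n2) {
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
}

# Fixed-effect inverse-variance meta-analysis.
fe_meta_oracle <- function(betas, ses) {
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  c(beta = beta, se = se)
}

# Expected case allele frequency under retrospective HWE sampling:
# weights HWE(g) * OR^g over g in 0:2.
retro_af_oracle <- function(maf, or) {
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  w <- hwe * or^(0:2)
  sum((0:2) / 2 * w) / sum(w)
}

# Small planted-subtype feature generator used where the full cohort
# simulator would be overkill.
planted_features <- function(n_per, K = 3, J = 9, hi = 0.9, lo = 0.05,
                             seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(seq_len(K), each = n_per)
    P <- matrix(lo, J, K)
    own <- split(seq_len(J), rep(seq_len(K), length.out = J))
    for (k in seq_len(K)) P[own[[k]], k] <- hi
    X <- matrix(0L, length(lab), J,
                dimnames = list(sprintf("P%04d", seq_along(lab)),
                                sprintf("f%02d", seq_len(J))))
    for (k in seq_len(K)) {
      idx <- which(lab == k)
      X[idx, ] <- matrix(rbinom(length(idx) * J, 1, rep(P[, k], each = length(idx))),
                         ncol = J)
    }
    list(X = X, labels = lab)
  })
}
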