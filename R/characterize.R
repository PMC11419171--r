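#' Two-population proportion z-test
#'
#' Pooled two-proportion z-statistic:
#' `z = (x1/n1 - x2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (x1 + x2)/(n1 + n2)`, and a two-sided normal p-value. `z^2`
#' equals the Pearson chi-square statistic of the 2x2 table (no continuity
#' correction). When the pooled proportion is 0 or 1 the statistic is
#' undefined and the result is flagged degenerate rather than silently 0.
#'
#' @param x1,n1 successes and size in the first population.
#' @param x2,n2 successes and size in the second population.
#' @return list with `z`, `p`, `degenerate`.
#' @export
proportion_z_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1)
    return(list(z = NA_real_, p = NA_real_, degenerate = TRUE))
  z <- (x1 / n1 - x2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Cluster-vs-rest feature enrichment table
#'
#' For every (feature, cluster) pair, compares the feature's prevalence in
#' the cluster against the union of all other clusters with the pooled
#' proportion z-test, and flags significance after Bonferroni correction
#' over all feature x cluster tests. Characterization variables that are
#' not clustering inputs (anatomical lesion-site flags, chart-review-style
#' abstractions) enter through `extra_flags` and the same code path.
#'
#' @param X binary feature matrix (subjects x features).
#' @param labels cluster labels aligned to rows of `X`.
#' @param extra_flags optional additional binary matrix (same rows).
#' @param alpha family-wise error rate for the Bonferroni flag (default 0.05).
#' @return data.frame with `feature`, `cluster`, `x_in`, `n_in`, `x_out`,
#'   `n_out`, `prevalence_in`, `prevalence_out`, `z`, `p`, `degenerate`,
#'   `significant`.
#' @export
enrichment_table <- function(X, labels, extra_flags = NULL, alpha = 0.05) {
  if (!is.null(extra_flags)) {
    stopifnot(nrow(extra_flags) == nrow(X))
    X <- cbind(X, extra_flags)
  }
  X <- as.matrix(X)
  clusters <- sort(unique(labels[labels != -1L]))
  if (length(clusters) < 2)
    stop("enrichment requires at least 2 clusters", call. = FALSE)
  rows <- list()
  for (cl in clusters) {
    inside <- labels == cl
    outside <- labels != cl & labels != -1L
    n_in <- sum(inside); n_out <- sum(outside)
    x_in <- colSums(X[inside, , drop = FALSE])
    x_out <- colSums(X[outside, , drop = FALSE])
    for (j in seq_len(ncol(X))) {
      tst <- if (n_in == 0 || n_out == 0) {
        list(z = NA_real_, p = NA_real_, degenerate = TRUE)
      } else proportion_z_test(x_in[j], n_in, x_out[j], n_out)
      rows[[length(rows) + 1]] <- data.frame(
        feature = colnames(X)[j], cluster = cl,
        x_in = x_in[j], n_in = n_in, x_out = x_out[j], n_out = n_out,
        prevalence_in = if (n_in) x_in[j] / n_in else NA_real_,
        prevalence_out = if (n_out) x_out[j] / n_out else NA_real_,
        z = tst$z, p = tst$p, degenerate = tst$degenerate)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_tests <- sum(!out$degenerate)
  out$significant <- !out$degenerate & !is.na(out$p) & out$p < alpha / max(n_tests, 1)
  out
}
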