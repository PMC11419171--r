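#' DerSimonian-Laird random-effects meta-analysis
#'
#' Classic moment estimator: with fixed-effect weights `w_i = 1/se_i^2`,
#' `Q = sum w_i (beta_i - beta_FE)^2`,
#' `tau^2 = max(0, (Q - (k-1)) / (sum w_i - sum w_i^2 / sum w_i))`, and the
#' random-effects estimate uses weights `1/(se_i^2 + tau^2)`. With one
#' stratum the input is returned unchanged; whenever `Q <= k-1`, `tau^2`
#' truncates to 0 and the result equals the fixed-effect inverse-variance
#' meta-analysis exactly.
#'
#' @param betas per-stratum effect estimates (log-odds).
#' @param ses per-stratum standard errors.
#' @return one-row data.frame: `beta`, `se`, `p`, `Q`, `tau2`, `I2`,
#'   `k_strata`.
#' @export
dl_meta <- function(betas, ses) {
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  betas <- betas[ok]; ses <- ses[ok]
  k <- length(betas)
  if (k == 0)
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      Q = NA_real_, tau2 = NA_real_, I2 = NA_real_,
                      k_strata = 0L))
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - beta_fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wr <- 1 / (ses^2 + tau2)
  beta <- sum(wr * betas) / sum(wr)
  se <- sqrt(1 / sum(wr))
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  data.frame(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
             Q = Q, tau2 = tau2, I2 = I2, k_strata = k)
}

#' Meta-analyze stratified association results
#'
#' Applies [dl_meta()] per phenotype x variant across strata.
#'
#' @param assoc data.frame from [run_stratified_assoc()].
#' @return data.frame with `variant`, `phenotype`, meta columns from
#'   [dl_meta()], and total `n_case` / `n_control`.
#' @export
meta_analyze <- function(assoc) {
  assoc <- assoc[!assoc$skipped, ]
  key <- interaction(assoc$phenotype, assoc$variant, drop = TRUE)
  rows <- lapply(split(assoc, key), function(d) {
    cbind(data.frame(variant = d$variant[1], phenotype = d$phenotype[1]),
          dl_meta(d$beta, d$se),
          data.frame(n_case = sum(d$n_case), n_control = sum(d$n_control)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positive-control association: overall endometriosis
#'
#' Pools cases from all clusters into a single phenotype and runs the same
#' stratified association + meta-analysis machinery, giving the baseline
#' the cluster phenotypes are compared against.
#'
#' @inheritParams run_stratified_assoc
#' @param ... passed to [run_stratified_assoc()].
#' @return stratified association data.frame with phenotype
#'   `"positive_control"`.
#' @export
positive_control <- function(G, variants, subjects, case_labels, ...) {
  run_stratified_assoc(G, variants, subjects, case_labels,
                       phenotypes = list(positive_control =
                                           unique(case_labels)),
                       ...)
}

#' Size-preserving randomized negative control labels
#'
#' Permutes the multiset of cluster labels uniformly at random across the
#' cases, independently within each dataset, so every negative-control
#' cluster has exactly the same per-dataset case counts as the real one.
#'
#' @param case_labels named vector subject id -> cluster label.
#' @param datasets named vector subject id -> dataset label (single
#'   dataset assumed if NULL).
#' @param seed integer seed.
#' @return named vector of permuted labels, same names as `case_labels`.
#' @export
negative_control <- function(case_labels, datasets = NULL, seed = 1) {
  out <- case_labels
  ids <- names(case_labels)
  grp <- if (is.null(datasets)) rep("all", length(ids)) else datasets[ids]
  with_seed(seed, {
    for (g in unique(grp)) {
      idx <- which(grp == g)
      out[idx] <- sample(case_labels[idx])
    }
  })
  out
}

#' Format a locus replication fraction
#'
#' @param k replicating loci.
#' @param n loci tested.
#' @return string such as `"17 / 39 (44%)"` (percent rounded to integer).
#' @export
format_locus_fraction <- function(k, n) {
  sprintf("%d / %d (%.0f%%)", k, n, 100 * k / n)
}

#' Significance summary across loci and phenotypes
#'
#' Collapses meta-analyzed results to the locus level (minimum p over the
#' lead and its LD tags, no per-locus multiplicity adjustment), then counts
#' per phenotype: Bonferroni-significant loci (`p < bonferroni_alpha /
#' n_loci`, strict), genome-wide-significant loci (`p < gw_alpha`, strict),
#' and loci where the phenotype's p beats the positive control's. Negative
#' control phenotypes (names starting with `"negative_control"`) are
#' summarized the same way.
#'
#' @param meta data.frame from [meta_analyze()].
#' @param locus_set locus set from [ld_expand()] (maps variants to leads);
#'   if NULL every variant is its own locus.
#' @param n_loci number of candidate loci for the Bonferroni divisor
#'   (default 39).
#' @param bonferroni_alpha family-wise alpha (default 0.05).
#' @param gw_alpha genome-wide threshold (default 5e-8).
#' @return list with `locus_p` (locus x phenotype minimum p table, long
#'   format) and `summary` (per-phenotype counts and formatted replication
#'   fraction).
#' @export
significance_summary <- function(meta, locus_set = NULL, n_loci = 39,
                                 bonferroni_alpha = 0.05, gw_alpha = 5e-8) {
  if (nrow(meta) == 0)
    return(list(locus_p = data.frame(), summary = data.frame()))
  lead_of <- if (is.null(locus_set)) {
    setNames(unique(meta$variant), unique(meta$variant))
  } else setNames(locus_set$lead, locus_set$variant)
  meta$locus <- lead_of[meta$variant]
  key <- interaction(meta$phenotype, meta$locus, drop = TRUE)
  locus_p <- do.call(rbind, lapply(split(meta, key), function(d)
    data.frame(phenotype = d$phenotype[1], locus = d$locus[1],
               p = if (all(is.na(d$p))) NA_real_ else min(d$p, na.rm = TRUE))))
  rownames(locus_p) <- NULL
  bonf <- bonferroni_alpha / n_loci
  pos <- locus_p[locus_p$phenotype == "positive_control", ]
  has_pos <- nrow(pos) > 0
  if (!has_pos)
    warning("no positive control results; baseline comparison fields empty")
  phs <- unique(locus_p$phenotype)
  summary <- do.call(rbind, lapply(phs, function(ph) {
    d <- locus_p[locus_p$phenotype == ph, ]
    n_bonf <- sum(d$p < bonf, na.rm = TRUE)
    beats <- if (has_pos && ph != "positive_control") {
      pp <- pos$p[match(d$locus, pos$locus)]
      sum(d$p < pp, na.rm = TRUE)
    } else NA_integer_
    data.frame(phenotype = ph, loci_tested = nrow(d),
               bonferroni_significant = n_bonf,
               genomewide_significant = sum(d$p < gw_alpha, na.rm = TRUE),
               beats_positive_control = beats,
               replication = format_locus_fraction(n_bonf, n_loci))
  }))
  rownames(summary) <- NULL
  list(locus_p = locus_p, summary = summary)
}
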