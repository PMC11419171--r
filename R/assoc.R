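#' Genetic principal components
#'
#' PCs of the centered, allele-frequency-standardized dosage matrix
#' (center `2*p`, scale `sqrt(2*p*(1-p))`), the standard population-
#' structure covariates. Missing dosages are mean-imputed per variant;
#' monomorphic variants are dropped before decomposition.
#'
#' @param G dosage matrix, subjects x variants (values in `[0, 2]`, NA
#'   allowed).
#' @param n_pcs number of components (default 4).
#' @return numeric matrix subjects x `n_pcs` with orthogonal columns.
#' @export
compute_pcs <- function(G, n_pcs = 4) {
  G <- as.matrix(G)
  G <- apply(G, 2, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g })
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1 & apply(G, 2, sd) > 0
  if (sum(poly) < n_pcs)
    stop(sprintf("need at least %d non-monomorphic variants, have %d",
                 n_pcs, sum(poly)), call. = FALSE)
  Gs <- scale(G[, poly, drop = FALSE], center = 2 * p[poly],
              scale = sqrt(2 * p[poly] * (1 - p[poly])))
  pcs <- prcomp(Gs, center = FALSE, scale. = FALSE, rank. = n_pcs)$x
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  rownames(pcs) <- rownames(G)
  pcs
}

#' Expand candidate loci to LD tag SNPs
#'
#' For each lead variant, tags are reference-panel variants on the same
#' chromosome with `|pos_tag - pos_lead| < window` (strict) and squared
#' Pearson dosage correlation `r^2 > r2_min` (strict). The lead itself is
#' carried with `r2 = 1`, `distance = 0`. A lead that is monomorphic in the
#' reference cannot anchor correlations and is emitted lead-only with a
#' warning.
#'
#' @param reference dosage matrix of the LD reference panel
#'   (subjects x variants).
#' @param variants variant table (`id`, `chrom`, `pos`) aligned to the
#'   columns of `reference`.
#' @param leads character vector of lead variant ids (must be in `variants`).
#' @param window base-pair window (default 5e5, i.e. 0.5 Mb).
#' @param r2_min r-squared lower bound (default 0.1).
#' @return data.frame locus set: `lead`, `variant`, `chrom`, `pos`, `r2`,
#'   `distance`.
#' @export
ld_expand <- function(reference, variants, leads, window = 5e5, r2_min = 0.1) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(variants)),
            ncol(reference) == nrow(variants))
  missing <- setdiff(leads, variants$id)
  if (length(missing))
    stop("leads absent from reference: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (lead in leads) {
    li <- match(lead, variants$id)
    out[[length(out) + 1]] <- data.frame(
      lead = lead, variant = lead, chrom = variants$chrom[li],
      pos = variants$pos[li], r2 = 1, distance = 0L)
    g_lead <- reference[, li]
    if (sd(g_lead, na.rm = TRUE) == 0) {
      warning(sprintf("lead %s monomorphic in reference; emitted lead-only", lead))
      next
    }
    cand <- which(variants$chrom == variants$chrom[li] &
                    abs(variants$pos - variants$pos[li]) < window &
                    variants$id != lead)
    for (ci in cand) {
      g <- reference[, ci]
      if (sd(g, na.rm = TRUE) == 0) next
      r2 <- cor(g_lead, g, use = "complete.obs")^2
      if (is.finite(r2) && r2 > r2_min)
        out[[length(out) + 1]] <- data.frame(
          lead = lead, variant = variants$id[ci], chrom = variants$chrom[ci],
          pos = variants$pos[ci], r2 = r2,
          distance = abs(variants$pos[ci] - variants$pos[li]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Null logistic model y ~ covariates, prepared for repeated score tests.
null_logistic <- function(y, covars) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covars))
  fit <- glm.fit(X, y, family = binomial())
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  XtWXinv_XtW <- solve(crossprod(X, X * W), t(X * W))
  list(y = y, X = X, mu = mu, W = W, XtWXinv_XtW = XtWXinv_XtW,
       separation = any(mu < 1e-8 | mu > 1 - 1e-8))
}

score_test <- function(null, g) {
  U <- sum(g * (null$y - null$mu))
  g_adj <- g - null$X %*% (null$XtWXinv_XtW %*% g)
  V <- sum(null$W * g * g_adj)
  if (V <= 0) return(list(U = U, V = V, z = NA_real_, p = NA_real_))
  z <- U / sqrt(V)
  list(U = U, V = V, z = z, p = 2 * pnorm(-abs(z)))
}

#' Covariate-adjusted logistic association test for one variant
#'
#' Fits the null logistic model `y ~ covariates`, computes the score test
#' for the dosage term (the working replacement for a mixed-model score
#' test when no relatedness structure is present), and reports the effect
#' size either from the full logistic fit (`beta_method = "fit"`, Wald
#' beta/se) or from the one-step approximation `U/V` (`"onestep"`, cheap
#' for large scans). Missing dosages are mean-imputed; a variant that is
#' monomorphic after imputation is skipped with a reason rather than an
#' error. Quasi-separation is flagged; the score p-value is still valid.
#'
#' @param g dosage vector.
#' @param y binary case flags (0/1).
#' @param covars covariate matrix / data.frame (e.g. age + 4 PCs).
#' @param beta_method `"fit"` or `"onestep"`.
#' @param null optional pre-computed [null_logistic()] object (shared
#'   across variants of the same phenotype/stratum).
#' @return one-row data.frame: `beta`, `se`, `statistic` (score z), `p`,
#'   `n_case`, `n_control`, `skipped`, `reason`.
#' @export
logistic_assoc <- function(g, y, covars, beta_method = c("fit", "onestep"),
                           null = NULL) {
  beta_method <- match.arg(beta_method)
  stopifnot(length(g) == length(y))
  if (sum(y) < 1 || sum(1 - y) < 1)
    stop("need at least one case and one control", call. = FALSE)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  res <- data.frame(beta = NA_real_, se = NA_real_, statistic = NA_real_,
                    p = NA_real_, n_case = sum(y), n_control = sum(1 - y),
                    skipped = FALSE, reason = "")
  if (sd(g) == 0) {
    res$skipped <- TRUE; res$reason <- "monomorphic"
    return(res)
  }
  if (is.null(null)) null <- null_logistic(y, covars)
  st <- score_test(null, g)
  res$statistic <- st$z
  res$p <- st$p
  if (beta_method == "onestep") {
    res$beta <- st$U / st$V
    res$se <- 1 / sqrt(st$V)
  } else {
    Xf <- cbind(`(Intercept)` = 1, g = g, as.matrix(covars))
    fit <- suppressWarnings(glm.fit(Xf, y, family = binomial()))
    cf <- fit$coefficients["g"]
    cov_g <- tryCatch({
      W <- fit$fitted.values * (1 - fit$fitted.values)
      solve(crossprod(Xf, Xf * W))["g", "g"]
    }, error = function(e) NA_real_)
    res$beta <- unname(cf)
    res$se <- sqrt(cov_g)
    if (null$separation || !fit$converged || abs(cf) > 15)
      res$reason <- "possible separation"
  }
  res
}

#' Cluster-stratified candidate-locus association
#'
#' For each phenotype (each cluster, plus any control phenotypes), each
#' ancestry x dataset stratum and each variant: cases are the phenotype's
#' cluster members in the stratum, controls are the stratum's
#' non-endometriosis females, and the covariate-adjusted logistic score
#' test is run with age plus the stratum's first `n_pcs` genetic PCs as
#' covariates. Strata without cases for a phenotype are skipped (recorded
#' in the attribute `"skipped"`); a phenotype with no cases anywhere is an
#' error.
#'
#' @param G dosage matrix (subjects x variants), rownames = subject ids.
#' @param variants variant table aligned to columns of `G`.
#' @param subjects subject table (`subject_id`, `age`, `sex`, `ancestry`,
#'   `dataset`).
#' @param case_labels named vector: endometriosis case subject id ->
#'   cluster label. Subjects absent from it are controls.
#' @param phenotypes named list: phenotype name -> vector of cluster
#'   labels whose members are cases (e.g. `list(cluster1 = 1,
#'   positive_control = 1:5)`).
#' @param n_pcs number of genetic PCs per stratum (default 4; reduced if a
#'   stratum lacks variants).
#' @param beta_method passed to [logistic_assoc()].
#' @param min_stratum_cases strata with fewer cases are skipped (default 10).
#' @return data.frame with `variant`, `chrom`, `pos`, `effect_allele`,
#'   `phenotype`, `stratum`, `beta`, `se`, `statistic`, `p`, `n_case`,
#'   `n_control`, `skipped`, `reason`.
#' @export
run_stratified_assoc <- function(G, variants, subjects, case_labels, phenotypes,
                                 n_pcs = 4, beta_method = "fit",
                                 min_stratum_cases = 10) {
  stopifnot(!is.null(rownames(G)), nrow(variants) == ncol(G))
  subjects <- subjects[subjects$subject_id %in% rownames(G) &
                         subjects$sex == "female", ]
  strata <- interaction(subjects$ancestry, subjects$dataset, drop = TRUE,
                        sep = ":")
  is_case_overall <- subjects$subject_id %in% names(case_labels)
  rows <- list(); skipped_log <- character(0)
  for (ph in names(phenotypes)) {
    members <- names(case_labels)[case_labels %in% phenotypes[[ph]]]
    if (!length(members))
      stop(sprintf("phenotype '%s' has no cases in any stratum", ph),
           call. = FALSE)
    for (st in levels(strata)) {
      in_st <- strata == st
      case_ids <- subjects$subject_id[in_st & subjects$subject_id %in% members]
      ctrl_ids <- subjects$subject_id[in_st & !is_case_overall]
      if (length(case_ids) < min_stratum_cases || length(ctrl_ids) < 1) {
        skipped_log <- c(skipped_log, sprintf(
          "%s / %s: %d cases, %d controls -- skipped", ph, st,
          length(case_ids), length(ctrl_ids)))
        next
      }
      ids <- c(case_ids, ctrl_ids)
      y <- c(rep(1L, length(case_ids)), rep(0L, length(ctrl_ids)))
      Gs <- G[ids, , drop = FALSE]
      age <- subjects$age[match(ids, subjects$subject_id)]
      # PCs only when the panel is big enough to support them; a PC basis
      # drawn from fewer variants than n_pcs would just re-encode the
      # tested dosages as covariates
      pcs <- if (n_pcs >= 1 && ncol(Gs) > n_pcs) {
        tryCatch(compute_pcs(Gs, n_pcs = n_pcs), error = function(e) NULL)
      } else NULL
      covars <- if (is.null(pcs)) cbind(age = age) else cbind(age = age, pcs)
      null <- null_logistic(y, covars)
      for (v in seq_len(nrow(variants))) {
        r <- logistic_assoc(Gs[, v], y, covars, beta_method = beta_method,
                            null = null)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(variant = variants$id[v], chrom = variants$chrom[v],
                     pos = variants$pos[v],
                     effect_allele = variants$alt[v] %||% "G",
                     phenotype = ph, stratum = st),
          r)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped_log
  out
}
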