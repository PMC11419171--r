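#' Simulation configuration for synthetic EHR cohorts
#'
#' Describes a case-control cohort with `K` latent disease subtypes.
#' Cases of subtype `k` draw binary clinical features from
#' `Bernoulli(p[j, k])`; controls draw from `p0[j]`. Genotypes follow
#' Hardy-Weinberg proportions in controls and retrospective
#' (case-conditional) sampling with subtype-specific log-odds-ratios in
#' cases, so configured case counts are exact by construction, matching
#' case-control ascertainment.
#'
#' @param n_controls number of control subjects.
#' @param n_cases_per_subtype integer vector, cases per latent subtype.
#' @param feature_prevalence numeric matrix `p[j, k]` (features x subtypes)
#'   of case feature probabilities; rownames are feature names present in
#'   `catalog`.
#' @param control_feature_prevalence numeric vector `p0[j]`, same features.
#' @param variant_specs data.frame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf` and a numeric column `beta.k` per subtype holding
#'   the per-allele log-odds-ratio in subtype `k`.
#' @param strata data.frame with columns `ancestry` and `fraction`
#'   (fractions sum to 1); subjects are assigned ancestries at random.
#' @param stratum_maf optional named list `ancestry -> numeric vector`
#'   (length `nrow(variant_specs)`) overriding `maf` per ancestry, to
#'   induce allele-frequency heterogeneity across strata.
#' @param icd_sensitivity probability that a positive feature emits its ICD
#'   code (default 1).
#' @param dataset dataset label stamped on subjects.
#' @param catalog feature catalog used for ICD emission.
#' @return validated config object of class `endo_sim_config`.
#' @export
sim_config <- function(n_controls,
                       n_cases_per_subtype,
                       feature_prevalence,
                       control_feature_prevalence,
                       variant_specs = NULL,
                       strata = data.frame(ancestry = c("AFR", "EUR"),
                                           fraction = c(0.3, 0.7)),
                       stratum_maf = NULL,
                       icd_sensitivity = 1,
                       dataset = "SIM",
                       catalog = default_feature_catalog()) {
  if (!is.numeric(n_controls) || length(n_controls) != 1 || n_controls < 0)
    stop_cfg("n_controls", "must be a single count >= 0")
  if (!is.numeric(n_cases_per_subtype) || any(n_cases_per_subtype < 0))
    stop_cfg("n_cases_per_subtype", "must be counts >= 0")
  p <- as.matrix(feature_prevalence)
  check_prob(p, "feature_prevalence")
  check_prob(control_feature_prevalence, "control_feature_prevalence")
  if (is.null(rownames(p)))
    stop_cfg("feature_prevalence", "must have feature rownames")
  if (length(control_feature_prevalence) != nrow(p))
    stop_cfg("control_feature_prevalence", "length must match feature_prevalence rows")
  if (ncol(p) != length(n_cases_per_subtype))
    stop_cfg("feature_prevalence", "needs one column per subtype")
  validate_catalog(catalog)
  missing_feat <- setdiff(rownames(p), catalog$feature)
  if (length(missing_feat))
    stop_cfg("feature_prevalence",
             paste("has features absent from catalog:",
                   paste(missing_feat, collapse = ", ")))
  if (!is.null(variant_specs)) {
    need <- c("id", "chrom", "pos", "maf")
    if (!all(need %in% names(variant_specs)))
      stop_cfg("variant_specs", paste("must have columns", paste(need, collapse = ", ")))
    check_maf(variant_specs$maf, "variant_specs$maf")
    bcols <- paste0("beta.", seq_along(n_cases_per_subtype))
    if (!all(bcols %in% names(variant_specs)))
      stop_cfg("variant_specs", paste("must have columns", paste(bcols, collapse = ", ")))
    if (is.null(variant_specs$ref)) variant_specs$ref <- "A"
    if (is.null(variant_specs$alt)) variant_specs$alt <- "G"
  }
  check_prob(strata$fraction, "strata$fraction")
  if (abs(sum(strata$fraction) - 1) > 1e-8)
    stop_cfg("strata$fraction", "must sum to 1")
  if (!is.null(stratum_maf)) {
    for (anc in names(stratum_maf)) check_maf(stratum_maf[[anc]], paste0("stratum_maf$", anc))
  }
  check_prob(icd_sensitivity, "icd_sensitivity")
  structure(list(n_controls = as.integer(n_controls),
                 n_cases_per_subtype = as.integer(n_cases_per_subtype),
                 subtype_proportions = n_cases_per_subtype / sum(n_cases_per_subtype),
                 feature_prevalence = p,
                 control_feature_prevalence = setNames(control_feature_prevalence, rownames(p)),
                 variant_specs = variant_specs,
                 strata = strata,
                 stratum_maf = stratum_maf,
                 icd_sensitivity = icd_sensitivity,
                 dataset = dataset,
                 catalog = catalog),
            class = "endo_sim_config")
}

#' Default study-conditions simulation config
#'
#' Five latent subtypes shaped after the sub-phenotypes recovered from real
#' EHR cohorts: pain comorbidities, uterine disorders, pregnancy
#' complications, cardiometabolic comorbidities, and an EHR-asymptomatic
#' subtype with baseline prevalences only. Seventeen clustering features
#' carry the signal (subtype-specific prevalence 0.8 against a 0.05
#' background); the remaining non-anatomical catalog features sit below the
#' 5% case-prevalence filter, so feature selection reproduces a 17-column
#' clustering input from the 39-feature catalog. Anatomical lesion-site
#' codes are emitted for cases only, enriched in the uterine, pregnancy and
#' asymptomatic subtypes as in the real cohort characterization.
#'
#' @param n_cases_per_subtype cases per subtype (default 500 each).
#' @param n_controls number of controls (default 5000).
#' @param hi,lo subtype-specific and background feature probabilities.
#' @param variant_specs optional variant table; default plants one OR-1.5
#'   variant per subtype, one global OR-1.2 variant and four null variants.
#' @param ... passed to [sim_config()].
#' @return an `endo_sim_config`.
#' @export
default_sim_config <- function(n_cases_per_subtype = rep(500L, 5),
                               n_controls = 5000,
                               hi = 0.8, lo = 0.05,
                               variant_specs = NULL, ...) {
  catalog <- default_feature_catalog()
  K <- length(n_cases_per_subtype)
  own <- list(
    c("migraine", "irritable_bowel_syndrome", "fibromyalgia", "dysuria"),
    c("dysmenorrhea", "irregular_menstruation", "leiomyoma_of_uterus", "infertility"),
    c("high_risk_pregnancy", "spontaneous_abortion", "early_pregnancy_hemorrhage"),
    c("hypertension", "abnormal_cholesterol", "obesity"),
    c("pelvic_pain", "lower_abdominal_pain", "dyspareunia"))
  cluster_feats <- unlist(own)
  feats <- catalog$feature
  anat <- catalog$feature[catalog$group == "anatomical_subtype"]
  p0 <- setNames(rep(0.02, length(feats)), feats)
  p0[cluster_feats] <- lo
  p0[anat] <- 0  # controls carry no endometriosis lesion codes
  P <- matrix(rep(p0, K), ncol = K, dimnames = list(feats, NULL))
  for (k in seq_len(min(K, length(own)))) P[own[[k]], k] <- hi
  P[anat, ] <- 0.02
  if (K >= 2) P["uterine_endometriosis", 2] <- 0.25
  if (K >= 3) P["superficial_lesions", 3] <- 0.25
  if (K >= 5) P["unspecified_endometriosis", 5] <- 0.25
  if (is.null(variant_specs)) {
    nb <- function(...) { b <- rep(0, K); v <- list(...)
      for (k in names(v)) b[as.integer(k)] <- v[[k]]; b }
    betas <- rbind(nb("1" = log(1.5)), nb("2" = log(1.5)), nb("3" = log(1.5)),
                   nb("4" = log(1.5)), nb("5" = log(1.5)),
                   matrix(log(1.2), 1, K), matrix(0, 4, K))
    variant_specs <- data.frame(id = sprintf("rsS%02d", seq_len(10)),
                                chrom = as.character(seq_len(10)),
                                pos = 1000000L + 50000L * seq_len(10),
                                ref = "A", alt = "G",
                                maf = rep(c(0.3, 0.2), 5))
    colnames(betas) <- paste0("beta.", seq_len(K))
    variant_specs <- cbind(variant_specs, betas)
  }
  sim_config(n_controls = n_controls, n_cases_per_subtype = n_cases_per_subtype,
             feature_prevalence = P, control_feature_prevalence = p0,
             variant_specs = variant_specs, catalog = catalog, ...)
}

#' Simulate a full synthetic cohort
#'
#' Draws subjects, latent subtype labels, binary clinical features, the ICD
#' long table that encodes them, and genotype dosages. Identical
#' `config` + `seed` give byte-identical output.
#'
#' @param config an `endo_sim_config`.
#' @param seed integer seed.
#' @return object of class `endo_cohort`: list with `subjects`, `icd`,
#'   `features` (true binary flags), `geno` (subjects x variants dosage
#'   matrix), `variants`, and `truth` (latent subtype per subject, NA for
#'   controls, plus the generating parameters).
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "endo_sim_config"))
  n_case <- sum(config$n_cases_per_subtype)
  n <- n_case + config$n_controls
  K <- length(config$n_cases_per_subtype)
  ids <- sprintf("S%06d", seq_len(n))
  subtype <- c(rep(seq_len(K), times = config$n_cases_per_subtype),
               rep(NA_integer_, config$n_controls))
  with_seed(seed, {
    ancestry <- sample(config$strata$ancestry, n, replace = TRUE,
                       prob = config$strata$fraction)
    age <- round(pmin(pmax(rnorm(n, 50, 13), 18), 90), 1)
    subjects <- data.frame(subject_id = ids, age = age, sex = "female",
                           ancestry = ancestry, dataset = config$dataset)
    # features
    feats <- rownames(config$feature_prevalence)
    X <- matrix(0L, n, length(feats), dimnames = list(ids, feats))
    for (k in seq_len(K)) {
      idx <- which(!is.na(subtype) & subtype == k)
      if (!length(idx)) next
      X[idx, ] <- matrix(rbinom(length(idx) * length(feats), 1,
                                rep(config$feature_prevalence[, k], each = length(idx))),
                         nrow = length(idx))
    }
    ctrl <- which(is.na(subtype))
    if (length(ctrl))
      X[ctrl, ] <- matrix(rbinom(length(ctrl) * length(feats), 1,
                                 rep(config$control_feature_prevalence, each = length(ctrl))),
                          nrow = length(ctrl))
  })
  icd <- emit_icd_records(X, config$catalog,
                          icd_sensitivity = config$icd_sensitivity,
                          seed = seed + 1003L,
                          case_ids = ids[!is.na(subtype)])
  truth <- list(subtype = setNames(subtype, ids),
                feature_prevalence = config$feature_prevalence,
                control_feature_prevalence = config$control_feature_prevalence,
                variant_specs = config$variant_specs)
  geno <- NULL
  if (!is.null(config$variant_specs)) {
    geno <- simulate_genotypes(subjects, truth, config$variant_specs,
                               seed = seed + 2003L,
                               stratum_maf = config$stratum_maf)
  }
  structure(list(subjects = subjects, icd = icd, features = X,
                 geno = geno, variants = config$variant_specs,
                 truth = truth, config = config),
            class = "endo_cohort")
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' Simulate genotype dosages with subtype-specific effects
#'
#' Controls draw genotypes `g ~ Binomial(2, maf)` (Hardy-Weinberg). Cases of
#' subtype `k` draw `g` with probability proportional to
#' `HWE(g) * exp(beta_k * g)` — retrospective (case-conditional) logistic
#' sampling, so the case allele frequency rises monotonically with
#' `beta_k`.
#'
#' @param subjects subject table (`subject_id`, `ancestry`).
#' @param truth list with element `subtype` (named integer vector, NA for
#'   controls).
#' @param variant_specs variant table as in [sim_config()].
#' @param seed integer seed.
#' @param stratum_maf optional named list of per-ancestry maf vectors.
#' @return integer dosage matrix, subjects x variants.
#' @export
simulate_genotypes <- function(subjects, truth, variant_specs, seed = 1,
                               stratum_maf = NULL) {
  check_maf(variant_specs$maf, "variant_specs$maf")
  subtype <- truth$subtype[subjects$subject_id]
  if (any(is.na(subtype) & subjects$subject_id %in%
            names(truth$subtype)[!is.na(truth$subtype)]))
    stop("every case must have a subtype", call. = FALSE)
  n <- nrow(subjects)
  K <- sum(startsWith(names(variant_specs), "beta."))
  B <- as.matrix(variant_specs[, paste0("beta.", seq_len(K)), drop = FALSE])
  G <- matrix(0L, n, nrow(variant_specs),
              dimnames = list(subjects$subject_id, variant_specs$id))
  with_seed(seed, {
    for (v in seq_len(nrow(variant_specs))) {
      maf <- rep(variant_specs$maf[v], n)
      if (!is.null(stratum_maf)) {
        for (anc in names(stratum_maf))
          maf[subjects$ancestry == anc] <- stratum_maf[[anc]][v]
      }
      g <- integer(n)
      ctrl <- is.na(subtype)
      g[ctrl] <- rbinom(sum(ctrl), 2, maf[ctrl])
      for (k in seq_len(K)) {
        idx <- which(!ctrl & subtype == k)
        if (!length(idx)) next
        w <- exp(B[v, k] * 0:2)
        for (m in unique(maf[idx])) {
          sub <- idx[maf[idx] == m]
          pr <- hwe_probs(m) * w
          g[sub] <- sample(0:2, length(sub), replace = TRUE, prob = pr / sum(pr))
        }
      }
      G[, v] <- g
    }
  })
  G
}

#' Emit an ICD long table from binary feature flags
#'
#' Inverse of [extract_features()]: each positive flag emits the feature's
#' first ICD-9 or ICD-10 prefix (vocabulary drawn at random) with
#' probability `icd_sensitivity`. Cases additionally emit a bare
#' endometriosis stem code ("617" / "N80"), which defines case status
#' without touching any anatomical-subtype feature. At sensitivity 1 the
#' round trip `extract_features(emit_icd_records(X))` reproduces `X`
#' exactly.
#'
#' @param flags binary matrix, subjects x features (rownames = subject ids).
#' @param catalog feature catalog; every flagged feature must appear in it.
#' @param icd_sensitivity emission probability per positive flag.
#' @param seed integer seed.
#' @param case_ids subjects that receive the endometriosis stem code.
#' @return ICD long data.frame (`subject_id`, `vocabulary`, `code`).
#' @export
emit_icd_records <- function(flags, catalog = default_feature_catalog(),
                             icd_sensitivity = 1, seed = 1,
                             case_ids = character(0)) {
  validate_catalog(catalog)
  check_prob(icd_sensitivity, "icd_sensitivity")
  miss <- setdiff(colnames(flags), catalog$feature)
  if (length(miss))
    stop("features missing from catalog: ", paste(miss, collapse = ", "),
         call. = FALSE)
  j9 <- vapply(split_prefixes(catalog$icd9), function(p) p[1] %||% NA_character_, "")
  j10 <- vapply(split_prefixes(catalog$icd10), function(p) p[1] %||% NA_character_, "")
  names(j9) <- names(j10) <- catalog$feature
  pos <- which(flags == 1L, arr.ind = TRUE)
  with_seed(seed, {
    keep <- runif(nrow(pos)) < icd_sensitivity
    pos <- pos[keep, , drop = FALSE]
    feat <- colnames(flags)[pos[, 2]]
    use9 <- runif(nrow(pos)) < 0.5
    use9[is.na(j9[feat])] <- FALSE
    use9[is.na(j10[feat])] <- TRUE
    rec <- data.frame(subject_id = rownames(flags)[pos[, 1]],
                      vocabulary = ifelse(use9, "ICD9", "ICD10"),
                      code = ifelse(use9, j9[feat], j10[feat]))
    if (length(case_ids)) {
      use9c <- runif(length(case_ids)) < 0.5
      rec <- rbind(rec, data.frame(subject_id = case_ids,
                                   vocabulary = ifelse(use9c, "ICD9", "ICD10"),
                                   code = ifelse(use9c, "617", "N80")))
    }
  })
  rec <- rec[order(rec$subject_id, rec$vocabulary, rec$code), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
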