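test_that("identical config and seed give byte-identical cohorts", {
  cfg <- default_sim_config(n_cases_per_subtype = rep(40L, 5), n_controls = 100L)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a$icd, b$icd)
  expect_identical(a$geno, b$geno)
  expect_identical(a$features, b$features)
  c <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$icd, c$icd))
})

test_that("invalid configuration errors name the offending field", {
  P <- matrix(0.5, 2, 2, dimnames = list(c("migraine", "asthma"), NULL))
  expect_error(sim_config(10, c(5, 5), P * 3, c(0.1, 0.1)),
               "feature_prevalence")
  expect_error(sim_config(10, c(5, 5), P, c(0.1, 1.2)),
               "control_feature_prevalence")
  expect_error(
    sim_config(10, c(5, 5), P, c(0.1, 0.1),
               variant_specs = data.frame(id = "v", chrom = "1", pos = 1L,
                                          maf = 0.7, beta.1 = 0, beta.2 = 0)),
    "maf")
})

test_that("feature prevalences are recovered within 3 binomial SDs", {
  n <- 2000L
  P <- matrix(c(0.8, 0.3), 2, 1,
              dimnames = list(c("migraine", "asthma"), NULL))
  cfg <- sim_config(n_controls = n, n_cases_per_subtype = n,
                    feature_prevalence = P,
                    control_feature_prevalence = c(0.1, 0.3))
  co <- simulate_cohort(cfg, seed = 21)
  cases <- !is.na(co$truth$subtype)
  sd_of <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$features[cases, "migraine"]) - 0.8), 3 * sd_of(0.8))
  expect_lt(abs(mean(co$features[!cases, "migraine"]) - 0.1), 3 * sd_of(0.1))
})

test_that("null feature config gives uniform cluster-vs-rest test statistics", {
  # p_jk == p_j0: any case partition is exchangeable, z-tests ~ null
  P <- matrix(0.3, 4, 2, dimnames = list(c("migraine", "asthma",
                                           "obesity", "fatigue"), NULL))
  cfg <- sim_config(n_controls = 0, n_cases_per_subtype = c(400L, 400L),
                    feature_prevalence = P,
                    control_feature_prevalence = rep(0.3, 4))
  co <- simulate_cohort(cfg, seed = 31)
  lab <- co$truth$subtype[rownames(co$features)]
  en <- enrichment_table(co$features[, rownames(P)], lab)
  expect_false(any(en$significant))
  expect_gt(min(en$p), 0.001)  # no extreme statistic under the null
})

test_that("retrospective genotype sampling matches the closed-form HWE enumeration", {
  # expected case AF = sum (g/2) HWE(g) OR^g / sum HWE(g) OR^g = 0.39131
  # at maf 0.3, OR 1.5 (computed by retro_af_oracle)
  expect_equal(retro_af_oracle(0.3, 1.5), 0.3913043, tolerance = 1e-6)
  n <- 4000L
  spec <- data.frame(id = "v1", chrom = "1", pos = 100L, ref = "A", alt = "G",
                     maf = 0.3, beta.1 = log(1.5))
  subjects <- data.frame(subject_id = sprintf("s%04d", 1:n), ancestry = "EUR")
  truth <- list(subtype = setNames(rep(1L, n), subjects$subject_id))
  G <- simulate_genotypes(subjects, truth, spec, seed = 5)
  af <- mean(G[, 1]) / 2
  se <- sqrt(0.3913 * (1 - 0.3913) / (2 * n))
  expect_lt(abs(af - 0.3913043), 4 * se)
})

test_that("null genetic effects leave case and control allele frequencies equal", {
  spec <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(1L, 2L),
                     ref = "A", alt = "G", maf = c(0.3, 0.5),
                     beta.1 = 0)
  n <- 3000L
  subjects <- data.frame(subject_id = sprintf("s%04d", 1:(2 * n)), ancestry = "EUR")
  truth <- list(subtype = setNames(c(rep(1L, n), rep(NA_integer_, n)),
                                   subjects$subject_id))
  G <- simulate_genotypes(subjects, truth, spec, seed = 6)
  af_case <- colMeans(G[1:n, ]) / 2
  af_ctrl <- colMeans(G[(n + 1):(2 * n), ]) / 2
  expect_lt(max(abs(af_case - af_ctrl)), 4 * sqrt(0.25 / n))
  expect_lt(abs(mean(G[, "v2"]) - 1), 4 * sqrt(0.5 / (2 * n)))  # maf .5 -> dosage 1
})

test_that("case allele frequency increases monotonically with the planted effect", {
  n <- 3000L
  subjects <- data.frame(subject_id = sprintf("s%04d", 1:n), ancestry = "EUR")
  truth <- list(subtype = setNames(rep(1L, n), subjects$subject_id))
  afs <- vapply(c(0, log(1.3), log(2)), function(b) {
    spec <- data.frame(id = "v", chrom = "1", pos = 1L, ref = "A", alt = "G",
                       maf = 0.2, beta.1 = b)
    mean(simulate_genotypes(subjects, truth, spec, seed = 8)) / 2
  }, numeric(1))
  expect_true(all(diff(afs) > 0))
})

test_that("ICD emission inverts feature extraction at sensitivity 1", {
  cfg <- default_sim_config(n_cases_per_subtype = rep(30L, 5), n_controls = 80L)
  co <- simulate_cohort(cfg, seed = 41)
  X <- extract_features(co$icd, cfg$catalog,
                        subject_ids = co$subjects$subject_id)
  expect_identical(unname(X), unname(co$features))
  st <- case_status(co$icd, co$subjects)
  expect_equal(sum(st$status == "case"), 150)
})

test_that("ICD emission respects sensitivity 0 and binomial thinning at 0.5", {
  flags <- matrix(1L, 100, 4,
                  dimnames = list(sprintf("s%03d", 1:100),
                                  c("migraine", "asthma", "obesity", "fatigue")))
  none <- emit_icd_records(flags, icd_sensitivity = 0, seed = 1)
  expect_equal(nrow(none), 0)
  some <- emit_icd_records(flags, icd_sensitivity = 0.5, seed = 2)
  # 400 positive flags; emitted count within 3 binomial SDs of 200
  expect_lt(abs(nrow(some) - 200), 3 * sqrt(400 * 0.25))
  expect_error(emit_icd_records(
    matrix(1L, 2, 1, dimnames = list(c("a", "b"), "not_a_feature"))),
    "missing from catalog")
})
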