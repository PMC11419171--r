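make_geno <- function(n, mafs, seed = 1) {
  withr::with_seed(seed, {
    G <- sapply(mafs, function(m) rbinom(n, 2, m))
    rownames(G) <- sprintf("s%05d", seq_len(n))
    colnames(G) <- sprintf("v%03d", seq_along(mafs))
    G
  })
}

test_that("PCs separate divergent ancestry groups and are orthogonal", {
  n <- 200
  withr::with_seed(31, {
    maf_a <- runif(50, 0.05, 0.45)
    maf_b <- pmin(0.5, pmax(0.02, maf_a + sample(c(-1, 1), 50, TRUE) * 0.3))
    G <- rbind(sapply(maf_a, function(m) rbinom(n, 2, m)),
               sapply(maf_b, function(m) rbinom(n, 2, m)))
  })
  rownames(G) <- sprintf("s%04d", seq_len(2 * n))
  pcs <- compute_pcs(G, n_pcs = 4)
  grp <- rep(0:1, each = n)
  expect_gt(abs(cor(pcs[, 1], grp)), 0.9)
  crossp <- crossprod(pcs)
  expect_lt(max(abs(crossp[upper.tri(crossp)])) /
              min(diag(crossp)), 1e-8)
  # duplicated subjects land on identical coordinates
  G2 <- G[c(1, 1, 2, 2, seq_len(2 * n)), ]
  pcs2 <- compute_pcs(G2, n_pcs = 2)
  expect_equal(pcs2[1, ], pcs2[2, ], tolerance = 1e-8)
  expect_error(compute_pcs(G[, 1:2], n_pcs = 4), "non-monomorphic")
})

test_that("LD expansion applies the strict window and r2 rules", {
  n <- 400
  withr::with_seed(33, {
    g1 <- rbinom(n, 2, 0.3)
    g_ind <- rbinom(n, 2, 0.3)
  })
  G <- cbind(lead = g1, dup = g1, ind = g_ind, far = g1,
             mono = rep(0L, n))
  rownames(G) <- sprintf("s%04d", 1:n)
  variants <- data.frame(id = colnames(G), chrom = "2",
                         pos = c(1e6, 1e6 + 1000, 1e6 + 2000, 1.5e6, 1e6 + 3000))
  ls <- ld_expand(G, variants, "lead")
  expect_true("dup" %in% ls$variant)           # r2 = 1
  expect_equal(ls$r2[ls$variant == "dup"], 1)
  expect_false("ind" %in% ls$variant)          # independent, r2 ~ 0
  expect_false("far" %in% ls$variant)          # exactly 0.5 Mb: strict <
  expect_false("mono" %in% ls$variant)
  expect_equal(ls$variant[ls$r2 == 1 & ls$distance == 0], "lead")
  # monomorphic lead: lead-only with warning
  expect_warning(ls2 <- ld_expand(G, variants, "mono"), "monomorphic")
  expect_equal(ls2$variant, "mono")
  # r2 is invariant to allele flip of the tag
  G2 <- G; G2[, "dup"] <- 2L - G2[, "dup"]
  ls3 <- ld_expand(G2, variants, "lead")
  expect_equal(ls3$r2[ls3$variant == "dup"], 1)
})

test_that("score test agrees with the likelihood-ratio test at moderate n", {
  withr::with_seed(35, {
    n <- 1500
    covars <- cbind(age = rnorm(n, 50, 10))
    g <- rbinom(n, 2, 0.3)
    eta <- -1 + 0.3 * g
    y <- rbinom(n, 1, plogis(eta))
  })
  r <- logistic_assoc(g, y, covars)
  full <- glm(y ~ g + covars, family = binomial())
  nullm <- glm(y ~ covars, family = binomial())
  p_lrt <- pchisq(nullm$deviance - full$deviance, 1, lower.tail = FALSE)
  expect_equal(r$p, p_lrt, tolerance = 0.05)
  expect_equal(r$beta, unname(coef(full)["g"]), tolerance = 1e-6)
  expect_equal(r$se, unname(sqrt(vcov(full)["g", "g"])), tolerance = 1e-6)
  # one-step beta approximates the MLE
  r1 <- logistic_assoc(g, y, covars, beta_method = "onestep")
  expect_equal(r1$beta, r$beta, tolerance = 0.15)
  # constant dosage is skipped, not an error
  rc <- logistic_assoc(rep(1, n), y, covars)
  expect_true(rc$skipped)
  expect_equal(rc$reason, "monomorphic")
})

test_that("null score test is calibrated at alpha = 0.05", {
  withr::with_seed(36, {
    n <- 2500
    y <- c(rep(1L, 500), rep(0L, 2000))
    covars <- cbind(age = rnorm(n, 50, 10), pc = rnorm(n))
    null <- endoclust:::null_logistic(y, covars)
    p <- replicate(600, endoclust:::score_test(null, rbinom(n, 2, 0.25))$p)
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("stratified association does the bookkeeping per phenotype and stratum", {
  cfg <- default_sim_config(n_cases_per_subtype = rep(60L, 5), n_controls = 600L)
  co <- simulate_cohort(cfg, seed = 51)
  labels <- co$truth$subtype[!is.na(co$truth$subtype)]
  phen <- c(setNames(as.list(1:5), paste0("cluster", 1:5)),
            list(positive_control = 1:5))
  res <- run_stratified_assoc(co$geno, co$variants, co$subjects, labels, phen,
                              min_stratum_cases = 1)
  # <= phenotypes x strata x variants rows
  expect_lte(nrow(res), 6 * 2 * nrow(co$variants))
  # partition identity: cluster case counts sum to the positive control's
  one_variant <- res[res$variant == res$variant[1], ]
  by_stratum <- split(one_variant, one_variant$stratum)
  for (d in by_stratum) {
    expect_equal(sum(d$n_case[d$phenotype != "positive_control"]),
                 d$n_case[d$phenotype == "positive_control"])
  }
  expect_error(run_stratified_assoc(co$geno, co$variants, co$subjects, labels,
                                    list(ghost = 99)),
               "no cases")
})
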