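test_that("ICD codes canonicalize to uppercase dot-free form", {
  expect_equal(normalize_icd("n80.1"), "N801")
  expect_equal(normalize_icd("617.0"), "6170")
  expect_equal(normalize_icd("N80"), "N80")
  expect_equal(normalize_icd(c(" k58 ", "R10.2")), c("K58", "R102"))
  expect_error(normalize_icd(""), "empty")
  expect_error(normalize_icd(NA_character_), "empty")
})

test_that("default catalog has the 9/14/8/8 group partition and unique emission prefixes", {
  cat <- default_feature_catalog()
  expect_equal(nrow(cat), 39)
  expect_equal(as.integer(table(cat$group)[c("anatomical_subtype", "comorbidity",
                                             "symptom", "pregnancy")]),
               c(9L, 14L, 8L, 8L))
  # the first prefix of each feature must map back to that feature only,
  # otherwise ICD emission cannot round-trip
  for (vocab in c("icd9", "icd10")) {
    first <- vapply(strsplit(cat[[vocab]], ","), `[`, "", 1)
    all_pref <- strsplit(cat[[vocab]], ",")
    for (j in seq_len(nrow(cat))) {
      if (!nzchar(first[j])) next
      hits <- vapply(all_pref, function(p)
        any(nzchar(p) & startsWith(first[j], p)), logical(1))
      expect_equal(cat$feature[hits], cat$feature[j])
    }
  }
})

test_that("catalog YAML round-trips", {
  cat <- default_feature_catalog()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_catalog(cat, path)
  expect_equal(read_feature_catalog(path), cat)
})

test_that("case status follows the 617/N80 prefix rule restricted to females", {
  subjects <- data.frame(subject_id = c("a", "b", "c", "d", "e"),
                         sex = c("female", "female", "female", "male", "female"))
  records <- data.frame(
    subject_id = c("a", "b", "c", "d"),
    vocabulary = c("ICD10", "ICD10", "ICD9", "ICD10"),
    code = c("N80.3", "N81", "617.9", "N80.1"))
  st <- case_status(records, subjects)
  expect_setequal(st$subject_id, c("a", "b", "c", "e"))  # male d excluded
  expect_equal(st$status[st$subject_id == "a"], "case")    # N80.3
  expect_equal(st$status[st$subject_id == "b"], "control") # N81 is not N80
  expect_equal(st$status[st$subject_id == "c"], "case")    # ICD-9 617.9
  expect_equal(st$status[st$subject_id == "e"], "control") # no codes
})

test_that("feature extraction uses ever-coded OR semantics and handles empty histories", {
  cat <- default_feature_catalog()
  rec <- data.frame(subject_id = c("s1", "s1", "s2"),
                    vocabulary = c("ICD9", "ICD10", "ICD10"),
                    code = c("346.1", "G43.9", "J45"))
  X <- extract_features(rec, cat, subject_ids = c("s1", "s2", "s3"))
  expect_equal(unname(X["s1", "migraine"]), 1L)  # two codes, one feature
  expect_equal(unname(X["s2", "asthma"]), 1L)
  expect_equal(sum(X["s3", ]), 0L)               # no records: all-zero row
  expect_true(all(X %in% 0:1))
  expect_error(extract_features(data.frame(subject_id = "s", vocabulary = "ICD11",
                                           code = "X"), cat),
               "vocabulary")
})

test_that("adding codes never flips features off (monotonicity)", {
  cat <- default_feature_catalog()
  base <- data.frame(subject_id = "s1", vocabulary = "ICD10", code = "G43")
  withr::with_seed(42, {
    pool <- data.frame(
      subject_id = "s1",
      vocabulary = sample(c("ICD9", "ICD10"), 30, replace = TRUE),
      code = sample(c("J45", "N80.1", "I10", "E66", "R30", "Z99", "K58"),
                    30, replace = TRUE))
  })
  prev <- extract_features(base, cat, subject_ids = "s1")
  for (i in seq_len(nrow(pool))) {
    cur <- extract_features(rbind(base, pool[seq_len(i), ]), cat,
                            subject_ids = "s1")
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("prevalence filter drops anatomical columns and applies a closed threshold", {
  cat <- default_feature_catalog()
  n <- 1000
  X <- matrix(0L, n, nrow(cat), dimnames = list(NULL, cat$feature))
  X[seq_len(49), "migraine"] <- 1L   # prevalence 0.049 -> dropped
  X[seq_len(50), "asthma"] <- 1L     # prevalence 0.050 -> kept (at least 5%)
  X[seq_len(900), "uterine_endometriosis"] <- 1L  # anatomical -> dropped anyway
  out <- prevalence_filter(X, rep(TRUE, n), cat)
  expect_false("migraine" %in% colnames(out))
  expect_true("asthma" %in% colnames(out))
  expect_false("uterine_endometriosis" %in% colnames(out))
  expect_error(prevalence_filter(X, rep(FALSE, n), cat), "no cases")
})

test_that("prevalence filter keeps exactly the columns above threshold and is idempotent", {
  cat <- default_feature_catalog()
  nonanat <- cat$feature[cat$group != "anatomical_subtype"]  # 30 features
  n <- 400
  X <- matrix(0L, n, nrow(cat), dimnames = list(NULL, cat$feature))
  # exact counts: 17 features at prevalence 0.20, the other 13 at 0.02
  for (j in seq_along(nonanat)) {
    k <- if (j <= 17) 80L else 8L
    X[seq_len(k), nonanat[j]] <- 1L
  }
  out <- prevalence_filter(X, rep(TRUE, n), cat)
  expect_equal(ncol(out), 17)
  expect_equal(colnames(out), nonanat[1:17])
  twice <- prevalence_filter(out, rep(TRUE, n), cat)
  expect_identical(twice, out)
  expect_true(all(colnames(out) %in% colnames(X)))
})
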