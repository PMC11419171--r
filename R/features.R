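#' Canonicalize ICD codes
#'
#' Uppercases and strips dots so prefix matching operates on a single
#' canonical form ("n80.1" -> "N801"). Billing extracts differ in whether
#' they keep the decimal point; all matching in this package happens on the
#' canonical form.
#'
#' @param code character vector of ICD-9 or ICD-10 codes.
#' @return character vector of canonical codes.
#' @export
normalize_icd <- function(code) {
  if (length(code) == 0) return(character(0))
  code <- as.character(code)
  if (anyNA(code) || any(!nzchar(trimws(code))))
    stop("empty ICD code cannot be normalized", call. = FALSE)
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

check_icd_table <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("subject_id", "vocabulary", "code")
  if (!all(need %in% names(records)))
    stop("ICD table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(records$vocabulary), c("ICD9", "ICD10"))
  if (length(bad))
    stop("unknown vocabulary in ICD table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Endometriosis case status from ICD history
#'
#' A subject is an endometriosis case iff she carries any ICD-9 code with
#' canonical prefix "617" or any ICD-10 code with canonical prefix "N80"
#' (N80.x only; N81 etc. do not match). The cohort is restricted to
#' females: non-female subjects are excluded, and every female without a
#' qualifying code is a control.
#'
#' @param records ICD long table (`subject_id`, `vocabulary`, `code`).
#' @param subjects subject table with `subject_id` and `sex`.
#' @return data.frame (`subject_id`, `status`) with status
#'   `"case"`/`"control"`, one row per female subject.
#' @export
case_status <- function(records, subjects) {
  check_icd_table(records)
  stopifnot(all(c("subject_id", "sex") %in% names(subjects)))
  females <- subjects$subject_id[subjects$sex == "female"]
  code <- normalize_icd(records$code)
  hit <- (records$vocabulary == "ICD9" & startsWith(code, "617")) |
         (records$vocabulary == "ICD10" & startsWith(code, "N80"))
  cases <- unique(records$subject_id[hit])
  data.frame(subject_id = females,
             status = ifelse(females %in% cases, "case", "control"))
}

#' Binary clinical feature matrix from ICD history
#'
#' Ever-coded semantics: a cell is 1 iff the subject ever carries any code
#' whose canonical form starts with any of that feature's prefixes (in the
#' matching vocabulary). Subjects with no records get all-zero rows.
#'
#' @param records ICD long table.
#' @param catalog feature catalog (see [default_feature_catalog()]).
#' @param subject_ids character vector fixing row order; defaults to the
#'   subjects present in `records`.
#' @return binary matrix, subjects x features, dimnames set.
#' @export
extract_features <- function(records, catalog = default_feature_catalog(),
                             subject_ids = NULL) {
  check_icd_table(records)
  validate_catalog(catalog)
  if (is.null(subject_ids)) subject_ids <- sort(unique(records$subject_id))
  X <- matrix(0L, nrow = length(subject_ids), ncol = nrow(catalog),
              dimnames = list(subject_ids, catalog$feature))
  if (nrow(records) == 0) return(X)
  code <- normalize_icd(records$code)
  p9 <- split_prefixes(catalog$icd9)
  p10 <- split_prefixes(catalog$icd10)
  is9 <- records$vocabulary == "ICD9"
  row_of <- match(records$subject_id, subject_ids)
  for (j in seq_len(nrow(catalog))) {
    hit <- rep(FALSE, length(code))
    for (p in p9[[j]])  hit <- hit | (is9 & startsWith(code, p))
    for (p in p10[[j]]) hit <- hit | (!is9 & startsWith(code, p))
    rows <- unique(row_of[hit & !is.na(row_of)])
    if (length(rows)) X[rows, j] <- 1L
  }
  X
}

#' Select clustering features by case prevalence
#'
#' Drops the anatomical-subtype columns (reserved for downstream
#' characterization) and keeps, among the remaining groups, the features
#' whose prevalence among cases is at least `min_prevalence` (closed
#' threshold). Column order is preserved. With the default 39-feature
#' catalog and realistic cohorts this reproduces a 17-feature clustering
#' input.
#'
#' @param X binary phenotype matrix (subjects x features).
#' @param case_flags logical vector (or "case"/"control" character) marking
#'   case rows of `X`.
#' @param catalog feature catalog supplying column groups.
#' @param groups_to_keep feature groups eligible for clustering.
#' @param min_prevalence closed lower bound on case prevalence (default 0.05).
#' @return the filtered matrix.
#' @export
prevalence_filter <- function(X, case_flags, catalog = default_feature_catalog(),
                              groups_to_keep = c("comorbidity", "symptom", "pregnancy"),
                              min_prevalence = 0.05) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  if (is.character(case_flags)) case_flags <- case_flags == "case"
  if (length(case_flags) != nrow(X))
    stop("case_flags length must match rows of X", call. = FALSE)
  if (!any(case_flags))
    stop("prevalence undefined: no cases in cohort", call. = FALSE)
  grp <- catalog$group[match(colnames(X), catalog$feature)]
  if (anyNA(grp))
    stop("columns missing from catalog: ",
         paste(colnames(X)[is.na(grp)], collapse = ", "), call. = FALSE)
  keep_grp <- grp %in% groups_to_keep
  prev <- colMeans(X[case_flags, , drop = FALSE])
  X[, keep_grp & prev >= min_prevalence, drop = FALSE]
}
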