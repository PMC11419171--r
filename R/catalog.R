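#' Default endometriosis clinical feature catalog
#'
#' A 39-entry catalog of binary ICD-derived clinical features partitioned
#' into 9 anatomical lesion-site subtypes, 14 comorbidities, 8 symptoms and
#' 8 pregnancy-related phenotypes. Anatomical subtypes are ICD 617.x / N80.x
#' lesion-location codes; they are extracted for cluster characterization
#' but always removed before clustering. The remaining 30 features are the
#' candidate clustering inputs, subject to the case-prevalence filter.
#'
#' Prefix lists are editable defaults (site coding conventions differ);
#' use [read_feature_catalog()] / [write_feature_catalog()] to round-trip a
#' user-modified catalog through YAML.
#'
#' @return data.frame with columns `feature`, `group`
#'   (`anatomical_subtype`, `comorbidity`, `symptom`, `pregnancy`),
#'   `icd9`, `icd10` (comma-separated canonical dot-free code prefixes).
#' @export
default_feature_catalog <- function() {
  e <- function(feature, group, icd9, icd10)
    data.frame(feature = feature, group = group, icd9 = icd9, icd10 = icd10)
  cat <- rbind(
    # 9 anatomical lesion-site subtypes (617.x / N80.x)
    e("uterine_endometriosis",       "anatomical_subtype", "6170", "N800"),
    e("ovarian_endometriosis",       "anatomical_subtype", "6171", "N801"),
    e("fallopian_tube_endometriosis","anatomical_subtype", "6172", "N802"),
    e("superficial_lesions",         "anatomical_subtype", "6173", "N803"),
    e("rectovaginal_endometriosis",  "anatomical_subtype", "6174", "N804"),
    e("intestinal_endometriosis",    "anatomical_subtype", "6175", "N805"),
    e("cutaneous_scar_endometriosis","anatomical_subtype", "6176", "N806"),
    e("other_site_endometriosis",    "anatomical_subtype", "6178", "N808"),
    e("unspecified_endometriosis",   "anatomical_subtype", "6179", "N809"),
    # 14 comorbidities
    e("migraine",              "comorbidity", "346",        "G43"),
    e("irritable_bowel_syndrome", "comorbidity", "5641",    "K58"),
    e("fibromyalgia",          "comorbidity", "7291",       "M797"),
    e("asthma",                "comorbidity", "493",        "J45"),
    e("hypertension",          "comorbidity", "401",        "I10"),
    e("abnormal_cholesterol",  "comorbidity", "272",        "E78"),
    e("depression",            "comorbidity", "311,2962,2963", "F32,F33"),
    e("anxiety",               "comorbidity", "30000,30002","F41"),
    e("leiomyoma_of_uterus",   "comorbidity", "218",        "D25"),
    e("interstitial_cystitis", "comorbidity", "5951",       "N3010"),
    e("ovarian_cyst",          "comorbidity", "620",        "N83"),
    e("obesity",               "comorbidity", "278",        "E66"),
    e("type_2_diabetes",       "comorbidity", "250",        "E11"),
    e("pelvic_inflammatory_disease", "comorbidity", "614",  "N73"),
    # 8 symptoms
    e("dysmenorrhea",          "symptom", "6253",           "N944,N945,N946"),
    e("dysuria",               "symptom", "7881",           "R30"),
    e("dyspareunia",           "symptom", "6250",           "N941"),
    e("pelvic_pain",           "symptom", "6259",           "R102"),
    e("lower_abdominal_pain",  "symptom", "7890",           "R103"),
    e("irregular_menstruation","symptom", "6264,6266",      "N92"),
    e("shortness_of_breath",   "symptom", "78605",          "R0602"),
    e("fatigue",               "symptom", "7807",           "R53"),
    # 8 pregnancy-related phenotypes
    e("infertility",                 "pregnancy", "628",   "N97"),
    e("high_risk_pregnancy",         "pregnancy", "V23",   "O09"),
    e("spontaneous_abortion",        "pregnancy", "634",   "O03"),
    e("ectopic_pregnancy",           "pregnancy", "633",   "O00"),
    e("preeclampsia",                "pregnancy", "6424,6425", "O14"),
    e("gestational_diabetes",        "pregnancy", "6488",  "O244"),
    e("preterm_labor",               "pregnancy", "6442",  "O60"),
    e("early_pregnancy_hemorrhage",  "pregnancy", "640",   "O20")
  )
  rownames(cat) <- NULL
  cat
}

feature_groups <- c("anatomical_subtype", "comorbidity", "symptom", "pregnancy")

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("feature", "group", "icd9", "icd10") %in% names(catalog)))
  if (anyDuplicated(catalog$feature))
    stop("feature catalog contains duplicate feature names", call. = FALSE)
  if (!all(catalog$group %in% feature_groups))
    stop("feature catalog contains unknown groups: ",
         paste(setdiff(catalog$group, feature_groups), collapse = ", "),
         call. = FALSE)
  has_prefix <- nzchar(catalog$icd9) | nzchar(catalog$icd10)
  if (!all(has_prefix))
    stop("feature catalog entries without any ICD prefix: ",
         paste(catalog$feature[!has_prefix], collapse = ", "), call. = FALSE)
  invisible(catalog)
}

split_prefixes <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(p) normalize_icd(p[nzchar(p)]))
}

#' Read / write a feature catalog as YAML
#'
#' @param path file path.
#' @return `read_feature_catalog()` returns the catalog data.frame;
#'   `write_feature_catalog()` returns `path` invisibly.
#' @export
read_feature_catalog <- function(path) {
  y <- yaml::read_yaml(path)
  cat <- do.call(rbind, lapply(y$features, function(f)
    data.frame(feature = f$feature, group = f$group,
               icd9 = paste(f$icd9 %||% character(), collapse = ","),
               icd10 = paste(f$icd10 %||% character(), collapse = ","))))
  validate_catalog(cat)
}

#' @rdname read_feature_catalog
#' @param catalog feature catalog data.frame.
#' @export
write_feature_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  feats <- lapply(seq_len(nrow(catalog)), function(i) {
    sp <- function(x) { p <- strsplit(x, ",", fixed = TRUE)[[1]]; p[nzchar(p)] }
    list(feature = catalog$feature[i], group = catalog$group[i],
         icd9 = as.list(sp(catalog$icd9[i])), icd10 = as.list(sp(catalog$icd10[i])))
  })
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}
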