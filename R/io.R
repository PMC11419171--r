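#' Tab-separated readers and writers for pipeline artifacts
#'
#' All tables are plain TSV with a header row; `write_*`/`read_*` pairs
#' round-trip exactly. Dosage tables are variants-in-rows
#' (`id`, `chrom`, `pos`, `ref`, `alt`, then one column per subject).
#'
#' @param x object to write.
#' @param path file path.
#' @name endoclust-io
NULL

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' @rdname endoclust-io
#' @export
write_subjects <- function(x, path) write_tsv(x, path)

#' @rdname endoclust-io
#' @export
read_subjects <- function(path) {
  x <- read_tsv(path, colClasses = c(subject_id = "character"))
  need <- c("subject_id", "age", "sex", "ancestry", "dataset")
  if (!all(need %in% names(x)))
    stop("subjects TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname endoclust-io
#' @export
write_icd_long <- function(x, path) write_tsv(x, path)

#' @rdname endoclust-io
#' @export
read_icd_long <- function(path) {
  x <- read_tsv(path, colClasses = c(subject_id = "character",
                                     code = "character"))
  check_icd_table(x)
}

#' @rdname endoclust-io
#' @export
write_feature_matrix <- function(x, path) {
  write_tsv(data.frame(subject_id = rownames(x), x, check.names = FALSE),
            path)
}

#' @rdname endoclust-io
#' @export
read_feature_matrix <- function(path) {
  d <- read_tsv(path, colClasses = c(subject_id = "character"))
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d$subject_id
  m
}

#' @rdname endoclust-io
#' @param variants variant table aligned to rows of the dosage matrix.
#' @export
write_dosage_tsv <- function(x, variants, path) {
  out <- cbind(variants[, c("id", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(x), check.names = FALSE))
  write_tsv(out, path)
}

#' @rdname endoclust-io
#' @return `read_dosage_tsv()` returns `list(G, variants)` with `G`
#'   subjects x variants.
#' @export
read_dosage_tsv <- function(path) {
  d <- read_tsv(path, colClasses = c(id = "character", chrom = "character"))
  meta <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta %in% names(d)))
    stop("dosage TSV must start with columns: ", paste(meta, collapse = ", "),
         call. = FALSE)
  G <- t(as.matrix(d[, setdiff(names(d), meta), drop = FALSE]))
  colnames(G) <- d$id
  list(G = G, variants = d[, meta])
}

#' @rdname endoclust-io
#' @export
write_locus_list <- function(x, path) write_tsv(x, path)

#' @rdname endoclust-io
#' @export
read_locus_list <- function(path) {
  x <- read_tsv(path, colClasses = c(id = "character", chrom = "character"))
  if (!all(c("id", "chrom", "pos") %in% names(x)))
    stop("locus list must have columns id, chrom, pos", call. = FALSE)
  x
}

sumstats_cols <- c("variant", "chrom", "pos", "effect_allele", "phenotype",
                   "stratum", "beta", "se", "p", "n_case", "n_control")

#' @rdname endoclust-io
#' @export
write_sumstats <- function(x, path) {
  miss <- setdiff(sumstats_cols, names(x))
  if (length(miss))
    stop("summary statistics missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  write_tsv(x[, c(sumstats_cols, setdiff(names(x), sumstats_cols))], path)
}

#' @rdname endoclust-io
#' @export
read_sumstats <- function(path) read_tsv(path, colClasses = c(variant = "character",
                                                              chrom = "character"))

#' Minimal VCF writer / reader for dosage matrices
#'
#' `write_vcf()` writes a VCFv4.2 file with GT (hard genotypes where the
#' dosage is integral) and DS fields. `read_vcf_dosages()` reads dosages
#' back, preferring the DS field and otherwise counting alt alleles in GT
#' (`"0/1"` -> 1; `"./."` -> NA). Reading uses the vcfR package.
#'
#' @param G dosage matrix, subjects x variants.
#' @param variants variant table (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @param path file path (uncompressed `.vcf`).
#' @return `read_vcf_dosages()` returns `list(G, variants)`.
#' @export
write_vcf <- function(G, variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  gt_of <- function(d) {
    ifelse(is.na(d), "./.",
           ifelse(d == 0, "0/0", ifelse(d == 1, "0/1",
                  ifelse(d == 2, "1/1", "./."))))
  }
  for (v in seq_len(ncol(G))) {
    d <- G[, v]
    fields <- paste0(gt_of(d), ":",
                     ifelse(is.na(d), ".", formatC(d, format = "g")))
    writeLines(paste(c(variants$chrom[v], variants$pos[v], variants$id[v],
                       variants$ref[v] %||% "A", variants$alt[v] %||% "G",
                       ".", "PASS", ".", "GT:DS", fields), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"])
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(s) {
      if (is.na(s) || grepl("\\.", s)) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0)
    }
    ds <- apply(gt, c(1, 2), count_alt)
  }
  G <- t(ds)
  colnames(G) <- variants$id
  list(G = G, variants = variants)
}

#' @rdname endoclust-io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(list(subtype = as.list(x$subtype)), path,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}
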