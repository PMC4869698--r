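# Interchange formats: VCF 4.2 with GT/DS, tab-separated cohort and
# results tables. Plain text only; files are small at desk scale.

#' Write variants to a VCF 4.2 file
#'
#' Emits GT (hard call) and DS (alt-allele dosage) FORMAT fields and an
#' `INFO=<score>` INFO key; positions are 1-based. Missing samples are
#' written as `./.:.`.
#'
#' @param variants List of [variant_record()]s over a common sample set.
#' @param path Output file.
#' @param sample_ids Sample names for the header; defaults to S000001...
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_ids = NULL) {
  n <- if (length(variants)) length(variants[[1]]$dosage) else 0L
  if (is.null(sample_ids)) sample_ids <- sprintf("S%06d", seq_len(n))
  stopifnot(length(sample_ids) == n)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=domdev",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- vapply(variants, function(v) {
    g <- hard_call(v)
    field <- ifelse(is.na(g), "./.:.",
                    paste0(gt_str[g + 1L], ":",
                           formatC(v$dosage, digits = 8, format = "g")))
    paste(c(v$chrom, v$pos, v$vid, v$ref_allele, v$alt_allele, ".", "PASS",
            sprintf("INFO=%.6g", v$info), "GT:DS", field), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Parses the fixed GT/DS dialect written by [write_vcf()] (any VCF 4.x
#' with GT and/or DS FORMAT fields and optional `INFO=` key works).
#' Dosages come from DS when present, otherwise from the GT hard call.
#' Genotype probabilities are reconstructed from the dosage d as
#' (1-d, d, 0) for d <= 1 and (0, 2-d, d-1) otherwise — the minimal
#' two-class distribution with that mean; the original class
#' probabilities are not recoverable from GT/DS and only dosages are
#' guaranteed to round-trip. Samples with `.` genotypes are masked.
#'
#' @param path VCF file (uncompressed).
#' @return List with `variants` (list of [variant_record()]s) and
#'   `sample_ids`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF: no #CHROM header line")
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  sample_ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  variants <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    i_gt <- match("GT", fmt)
    i_ds <- match("DS", fmt)
    if (is.na(i_gt) && is.na(i_ds)) {
      warning("record ", f[3], " skipped: no GT or DS FORMAT field")
      next
    }
    parts <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    dosage <- vapply(parts, function(p) {
      if (!is.na(i_ds) && length(p) >= i_ds && p[i_ds] != ".")
        return(as.numeric(p[i_ds]))
      if (!is.na(i_gt) && length(p) >= i_gt) {
        gt <- p[i_gt]
        if (grepl("\\.", gt)) return(NA_real_)
        return(sum(as.numeric(strsplit(gt, "[/|]")[[1]])))
      }
      NA_real_
    }, 0)
    probs <- cbind(pmax(0, 1 - dosage),
                   ifelse(dosage <= 1, dosage, 2 - dosage),
                   pmax(0, dosage - 1))
    probs[is.na(dosage), ] <- NA_real_
    info <- NA_real_
    m <- regmatches(f[8], regexec("(?:^|;)INFO=([0-9.eE+-]+)", f[8]))[[1]]
    if (length(m) == 2) info <- as.numeric(m[2])
    variants[[length(variants) + 1L]] <-
      variant_record(chrom = f[1], pos = as.integer(f[2]), vid = f[3],
                     ref_allele = f[4], alt_allele = f[5],
                     genotype_probs = probs,
                     info = if (is.na(info)) NULL else info)
  }
  list(variants = variants, sample_ids = sample_ids)
}

#' Write / read a cohort table as tab-separated text
#'
#' Missing values are encoded `NA`; a header row is always present.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort_table <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  if (anyDuplicated(out$sample_id)) stop("duplicated sample_id in cohort")
  out
}

#' Write association results with a stable column order
#'
#' @param results Results data.frame from [scan_assoc()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  order_cols <- c("vid", "chrom", "pos", "effect_allele", "n_used",
                  "beta_add", "se_add", "p_add",
                  "beta_domdev", "se_domdev", "p_domdev",
                  "beta_rec", "se_rec", "p_rec",
                  "n_hom_ref", "n_het", "n_hom_alt")
  extra <- setdiff(names(results), order_cols)
  results <- results[c(order_cols, extra)]
  data.table::fwrite(results, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genotype-class summary table
#'
#' Expects a TSV with columns `class` (hom_ref/het/hom_alt), `n`, `mean`,
#' `sd`.
#'
#' @param path TSV file.
#' @return A [class_summary()].
#' @export
read_class_summary <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  tab <- tab[match(c("hom_ref", "het", "hom_alt"), tab$class), ]
  class_summary(n = tab$n, mean = tab$mean, sd = tab$sd)
}
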