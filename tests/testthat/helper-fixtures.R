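# Fixture builders shared across test files. Everything is generated in
# code; no stored binary data.

# Variant with exact hard-call class counts (one-hot probabilities).
variant_from_counts <- function(n_hom_ref, n_het, n_hom_alt, info = NULL,
                                vid = "vfix", pos = 1L) {
  g <- rep(0:2, times = c(n_hom_ref, n_het, n_hom_alt))
  probs <- matrix(0, length(g), 3)
  probs[cbind(seq_along(g), g + 1L)] <- 1
  variant_record(chrom = "1", pos = pos, vid = vid, ref_allele = "A",
                 alt_allele = "G", genotype_probs = probs, info = info)
}

# Variant from an explicit hard-call vector (keeps sample order).
variant_from_genotypes <- function(g, vid = "vfix", pos = 1L, info = NULL) {
  probs <- matrix(0, length(g), 3)
  ok <- !is.na(g)
  probs[!ok, ] <- NA_real_
  probs[cbind(which(ok), g[ok] + 1L)] <- 1
  variant_record(chrom = "1", pos = pos, vid = vid, ref_allele = "A",
                 alt_allele = "G", genotype_probs = probs, info = info)
}

# Random HWE variant at frequency f (hard calls, info = 1).
random_hwe_variant <- function(n, f, vid = "vr", pos = 1L) {
  g <- sample.int(3, n, replace = TRUE,
                  prob = c((1 - f)^2, 2 * f * (1 - f), f^2)) - 1L
  variant_from_genotypes(g, vid = vid, pos = pos)
}

# The printed FTO genotype-class table (counts, means kg/m^2, SDs).
fto_class_summary <- function() {
  class_summary(n = c(42835, 57524, 19329),
                mean = c(27.27, 27.54, 28.07),
                sd = c(4.68, 4.80, 5.11))
}

# QC fixture enumerating the 2^3 criterion combinations (info, hwe, maf).
# Returns list(variants, expected_fail) where expected_fail is a logical
# matrix with columns info/hwe/maf.
qc_combination_fixture <- function(n = 10000) {
  hwe_ok <- function(f) {
    k <- round(n * c((1 - f)^2, 2 * f * (1 - f), f^2))
    k[1] <- n - k[2] - k[3]
    k
  }
  good <- hwe_ok(0.3)            # passes all three
  bad_hwe <- c(n / 2, 0, n / 2)  # MAF 0.5, no hets: extreme HWE failure
  bad_maf <- hwe_ok(0.002)       # MAF 0.002 < 0.005, HWE consistent
  bad_hwe_maf <- c(n - 10, 0, 10)  # rare allele, all homozygous
  combos <- list(
    none         = list(counts = good,        info = 1.0),
    info         = list(counts = good,        info = 0.5),
    hwe          = list(counts = bad_hwe,     info = 1.0),
    maf          = list(counts = bad_maf,     info = 1.0),
    info_hwe     = list(counts = bad_hwe,     info = 0.5),
    info_maf     = list(counts = bad_maf,     info = 0.5),
    hwe_maf      = list(counts = bad_hwe_maf, info = 1.0),
    info_hwe_maf = list(counts = bad_hwe_maf, info = 0.5))
  variants <- lapply(seq_along(combos), function(i) {
    cm <- combos[[i]]
    variant_from_counts(cm$counts[1], cm$counts[2], cm$counts[3],
                        info = cm$info, vid = names(combos)[i],
                        pos = i * 1000L)
  })
  expected_fail <- t(vapply(names(combos), function(nm) {
    c(info = grepl("info", nm), hwe = grepl("hwe", nm),
      maf = grepl("maf", nm))
  }, logical(3)))
  list(variants = variants, expected_fail = expected_fail)
}

# Eight-sample questionnaire fixture: one clean case, four samples each
# violating a single exclusion rule, three non-reporters.
t2d_rule_fixture <- function() {
  data.frame(
    sample_id = sprintf("S%d", 1:8),
    t2d_self_report = c("type2", "generic", "type2", "generic", "type2",
                        "none", "none", "none"),
    age_at_diagnosis = c(50, 45, NA, 34, 50, NA, NA, NA),
    insulin_first_year = c("no", "yes", "no", "no", "no",
                           "unknown", "unknown", "unknown"),
    years_since_diagnosis = c(5, 5, 5, 5, 0.5, NA, NA, NA),
    stringsAsFactors = FALSE)
}

# Grouped-vs-individual oracle: expand class-constant data and fit OLS.
expand_and_fit_ols <- function(summary, model = "genotypic") {
  y <- rep(summary$mean, times = summary$n)
  g <- rep(0:2, times = summary$n)
  X <- if (model == "genotypic") cbind(1, g, as.numeric(g == 1))
       else cbind(1, g)
  stats::lm.fit(X, y)$coefficients
}
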