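# Variant-level QC: allele frequency, Hardy-Weinberg exact test, the
# info/HWE/MAF filter, pairwise LD and greedy independent-variant counting.

#' QC thresholds
#'
#' Exclusion is by strict inequality: a variant fails if info < `min_info`,
#' HWE p < `hwe_alpha`, or MAF < `min_maf`; values exactly at a boundary
#' pass.
#'
#' @param min_info Minimum imputation info score (default 0.9).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level
#'   (default 1e-6).
#' @param min_maf Minimum minor allele frequency (default 0.005).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_info = 0.9, hwe_alpha = 1e-6,
                          min_maf = 0.005) {
  stopifnot(min_info > 0, min_info < 1 || min_info == 1,
            hwe_alpha > 0, hwe_alpha < 1, min_maf > 0, min_maf < 1)
  structure(list(min_info = min_info, hwe_alpha = hwe_alpha,
                 min_maf = min_maf), class = "qc_thresholds")
}

#' Alternate-allele frequency of a variant
#'
#' @param variant A [variant_record()].
#' @return Mean dosage / 2, in `[0, 1]`. The MAF is `min(f, 1 - f)`.
#' @export
allele_frequency <- function(variant) {
  d <- variant$dosage[!is.na(variant$dosage)]
  if (!length(d)) stop("all samples missing for variant ", variant$vid)
  mean(d) / 2
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test on hard-call genotype counts: conditional on the
#' allele counts, the probability of every possible heterozygote count is
#' evaluated under the HWE (random-union-of-gametes) null, and the p value
#' is the sum of probabilities no greater than that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt Nonnegative genotype counts.
#' @return Exact p value in `(0, 1]`.
#' @references Wigginton JE, Cutler DJ, Abecasis GR (2005) A note on exact
#'   tests of Hardy-Weinberg equilibrium. Am J Hum Genet 76:887-893.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("negative genotype count")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped sample required")
  n_alt <- n_het + 2 * n_hom_alt
  n_ref <- 2 * n - n_alt
  rare <- min(n_alt, n_ref)
  if (rare == 0) return(1.0)
  # all heterozygote counts compatible with the allele counts
  hets <- seq(rare %% 2, rare, by = 2)
  hom_alt <- (n_alt - hets) / 2
  hom_ref <- n - hets - hom_alt
  logp <- lfactorial(n) - lfactorial(hom_ref) - lfactorial(hets) -
    lfactorial(hom_alt) + hets * log(2) +
    lfactorial(n_alt) + lfactorial(n_ref) - lfactorial(2 * n)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[hets == n_het]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Hard-call genotype counts for a variant
#'
#' @param variant A [variant_record()].
#' @return Length-3 vector (hom-ref, het, hom-alt) over non-missing
#'   samples.
#' @export
genotype_counts <- function(variant) {
  g <- hard_call(variant)
  g <- g[!is.na(g)]
  c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
}

#' Apply variant QC filters
#'
#' A variant passes if info >= `min_info`, HWE exact p >= `hwe_alpha` and
#' MAF >= `min_maf` (see [qc_thresholds()] for the boundary convention).
#' All failed criteria are recorded, not just the first.
#'
#' @param variants List of [variant_record()]s.
#' @param thresholds A [qc_thresholds()].
#' @return List with `passing` (the surviving [variant_record()]s) and
#'   `reasons`, a data.frame with one row per input variant: `vid`,
#'   logical `fail_info` / `fail_hwe` / `fail_maf`, `pass`, and a
#'   comma-separated `reason` string (empty when passing).
#' @export
apply_filters <- function(variants, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!length(variants)) {
    return(list(passing = list(),
                reasons = data.frame(vid = character(), fail_info = logical(),
                                     fail_hwe = logical(), fail_maf = logical(),
                                     pass = logical(), reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  rows <- lapply(variants, function(v) {
    f <- allele_frequency(v)
    maf <- min(f, 1 - f)
    hwe_p <- do.call(hwe_exact_test, as.list(genotype_counts(v)))
    data.frame(vid = v$vid,
               fail_info = v$info < thresholds$min_info,
               fail_hwe = hwe_p < thresholds$hwe_alpha,
               fail_maf = maf < thresholds$min_maf,
               stringsAsFactors = FALSE)
  })
  reasons <- do.call(rbind, rows)
  reasons$pass <- !(reasons$fail_info | reasons$fail_hwe | reasons$fail_maf)
  reasons$reason <- apply(reasons[c("fail_info", "fail_hwe", "fail_maf")], 1,
                          function(r) paste(c("info", "hwe", "maf")[r],
                                            collapse = ","))
  list(passing = variants[reasons$pass], reasons = reasons)
}

#' Pairwise linkage disequilibrium between two variants
#'
#' `r2` is the squared Pearson correlation of dosages. `d_prime` is the
#' normalised composite disequilibrium coefficient estimated from hard
#' calls without phase: D is the composite covariance of allele counts / 2,
#' normalised by its bound given the allele frequencies.
#'
#' @param a,b [variant_record()]s over the same samples.
#' @return List with `r2` and `d_prime`, both in `[0, 1]`.
#' @export
pairwise_r2 <- function(a, b) {
  da <- a$dosage; db <- b$dosage
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]
  if (length(da) != length(db) || !length(da))
    stop("variants must share a sample set")
  if (stats::var(da) == 0 || stats::var(db) == 0)
    stop("monomorphic variant in LD computation")
  r2 <- stats::cor(da, db)^2
  ga <- hard_call(a)[ok]; gb <- hard_call(b)[ok]
  pa <- mean(ga) / 2; pb <- mean(gb) / 2
  D <- mean(ga * gb) / 2 - 2 * pa * pb  # composite D (Burrows) / 2
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  d_prime <- if (dmax <= 0) 0 else min(1, abs(D) / dmax)
  list(r2 = r2, d_prime = d_prime)
}

#' Count variants estimated as independent by greedy LD pruning
#'
#' Variants are visited in position order; each is retained unless its
#' dosage r^2 with an already-retained variant within the sliding window
#' exceeds `r2_threshold` (ties keep the earlier variant).
#'
#' @param variants List of [variant_record()]s.
#' @param r2_threshold r^2 above which a variant is considered redundant
#'   (default 0.9).
#' @param window_variants,window_bp Window extent: comparisons are limited
#'   to the last `window_variants` retained variants within `window_bp`
#'   base pairs on the same chromosome.
#' @return Number of retained (independent) variants.
#' @export
count_independent <- function(variants, r2_threshold = 0.9,
                              window_variants = 1000L, window_bp = 1e6) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (!length(variants)) return(0L)
  ord <- order(vapply(variants, `[[`, "", "chrom"),
               vapply(variants, `[[`, 1L, "pos"))
  kept <- list()
  n_kept <- 0L
  for (i in ord) {
    v <- variants[[i]]
    indep <- TRUE
    j <- n_kept
    while (j >= 1 && n_kept - j < window_variants) {
      u <- kept[[j]]
      if (u$chrom != v$chrom || v$pos - u$pos > window_bp) break
      if (stats::var(u$dosage) > 0 && stats::var(v$dosage) > 0 &&
          stats::cor(u$dosage, v$dosage)^2 > r2_threshold) {
        indep <- FALSE
        break
      }
      j <- j - 1L
    }
    if (indep) {
      n_kept <- n_kept + 1L
      kept[[n_kept]] <- v
    }
  }
  n_kept
}
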