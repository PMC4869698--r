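# Fixed-effects meta-analysis, significance-threshold derivation,
# and power / variance-explained calculations.

#' Standard error from a 95% confidence interval
#'
#' @param ci_low,ci_high CI bounds, `ci_high > ci_low`.
#' @return `(ci_high - ci_low) / (2 * 1.959964)`.
#' @export
se_from_ci <- function(ci_low, ci_high) {
  if (ci_high <= ci_low) stop("inverted confidence interval")
  (ci_high - ci_low) / (2 * stats::qnorm(0.975))
}

#' One study for meta-analysis
#'
#' The standard error is recovered with precedence: explicit `se`, then
#' CI-derived via [se_from_ci()], then p-derived as `|beta| / z(p)` with
#' z the two-sided normal quantile.
#'
#' @param label Study name.
#' @param beta Effect estimate (consistent scale across studies).
#' @param se Standard error (optional).
#' @param ci Length-2 95% CI (optional).
#' @param p Two-sided p value (optional).
#' @param n Sample size.
#' @return A `meta_study` object with a resolved `se`.
#' @export
meta_study <- function(label, beta, se = NULL, ci = NULL, p = NULL, n) {
  if (is.null(se) || is.na(se)) {
    if (!is.null(ci) && !anyNA(ci)) {
      se <- se_from_ci(ci[1], ci[2])
    } else if (!is.null(p) && !is.na(p)) {
      z <- stats::qnorm(p / 2, lower.tail = FALSE)
      if (!is.finite(z) || z <= 0) stop("cannot recover SE from p = ", p)
      se <- abs(beta) / z
    } else {
      stop("study '", label, "': one of se, ci, p is required")
    }
  }
  stopifnot(se > 0, n > 0)
  structure(list(label = label, beta = beta, se = se, n = n),
            class = "meta_study")
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Weights w_i = 1 / SE_i^2; combined beta = sum(w b) / sum(w),
#' SE = 1 / sqrt(sum(w)), two-sided p from the standard normal.
#'
#' @param studies List of [meta_study()] objects (>= 2).
#' @return List with `beta`, `se`, `z`, `p`, `n_total`, `n_studies`.
#' @export
fixed_effects_meta <- function(studies) {
  stopifnot(length(studies) >= 2)
  for (s in studies) stopifnot(inherits(s, "meta_study"))
  b <- vapply(studies, `[[`, 0, "beta")
  se <- vapply(studies, `[[`, 0, "se")
  n <- vapply(studies, `[[`, 0, "n")
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  se_c <- 1 / sqrt(sum(w))
  z <- beta / se_c
  list(beta = beta, se = se_c, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       n_total = sum(n), n_studies = length(studies))
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha_total Family-wise level (e.g. 0.05).
#' @param n_tests Number of (effective) tests, >= 1.
#' @return List with `threshold` (= alpha_total / n_tests) and `rendered`,
#'   a one-significant-figure string like `"3 x 10^-9"`
#'   (round-half-away-from-zero on the mantissa).
#' @export
bonferroni_threshold <- function(alpha_total, n_tests) {
  stopifnot(alpha_total > 0, alpha_total <= 1)
  if (n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha_total / n_tests
  list(threshold = thr, rendered = render_sigfig1(thr))
}

#' Render a positive number at one significant figure
#'
#' Round-half-away-from-zero on the mantissa, scientific form:
#' 6.94e-4 -> `"7 x 10^-4"`, 7.58e-4 -> `"8 x 10^-4"`.
#'
#' @param x Positive number.
#' @return Character scalar.
#' @export
render_sigfig1 <- function(x) {
  stopifnot(x > 0)
  e <- floor(log10(x))
  m <- x / 10^e
  m <- floor(m + 0.5)  # half away from zero (x > 0)
  if (m == 10) { m <- 1; e <- e + 1 }
  sprintf("%d x 10^%d", m, e)
}

#' Power of a 1-df chi-square test
#'
#' Non-centrality NCP = n * r2 (sample size times fraction of trait
#' variance explained); power is the probability that a non-central
#' chi-square (1 df, NCP) exceeds the central 1-df quantile at 1 - alpha.
#'
#' @param n Sample size.
#' @param r2 Fraction of phenotypic variance explained, in (0, 1).
#' @param alpha Significance level, in (0, 1].
#' @return Power in (0, 1].
#' @export
power_1df <- function(n, r2, alpha) {
  stopifnot(n > 0, r2 >= 0, r2 < 1, alpha > 0, alpha <= 1)
  if (alpha == 1) return(1)
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(crit, df = 1, ncp = n * r2, lower.tail = FALSE)
}

#' Variance explained by a purely recessive effect
#'
#' The recessive indicator (homozygous carrier of an allele at frequency
#' q) has variance q^2 (1 - q^2); a mean shift of `effect` trait units in
#' that group explains `effect^2 q^2 (1 - q^2) / trait_sd^2` of the
#' phenotypic variance.
#'
#' @param effect Recessive mean shift in trait units (e.g. kg/m^2).
#' @param allele_freq Frequency q of the recessive allele, in (0, 1).
#' @param trait_sd Phenotypic SD in the same units.
#' @return Percent of phenotypic variance explained.
#' @export
recessive_variance_explained <- function(effect, allele_freq, trait_sd) {
  stopifnot(allele_freq > 0, allele_freq < 1)
  if (trait_sd <= 0) stop("trait SD must be positive")
  q2 <- allele_freq^2
  100 * effect^2 * q2 * (1 - q2) / trait_sd^2
}

#' Effective sample size of a case-control study
#'
#' The quantitative-trait-equivalent n: `4 / (1/n_cases + 1/n_controls)`.
#'
#' @param n_cases,n_controls Positive counts.
#' @return Effective sample size.
#' @export
effective_n_case_control <- function(n_cases, n_controls) {
  if (n_cases <= 0 || n_controls <= 0) stop("counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}
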