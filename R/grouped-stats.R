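# Grouped statistics: model fits, odds ratios and derived quantities
# computed from printed genotype-class summary tables alone, with no
# individual-level data.

#' Genotype-class summary triplets
#'
#' @param n Counts per class (hom-ref, het, hom-alt).
#' @param mean Class means (e.g. kg/m^2).
#' @param sd Class SDs.
#' @return A `class_summary` object.
#' @export
class_summary <- function(n, mean, sd) {
  stopifnot(length(n) == 3, length(mean) == 3, length(sd) == 3,
            all(n[!is.na(mean)] > 0), all(sd >= 0, na.rm = TRUE))
  structure(list(n = as.numeric(n), mean = as.numeric(mean),
                 sd = as.numeric(sd)), class = "class_summary")
}

#' Fit genetic models to genotype-class summaries
#'
#' Weighted least squares of the class means on the genotype coding with
#' weights equal to the class counts — exactly equivalent to
#' individual-level OLS on data that are constant within class. The
#' genotypic (additive + heterozygote-deviation) fit is saturated, so
#' `b0 = m0`, `beta_add = (m2 - m0) / 2`,
#' `beta_domdev = m1 - (m0 + m2) / 2`. Sums of squares use
#' within-SS = sum((n_g - 1) sd_g^2) and total-SS = within + between.
#'
#' @param summary A [class_summary()] with all three classes present.
#' @param model `"genotypic"` or `"additive"`.
#' @return List with `b0`, `beta_add`, (`beta_domdev`,) `ss_model`
#'   (between-class SS explained), `ss_within`, `ss_total` and `r2`.
#' @export
fit_from_class_summaries <- function(summary,
                                     model = c("genotypic", "additive")) {
  model <- match.arg(model)
  stopifnot(inherits(summary, "class_summary"))
  n <- summary$n; m <- summary$mean; s <- summary$sd
  if (any(n == 0) || any(is.na(m))) stop("all three classes required")
  N <- sum(n)
  gm <- sum(n * m) / N
  within <- sum((n - 1) * s^2)
  between <- sum(n * (m - gm)^2)
  total <- within + between
  x <- c(0, 1, 2)
  if (model == "genotypic") {
    b0 <- m[1]
    beta_add <- (m[3] - m[1]) / 2
    beta_domdev <- m[2] - (m[1] + m[3]) / 2
    fitted <- m  # saturated
    ss_model <- sum(n * (fitted - gm)^2)
    out <- list(b0 = b0, beta_add = beta_add, beta_domdev = beta_domdev)
  } else {
    xbar <- sum(n * x) / N
    slope <- sum(n * (x - xbar) * (m - gm)) / sum(n * (x - xbar)^2)
    b0 <- gm - slope * xbar
    fitted <- b0 + slope * x
    ss_model <- sum(n * (fitted - gm)^2)
    out <- list(b0 = b0, beta_add = slope)
  }
  c(out, list(ss_model = ss_model, ss_within = within, ss_total = total,
              r2 = ss_model / total))
}

#' Additional variance explained by the genotypic over the additive model
#'
#' R^2(genotypic) - R^2(additive), both against the same total SS,
#' returned in percent.
#'
#' @param summary A [class_summary()].
#' @return Percent of trait variance.
#' @export
variance_increment <- function(summary) {
  g <- fit_from_class_summaries(summary, "genotypic")
  a <- fit_from_class_summaries(summary, "additive")
  if (g$ss_total <= 0) stop("degenerate total sum of squares")
  100 * (g$r2 - a$r2)
}

#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' OR = ad / bc with log-scale SE sqrt(1/a + 1/b + 1/c + 1/d) and 95% CI
#' exp(log OR +/- 1.96 SE). A zero cell triggers the Haldane-Anscombe
#' 0.5 continuity correction on all cells, with `corrected = TRUE`.
#'
#' @param a,b,c,d Exposed cases, unexposed cases, exposed controls,
#'   unexposed controls.
#' @return List with `or`, `ci_low`, `ci_high`, `log_se`, `corrected`.
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  log_se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  list(or = or,
       ci_low = exp(log(or) - z * log_se),
       ci_high = exp(log(or) + z * log_se),
       log_se = log_se, corrected = corrected)
}

#' Homozygote OR expected under a per-allele multiplicative model
#'
#' Under log-additivity the homozygote OR is the square of the
#' heterozygote OR.
#'
#' @param or_het Heterozygote (one risk allele vs none) odds ratio.
#' @return `or_het^2`.
#' @export
expected_hom_or_under_additive <- function(or_het) {
  if (or_het <= 0) stop("odds ratio must be positive")
  or_het^2
}

#' Heterozygote OR expected under a per-allele multiplicative model
#'
#' @param or_hom Homozygote (two risk alleles vs none) odds ratio.
#' @return `sqrt(or_hom)`.
#' @export
expected_het_or_under_additive <- function(or_hom) {
  if (or_hom <= 0) stop("odds ratio must be positive")
  sqrt(or_hom)
}

#' Convert a BMI difference to a weight difference
#'
#' @param delta_bmi BMI difference in kg/m^2.
#' @param height Height in metres.
#' @return Weight difference in kg: `delta_bmi * height^2`.
#' @export
bmi_diff_to_kg <- function(delta_bmi, height) {
  if (height <= 0) stop("height must be positive")
  delta_bmi * height^2
}

#' Pooled trait SD from genotype-class summaries
#'
#' sqrt(total SS / (N - 1)) with total SS = within + between.
#'
#' @param summary A [class_summary()].
#' @return Pooled SD in trait units.
#' @export
pooled_sd <- function(summary) {
  f <- fit_from_class_summaries(summary, "genotypic")
  sqrt(f$ss_total / (sum(summary$n) - 1))
}
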