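# Phenotype preparation: reconciling the two BMI measures, covariate
# residualisation, rank inverse-normal transform, and case/control
# definitions for obesity, severe obesity and type 2 diabetes.

#' Resolve a single BMI value per sample from two measures
#'
#' Where both the standard (weight/height^2) and impedance BMI are present
#' the standard measure is used, but the sample is excluded if the absolute
#' difference between the two exceeds `k_sd` times the SD of the difference
#' vector. The SD is computed once, over all samples with both measures,
#' before any exclusion (no re-computation after removal). Where only one
#' measure is available it is used as-is; samples with neither are dropped
#' with a reason code.
#'
#' @param cohort Cohort data.frame with `bmi_standard` and/or
#'   `bmi_impedance` columns.
#' @param k_sd Discordance multiple (default 4.56).
#' @return List with `bmi` (numeric, NA where excluded/missing),
#'   `excluded` (logical) and `reason` (`""`, `"bmi_discordant"` or
#'   `"bmi_missing"`).
#' @export
resolve_bmi <- function(cohort, k_sd = 4.56) {
  std <- if ("bmi_standard" %in% names(cohort)) cohort$bmi_standard
         else rep(NA_real_, nrow(cohort))
  imp <- if ("bmi_impedance" %in% names(cohort)) cohort$bmi_impedance
         else rep(NA_real_, nrow(cohort))
  if (all(is.na(std)) && all(is.na(imp)))
    stop("cohort has no BMI measure")
  both <- !is.na(std) & !is.na(imp)
  reason <- rep("", nrow(cohort))
  bmi <- ifelse(is.na(std), imp, std)
  if (any(both)) {
    diffs <- imp[both] - std[both]
    s <- stats::sd(diffs)
    if (is.finite(s) && s > 0) {
      disc <- both
      disc[both] <- abs(diffs) > k_sd * s
      bmi[disc] <- NA_real_
      reason[disc] <- "bmi_discordant"
    }
  }
  none <- is.na(std) & is.na(imp)
  reason[none] <- "bmi_missing"
  list(bmi = bmi, excluded = reason != "", reason = reason)
}

#' Residualise a trait on covariates
#'
#' Ordinary least squares of `values` on an intercept plus the covariate
#' columns; character/factor columns are expanded to treatment-coded
#' indicators. Rows with missing values keep `NA` residuals.
#'
#' @param values Numeric trait vector.
#' @param covariates data.frame of covariates (numeric or categorical);
#'   `NULL` or zero columns residualises on the intercept only.
#' @return Residual vector, same length and order as `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1)
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    X <- stats::model.matrix(~ ., data = covariates,
                             na.action = stats::na.pass)
    # model.matrix with na.pass keeps rows; rebuild to guarantee alignment
    if (nrow(X) != n) stop("covariate expansion dropped rows")
  }
  ok <- !is.na(values) & stats::complete.cases(X)
  fit <- stats::lm.fit(X[ok, , drop = FALSE], values[ok])
  if (fit$rank < ncol(X)) stop("rank-deficient covariate design")
  out <- rep(NA_real_, n)
  out[ok] <- fit$residuals
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps the value with rank r among n non-missing values to the standard
#' normal quantile of `(r - c) / (n - 2c + 1)`; ties receive average ranks
#' (deterministic). The default offset `c = 3/8` is Blom's.
#'
#' @param values Numeric vector (NAs propagate).
#' @param offset Rank offset c in `[0, 0.5]`.
#' @return Vector in SD units; mean ~ 0, SD ~ 1 for large n.
#' @export
inverse_normalize <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2) stop("need at least 2 distinct values")
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Obesity and severe-obesity case/control labels
#'
#' Case if BMI > 30 (obese) or > 40 (severely obese); control for both if
#' BMI < 25; the intermediate band is excluded (neither case nor control).
#' Boundaries are strict, so BMI exactly 30 is excluded and exactly 25 is
#' excluded.
#'
#' @param bmi Resolved BMI vector (NA allowed).
#' @return data.frame with factor columns `obese` and `severely_obese`,
#'   levels `case` / `control` / `excluded`.
#' @export
classify_obesity <- function(bmi) {
  lab <- function(case_thr) {
    out <- rep("excluded", length(bmi))
    out[!is.na(bmi) & bmi > case_thr] <- "case"
    out[!is.na(bmi) & bmi < 25] <- "control"
    factor(out, levels = c("case", "control", "excluded"))
  }
  data.frame(obese = lab(30), severely_obese = lab(40))
}

#' Type 2 diabetes case/control labels from questionnaire fields
#'
#' Case: self-reported type 2 or generic diabetes, no insulin within the
#' first year of diagnosis, known age at diagnosis of at least 35 years,
#' and diagnosis more than `study_end_window_years` before data
#' extraction. Reporters failing any of those rules are excluded, as are
#' self-reported type 1 diabetics; all non-reporters are controls.
#'
#' @param cohort Cohort data.frame with `t2d_self_report`
#'   (none/generic/type2/type1), `age_at_diagnosis`, `insulin_first_year`
#'   (yes/no/unknown) and `years_since_diagnosis`.
#' @param study_end_window_years Recency exclusion window (default 1).
#' @return List with `t2d` (factor case/control/excluded) and `reason`
#'   (character code per sample, `""` unless excluded).
#' @export
classify_t2d <- function(cohort, study_end_window_years = 1) {
  need <- c("t2d_self_report", "age_at_diagnosis", "insulin_first_year",
            "years_since_diagnosis")
  stopifnot(all(need %in% names(cohort)))
  self <- cohort$t2d_self_report
  reports <- self %in% c("type2", "generic")
  lab <- rep("control", nrow(cohort))
  reason <- rep("", nrow(cohort))

  excl <- function(cond, code) {
    hit <- reports & cond & lab != "excluded"
    lab[hit] <<- "excluded"
    reason[hit] <<- code
  }
  excl(!is.na(cohort$insulin_first_year) &
         cohort$insulin_first_year == "yes", "insulin_first_year")
  excl(is.na(cohort$age_at_diagnosis), "unknown_age_at_diagnosis")
  excl(!is.na(cohort$age_at_diagnosis) & cohort$age_at_diagnosis < 35,
       "diagnosed_under_35")
  excl(is.na(cohort$years_since_diagnosis) |
         cohort$years_since_diagnosis <= study_end_window_years,
       "recent_diagnosis")
  lab[reports & lab == "control"] <- "case"
  t1 <- self == "type1"
  lab[t1] <- "excluded"
  reason[t1] <- "type1_self_report"
  list(t2d = factor(lab, levels = c("case", "control", "excluded")),
       reason = reason)
}

#' Prepare all analysis phenotypes from a cohort table
#'
#' Runs [resolve_bmi()], residualises resolved BMI on age, sex, centre and
#' pc1..pc5, inverse-normalises the residuals, and attaches obesity and
#' type 2 diabetes labels.
#'
#' @param cohort Cohort data.frame as produced by [simulate_phenotypes()]
#'   or [read_cohort_table()].
#' @param bmi_k_sd Discordance multiple for [resolve_bmi()].
#' @param study_end_window_years Passed to [classify_t2d()].
#' @return data.frame keyed by `sample_id` with `bmi_raw`, `bmi_invnorm`,
#'   `obese`, `severely_obese`, `t2d` and `exclusion_reason`.
#' @export
prepare_phenotypes <- function(cohort, bmi_k_sd = 4.56,
                               study_end_window_years = 1) {
  res <- resolve_bmi(cohort, k_sd = bmi_k_sd)
  covs <- cohort[intersect(c("age", "sex", "centre",
                             paste0("pc", 1:5)), names(cohort))]
  resid <- rep(NA_real_, nrow(cohort))
  ok <- !is.na(res$bmi)
  if (any(ok))
    resid[ok] <- residualize(res$bmi[ok], covs[ok, , drop = FALSE])
  invn <- rep(NA_real_, nrow(cohort))
  if (sum(!is.na(resid)) >= 2) invn <- inverse_normalize(resid)
  ob <- classify_obesity(res$bmi)
  t2 <- classify_t2d(cohort, study_end_window_years)
  data.frame(sample_id = cohort$sample_id,
             bmi_raw = res$bmi, bmi_invnorm = invn,
             obese = ob$obese, severely_obese = ob$severely_obese,
             t2d = t2$t2d,
             exclusion_reason = ifelse(res$reason != "", res$reason,
                                       t2$reason),
             stringsAsFactors = FALSE)
}
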