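# Synthetic cohort generation: imputed genotypes under HWE with a tunable
# info score, and phenotypes (two BMI measures, covariates, T2D
# questionnaire fields) with planted additive + dominance-deviation effects.

#' Simulation configuration
#'
#' Collects every generative knob for the synthetic cohort. The same config
#' (including `seed`) always produces byte-identical output; per-stage
#' substreams are derived from the single global seed so genotype and
#' phenotype generation are individually reproducible.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of independent variants.
#' @param maf_range Length-2 numeric, allele-frequency range in (0, 0.5].
#'   Each variant's frequency is drawn uniformly from this range.
#' @param info_range Length-2 numeric in (0, 1], target imputation info
#'   score range; 1 means hard calls with no imputation noise.
#' @param seed Integer seed fully determining the output.
#' @param effect_spec List of [planted_effect()] entries.
#' @param bmi_base_mean,bmi_base_sd Baseline BMI mean and SD (kg/m^2).
#' @param skew Nonnegative log-SD of the exponentiated-normal residual;
#'   0 gives Gaussian noise, larger values give heavier right skew.
#' @param discordance_rate Probability that a sample's impedance BMI
#'   carries a gross (> 5 SD) offset relative to the standard measure.
#' @param t2d_base_rate Approximate marginal type 2 diabetes prevalence.
#' @param t2d_type1_frac,t2d_insulin_frac,t2d_young_dx_frac,
#'   t2d_recent_dx_frac,t2d_unknown_age_frac Fractions of diabetes
#'   reporters violating, respectively, each downstream exclusion rule
#'   (type 1 self-report, insulin in first year, diagnosis under 35,
#'   diagnosis within the last year, unknown age at diagnosis).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 120286L, n_variants = 100L,
                       maf_range = c(0.01, 0.5), info_range = c(0.9, 1.0),
                       seed = 1L, effect_spec = list(),
                       bmi_base_mean = 27.5, bmi_base_sd = 4.8,
                       skew = 0.17, discordance_rate = 0.001,
                       t2d_base_rate = 0.035,
                       t2d_type1_frac = 0.05, t2d_insulin_frac = 0.05,
                       t2d_young_dx_frac = 0.05, t2d_recent_dx_frac = 0.05,
                       t2d_unknown_age_frac = 0.05) {
  num <- c(n_samples = n_samples, n_variants = n_variants,
           maf_range, info_range, seed = seed,
           bmi_base_mean = bmi_base_mean, bmi_base_sd = bmi_base_sd,
           skew = skew, discordance_rate = discordance_rate,
           t2d_base_rate = t2d_base_rate,
           t2d_type1_frac, t2d_insulin_frac, t2d_young_dx_frac,
           t2d_recent_dx_frac, t2d_unknown_age_frac)
  if (any(!is.finite(num))) stop("non-finite value in sim_config")
  stopifnot(n_samples >= 1, n_variants >= 0,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            length(info_range) == 2, info_range[1] <= info_range[2],
            info_range[1] > 0, info_range[2] <= 1,
            skew >= 0, discordance_rate >= 0, discordance_rate <= 1,
            bmi_base_sd > 0)
  for (ef in effect_spec) {
    stopifnot(inherits(ef, "planted_effect"))
    if (ef$variant_index > n_variants)
      stop("planted effect variant_index exceeds n_variants")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, info_range = info_range,
                 seed = as.integer(seed), effect_spec = effect_spec,
                 bmi_base_mean = bmi_base_mean, bmi_base_sd = bmi_base_sd,
                 skew = skew, discordance_rate = discordance_rate,
                 t2d_base_rate = t2d_base_rate,
                 t2d_type1_frac = t2d_type1_frac,
                 t2d_insulin_frac = t2d_insulin_frac,
                 t2d_young_dx_frac = t2d_young_dx_frac,
                 t2d_recent_dx_frac = t2d_recent_dx_frac,
                 t2d_unknown_age_frac = t2d_unknown_age_frac),
            class = "sim_config")
}

#' Planted genetic effect
#'
#' Effect sizes are in trait-SD units per the regression
#' `y = b0 + beta_add * g + beta_domdev * h + e` with g the 0/1/2 allele
#' count and h the 0/1/0 heterozygote indicator. A pure recessive shift of
#' `delta` trait SDs corresponds to `beta_add = delta / 2`,
#' `beta_domdev = -delta / 2`.
#'
#' @param variant_index 1-based index into the simulated variant list.
#' @param beta_add Additive effect per allele (trait-SD units, or log-odds
#'   for the liability trait).
#' @param beta_domdev Heterozygote deviation (same units).
#' @param trait `"bmi"` or `"t2d_liability"`.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(variant_index, beta_add = 0, beta_domdev = 0,
                           trait = c("bmi", "t2d_liability")) {
  trait <- match.arg(trait)
  stopifnot(variant_index >= 1, is.finite(beta_add), is.finite(beta_domdev))
  structure(list(variant_index = as.integer(variant_index),
                 beta_add = beta_add, beta_domdev = beta_domdev,
                 trait = trait),
            class = "planted_effect")
}

# Derive a per-stage substream seed (< 2^31) from the global seed.
stage_seed <- function(seed, stage) {
  off <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

#' Construct a variant record
#'
#' @param chrom,pos,vid,ref_allele,alt_allele Identifiers; `pos` is 1-based.
#' @param genotype_probs n x 3 matrix of per-sample genotype probabilities
#'   (hom-ref, het, hom-alt), rows summing to 1. Rows of `NA` mark missing
#'   samples.
#' @param info Imputation info score in `[0, 1]`; if `NULL`, the realised
#'   statistic var(dosage) / (2 p q) is computed from the dosages.
#' @param effect_allele Which allele the dosage counts (default alt).
#' @return An object of class `variant_record` with a `dosage` field equal
#'   to `P(het) + 2 P(hom-alt)` per sample.
#' @export
variant_record <- function(chrom, pos, vid, ref_allele, alt_allele,
                           genotype_probs, info = NULL,
                           effect_allele = alt_allele) {
  genotype_probs <- as.matrix(genotype_probs)
  stopifnot(ncol(genotype_probs) == 3)
  ok <- stats::complete.cases(genotype_probs)
  if (any(ok)) {
    p <- genotype_probs[ok, , drop = FALSE]
    if (any(p < -1e-12) || any(abs(rowSums(p) - 1) > 1e-9))
      stop("genotype probabilities must be nonnegative and sum to 1")
  }
  dosage <- genotype_probs[, 2] + 2 * genotype_probs[, 3]
  if (is.null(info)) info <- realised_info(dosage)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 vid = as.character(vid),
                 ref_allele = as.character(ref_allele),
                 alt_allele = as.character(alt_allele),
                 effect_allele = as.character(effect_allele),
                 info = as.numeric(info),
                 genotype_probs = genotype_probs, dosage = dosage),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s %s:%d %s/%s info=%.3f n=%d\n",
              x$vid, x$chrom, x$pos, x$ref_allele, x$alt_allele,
              x$info, length(x$dosage)))
  invisible(x)
}

# Realised info statistic: dosage variance over the 2pq expected under HWE
# at the dosage-implied allele frequency.
realised_info <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (!length(d)) return(NA_real_)
  f <- mean(d) / 2
  denom <- 2 * f * (1 - f)
  if (denom <= 0) return(NA_real_)
  min(1, stats::var(d) * (length(d) - 1) / length(d) / denom)
}

#' Simulate imputed genotypes
#'
#' For each variant an allele frequency is drawn uniformly from
#' `maf_range` and hard genotypes are drawn from the Hardy-Weinberg
#' proportions p^2, 2pq, q^2. Imputation uncertainty with target info
#' score `s` is introduced by mixing each sample's one-hot genotype vector
#' with the population HWE vector using weight `w = 1 - sqrt(s)`:
#' this scales the dosage SD by `sqrt(s)` about an unchanged mean, so the
#' realised info statistic var(dosage)/2pq approximates `s` and equals 1
#' (dosage == hard call) when `s = 1`.
#'
#' @param config A [sim_config()].
#' @return List of [variant_record()] objects, one per variant.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_samples
  lapply(seq_len(config$n_variants), function(i) {
    f <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    s <- stats::runif(1, config$info_range[1], config$info_range[2])
    hwe <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    g <- sample.int(3, n, replace = TRUE, prob = hwe) - 1L
    onehot <- matrix(0, n, 3)
    onehot[cbind(seq_len(n), g + 1L)] <- 1
    w <- 1 - sqrt(s)
    probs <- (1 - w) * onehot +
      w * matrix(hwe, n, 3, byrow = TRUE)
    # at target 1 the dosage IS the hard call: info is exactly 1 by
    # construction; otherwise report the realised statistic
    variant_record(chrom = "1", pos = i * 10000L,
                   vid = sprintf("sim%d", i),
                   ref_allele = "A", alt_allele = "G",
                   genotype_probs = probs,
                   info = if (w == 0) 1.0 else NULL)
  })
}

# Zero-mean, unit-SD exponentiated-normal deviate; skew > 0 gives right
# skew, skew == 0 degenerates to the standard normal.
skewed_residual <- function(n, skew) {
  z <- stats::rnorm(n)
  if (skew <= 0) return(z)
  m <- exp(skew^2 / 2)
  (exp(skew * z) - m) / sqrt((exp(skew^2) - 1) * exp(skew^2))
}

#' Simulate phenotypes and covariates for a genotyped cohort
#'
#' BMI is built as `bmi_base_mean` + mild age and sex effects + planted
#' genetic effects (in units of `bmi_base_sd`) + right-skewed residual
#' noise of SD `bmi_base_sd`. The impedance BMI repeats the standard
#' measure plus small noise, except that with probability
#' `discordance_rate` a gross offset (well beyond 5 SD of the difference
#' distribution) is added, emulating occasional instrument failures.
#' Type 2 diabetes status is drawn from a logistic model on age, sex and
#' planted liability effects; questionnaire fields are then populated so
#' that configured fractions of reporters violate each downstream
#' exclusion rule.
#'
#' @param config A [sim_config()].
#' @param variants List of [variant_record()]s from [simulate_genotypes()].
#' @return A `data.frame` (the cohort table) with one row per sample:
#'   `sample_id`, `bmi_standard`, `bmi_impedance`, `age`, `sex`, `centre`,
#'   `chip`, `pc1`..`pc5`, `t2d_self_report`, `age_at_diagnosis`,
#'   `insulin_first_year`, `years_since_diagnosis`.
#' @export
simulate_phenotypes <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  for (ef in config$effect_spec)
    if (ef$variant_index > length(variants))
      stop("planted effect variant_index exceeds variant list")
  set.seed(stage_seed(config$seed, "phenotypes"))
  n <- config$n_samples

  age <- round(stats::runif(n, 40, 70), 1)
  sex <- stats::rbinom(n, 1, 0.5)
  centre <- sample(paste0("centre", 1:6), n, replace = TRUE)
  chip <- sample(c("chipA", "chipB"), n, replace = TRUE, prob = c(0.4, 0.6))
  pcs <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))

  gen_bmi <- numeric(n)
  gen_liab <- numeric(n)
  for (ef in config$effect_spec) {
    v <- variants[[ef$variant_index]]
    g <- hard_call(v)
    h <- as.numeric(g == 1L)
    contrib <- ef$beta_add * g + ef$beta_domdev * h
    if (ef$trait == "bmi") gen_bmi <- gen_bmi + contrib
    else gen_liab <- gen_liab + contrib
  }

  bmi <- config$bmi_base_mean +
    0.02 * (age - 55) + 0.4 * sex +
    gen_bmi * config$bmi_base_sd +
    skewed_residual(n, config$skew) * config$bmi_base_sd

  imp_noise_sd <- 0.5
  bmi_imp <- bmi + stats::rnorm(n, 0, imp_noise_sd)
  gross <- stats::runif(n) < config$discordance_rate
  if (any(gross)) {
    k <- sum(gross)
    bmi_imp[gross] <- bmi_imp[gross] +
      sample(c(-1, 1), k, replace = TRUE) *
        stats::runif(k, 8, 12) * imp_noise_sd
  }

  # prevalence intercept: logit of base rate at the covariate centre
  lin <- log(config$t2d_base_rate / (1 - config$t2d_base_rate)) +
    0.04 * (age - 55) + 0.3 * (sex - 0.5) + gen_liab
  d <- stats::rbinom(n, 1, 1 / (1 + exp(-lin)))

  self <- rep("none", n)
  age_dx <- rep(NA_real_, n)
  insulin <- rep("unknown", n)
  yrs <- rep(NA_real_, n)
  idx <- which(d == 1L)
  if (length(idx)) {
    k <- length(idx)
    self[idx] <- ifelse(stats::runif(k) < config$t2d_type1_frac, "type1",
                        ifelse(stats::runif(k) < 0.5, "type2", "generic"))
    age_dx[idx] <- pmin(round(stats::runif(k, 36, pmax(37, age[idx] - 2))),
                        age[idx])
    young <- idx[stats::runif(k) < config$t2d_young_dx_frac]
    age_dx[young] <- round(stats::runif(length(young), 18, 34))
    unk <- idx[stats::runif(k) < config$t2d_unknown_age_frac]
    age_dx[unk] <- NA_real_
    yrs[idx] <- round(stats::runif(k, 1.5, 20), 1)
    recent <- idx[stats::runif(k) < config$t2d_recent_dx_frac]
    yrs[recent] <- round(stats::runif(length(recent), 0, 1), 2)
    insulin[idx] <- ifelse(stats::runif(k) < config$t2d_insulin_frac,
                           "yes", "no")
  }

  out <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    bmi_standard = round(bmi, 4),
    bmi_impedance = round(bmi_imp, 4),
    age = age, sex = sex, centre = centre, chip = chip,
    pcs,
    t2d_self_report = self,
    age_at_diagnosis = age_dx,
    insulin_first_year = insulin,
    years_since_diagnosis = yrs,
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$sample_id), all(out$age > 0))
  out
}
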