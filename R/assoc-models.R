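# Per-variant association models: additive, dominance-deviation
# (genotypic), recessive and dominant codings for quantitative (OLS) and
# binary (logistic) traits, plus the genome-wide scan.

#' Maximum-probability hard-call genotypes
#'
#' Per-sample argmax of the genotype probabilities, as alt-allele counts
#' 0/1/2; ties are broken toward fewer alt alleles. Missing samples stay
#' `NA`.
#'
#' @param variant A [variant_record()].
#' @return Integer vector in `{0, 1, 2, NA}`.
#' @export
hard_call <- function(variant) {
  p <- variant$genotype_probs
  g <- rep(NA_integer_, nrow(p))
  ok <- stats::complete.cases(p)
  if (any(ok)) {
    pm <- p[ok, , drop = FALSE]
    g[ok] <- max.col(pm, ties.method = "first") - 1L
  }
  g
}

#' Encode a variant's genotypes for regression
#'
#' @param variant A [variant_record()].
#' @param mode `"hardcall"` (maximum-probability genotype; ties toward
#'   fewer alt alleles) or `"dosage"` (g = expected allele count,
#'   h = P(het), the expectation of the 0/1/0 code).
#' @return List with `g` (additive code in `[0, 2]`), `h` (heterozygote
#'   code in `[0, 1]`) and `mask` (logical, usable samples).
#' @export
encode_genotype <- function(variant, mode = c("hardcall", "dosage")) {
  mode <- match.arg(mode)
  if (mode == "hardcall") {
    g <- as.numeric(hard_call(variant))
    h <- as.numeric(g == 1)
  } else {
    g <- variant$dosage
    h <- variant$genotype_probs[, 2]
  }
  list(g = g, h = h, mask = !is.na(g))
}

# Design matrix for a genetic model. coding selects the genetic columns:
# additive g; domdev/genotypic g + h; recessive 1[g == 2] (on hard calls,
# or P(hom-alt) in dosage mode not used here); dominant 1[g >= 1].
genetic_columns <- function(coding, g, h) {
  switch(coding,
         additive = cbind(g = g),
         domdev = ,
         genotypic = cbind(g = g, h = h),
         recessive = cbind(rec = as.numeric(g >= 1.5)),
         dominant = cbind(dom = as.numeric(g >= 0.5)),
         stop("unknown coding: ", coding))
}

# Build intercept + genetic + covariate design; categorical covariates
# expanded via model.matrix.
build_design <- function(gen_cols, covariates, n) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- cbind(`(Intercept)` = rep(1, n), gen_cols)
  } else {
    covariates <- as.data.frame(covariates)
    C <- stats::model.matrix(~ ., data = covariates,
                             na.action = stats::na.pass)
    X <- cbind(C[, 1, drop = FALSE], gen_cols, C[, -1, drop = FALSE])
  }
  X
}

# OLS fit with Wald p values; t reference for small n, normal otherwise.
ols_wald <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  if (r < ncol(X)) stop("rank-deficient design")
  n <- length(y)
  if (n <= ncol(X)) stop("fewer observations than parameters")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - r)
  # undo LINPACK column pivoting before inverting X'X
  piv <- fit$qr$pivot
  inv_piv <- chol2inv(qr.R(fit$qr))
  XtXinv <- matrix(NA_real_, ncol(X), ncol(X))
  XtXinv[piv, piv] <- inv_piv
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  names(se) <- colnames(X)
  beta <- fit$coefficients
  se[se == 0] <- NA_real_
  tval <- beta / se
  p <- if (n > 1000) 2 * stats::pnorm(-abs(tval))
       else 2 * stats::pt(-abs(tval), df = n - r)
  p[is.na(p)] <- 1
  beta[is.na(beta)] <- 0
  list(beta = beta, se = se, p = pmin(pmax(p, .Machine$double.xmin), 1),
       n = n, sigma2 = sigma2)
}

#' Fit a linear genetic model for a quantitative trait
#'
#' Ordinary least squares of the trait on an intercept, the genetic terms
#' selected by `coding` and any covariates, with two-sided Wald p values
#' (normal reference for n > 1000, t otherwise).
#'
#' @param y Quantitative trait vector.
#' @param coding Genotype coding from [encode_genotype()].
#' @param covariates Optional data.frame of covariates.
#' @param model `"genotypic"` (additive + heterozygote terms, the
#'   dominance-deviation model), `"additive"`, `"recessive"` or
#'   `"dominant"`.
#' @return List with named `beta`, `se`, `p` vectors (genetic terms named
#'   `g`, `h`, `rec`, `dom`), `n_used`, and `sigma2`.
#' @export
fit_linear <- function(y, coding, covariates = NULL,
                       model = c("genotypic", "additive", "recessive",
                                 "dominant")) {
  model <- match.arg(model)
  gen <- genetic_columns(model, coding$g, coding$h)
  ok <- coding$mask & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  X <- build_design(gen, covariates, length(y))
  if (stats::var(y[ok]) == 0) {
    k <- ncol(gen)
    nm <- colnames(gen)
    return(list(beta = stats::setNames(rep(0, k), nm),
                se = stats::setNames(rep(NA_real_, k), nm),
                p = stats::setNames(rep(1, k), nm),
                n_used = sum(ok), sigma2 = 0))
  }
  fit <- ols_wald(X[ok, , drop = FALSE], y[ok])
  keep <- colnames(gen)
  list(beta = fit$beta[keep], se = fit$se[keep], p = fit$p[keep],
       n_used = fit$n, sigma2 = fit$sigma2)
}

#' Fit a logistic genetic model for a binary trait
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm.fit`, convergence tolerance 1e-10, at most 50 iterations)
#' with Wald standard errors from the observed information. Complete
#' separation is detected as any |beta| > 15 or non-convergence and
#' reported through the `flagged` field rather than an error.
#'
#' @param status 0/1 (or logical / case-control factor) outcome.
#' @param coding Genotype coding from [encode_genotype()].
#' @param covariates Optional covariate data.frame.
#' @param model As in [fit_linear()].
#' @return List with `beta` (log-odds), `se`, `p`, `or` (= exp(beta)) for
#'   the genetic terms, `n_used`, `converged` and `flagged`.
#' @export
fit_logistic <- function(status, coding, covariates = NULL,
                         model = c("genotypic", "additive", "recessive",
                                   "dominant")) {
  model <- match.arg(model)
  if (is.factor(status)) status <- as.integer(status == "case")
  status <- as.numeric(status)
  gen <- genetic_columns(model, coding$g, coding$h)
  ok <- coding$mask & !is.na(status)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  if (length(unique(status[ok])) < 2)
    stop("both outcome classes must be present")
  X <- build_design(gen, covariates, length(status))[ok, , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(X, status[ok], family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 50)))
  beta <- fit$coefficients
  # observed-information covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(chol2inv(chol(XtWX)),
                  error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(beta)
  flagged <- !fit$converged || any(abs(beta) > 15, na.rm = TRUE)
  z <- beta / se
  p <- pmin(pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin), 1)
  keep <- colnames(gen)
  list(beta = beta[keep], se = se[keep], p = p[keep],
       or = exp(beta[keep]), n_used = sum(ok),
       converged = fit$converged, flagged = flagged)
}

# One variant, one quantitative or binary trait -> a flat result row.
assoc_one <- function(variant, y, covariates, trait_kind, mode) {
  coding <- encode_genotype(variant, mode)
  hc <- hard_call(variant)
  counts <- c(sum(hc == 0L, na.rm = TRUE), sum(hc == 1L, na.rm = TRUE),
              sum(hc == 2L, na.rm = TRUE))
  fitter <- if (trait_kind == "binary") fit_logistic else fit_linear
  add <- fitter(y, coding, covariates, model = "additive")
  joint <- fitter(y, coding, covariates, model = "genotypic")
  rec <- fitter(y, coding, covariates, model = "recessive")
  data.frame(vid = variant$vid, chrom = variant$chrom, pos = variant$pos,
             effect_allele = variant$effect_allele, n_used = joint$n_used,
             beta_add = unname(add$beta["g"]), se_add = unname(add$se["g"]),
             p_add = unname(add$p["g"]),
             beta_domdev = unname(joint$beta["h"]),
             se_domdev = unname(joint$se["h"]),
             p_domdev = unname(joint$p["h"]),
             beta_rec = unname(rec$beta["rec"]),
             se_rec = unname(rec$se["rec"]), p_rec = unname(rec$p["rec"]),
             n_hom_ref = counts[1], n_het = counts[2], n_hom_alt = counts[3],
             flagged = isTRUE(joint$flagged),
             stringsAsFactors = FALSE)
}

#' Genome-wide association scan
#'
#' Fits, per variant, the additive-only, genotypic (additive +
#' dominance-deviation) and recessive models. The additive p value is
#' reported from the additive-only fit; the dominance-deviation p value
#' from the joint fit.
#'
#' @param variants List of QC-passing [variant_record()]s.
#' @param y Trait vector (quantitative, or 0/1 / case-control factor for
#'   binary).
#' @param covariates Optional covariate data.frame (e.g. genotyping chip;
#'   for logistic fits also age, sex, PCs).
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @param mode Genotype mode for the regression terms (default dosage).
#' @return List with `results` (one data.frame row per variant), `qq`
#'   (sorted observed vs expected -log10 dominance-deviation p) and
#'   `lambda`, the genomic-inflation factor
#'   median(chi^2) / qchisq(0.5, 1) of the dominance-deviation tests.
#' @export
scan_assoc <- function(variants, y, covariates = NULL,
                       trait_kind = c("quantitative", "binary"),
                       mode = c("dosage", "hardcall")) {
  trait_kind <- match.arg(trait_kind)
  mode <- match.arg(mode)
  rows <- lapply(variants, assoc_one, y = y, covariates = covariates,
                 trait_kind = trait_kind, mode = mode)
  if (length(rows)) {
    results <- do.call(rbind, rows)
  } else {
    results <- data.frame(vid = character(), chrom = character(),
                          pos = integer(), effect_allele = character(),
                          n_used = integer(), beta_add = numeric(),
                          se_add = numeric(), p_add = numeric(),
                          beta_domdev = numeric(), se_domdev = numeric(),
                          p_domdev = numeric(), beta_rec = numeric(),
                          se_rec = numeric(), p_rec = numeric(),
                          n_hom_ref = integer(), n_het = integer(),
                          n_hom_alt = integer(), flagged = logical(),
                          stringsAsFactors = FALSE)
  }
  p <- results$p_domdev
  p <- p[!is.na(p)]
  if (length(p)) {
    obs <- sort(-log10(p))
    exp_ <- -log10((length(p):1 - 0.5) / length(p))
    qq <- data.frame(expected = sort(exp_), observed = obs)
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
    lambda <- stats::median(chisq) / stats::qchisq(0.5, 1)
  } else {
    qq <- data.frame(expected = numeric(), observed = numeric())
    lambda <- NA_real_
  }
  list(results = results, qq = qq, lambda = lambda)
}

#' Genotype-class summary of a trait
#'
#' Per hard-call genotype class: n, mean, SD and the 95% CI
#' mean +/- 1.96 * SD / sqrt(n). Empty classes yield NA summaries.
#'
#' @param variant A [variant_record()] (hard calls are derived from it).
#' @param y Trait vector.
#' @return A `genotype_class_summary`: data.frame with one row per class
#'   (`hom_ref`, `het`, `hom_alt`) and columns `n`, `mean`, `sd`,
#'   `ci_low`, `ci_high`.
#' @export
genotype_class_summary <- function(variant, y) {
  g <- hard_call(variant)
  rows <- lapply(0:2, function(k) {
    yy <- y[!is.na(g) & !is.na(y) & g == k]
    n <- length(yy)
    if (n == 0)
      return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    m <- mean(yy)
    s <- if (n > 1) stats::sd(yy) else 0
    half <- 1.96 * s / sqrt(n)
    data.frame(n = n, mean = m, sd = s, ci_low = m - half,
               ci_high = m + half)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- c("hom_ref", "het", "hom_alt")
  class(out) <- c("genotype_class_summary", "data.frame")
  out
}
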