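test_that("encode_genotype covers both modes, ties and missingness", {
  probs <- rbind(c(1, 0, 0), c(0.2, 0.5, 0.3), c(0.5, 0.5, 0),
                 c(NA, NA, NA))
  v <- variant_record("1", 1L, "v", "A", "G", probs)
  hc <- encode_genotype(v, "hardcall")
  ds <- encode_genotype(v, "dosage")
  expect_equal(hc$g[1:3], c(0, 1, 0))  # tie broken toward fewer alt alleles
  expect_equal(hc$h[1:3], c(0, 1, 0))
  expect_equal(ds$g[1:3], c(0, 1.1, 0.5))
  expect_equal(ds$h[1:3], c(0, 0.5, 0.5))
  expect_false(hc$mask[4])
  expect_false(ds$mask[4])
})

test_that("the genotypic fit on class-constant data is the saturated 3-class model", {
  m <- c(27.27, 27.54, 28.07)
  k <- c(42835, 57524, 19329)
  # scaled-down expansion with identical class means
  n <- round(k / 50)
  y <- rep(m, times = n)
  v <- variant_from_counts(n[1], n[2], n[3])
  coding <- encode_genotype(v, "hardcall")
  fit <- fit_linear(y, coding, model = "genotypic")
  expect_equal(unname(fit$beta["g"]), (m[3] - m[1]) / 2, tolerance = 1e-10)
  expect_equal(unname(fit$beta["h"]), m[2] - (m[1] + m[3]) / 2,
               tolerance = 1e-10)
  # coding algebra holds for arbitrary class means
  set.seed(33)
  for (i in 1:5) {
    mm <- rnorm(3, 25, 3)
    yy <- rep(mm, times = n)
    f <- fit_linear(yy, coding, model = "genotypic")
    expect_equal(unname(f$beta["g"]), (mm[3] - mm[1]) / 2, tolerance = 1e-8)
    expect_equal(unname(f$beta["h"]), mm[2] - (mm[1] + mm[3]) / 2,
                 tolerance = 1e-8)
  }
  # constant y: zero effects, p = 1
  f0 <- fit_linear(rep(5, sum(n)), coding, model = "genotypic")
  expect_equal(unname(f0$beta), c(0, 0))
  expect_equal(unname(f0$p), c(1, 1))
})

test_that("pure recessive simulations give beta_domdev ~ -beta_add", {
  set.seed(55)
  n <- 100000
  f <- 0.4
  g <- sample(0:2, n, replace = TRUE,
              prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
  delta <- 0.2
  y <- delta * (g == 2) + rnorm(n)
  v <- variant_from_genotypes(g)
  fit <- fit_linear(y, encode_genotype(v, "hardcall"), model = "genotypic")
  expect_true(fit$beta["h"] / fit$beta["g"] > -1.15 &&
                fit$beta["h"] / fit$beta["g"] < -0.85)
  # with no planted deviation, beta_domdev is within 3 SE of zero
  y0 <- 0.1 * g + rnorm(n)
  fit0 <- fit_linear(y0, encode_genotype(v, "hardcall"),
                     model = "genotypic")
  expect_lt(abs(fit0$beta["h"]), 3 * fit0$se["h"])
})

test_that("additive and domdev estimates recover planted effect sizes", {
  # 200 replicates at n = 20000 with the observed FTO effect sizes
  set.seed(66)
  n <- 20000
  f <- 0.4
  beta_add <- 0.076
  beta_domdev <- -0.025
  est <- matrix(NA_real_, 200, 2)
  for (i in 1:200) {
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    y <- beta_add * g + beta_domdev * (g == 1) + rnorm(n)
    v <- variant_from_genotypes(g)
    fit <- fit_linear(y, encode_genotype(v, "hardcall"),
                      model = "genotypic")
    est[i, ] <- unname(fit$beta[c("g", "h")])
  }
  expect_lt(abs(mean(est[, 1]) - beta_add), 0.005)
  expect_lt(abs(mean(est[, 2]) - beta_domdev), 0.005)
})

test_that("logistic fits reproduce the 2x2 odds ratio and flag separation", {
  # cases: 100 exposed, 100 unexposed; controls: 50 exposed, 200 unexposed
  exposure <- c(rep(1, 100), rep(0, 100), rep(1, 50), rep(0, 200))
  status <- c(rep(1, 200), rep(0, 250))
  coding <- list(g = exposure, h = rep(0, 450), mask = rep(TRUE, 450))
  fit <- fit_logistic(status, coding, model = "additive")
  expect_equal(unname(fit$or["g"]), 4.0, tolerance = 1e-6)
  expect_false(fit$flagged)
  # agreement with a brute-force likelihood maximisation at small n
  set.seed(77)
  g <- sample(0:2, 30, replace = TRUE)
  st <- rbinom(30, 1, plogis(-0.5 + 0.4 * g))
  if (length(unique(st)) == 1) st[1] <- 1 - st[1]
  fit_small <- fit_logistic(st, list(g = as.numeric(g), h = rep(0, 30),
                                     mask = rep(TRUE, 30)),
                            model = "additive")
  nll <- function(b) -sum(st * (b[1] + b[2] * g) -
                            log1p(exp(b[1] + b[2] * g)))
  oracle <- optim(c(0, 0), nll, method = "BFGS")$par
  expect_equal(unname(fit_small$beta["g"]), oracle[2], tolerance = 1e-4)
  # complete separation: flagged, not an error
  sep_status <- as.numeric(g == 2)
  fit_sep <- fit_logistic(sep_status,
                          list(g = as.numeric(g == 2), h = rep(0, 30),
                               mask = rep(TRUE, 30)), model = "additive")
  expect_true(fit_sep$flagged)
})

test_that("domdev type-I error is nominal for the logistic model", {
  # 200 null variants at n = 50000 binary outcome
  set.seed(88)
  n <- 50000
  status <- rbinom(n, 1, 0.1)
  hits <- 0L
  for (i in 1:200) {
    f <- runif(1, 0.1, 0.5)
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    fit <- fit_logistic(status, list(g = as.numeric(g),
                                     h = as.numeric(g == 1),
                                     mask = rep(TRUE, n)),
                        model = "genotypic")
    if (fit$p["h"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("scan_assoc returns calibrated nulls, detects planted effects and handles empties", {
  # the sampling SD of lambda (a median ratio) is ~0.104/sqrt(k/500), so
  # 4000 variants make [0.9, 1.1] a ~2.7-sigma band
  set.seed(99)
  n <- 500
  variants <- lapply(1:4000, function(i)
    random_hwe_variant(n, runif(1, 0.1, 0.5), vid = paste0("v", i),
                       pos = i * 1000L))
  y <- rnorm(n)
  scan <- scan_assoc(variants, y, trait_kind = "quantitative",
                     mode = "hardcall")
  expect_gt(scan$lambda, 0.9)
  expect_lt(scan$lambda, 1.1)
  expect_equal(nrow(scan$qq), 4000L)
  # planted dominance deviation: p_domdev < 1e-4 at n = 20000, MAF 0.4
  n2 <- 20000
  g <- sample(0:2, n2, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  y2 <- -0.3 * (g == 1) + rnorm(n2)
  v <- variant_from_genotypes(g, vid = "planted")
  scan2 <- scan_assoc(list(v), y2, trait_kind = "quantitative")
  expect_lt(scan2$results$p_domdev, 1e-4)
  # empty variant list: valid empty results
  scan0 <- scan_assoc(list(), y, trait_kind = "quantitative")
  expect_equal(nrow(scan0$results), 0L)
  f <- tempfile(fileext = ".tsv")
  write_results(scan0$results, f)
  expect_equal(length(readLines(f)), 1L)  # header only
})

test_that("genotype_class_summary reports n, mean, SD and Wald CIs", {
  g <- c(rep(0L, 3), rep(1L, 2), 2L)
  v <- variant_from_genotypes(g)
  y <- c(5, 5, 5, 1, 3, 7)
  cs <- genotype_class_summary(v, y)
  expect_equal(cs["het", "mean"], 2)
  expect_equal(cs["het", "sd"], sqrt(2))
  expect_equal(cs["hom_ref", "sd"], 0)
  expect_equal(cs["hom_ref", "ci_low"], cs["hom_ref", "mean"])
  # CI arithmetic at printed scale: n = 42835, mean 27.27, SD 4.68
  half <- 1.96 * 4.68 / sqrt(42835)
  expect_equal(27.27 - half, 27.2257, tolerance = 1e-4)
  expect_equal(27.27 + half, 27.3143, tolerance = 1e-4)
  # empty class: NA summary
  v2 <- variant_from_genotypes(c(0L, 0L, 1L))
  cs2 <- genotype_class_summary(v2, c(1, 2, 3))
  expect_equal(cs2["hom_alt", "n"], 0L)
  expect_true(is.na(cs2["hom_alt", "mean"]))
})
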