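test_that("allele_frequency matches closed-form values", {
  v0 <- variant_from_genotypes(rep(0L, 50))
  v2 <- variant_from_genotypes(rep(2L, 50))
  expect_equal(allele_frequency(v0), 0)
  expect_equal(allele_frequency(v2), 1)
  # FTO genotype-class counts: alt frequency (57524 + 2*19329) / (2*119688)
  vfto <- variant_from_counts(42835, 57524, 19329)
  expect_equal(allele_frequency(vfto), 0.401803, tolerance = 1e-6)
  vna <- variant_from_genotypes(rep(NA_integer_, 5))
  expect_error(allele_frequency(vna), "missing")
})

test_that("hwe_exact_test matches enumeration, boundaries and chi-square oracle", {
  # monomorphic-by-genotype: unique most probable configuration
  expect_equal(hwe_exact_test(0, 0, 50), 1.0)
  expect_equal(hwe_exact_test(50, 0, 0), 1.0)
  # 100 diploids, 100 alt alleles, zero hets: brute-force enumeration
  brute <- local({
    hets <- seq(0, 100, by = 2)
    hom_alt <- (100 - hets) / 2
    hom_ref <- 100 - hets - hom_alt
    logp <- lfactorial(100) - lfactorial(hom_ref) - lfactorial(hets) -
      lfactorial(hom_alt) + hets * log(2) +
      2 * lfactorial(100) - lfactorial(200)
    p <- exp(logp - max(logp)); p <- p / sum(p)
    sum(p[p <= p[hets == 0] * (1 + 1e-12)])
  })
  expect_equal(hwe_exact_test(50, 0, 50), brute, tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  # large balanced counts agree with the chi-square test
  p_exact <- hwe_exact_test(42835, 57524, 19329)
  expect_gt(p_exact, 1e-6)
  chisq_oracle <- function(k) {
    n <- sum(k); f <- (k[2] + 2 * k[3]) / (2 * n)
    e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    pchisq(sum((k - e)^2 / e), df = 1, lower.tail = FALSE)
  }
  expect_equal(p_exact, chisq_oracle(c(42835, 57524, 19329)),
               tolerance = 5e-3)
  expect_error(hwe_exact_test(-1, 0, 5), "negative")
})

test_that("exact and chi-square HWE p values agree for well-populated tables", {
  set.seed(101)
  chisq_oracle <- function(k) {
    n <- sum(k); f <- (k[2] + 2 * k[3]) / (2 * n)
    e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    pchisq(sum((k - e)^2 / e), df = 1, lower.tail = FALSE)
  }
  checked <- 0L
  for (i in 1:200) {
    n <- sample(1000:20000, 1)
    f <- runif(1, 0.05, 0.5)
    k <- as.vector(rmultinom(1, n, c((1 - f)^2, 2 * f * (1 - f), f^2)))
    e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    if (any(e < 5)) next
    checked <- checked + 1L
    p1 <- hwe_exact_test(k[1], k[2], k[3])
    p2 <- chisq_oracle(k)
    expect_lt(abs(log10(p1) - log10(p2)), 0.3)
  }
  expect_gt(checked, 150L)
})

test_that("no HWE failures at alpha 1e-6 under the null across 1e5 variants", {
  set.seed(202)
  n <- 200L
  fails <- 0L
  for (i in 1:100000) {
    f <- runif(1, 0.05, 0.5)
    k <- as.vector(rmultinom(1, n, c((1 - f)^2, 2 * f * (1 - f), f^2)))
    if (hwe_exact_test(k[1], k[2], k[3]) < 1e-6) fails <- fails + 1L
  }
  expect_lte(fails / 1e5, 1e-5)
})

test_that("apply_filters enumerates criterion combinations and boundaries", {
  fx <- qc_combination_fixture()
  out <- apply_filters(fx$variants, qc_thresholds())
  expect_equal(length(out$passing), 1L)
  expect_equal(out$passing[[1]]$vid, "none")
  got <- as.matrix(out$reasons[c("fail_info", "fail_hwe", "fail_maf")])
  dimnames(got) <- dimnames(fx$expected_fail)
  expect_identical(got, fx$expected_fail)
  # every failed criterion is recorded, not just the first
  triple <- out$reasons[out$reasons$vid == "info_hwe_maf", ]
  expect_equal(triple$reason, "info,hwe,maf")
  # boundary convention: exactly at threshold passes
  v_bound <- variant_from_counts(4900, 4200, 900, info = 0.9)
  expect_false(apply_filters(list(v_bound))$reasons$fail_info)
  v_below <- variant_from_counts(4900, 4200, 900, info = 0.89)
  expect_true(apply_filters(list(v_below))$reasons$fail_info)
  # empty input yields empty output
  empty <- apply_filters(list())
  expect_length(empty$passing, 0)
  expect_equal(nrow(empty$reasons), 0)
})

test_that("tightening any threshold never grows the passing set", {
  set.seed(31)
  variants <- lapply(1:30, function(i)
    random_hwe_variant(500, runif(1, 0.002, 0.5), vid = paste0("v", i),
                       pos = i * 1000L))
  base <- qc_thresholds(min_info = 0.5, hwe_alpha = 1e-8, min_maf = 0.001)
  base_ids <- vapply(apply_filters(variants, base)$passing, `[[`, "", "vid")
  tighter <- list(qc_thresholds(0.95, 1e-8, 0.001),
                  qc_thresholds(0.5, 1e-4, 0.001),
                  qc_thresholds(0.5, 1e-8, 0.05))
  for (thr in tighter) {
    ids <- vapply(apply_filters(variants, thr)$passing, `[[`, "", "vid")
    expect_true(all(ids %in% base_ids))
  }
})

test_that("pairwise_r2 handles identity, complements and independent pairs", {
  set.seed(5)
  a <- random_hwe_variant(2000, 0.3, vid = "a")
  self <- pairwise_r2(a, a)
  expect_equal(self$r2, 1.0)
  # composite D' estimator: exactly 1 only at perfect HWE proportions
  expect_gt(self$d_prime, 0.9)
  # flipped coding: dosages b = 2 - a
  b <- variant_from_genotypes(2L - hard_call(a), vid = "b")
  expect_equal(pairwise_r2(a, b)$r2, 1.0)
  # independent pairs: r2 * n ~ chi-square(1), so r2 < 0.01 at n = 10000
  # in essentially every seed
  low <- 0L
  for (s in 1:50) {
    set.seed(s)
    u <- random_hwe_variant(10000, 0.3, vid = "u")
    v <- random_hwe_variant(10000, 0.3, vid = "v")
    if (pairwise_r2(u, v)$r2 < 0.01) low <- low + 1L
  }
  expect_gte(low, 50L * 0.99)
  mono <- variant_from_genotypes(rep(0L, 2000))
  expect_error(pairwise_r2(a, mono), "monomorphic")
})

test_that("count_independent prunes duplicated and cliqued variants", {
  set.seed(17)
  indep <- lapply(1:10, function(i)
    random_hwe_variant(800, 0.3, vid = paste0("v", i), pos = i * 1000L))
  expect_equal(count_independent(indep), 10L)
  # each variant duplicated exactly once (r^2 = 1 pairs)
  dups <- list()
  for (i in seq_along(indep)) {
    v <- indep[[i]]
    copy <- variant_from_genotypes(hard_call(v), vid = paste0(v$vid, "b"),
                                   pos = v$pos + 1L)
    dups <- c(dups, list(v, copy))
  }
  expect_equal(count_independent(dups), 10L)
  # planted 3-variant clique among 10: brute-force graph pruning keeps 8
  clique <- indep
  g4 <- hard_call(indep[[4]])
  clique[[5]] <- variant_from_genotypes(g4, vid = "v5c", pos = 5000L)
  clique[[6]] <- variant_from_genotypes(g4, vid = "v6c", pos = 6000L)
  expect_equal(count_independent(clique), 8L)
})
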