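test_that("exact signed-rank p is 2/2^n when all non-zero differences share a sign", {
  res <- wilcoxon_signed_rank_exact(c(rep(1, 9), rep(0, 13)))
  expect_identical(res$p_value, 2 / 2^9)
  expect_equal(res$n_used, 9L)
  expect_equal(res$n_zero, 13L)
  # magnitude-independence
  res2 <- wilcoxon_signed_rank_exact(c(5, 1, 2, 2, 7, 3, 9, 4, 1, rep(0, 13)))
  expect_identical(res2$p_value, 2 / 2^9)
  for (n in c(1, 4, 12)) {
    expect_equal(wilcoxon_signed_rank_exact(seq_len(n))$p_value, min(1, 2 / 2^n))
  }
})

test_that("single difference gives p = 1 and all-zero differences are degenerate", {
  expect_equal(wilcoxon_signed_rank_exact(1)$p_value, 1)
  res <- wilcoxon_signed_rank_exact(c(0, 0, 0))
  expect_equal(res$p_value, 1)
  expect_true("degenerate" %in% res$flags)
})

test_that("exact signed-rank p equals full 2^n enumeration, ties included", {
  expect_equal(wilcoxon_signed_rank_exact(c(3, -1, 2, -2, 5))$p_value,
               bf_signed_rank_p(c(3, -1, 2, -2, 5)))
  set.seed(14)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE) # ties guaranteed for n > 8
    expect_equal(wilcoxon_signed_rank_exact(d)$p_value, bf_signed_rank_p(d),
                 tolerance = 1e-12, label = paste(d, collapse = ","))
  }
})

test_that("exact signed-rank matches wilcox.test when ties and zeros are absent", {
  set.seed(15)
  for (i in 1:10) {
    d <- rnorm(12, 0.3, 1)
    if (any(d == 0) || any(duplicated(abs(d)))) next # continuous draws; ties have measure zero
    expect_equal(wilcoxon_signed_rank_exact(d)$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(16)
  d <- rnorm(40, 0.4)
  expect_message(res <- wilcoxon_signed_rank_exact(d), "normal approximation")
  expect_true("normal_approximation" %in% res$flags)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-10)
})

test_that("uncorrected McNemar reproduces chi-square arithmetic at the printed patterns", {
  r9 <- mcnemar_test(9, 0)
  expect_equal(r9$statistic, 9)
  expect_equal(r9$p_value, pchisq(9, 1, lower.tail = FALSE))
  expect_equal(round(r9$p_value, 4), 0.0027)
  r8 <- mcnemar_test(8, 0)
  expect_equal(r8$statistic, 8)
  expect_equal(round(r8$p_value, 4), 0.0047)
  # symmetry and the degenerate case
  expect_equal(mcnemar_test(3, 3)$p_value, 1)
  expect_equal(mcnemar_test(5, 2)$p_value, mcnemar_test(2, 5)$p_value)
  r0 <- mcnemar_test(0, 0)
  expect_equal(r0$p_value, 1)
  expect_true("degenerate" %in% r0$flags)
  # agrees with the base implementation without continuity correction
  tab <- matrix(c(4, 9, 2, 7), 2)
  expect_equal(mcnemar_test(9, 2)$p_value,
               stats::mcnemar.test(tab, correct = FALSE)$p.value)
})

test_that("exact McNemar doubles the binomial tail and dominates the chi-square at min(b,c)=0", {
  expect_equal(mcnemar_test(9, 0, mode = "exact")$p_value, 2 * 0.5^9)
  expect_equal(mcnemar_test(4, 6, mode = "exact")$p_value,
               min(1, 2 * pbinom(4, 10, 0.5)))
  for (bc in 1:10) {
    expect_gte(mcnemar_test(bc, 0, mode = "exact")$p_value,
               mcnemar_test(bc, 0, mode = "asymptotic")$p_value)
  }
  expect_true(mcnemar_test(paired_binary_table(5, 9, 0, 8))$statistic == 9)
})

test_that("relative risk matches hand arithmetic with a log-Wald interval", {
  rr <- relative_risk(3, 20, 11, 24)
  expect_equal(rr$estimate, (3 / 20) / (11 / 24), tolerance = 1e-12)
  expect_equal(round(rr$estimate, 2), 0.33)
  expect_equal(round(relative_risk(7, 20, 17, 24)$estimate, 2), 0.49)
  expect_equal(relative_risk(5, 10, 5, 10)$estimate, 1)
  se <- sqrt(1 / 3 - 1 / 20 + 1 / 11 - 1 / 24)
  expect_equal(rr$ci_low, exp(log(rr$estimate) - qnorm(0.975) * se))
  # reciprocal property
  ab <- relative_risk(7, 20, 17, 24)$estimate
  ba <- relative_risk(17, 24, 7, 20)$estimate
  expect_equal(ab * ba, 1)
  expect_true("undefined_reference_risk" %in% relative_risk(3, 20, 0, 24)$flags)
  expect_equal(relative_risk(0, 20, 5, 24)$estimate, 0)
})

test_that("rate ratio is a plain quotient with guarded degenerate cases", {
  expect_equal(rate_ratio(0.15, 1.19), 0.15 / 1.19)
  expect_equal(round(rate_ratio(0.15, 1.19), 2), 0.13)
  expect_equal(round(rate_ratio(0.15, 1.13), 2), 0.13)
  expect_equal(rate_ratio(0, 2), 0)
  expect_warning(out <- rate_ratio(1, 0), "undefined")
  expect_true(is.na(out))
  expect_error(rate_ratio(-1, 2), ">= 0")
})

test_that("gatekeeping stops at the first non-significant hypothesis", {
  res <- gatekeeping(c(0.0741, 0.001, 0.001), alpha = 0.05)
  expect_equal(res$tested, c(TRUE, FALSE, FALSE))
  expect_equal(res$significant, c(FALSE, FALSE, FALSE))
  res2 <- gatekeeping(c(0.0039, 0.0039, 0.0039, 0.0273, 0.0027, 0.0047), alpha = 0.10)
  expect_true(all(res2$tested))
  expect_true(all(res2$significant))
  expect_equal(nrow(gatekeeping(numeric(), 0.05)), 0)
  expect_error(gatekeeping(0.5, alpha = 1.2), "alpha")
})

test_that("raising an earlier p-value never rescues a later hypothesis", {
  set.seed(22)
  for (i in 1:20) {
    p <- runif(5)
    base <- gatekeeping(p, 0.1)
    j <- sample(5, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0.1, 0.9)) # degrade one hypothesis
    mod <- gatekeeping(p2, 0.1)
    expect_true(all(mod$significant <= base$significant))
  }
})

test_that("tidy and glance produce one-row summaries of test objects", {
  td <- tidy(mcnemar_test(9, 0))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("method", "estimate", "statistic", "p.value",
                     "conf.low", "conf.high", "flags"))
  expect_equal(td$p.value, glance(mcnemar_test(9, 0))$p.value)
})
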