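#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test with the classic zero handling: zero
#' differences are dropped, absolute differences are ranked with midranks
#' for ties, and the statistic is the sum of ranks of the positive
#' differences. For `n <= exact_limit` non-zero differences the null
#' distribution is computed exactly over all `2^n` equiprobable sign
#' assignments (evaluated by convolution over the doubled midranks, which
#' is mathematically identical to full enumeration); above that a normal
#' approximation with tie correction is used and a notice is emitted. The
#' two-sided p-value doubles the smaller tail (inclusive), capped at 1.
#'
#' With all non-zero differences sharing one sign the exact p-value is
#' `2 / 2^n` regardless of magnitudes — e.g. 9 positive differences among
#' 22 pairs give `2/512 = 0.00390625`.
#'
#' @param differences Numeric vector of paired differences (at least one).
#' @param zero_method `"drop"` (classic, default) or `"pratt"` (zeros are
#'   ranked with the rest, then discarded from the statistic).
#' @param exact_limit Largest n for the exact distribution (default 25).
#' @return An `ho_test` with `statistic` (rank sum of positive
#'   differences), `p_value`, `n_used`, `n_zero`. All-zero differences give
#'   p = 1 with a `"degenerate"` flag.
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(c(rep(1, 9), rep(0, 13)))$p_value # 0.00390625
wilcoxon_signed_rank_exact <- function(differences,
                                       zero_method = c("drop", "pratt"),
                                       exact_limit = 25) {
  zero_method <- match.arg(zero_method)
  d <- differences
  if (!length(d) || any(!is.finite(d))) abort("need at least one finite difference")
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    return(new_ho_test("exact Wilcoxon signed-rank", statistic = 0, p_value = 1,
                       flags = "degenerate", n_used = 0L, n_zero = n_zero))
  }
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  flags <- character()
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact Wilcoxon signed-rank"
  } else {
    inform(sprintf("n = %d non-zero differences: using normal approximation", n))
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    flags <- "normal_approximation"
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  new_ho_test(method, statistic = w, p_value = p, flags = flags,
              n_used = n, n_zero = n_zero)
}

# exact two-sided sign-flip p-value for rank vector r and observed rank sum w;
# distribution of the doubled rank sum by polynomial convolution
signed_rank_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[1:(tot + 1 - ri)]
    f <- g
  }
  f <- f / 2^length(r)
  w2 <- as.integer(round(2 * w))
  lower <- sum(f[seq_len(w2 + 1)])
  upper <- sum(f[(w2 + 1):(tot + 1)])
  min(1, 2 * min(lower, upper))
}

#' Cross-tabulate paired binary outcomes
#'
#' @param n11 Both periods positive; `n10` period 1 only (discordant `b`);
#'   `n01` period 2 only (discordant `c`); `n00` neither.
#' @param n10,n01,n00 See `n11`.
#' @return A one-row tibble with the four cells, `b`, `c` and `n_pairs`.
#' @export
paired_binary_table <- function(n11, n10, n01, n00) {
  cells <- c(n11, n10, n01, n00)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  tibble(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
         b = n10, c = n01, n_pairs = sum(cells))
}

#' McNemar's test for paired proportions
#'
#' Within-group comparison of a binary outcome across the two periods of a
#' crossover. The default asymptotic form is the uncorrected chi-square
#' `(b - c)^2 / (b + c)` on 1 df (no continuity correction); the exact form
#' is the two-sided binomial `min(1, 2 P(X <= min(b, c)))` with
#' `X ~ Binomial(b + c, 1/2)`. `b + c = 0` gives p = 1 with a degenerate
#' flag.
#'
#' @param b,c Discordant counts (period-1-only and period-2-only
#'   positives), or pass a [paired_binary_table()] as `b`.
#' @param mode `"asymptotic"` (default) or `"exact"`.
#' @return An `ho_test`.
#' @export
#' @examples
#' mcnemar_test(9, 0)$p_value # 0.0027
#' mcnemar_test(8, 0)$p_value # 0.0047
mcnemar_test <- function(b, c = NULL, mode = c("asymptotic", "exact")) {
  mode <- match.arg(mode)
  if (is.data.frame(b)) {
    tab <- b
    b <- tab$b
    c <- tab$c
  }
  if (is.null(c)) abort("supply both discordant counts `b` and `c`")
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    abort("discordant counts must be non-negative integers")
  }
  if (b + c == 0) {
    return(new_ho_test("McNemar", statistic = 0, p_value = 1, flags = "degenerate",
                       disc_b = b, disc_c = c))
  }
  if (mode == "asymptotic") {
    stat <- (b - c)^2 / (b + c)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    new_ho_test("McNemar chi-square (uncorrected)", statistic = stat, p_value = p,
                disc_b = b, disc_c = c)
  } else {
    p <- min(1, 2 * pbinom(min(b, c), b + c, 0.5))
    new_ho_test("McNemar exact binomial", statistic = min(b, c), p_value = p,
                disc_b = b, disc_c = c)
  }
}

#' Relative risk of two independent proportions
#'
#' `RR = (x1/n1) / (x2/n2)` with a log-scale Wald confidence interval
#' `exp(log RR +/- z * sqrt(1/x1 - 1/n1 + 1/x2 - 1/n2))` and a Wald z
#' p-value. A zero reference risk (`x2 = 0`) leaves the RR undefined
#' (flagged); a zero numerator gives RR 0 with no CI.
#'
#' @param x1,n1 Events and total in the index group.
#' @param x2,n2 Events and total in the reference group.
#' @param conf_level Confidence level, default 0.95.
#' @return An `ho_test` with `estimate` = RR.
#' @export
#' @examples
#' relative_risk(3, 20, 11, 24)$estimate # 0.327...
relative_risk <- function(x1, n1, x2, n2, conf_level = 0.95) {
  if (n1 <= 0 || n2 <= 0) abort("group totals must be > 0")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) abort("events must lie in [0, n]")
  if (x2 == 0) {
    return(new_ho_test("relative risk", flags = "undefined_reference_risk",
                       x1 = x1, n1 = n1, x2 = x2, n2 = n2))
  }
  rr <- (x1 / n1) / (x2 / n2)
  if (x1 == 0) {
    return(new_ho_test("relative risk", estimate = 0, flags = "zero_numerator",
                       x1 = x1, n1 = n1, x2 = x2, n2 = n2))
  }
  se <- sqrt(1 / x1 - 1 / n1 + 1 / x2 - 1 / n2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  zstat <- log(rr) / se
  new_ho_test("relative risk", statistic = zstat,
              p_value = 2 * pnorm(-abs(zstat)), estimate = rr,
              ci_low = exp(log(rr) - z * se), ci_high = exp(log(rr) + z * se),
              conf_level = conf_level, x1 = x1, n1 = n1, x2 = x2, n2 = n2)
}

#' Ratio of two event rates
#'
#' @param rate1 Index rate (e.g. new lesions/patient on treatment).
#' @param rate2 Reference rate; must be > 0 (a zero reference returns `NA`
#'   with a warning).
#' @return `rate1 / rate2` (scalar).
#' @export
#' @examples
#' rate_ratio(0.15, 1.19) # 0.126
rate_ratio <- function(rate1, rate2) {
  if (rate1 < 0 || rate2 < 0) abort("rates must be >= 0")
  if (rate2 == 0) {
    warn("reference rate is 0: rate ratio undefined")
    return(NA_real_)
  }
  rate1 / rate2
}

#' Fixed-sequence gatekeeping over an ordered hypothesis list
#'
#' Hypotheses are tested in the prespecified order; the first p-value at or
#' above `alpha` fails, stops the sequence, and leaves all later hypotheses
#' untested (descriptive only). This controls the family-wise error rate at
#' `alpha` without any p-value adjustment.
#'
#' @param p_values Ordered numeric vector of p-values.
#' @param alpha Significance level in (0, 1).
#' @param labels Optional hypothesis labels.
#' @return A tibble (class `ho_gatekeeping`) with `order`, `label`,
#'   `p_value`, `tested`, `significant`.
#' @export
#' @examples
#' gatekeeping(c(0.0741, 0.01), alpha = 0.05) # stops at the first
gatekeeping <- function(p_values, alpha, labels = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  k <- length(p_values)
  labels <- labels %||% sprintf("H%d", seq_len(k))
  out <- tibble(order = seq_len(k), label = labels, p_value = p_values,
                tested = FALSE, significant = FALSE)
  if (k == 0) {
    class(out) <- c("ho_gatekeeping", class(out))
    return(out)
  }
  for (i in seq_len(k)) {
    out$tested[i] <- TRUE
    out$significant[i] <- p_values[i] < alpha
    if (!out$significant[i]) break
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("ho_gatekeeping", class(out))
  out
}
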