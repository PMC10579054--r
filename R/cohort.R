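#' Specify a synthetic crossover cohort
#'
#' Parameters of the longitudinal cohort generator. Defaults emulate the
#' two-arm, two-period crossover design the analysis layer targets: 24
#' placebo and 20 treated patients; visits at weeks 0, 8, 28, 56 and 76;
#' period 1 ends at the week-28 scan, after which the placebo arm crosses
#' over to treatment; per-patient new-lesion counts are negative binomial
#' with a placebo rate of 1.19 lesions/patient/period (PET) and a treated
#' rate smaller by the rate ratio 0.13; diary flare-up probabilities 70.8%
#' (untreated) and 35.0% (treated) per period, investigator-reported 41.7%
#' and 10.0%; and missing-completely-at-random scan missingness.
#'
#' @param n_placebo,n_treated Patients per arm (must be >= 1).
#' @param visit_weeks Visit schedule; the first entry is baseline, period 1
#'   ends at `visit_weeks[3]`, period 2 at `visit_weeks[4]`.
#' @param placebo_new_lesion_rate Expected new PET lesions/patient/period
#'   off treatment.
#' @param treatment_rate_ratio Multiplicative effect of treatment on the
#'   new-lesion rate.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param ct_detection_prob Probability that a new PET lesion is also
#'   counted by CT (binomial thinning; default 1.13/1.19 so both printed
#'   marginal rates are matched).
#' @param flareup_prob_placebo,flareup_prob_treated Per-period diary
#'   flare-up probabilities off/on treatment.
#' @param flareup_inv_prob_placebo,flareup_inv_prob_treated Investigator-
#'   reported flare-up probabilities off/on treatment.
#' @param scan_missing_prob MCAR probability that a post-baseline scan is
#'   missing (COVID-like disruption).
#' @param pct_change_mean_wk8,pct_change_mean_wk28 Length-2 vectors
#'   (untreated, treated) of mean percent change from baseline in total
#'   lesion activity at weeks 8 and 28.
#' @param pct_change_sd SD of the percent-change draws.
#' @param seed Integer RNG seed used by [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_placebo = 24, n_treated = 20,
                        visit_weeks = c(0, 8, 28, 56, 76),
                        placebo_new_lesion_rate = 1.19,
                        treatment_rate_ratio = 0.13,
                        dispersion = 1,
                        ct_detection_prob = 1.13 / 1.19,
                        flareup_prob_placebo = 0.708,
                        flareup_prob_treated = 0.35,
                        flareup_inv_prob_placebo = 0.417,
                        flareup_inv_prob_treated = 0.10,
                        scan_missing_prob = 0.05,
                        pct_change_mean_wk8 = c(10, -5),
                        pct_change_mean_wk28 = c(20, -10),
                        pct_change_sd = 30,
                        seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  if (n_placebo < 1 || n_treated < 1) abort("both arms need at least one patient")
  probs <- c(ct_detection_prob, flareup_prob_placebo, flareup_prob_treated,
             flareup_inv_prob_placebo, flareup_inv_prob_treated, scan_missing_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (placebo_new_lesion_rate < 0) abort("`placebo_new_lesion_rate` must be >= 0")
  if (treatment_rate_ratio < 0) abort("`treatment_rate_ratio` must be >= 0")
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  if (length(visit_weeks) < 4) abort("need at least baseline + 3 follow-up visits")
  spec
}

rnb_counts <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a longitudinal crossover cohort
#'
#' Draws one row per patient-visit. Per-period new-lesion counts are
#' negative binomial with an arm- and period-specific mean: the placebo arm
#' uses the placebo rate in period 1 and the treated rate after the week-28
#' crossover, the treated arm uses the treated rate in both periods. Counts
#' (and the associated total new-lesion CT volume and PET activity) are
#' attached to the period-end visit rows (weeks 28 and 56); flare-up
#' indicators are per period; scan availability is MCAR per post-baseline
#' visit. Reproducible under `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `patient_id`, `arm`
#'   (`"placebo"`/`"treated"`), `visit_week`, `period` (0 = baseline),
#'   `on_treatment`, `scan_available`, `new_lesion_count_pet`,
#'   `new_lesion_count_ct`, `new_lesion_volume_ct_ml`, `new_lesion_tla_g`,
#'   `pct_change_tla` (weeks 8/28 only), `flareup_diary`,
#'   `flareup_investigator`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(coh, arm, visit_week)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_placebo + spec$n_treated
  arms <- rep(c("placebo", "treated"), c(spec$n_placebo, spec$n_treated))
  wk <- spec$visit_weeks
  wk_p1 <- wk[3]
  wk_p2 <- wk[4]

  # per-patient total of k lognormal lesion-level draws
  lognormal_totals <- function(k, meanlog, sdlog) {
    tot <- numeric(length(k))
    pos <- which(k > 0)
    if (length(pos)) {
      draws <- rlnorm(sum(k[pos]), meanlog, sdlog)
      tot[pos] <- rowsum(draws, rep(seq_along(pos), k[pos]))[, 1]
    }
    tot
  }

  with_seed(spec$seed, {
    ids <- sprintf("P%04d", seq_len(n))
    rows <- tibble(
      patient_id = rep(ids, each = length(wk)),
      arm = rep(arms, each = length(wk)),
      visit_week = rep(wk, n),
      period = rep(dplyr::case_when(wk == wk[1] ~ 0L, wk <= wk_p1 ~ 1L, TRUE ~ 2L), n),
      # placebo crosses over to treatment after the week-28 visit
      on_treatment = rep(arms == "treated", each = length(wk)) | rep(wk > wk_p1, n)
    )
    rows$scan_available <- rows$visit_week == wk[1] |
      runif(nrow(rows)) >= spec$scan_missing_prob

    rows$new_lesion_count_pet <- 0L
    rows$new_lesion_count_ct <- 0L
    rows$new_lesion_volume_ct_ml <- 0
    rows$new_lesion_tla_g <- 0
    for (end_wk in c(wk_p1, wk_p2)) {
      j <- which(rows$visit_week == end_wk)
      mu <- spec$placebo_new_lesion_rate *
        ifelse(rows$on_treatment[j], spec$treatment_rate_ratio, 1)
      k_pet <- rnb_counts(n, mu, spec$dispersion)
      k_ct <- rbinom(n, k_pet, spec$ct_detection_prob)
      rows$new_lesion_count_pet[j] <- k_pet
      rows$new_lesion_count_ct[j] <- k_ct
      # per-lesion sizes/activities: lognormal stand-ins at trial-like scale
      rows$new_lesion_volume_ct_ml[j] <- lognormal_totals(k_ct, log(8), 0.6)
      rows$new_lesion_tla_g[j] <- lognormal_totals(k_pet, log(150), 0.7)
    }

    rows$pct_change_tla <- NA_real_
    for (w in c(wk[2], wk_p1)) {
      j <- which(rows$visit_week == w)
      mu <- if (w == wk[2]) spec$pct_change_mean_wk8 else spec$pct_change_mean_wk28
      rows$pct_change_tla[j] <- rnorm(n, mu[rows$on_treatment[j] + 1L],
                                      spec$pct_change_sd)
    }

    rows$flareup_diary <- NA
    rows$flareup_investigator <- NA
    for (end_wk in c(wk_p1, wk_p2)) {
      j <- which(rows$visit_week == end_wk)
      trt <- rows$on_treatment[j]
      rows$flareup_diary[j] <- runif(n) <
        ifelse(trt, spec$flareup_prob_treated, spec$flareup_prob_placebo)
      rows$flareup_investigator[j] <- runif(n) <
        ifelse(trt, spec$flareup_inv_prob_treated, spec$flareup_inv_prob_placebo)
    }
    attr(rows, "cohort_spec") <- spec
    rows
  })
}
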