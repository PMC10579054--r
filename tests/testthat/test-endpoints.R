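test_that("TLA sums SUVmean times metabolic volume and is additive", {
  expect_equal(total_lesion_activity(tibble::tibble(suv_mean = numeric(),
                                                    metabolic_volume_ml = numeric())), 0)
  les <- tibble::tibble(suv_mean = c(4, 2), metabolic_volume_ml = c(10, 5))
  expect_equal(total_lesion_activity(les), 50)
  # additivity over disjoint lesion sets
  a <- tibble::tibble(suv_mean = runif(3, 1, 5), metabolic_volume_ml = runif(3, 1, 20))
  b <- tibble::tibble(suv_mean = runif(4, 1, 5), metabolic_volume_ml = runif(4, 1, 20))
  expect_equal(total_lesion_activity(dplyr::bind_rows(a, b)),
               total_lesion_activity(a) + total_lesion_activity(b))
  mixed <- tibble::tibble(suv_mean = 1, metabolic_volume_ml = 1, visit_week = c(0, 8))
  expect_error(total_lesion_activity(mixed), "per patient-visit")
})

test_that("percent change is anchored at baseline and flags zero baselines", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(473.4, 236.7), -50)
  expect_equal(percent_change(50, 100), 100)
  expect_warning(out <- percent_change(c(0, 10), c(5, 20)), "undefined")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 100)
})

test_that("TWA matches hand trapezoid arithmetic on all four missingness patterns", {
  # both observed
  expect_equal(twa_percent_change(0, 0), 0)
  expect_equal(twa_percent_change(-10, 30), bf_twa(-10, 30))
  # week 8 missing: linear interpolation baseline -> week 28
  expect_equal(twa_percent_change(NA, 30), bf_twa(30 * 8 / 28, 30))
  expect_equal(twa_percent_change(NA, 30), 15)
  # week 28 missing: week 8 carried forward
  expect_equal(twa_percent_change(-10, NA), bf_twa(-10, -10))
  expect_equal(twa_percent_change(-10, NA), -240 / 28)
  # both missing: placebo means substituted
  expect_equal(twa_percent_change(NA, NA, placebo_means = c(12, 40)),
               bf_twa(12, 40))
  expect_error(twa_percent_change(NA, NA), "placebo")
})

test_that("TWA lies between the extremes of the percent-change polyline", {
  set.seed(8)
  for (i in 1:25) {
    p8 <- runif(1, -80, 80)
    p28 <- runif(1, -80, 80)
    twa <- twa_percent_change(p8, p28)
    expect_gte(twa, min(0, p8, p28) - 1e-12)
    expect_lte(twa, max(0, p8, p28) + 1e-12)
  }
})

test_that("per-period summaries count lesions first detected in the period", {
  visits <- tibble::tibble(
    patient_id = "P1", arm = "placebo", visit_week = c(0, 8, 28, 56, 76),
    period = c(0, 1, 1, 2, 2), on_treatment = c(F, F, F, T, T),
    scan_available = TRUE,
    new_lesion_count_pet = c(0, 0, 2, 0, 0),
    new_lesion_count_ct = c(0, 0, 2, 0, 0),
    new_lesion_volume_ct_ml = c(0, 0, 5.19 + 13.69, 0, 0),
    new_lesion_tla_g = c(0, 0, 120, 0, 0),
    flareup_diary = NA, flareup_investigator = NA, pct_change_tla = NA_real_
  )
  p1 <- period_new_lesion_summary(visits, 1, "CT")
  expect_equal(p1$count, 2L)
  expect_equal(p1$total_volume_cm3, 18.88)
  expect_true(p1$any_new_lesion)
  # lesions that arose in period 1 do not count again in period 2
  p2 <- period_new_lesion_summary(visits, 2, "CT")
  expect_equal(p2$count, 0L)
  expect_equal(p2$total_volume_cm3, 0)
  expect_false(p2$any_new_lesion)
})

test_that("a missing week-56 scan is substituted by the first later scan, else excluded", {
  visits <- tibble::tibble(
    patient_id = "P1", arm = "placebo", visit_week = c(0, 8, 28, 56, 76),
    period = c(0, 1, 1, 2, 2), on_treatment = c(F, F, F, T, T),
    scan_available = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    new_lesion_count_pet = c(0, 0, 0, 3, 0),
    new_lesion_count_ct = c(0, 0, 0, 3, 0),
    new_lesion_volume_ct_ml = c(0, 0, 0, 9, 0),
    new_lesion_tla_g = c(0, 0, 0, 200, 0),
    flareup_diary = NA, flareup_investigator = NA, pct_change_tla = NA_real_
  )
  p2 <- period_new_lesion_summary(visits, 2, "PET")
  expect_equal(p2$count, 3L)
  expect_equal(p2$followup_week, 76)
  visits$scan_available <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  p2b <- period_new_lesion_summary(visits, 2, "PET")
  expect_true(is.na(p2b$count))
  expect_match(p2b$excluded_reason, "period 2")
})

test_that("derived endpoints partition counts by period and flag the mITT set", {
  coh <- generate_cohort(cohort_spec(seed = 19, scan_missing_prob = 0))
  ep <- derive_endpoints(coh)
  expect_equal(nrow(ep), 44)
  expect_true(all(ep$in_mitt == (ep$arm == "placebo")))
  # per-patient counts equal the generator's period-end rows
  wk28 <- coh[coh$visit_week == 28, ]
  expect_equal(ep$new_lesion_count_pet_p1[match(wk28$patient_id, ep$patient_id)],
               as.integer(wk28$new_lesion_count_pet))
  expect_true(all(ep$new_lesion_count_ct_p1 <= ep$new_lesion_count_pet_p1))
  expect_true(all(ep$any_new_ct_p1 == (ep$new_lesion_count_ct_p1 > 0)))
  expect_true(all(!is.na(ep$twa_tla_28wk)))
})

test_that("cohort summaries reproduce observed-rate arithmetic", {
  ep <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:40),
    arm = rep(c("placebo", "treated"), c(22, 18)),
    new_lesion_count_ct_p1 = c(rep(1, 22), rep(0, 16), 1, 1),
    new_lesion_count_ct_p2 = 0L,
    any_new_ct_p1 = c(rep(TRUE, 22), rep(FALSE, 16), TRUE, TRUE),
    any_new_ct_p2 = FALSE,
    flareup_diary_p1 = FALSE, flareup_diary_p2 = FALSE,
    flareup_inv_p1 = FALSE, flareup_inv_p2 = FALSE,
    in_mitt = TRUE
  )
  s <- cohort_summary(ep, "all", "CT")
  expect_equal(s$observed_rate[s$arm == "placebo" & s$period == 1], 1)    # 22 lesions / 22 patients
  expect_equal(s$observed_rate[s$arm == "treated" & s$period == 1], 2 / 18, tolerance = 1e-12)
  expect_equal(s$observed_rate[s$period == 2], c(0, 0))
  expect_equal(s$pct_with_new_lesion[s$arm == "placebo" & s$period == 1], 100)
  expect_error(cohort_summary(ep[0, ], "all", "CT"), "empty")
})
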