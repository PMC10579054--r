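#' Total lesion activity (TLA)
#'
#' TLA is the patient-level burden of actively mineralizing lesions at one
#' timepoint: the sum over pre-existing and new lesions of SUVmean times
#' metabolic volume. With metabolic volume in ml and the 1 ml == 1 g
#' convention the unit is grams. An empty lesion set has TLA 0. Mixed
#' visits (or patients) in one call are an error — TLA is a per-visit sum.
#'
#' @param lesions Tibble of lesion records with `suv_mean` and
#'   `metabolic_volume_ml`; optional `visit_week`/`patient_id` columns are
#'   checked for uniqueness.
#' @return TLA in g (scalar).
#' @export
#' @examples
#' total_lesion_activity(tibble::tibble(
#'   suv_mean = c(4, 2), metabolic_volume_ml = c(10, 5)
#' )) # 50
total_lesion_activity <- function(lesions) {
  stopifnot(is.data.frame(lesions))
  if (!nrow(lesions)) return(0)
  for (col in c("visit_week", "patient_id")) {
    if (col %in% names(lesions) && dplyr::n_distinct(lesions[[col]]) > 1) {
      abort(sprintf("lesion records span multiple values of `%s`; TLA is per patient-visit", col))
    }
  }
  sum(lesions$suv_mean * lesions$metabolic_volume_ml)
}

#' Percent change from baseline
#'
#' `100 * (value - baseline) / baseline`. A non-positive baseline makes the
#' quantity undefined; such entries return `NA` with a warning so callers
#' can exclude and log them.
#'
#' @param baseline,value Numeric vectors (recycled).
#' @return Percent change, same length as the inputs.
#' @export
percent_change <- function(baseline, value) {
  out <- 100 * (value - baseline) / baseline
  bad <- is.finite(baseline) & baseline <= 0
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("%d value(s) with non-positive baseline: percent change undefined, set to NA",
                 sum(bad, na.rm = TRUE)))
    out[bad] <- NA_real_
  }
  out
}

#' Time-weighted average percent change over 28 weeks, with imputation
#'
#' The TWA is the area under the percent-change-versus-time polyline through
#' (0, 0), (8, pc8), (28, pc28), by the trapezoidal rule, divided by the
#' full 28-week span — a time-weighted mean of the percent changes.
#' Missing scans are imputed by the prespecified rules:
#' \itemize{
#'   \item both weeks missing: the placebo-group mean percent changes at
#'     weeks 8 and 28 are substituted (error if not supplied);
#'   \item week 8 missing: linear interpolation between baseline and week
#'     28, i.e. `pc8 = (8/28) * pc28`;
#'   \item week 28 missing: week 8 carried forward, `pc28 = pc8`.
#' }
#'
#' @param pc_wk8,pc_wk28 Percent change at weeks 8 and 28 (scalars, `NA` if
#'   the scan is missing). Vectors are accepted and processed elementwise.
#' @param placebo_means Length-2 numeric `(mean pc8, mean pc28)` of the
#'   placebo group, used only when both values are missing.
#' @param weeks Visit weeks of the two follow-up scans, default `c(8, 28)`.
#' @return TWA percent change (same length as the inputs).
#' @export
#' @examples
#' twa_percent_change(NA, 30)  # 15
#' twa_percent_change(-10, NA) # -60/7
twa_percent_change <- function(pc_wk8, pc_wk28, placebo_means = NULL,
                               weeks = c(8, 28)) {
  n <- max(length(pc_wk8), length(pc_wk28))
  pc_wk8 <- rep_len(pc_wk8, n)
  pc_wk28 <- rep_len(pc_wk28, n)
  vapply(seq_len(n), function(i) {
    p8 <- pc_wk8[i]
    p28 <- pc_wk28[i]
    if (is.na(p8) && is.na(p28)) {
      if (is.null(placebo_means) || length(placebo_means) != 2 || any(is.na(placebo_means))) {
        abort("both scans missing and no placebo-group means supplied for imputation")
      }
      p8 <- placebo_means[1]
      p28 <- placebo_means[2]
    } else if (is.na(p8)) {
      p8 <- p28 * weeks[1] / weeks[2] # linear baseline -> week 28
    } else if (is.na(p28)) {
      p28 <- p8 # carried forward
    }
    auc <- weeks[1] * p8 / 2 + (weeks[2] - weeks[1]) * (p8 + p28) / 2
    auc / weeks[2]
  }, numeric(1))
}

# resolve the follow-up scan week for a period under the MCAR substitution
# rule: a missing period-2 scan is replaced by the first available later
# scan; returns NA if no usable scan exists
resolve_followup_week <- function(visits, period_end_week) {
  avail <- visits$visit_week[visits$scan_available]
  cand <- sort(avail[avail >= period_end_week])
  if (length(cand)) cand[1] else NA_real_
}

#' Per-period new-lesion summary for one patient
#'
#' Counts, total CT volume and total PET activity of the lesions first
#' detected in the given period, for one patient's visit rows. Period 1 is
#' the week-28 scan relative to baseline; period 2 the week-56 scan
#' relative to week 28, with the first available later scan substituting a
#' missing week-56 scan. A patient with no usable follow-up scan for the
#' period is excluded (`NA` row, `excluded_reason` set).
#'
#' @param visits One patient's rows of a [generate_cohort()]-format tibble.
#' @param period 1 or 2.
#' @param modality `"PET"` or `"CT"` (selects the count column; volume is
#'   CT-based, activity PET-based).
#' @return One-row tibble: `count`, `total_volume_cm3`, `total_tla_g`,
#'   `any_new_lesion`, `followup_week`, `excluded_reason`.
#' @export
period_new_lesion_summary <- function(visits, period, modality = c("PET", "CT")) {
  modality <- match.arg(modality)
  stopifnot(period %in% 1:2, is.data.frame(visits))
  if (dplyr::n_distinct(visits$patient_id) > 1) {
    abort("`visits` must contain a single patient")
  }
  wks <- sort(unique(visits$visit_week))
  end_wk <- if (period == 1) wks[3] else wks[4]
  use_wk <- if (period == 1) {
    if (visits$scan_available[visits$visit_week == end_wk]) end_wk else NA_real_
  } else {
    resolve_followup_week(visits, end_wk)
  }
  if (is.na(use_wk)) {
    return(tibble(count = NA_integer_, total_volume_cm3 = NA_real_,
                  total_tla_g = NA_real_, any_new_lesion = NA,
                  followup_week = NA_real_,
                  excluded_reason = sprintf("no usable scan for period %d", period)))
  }
  # new-lesion quantities are recorded on the period-end row; a substitute
  # scan observes the same lesions later
  row <- visits[visits$visit_week == end_wk, , drop = FALSE]
  cnt <- if (modality == "PET") row$new_lesion_count_pet else row$new_lesion_count_ct
  tibble(count = as.integer(cnt),
         total_volume_cm3 = row$new_lesion_volume_ct_ml,
         total_tla_g = row$new_lesion_tla_g,
         any_new_lesion = cnt > 0,
         followup_week = use_wk,
         excluded_reason = NA_character_)
}

#' Derive per-patient endpoints from a cohort table
#'
#' Produces one row per patient: per-period new-lesion counts by PET and
#' CT, total new-lesion CT volume and PET activity, any-new-lesion flags,
#' diary and investigator flare-up indicators per period, the TWA percent
#' change in total lesion activity over period 1 (with the prespecified
#' imputation, using observed placebo-arm means when both scans are
#' missing), and analysis-set flags. `in_mitt` marks crossover (placebo
#' arm) patients whose period-1 and period-2 scans both resolved.
#'
#' @param cohort A [generate_cohort()]-format tibble.
#' @return An endpoint tibble (class `ho_endpoints`).
#' @export
derive_endpoints <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  wks <- sort(unique(cohort$visit_week))
  # placebo-arm mean percent changes among observed scans, for imputation
  plc <- cohort[cohort$arm == "placebo" & cohort$scan_available, , drop = FALSE]
  plc_means <- c(
    mean(plc$pct_change_tla[plc$visit_week == wks[2]], na.rm = TRUE),
    mean(plc$pct_change_tla[plc$visit_week == wks[3]], na.rm = TRUE)
  )

  out <- cohort |>
    dplyr::group_by(.data$patient_id, .data$arm) |>
    dplyr::group_modify(function(visits, key) {
      visits$patient_id <- key$patient_id
      p1_pet <- period_new_lesion_summary(visits, 1, "PET")
      p1_ct <- period_new_lesion_summary(visits, 1, "CT")
      p2_pet <- period_new_lesion_summary(visits, 2, "PET")
      p2_ct <- period_new_lesion_summary(visits, 2, "CT")
      pc8 <- if (visits$scan_available[visits$visit_week == wks[2]]) {
        visits$pct_change_tla[visits$visit_week == wks[2]]
      } else NA_real_
      pc28 <- if (visits$scan_available[visits$visit_week == wks[3]]) {
        visits$pct_change_tla[visits$visit_week == wks[3]]
      } else NA_real_
      tibble(
        new_lesion_count_pet_p1 = p1_pet$count,
        new_lesion_count_ct_p1 = p1_ct$count,
        new_lesion_count_pet_p2 = p2_pet$count,
        new_lesion_count_ct_p2 = p2_ct$count,
        new_lesion_volume_p1 = p1_ct$total_volume_cm3,
        new_lesion_volume_p2 = p2_ct$total_volume_cm3,
        new_lesion_tla_p1 = p1_pet$total_tla_g,
        new_lesion_tla_p2 = p2_pet$total_tla_g,
        any_new_pet_p1 = p1_pet$any_new_lesion,
        any_new_ct_p1 = p1_ct$any_new_lesion,
        any_new_pet_p2 = p2_pet$any_new_lesion,
        any_new_ct_p2 = p2_ct$any_new_lesion,
        flareup_diary_p1 = visits$flareup_diary[visits$visit_week == wks[3]],
        flareup_diary_p2 = visits$flareup_diary[visits$visit_week == wks[4]],
        flareup_inv_p1 = visits$flareup_investigator[visits$visit_week == wks[3]],
        flareup_inv_p2 = visits$flareup_investigator[visits$visit_week == wks[4]],
        pct_change_tla_wk8 = pc8,
        pct_change_tla_wk28 = pc28,
        twa_tla_28wk = twa_percent_change(pc8, pc28, placebo_means = plc_means),
        followup_week_p2 = p2_pet$followup_week,
        excluded_reason = dplyr::coalesce(p1_pet$excluded_reason, p2_pet$excluded_reason)
      )
    }) |>
    dplyr::ungroup()
  out$in_mitt <- out$arm == "placebo" & is.na(out$excluded_reason)
  class(out) <- c("ho_endpoints", class(out))
  out
}

#' Arm-level endpoint summaries
#'
#' Per arm and period: total new lesions, observed rate (lesions/patient),
#' percent of patients with at least one new lesion, and flare-up
#' proportions, over patients with resolved scans.
#'
#' @param endpoints An endpoint tibble from [derive_endpoints()].
#' @param analysis_set `"all"` or `"mitt"` (crossover patients with usable
#'   scans in both periods).
#' @param modality `"PET"` or `"CT"`.
#' @return A tibble with one row per arm x period.
#' @export
cohort_summary <- function(endpoints, analysis_set = c("all", "mitt"),
                           modality = c("CT", "PET")) {
  analysis_set <- match.arg(analysis_set)
  modality <- match.arg(modality)
  df <- as_tibble(endpoints)
  if (analysis_set == "mitt") df <- df[df$in_mitt, , drop = FALSE]
  if (!nrow(df)) abort("empty analysis set")
  cnt_col <- function(p) sprintf("new_lesion_count_%s_p%d", tolower(modality), p)
  any_col <- function(p) sprintf("any_new_%s_p%d", tolower(modality), p)
  purrr::map_dfr(1:2, function(p) {
    df |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(
        period = p,
        n_patients = sum(!is.na(.data[[cnt_col(p)]])),
        total_new_lesions = sum(.data[[cnt_col(p)]], na.rm = TRUE),
        observed_rate = .data$total_new_lesions / .data$n_patients,
        pct_with_new_lesion = 100 * mean(.data[[any_col(p)]], na.rm = TRUE),
        pct_flareup_diary = 100 * mean(.data[[sprintf("flareup_diary_p%d", p)]], na.rm = TRUE),
        pct_flareup_investigator = 100 * mean(.data[[sprintf("flareup_inv_p%d", p)]], na.rm = TRUE),
        .groups = "drop"
      )
  }) |>
    dplyr::arrange(.data$arm, .data$period)
}
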