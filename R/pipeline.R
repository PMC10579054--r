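#' Default quantification and classification thresholds
#'
#' The constants of the read rules in one place: the active-lesion SUVmax
#' multiple (3), the metabolic-volume threshold fraction (0.40 of SUVmax),
#' the CT new-lesion density cut (200 HU, strict) and volume floor
#' (1 cm^3, inclusive), and the Dice overlap for lesion matching (0.2).
#'
#' @param activity_multiple,metabolic_fraction,hu_threshold,volume_floor_ml,dice_threshold
#'   Override any constant.
#' @return Named list of thresholds.
#' @export
ho_thresholds <- function(activity_multiple = 3, metabolic_fraction = 0.4,
                          hu_threshold = 200, volume_floor_ml = 1,
                          dice_threshold = 0.2) {
  vals <- list(activity_multiple = activity_multiple,
               metabolic_fraction = metabolic_fraction,
               hu_threshold = hu_threshold,
               volume_floor_ml = volume_floor_ml,
               dice_threshold = dice_threshold)
  if (any(unlist(vals) <= 0)) abort("all thresholds must be positive")
  vals
}

#' Period-2 crossover hierarchy analysis
#'
#' Runs the six-hypothesis fixed-sequence hierarchy of the open-label
#' period on the crossover (placebo-to-treatment) patients of an endpoint
#' table, each hypothesis comparing each patient's period-2 outcome with
#' their own period-1 outcome:
#' \enumerate{
#'   \item number of new CT lesions — exact Wilcoxon signed-rank;
#'   \item total volume of new CT lesions — exact Wilcoxon signed-rank;
#'   \item number of new PET lesions — exact Wilcoxon signed-rank;
#'   \item total activity (TLA) of new PET lesions — exact Wilcoxon;
#'   \item percent of patients with new CT lesions — McNemar;
#'   \item percent of patients with new PET lesions — McNemar.
#' }
#'
#' @param endpoints Endpoint tibble from [derive_endpoints()].
#' @param alpha Two-sided significance level for the hierarchy (default
#'   0.10, the open-label period convention).
#' @param mcnemar_mode Passed to [mcnemar_test()].
#' @return List of class `ho_analysis`: `tests` (named `ho_test`s),
#'   `hierarchy` (a [gatekeeping()] tibble), `n` (patients analyzed).
#' @export
analyze_crossover <- function(endpoints, alpha = 0.10,
                              mcnemar_mode = "asymptotic") {
  df <- as_tibble(endpoints)
  df <- df[df$in_mitt, , drop = FALSE]
  if (!nrow(df)) abort("no crossover patients with usable scans in both periods")
  wil <- function(p2, p1) wilcoxon_signed_rank_exact(p2 - p1)
  mcn <- function(a1, a2) {
    mcnemar_test(sum(a1 & !a2), sum(!a1 & a2), mode = mcnemar_mode)
  }
  tests <- list(
    new_ct_lesion_count = wil(df$new_lesion_count_ct_p2, df$new_lesion_count_ct_p1),
    new_ct_lesion_volume = wil(df$new_lesion_volume_p2, df$new_lesion_volume_p1),
    new_pet_lesion_count = wil(df$new_lesion_count_pet_p2, df$new_lesion_count_pet_p1),
    new_lesion_tla = wil(df$new_lesion_tla_p2, df$new_lesion_tla_p1),
    pct_patients_new_ct = mcn(df$any_new_ct_p1, df$any_new_ct_p2),
    pct_patients_new_pet = mcn(df$any_new_pet_p1, df$any_new_pet_p2)
  )
  hier <- gatekeeping(vapply(tests, function(t) t$p_value, numeric(1)),
                      alpha = alpha, labels = names(tests))
  structure(list(tests = tests, hierarchy = hier, n = nrow(df), alpha = alpha),
            class = "ho_analysis")
}

#' @export
print.ho_analysis <- function(x, ...) {
  cat(sprintf("<ho_analysis> period-2 crossover hierarchy, n = %d, alpha = %g\n",
              x$n, x$alpha))
  print(as.data.frame(x$hierarchy), row.names = FALSE)
  invisible(x)
}

#' Tidy the hierarchy of a crossover analysis
#'
#' @param x An `ho_analysis`.
#' @param ... Unused.
#' @return Tibble with one row per hypothesis: hierarchy position, method,
#'   statistic, p-value and gatekeeping outcome.
#' @export
tidy.ho_analysis <- function(x, ...) {
  dplyr::bind_cols(
    x$hierarchy,
    purrr::map_dfr(x$tests, function(t) {
      tibble(method = t$method, statistic = t$statistic)
    })
  )
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulation to report in one call: generates a crossover cohort, derives
#' per-patient endpoints, summarizes arms, and runs the period-2 hierarchy
#' with gatekeeping. Deterministic for a fixed `spec$seed`. When `out_dir`
#' is given, writes `cohort.tsv`, `endpoints.tsv`, `summary.tsv`,
#' `results.json` (per-hypothesis results with hierarchy metadata plus the
#' generating configuration) into it.
#'
#' @param spec A [cohort_spec()].
#' @param alpha Significance level of the period-2 hierarchy.
#' @param out_dir Optional output directory.
#' @return List of class `ho_run`: `cohort`, `endpoints`, `summary`
#'   (CT-modality arm summary), `analysis` (an `ho_analysis`).
#' @export
#' @examples
#' run <- run_ho_pipeline(cohort_spec(seed = 11))
#' run$analysis
run_ho_pipeline <- function(spec = cohort_spec(), alpha = 0.10, out_dir = NULL) {
  cohort <- generate_cohort(spec)
  endpoints <- derive_endpoints(cohort)
  summary <- cohort_summary(endpoints, analysis_set = "all", modality = "CT")
  analysis <- analyze_crossover(endpoints, alpha = alpha)
  run <- structure(list(cohort = cohort, endpoints = endpoints,
                        summary = summary, analysis = analysis, spec = spec),
                   class = "ho_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    readr::write_tsv(as_tibble(endpoints), file.path(out_dir, "endpoints.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
    res <- list(
      config = unclass(spec),
      alpha = alpha,
      n_analyzed = analysis$n,
      hypotheses = as.data.frame(tidy(analysis))
    )
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.ho_run <- function(x, ...) {
  cat(sprintf("<ho_run> %d patients (%d placebo, %d treated), seed %d\n",
              x$spec$n_placebo + x$spec$n_treated, x$spec$n_placebo,
              x$spec$n_treated, x$spec$seed))
  print(x$analysis)
  invisible(x)
}
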