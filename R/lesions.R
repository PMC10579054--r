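#' Active-lesion classification
#'
#' A heterotopic-ossification lesion is "active" when its SUVmax is at least
#' `multiple` (default 3) times the mean SUV of the normotopic
#' supra-acetabular reference region. The boundary is inclusive: exactly 3x
#' the reference mean is active.
#'
#' @param suv_max Lesion SUVmax (vectorized).
#' @param reference_suv_mean Reference-region mean SUV, must be > 0.
#' @param multiple Activity multiple, default 3.
#' @return Logical vector.
#' @export
#' @examples
#' classify_active(c(9, 8.9, 0), 3) # TRUE FALSE FALSE
classify_active <- function(suv_max, reference_suv_mean, multiple = 3) {
  if (any(!is.finite(reference_suv_mean)) || any(reference_suv_mean <= 0)) {
    abort("`reference_suv_mean` must be finite and > 0")
  }
  suv_max >= multiple * reference_suv_mean
}

#' Select baseline lesions to follow
#'
#' From the candidate active lesions at baseline, pick up to `max_n`
#' (default 7) lesions, beginning with the greatest SUVmax and continuing in
#' descending order of signal magnitude. Ties on SUVmax are broken by larger
#' metabolic volume, then by `lesion_id`, so selection is deterministic.
#'
#' @param candidates Tibble of baseline lesion records with at least
#'   `lesion_id`, `suv_max`, `is_active`; `metabolic_volume_ml` used for
#'   tie-breaking when present.
#' @param max_n Maximum number of lesions to keep (default 7).
#' @return The selected rows, ordered by decreasing SUVmax.
#' @export
select_baseline_lesions <- function(candidates, max_n = 7) {
  stopifnot(is.data.frame(candidates))
  if (!nrow(candidates)) return(as_tibble(candidates))
  cand <- as_tibble(candidates)
  if (!"metabolic_volume_ml" %in% names(cand)) cand$metabolic_volume_ml <- 0
  cand |>
    dplyr::filter(.data$is_active) |>
    dplyr::arrange(dplyr::desc(.data$suv_max),
                   dplyr::desc(.data$metabolic_volume_ml),
                   .data$lesion_id) |>
    head(max_n)
}

#' New-lesion rule for CT-only detections
#'
#' A candidate new lesion identified by CT alone must have a density above
#' 200 HU (strict: well above ~50 HU soft tissue) and a volume of at least
#' 1 cm^3 (inclusive: the smallest reliably measurable HO lesion on
#' low-dose CT). "Density" is the mean HU over the candidate mask by
#' default; set `density = "max"` upstream if the maximum is preferred.
#'
#' @param mean_hu Candidate density, HU (vectorized).
#' @param ct_volume_ml Candidate volume in ml (= cm^3); must be >= 0.
#' @param hu_threshold Density cut, default 200 (strict `>`).
#' @param volume_floor_ml Volume floor, default 1 (inclusive `>=`).
#' @return Logical vector.
#' @export
#' @examples
#' detect_new_ct_lesion(c(250, 200, 300), c(1.2, 5, 0.9)) # TRUE FALSE FALSE
detect_new_ct_lesion <- function(mean_hu, ct_volume_ml, hu_threshold = 200,
                                 volume_floor_ml = 1) {
  if (any(!is.finite(mean_hu)) || any(!is.finite(ct_volume_ml))) {
    abort("`mean_hu` and `ct_volume_ml` must be finite")
  }
  if (any(ct_volume_ml < 0)) abort("`ct_volume_ml` must be >= 0")
  mean_hu > hu_threshold & ct_volume_ml >= volume_floor_ml
}

#' New-lesion rule for PET detections
#'
#' A post-baseline lesion identified by PET (not matched to any baseline
#' lesion) counts as new if and only if it is active per
#' [classify_active()]. No volume floor applies to the PET rule.
#'
#' @inheritParams classify_active
#' @return Logical vector.
#' @export
detect_new_pet_lesion <- function(suv_max, reference_suv_mean, multiple = 3) {
  classify_active(suv_max, reference_suv_mean, multiple)
}

#' Match lesion calls across readers or visits by mask overlap
#'
#' Two calls refer to the same lesion when the Dice coefficient of their
#' voxel masks exceeds `dice_threshold` (default 0.2); when either mask is
#' missing, falls back to centroid distance below `centroid_mm`.
#'
#' @param mask_a,mask_b Logical arrays (or `NULL`).
#' @param centroid_a,centroid_b Numeric length-3 physical centroids, mm
#'   (used when a mask is missing).
#' @param dice_threshold Dice cut, default 0.2.
#' @param centroid_mm Centroid-distance fallback, default 15 mm.
#' @return `TRUE` if the calls match.
#' @export
lesion_match <- function(mask_a = NULL, mask_b = NULL,
                         centroid_a = NULL, centroid_b = NULL,
                         dice_threshold = 0.2, centroid_mm = 15) {
  if (!is.null(mask_a) && !is.null(mask_b)) {
    inter <- sum(mask_a & mask_b)
    denom <- sum(mask_a) + sum(mask_b)
    if (denom == 0) return(FALSE)
    return(2 * inter / denom > dice_threshold)
  }
  if (is.null(centroid_a) || is.null(centroid_b)) {
    abort("need either two masks or two centroids to match lesions")
  }
  sqrt(sum((centroid_a - centroid_b)^2)) < centroid_mm
}

#' Forced adjudication of dual-reader lesion calls
#'
#' Lesion calls made identically by both independent readers pass through
#' with provenance `"agreed"`. Every discrepancy — a lesion called by one
#' reader only, or called by both with conflicting active status — must be
#' resolved by an explicit adjudicator ruling; a discrepancy without a
#' ruling is an error naming the unresolved keys. The adjudicator is a
#' ruling table, not a third automatic reader.
#'
#' @param reader1,reader2 Tibbles of lesion calls with a `lesion_key` column
#'   and an `is_active` logical column (other columns are carried from the
#'   reader that contributed the row; reader1 wins for agreed rows).
#' @param rulings Tibble with `lesion_key`, `accept` (logical: keep the
#'   lesion?) and optionally `is_active` (resolved status; defaults to the
#'   calling reader's status, or `TRUE` on conflict when accepted).
#' @return Tibble of final calls with a `provenance` column
#'   (`"agreed"`/`"adjudicated"`).
#' @export
adjudicate <- function(reader1, reader2, rulings = NULL) {
  r1 <- as_tibble(reader1)
  r2 <- as_tibble(reader2)
  for (nm in list(r1, r2)) {
    if (!all(c("lesion_key", "is_active") %in% names(nm))) {
      abort("reader call tables need `lesion_key` and `is_active` columns")
    }
  }
  if (anyDuplicated(r1$lesion_key) || anyDuplicated(r2$lesion_key)) {
    abort("duplicate `lesion_key` within a reader's call set")
  }
  common <- intersect(r1$lesion_key, r2$lesion_key)
  st1 <- setNames(r1$is_active, r1$lesion_key)
  st2 <- setNames(r2$is_active, r2$lesion_key)
  agreed_keys <- common[st1[common] == st2[common]]
  conflict_keys <- setdiff(common, agreed_keys)
  only1 <- setdiff(r1$lesion_key, r2$lesion_key)
  only2 <- setdiff(r2$lesion_key, r1$lesion_key)
  discrepant <- c(conflict_keys, only1, only2)

  if (length(discrepant)) {
    ruled <- if (is.null(rulings)) character() else rulings$lesion_key
    missing_rulings <- setdiff(discrepant, ruled)
    if (length(missing_rulings)) {
      abort(paste0("unresolved reader discrepancies with no adjudicator ruling: ",
                   paste(missing_rulings, collapse = ", ")))
    }
  }

  agreed <- r1[r1$lesion_key %in% agreed_keys, , drop = FALSE]
  if (nrow(agreed)) agreed$provenance <- "agreed"

  adj_rows <- purrr::map_dfr(discrepant, function(key) {
    rul <- rulings[rulings$lesion_key == key, , drop = FALSE][1, ]
    if (!isTRUE(rul$accept)) return(tibble())
    src <- if (key %in% r1$lesion_key) r1[r1$lesion_key == key, , drop = FALSE]
           else r2[r2$lesion_key == key, , drop = FALSE]
    if ("is_active" %in% names(rul) && !is.na(rul$is_active)) {
      src$is_active <- rul$is_active
    } else if (key %in% conflict_keys) {
      src$is_active <- TRUE
    }
    src$provenance <- "adjudicated"
    src
  })
  out <- dplyr::bind_rows(agreed, adj_rows)
  if (!nrow(out)) {
    out <- r1[0, , drop = FALSE]
    out$provenance <- character()
  }
  as_tibble(out)
}
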