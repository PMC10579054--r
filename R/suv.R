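#' Convert an activity-concentration PET volume to SUV
#'
#' The standardized uptake value of a voxel is its decay-corrected activity
#' concentration \eqn{r} divided by the injected dose normalized by body
#' mass: \eqn{SUV = r / (A_0 / M_0)}. With \eqn{r} in kBq/ml, \eqn{A_0} in
#' kBq and \eqn{M_0} in g, the 1 ml == 1 g tissue-density convention makes
#' the result unitless. Idempotent on a volume already flagged as SUV.
#'
#' @param pet A [pet_volume()].
#' @return A [pet_volume()] with `units = "SUV"`.
#' @export
#' @examples
#' v <- pet_volume(array(7.5, c(2, 2, 2)), units = "kBq/ml",
#'                 injected_dose_kbq = 350000, body_mass_g = 70000)
#' to_suv(v)$values[1, 1, 1] # 7.5 / 5 = 1.5
to_suv <- function(pet) {
  stopifnot(inherits(pet, "pet_volume"))
  if (pet$units == "SUV") return(pet)
  if (is.null(pet$injected_dose_kbq) || pet$injected_dose_kbq <= 0) {
    abort("injected dose A0 must be present and > 0")
  }
  if (is.null(pet$body_mass_g) || pet$body_mass_g <= 0) {
    abort("body mass M0 must be present and > 0")
  }
  out <- pet
  out$values <- pet$values / (pet$injected_dose_kbq / pet$body_mass_g)
  out$units <- "SUV"
  out
}

check_mask <- function(vol, mask, arg = "mask") {
  if (!is.logical(mask) || !identical(dim(mask), dim(vol$values))) {
    abort(sprintf("`%s` must be a logical array with the same dimensions as the volume", arg))
  }
  if (!any(mask)) abort(sprintf("`%s` is empty: region statistics need at least one voxel", arg))
  invisible(mask)
}

#' SUV statistics over a region of interest
#'
#' `suv_max` is the SUV of the most intense voxel within the region;
#' `suv_mean` is the arithmetic mean over the region.
#'
#' @param suv A [pet_volume()] in SUV units.
#' @param mask Logical array (same dimensions) selecting the region; must be
#'   non-empty.
#' @return A one-row tibble with `suv_max`, `suv_mean` and `n_voxels`.
#' @export
region_stats <- function(suv, mask) {
  stopifnot(inherits(suv, "pet_volume"))
  check_mask(suv, mask)
  vals <- suv$values[mask]
  tibble(suv_max = max(vals), suv_mean = mean(vals), n_voxels = length(vals))
}

#' Metabolic volume by 40%-of-SUVmax thresholding
#'
#' Segments a lesion's metabolically active volume: voxels within the lesion
#' mask whose SUV is at or above `fraction` (default 0.40) of the lesion's
#' SUVmax, restricted (by default) to the connected component containing the
#' maximum voxel, minus any exclusion mask (e.g. reader-excluded normotopic
#' bone). The threshold comparison is inclusive (`>=`) so a uniform lesion
#' is segmented in full.
#'
#' @param suv A [pet_volume()] in SUV units.
#' @param lesion_mask Logical array selecting the lesion; non-empty.
#' @param exclusions Optional logical array of voxels to remove. Excluding
#'   the maximum voxel makes the segmentation ill-posed and is an error.
#' @param fraction Threshold as a fraction of SUVmax (default 0.4).
#' @param connected If `TRUE` (default) keep only the connected component of
#'   supra-threshold voxels containing the max voxel; if `FALSE`, pure
#'   thresholding within the lesion mask.
#' @param connectivity 26 (default) or 6 neighbourhood.
#' @return A list with `mask` (logical array), `volume_ml`, `threshold` and
#'   `suv_max`.
#' @export
metabolic_volume <- function(suv, lesion_mask, exclusions = NULL, fraction = 0.4,
                             connected = TRUE, connectivity = c(26, 6)) {
  stopifnot(inherits(suv, "pet_volume"))
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  check_mask(suv, lesion_mask, "lesion_mask")
  vals <- suv$values
  masked <- vals
  masked[!lesion_mask] <- -Inf
  max_idx <- which.max(masked) # first max voxel, deterministic under ties
  smax <- vals[max_idx]
  thr <- fraction * smax
  seg <- lesion_mask & (vals >= thr)
  if (connected) {
    seg <- flood_fill_3d(seg, max_idx, connectivity = as.integer(connectivity))
  }
  if (!is.null(exclusions)) {
    if (!is.logical(exclusions) || !identical(dim(exclusions), dim(vals))) {
      abort("`exclusions` must be a logical array matching the volume")
    }
    if (exclusions[max_idx]) {
      abort("exclusion mask removes the SUVmax voxel: segmentation is ill-posed")
    }
    seg <- seg & !exclusions
  }
  list(mask = seg, volume_ml = sum(seg) * voxel_volume_ml(suv),
       threshold = thr, suv_max = smax)
}

# connected component of `mask` containing linear index `seed`,
# by iterative frontier expansion
flood_fill_3d <- function(mask, seed, connectivity = 26L) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  visited <- array(FALSE, dims)
  if (!mask[seed]) return(visited)
  visited[seed] <- TRUE
  frontier <- matrix(arrayInd(seed, dims), ncol = 3)
  while (nrow(frontier)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      sweep(frontier, 2, offs[k, ], "+")
    }))
    keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * dims[1] + (cand[, 3] - 1L) * dims[1] * dims[2]
    lin <- unique(lin[mask[lin] & !visited[lin]])
    if (!length(lin)) break
    visited[lin] <- TRUE
    frontier <- arrayInd(lin, dims)
  }
  visited
}

#' Peak SUV: mean over a 1 ml sphere at the hottest voxel
#'
#' Mean SUV over the voxels whose centers lie within a 1 ml sphere (radius
#' about 6.2 mm) centered on the lesion's maximum voxel, clipped to the
#' image grid. An EANM-style convention; always `<=` SUVmax for non-uniform
#' lesions.
#'
#' @inheritParams metabolic_volume
#' @param sphere_volume_ml Sphere volume, default 1 ml.
#' @return Peak SUV (scalar).
#' @export
suv_peak <- function(suv, lesion_mask, sphere_volume_ml = 1) {
  stopifnot(inherits(suv, "pet_volume"))
  check_mask(suv, lesion_mask, "lesion_mask")
  vals <- suv$values
  masked <- vals
  masked[!lesion_mask] <- -Inf
  smax <- max(masked)
  # among tied maxima, center the sphere on the voxel nearest the lesion
  # centroid (deterministic; keeps a uniform lesion's peak at its value)
  tied <- arrayInd(which(masked == smax), dim(vals))
  centroid <- colMeans(arrayInd(which(lesion_mask), dim(vals)))
  d2 <- rowSums(sweep(sweep(tied, 2, centroid), 2, suv$spacing_mm, "*")^2)
  ctr <- tied[order(d2)[1], ]
  radius <- (3 * sphere_volume_ml * 1000 / (4 * pi))^(1 / 3)
  sphere <- physical_dist2(dim(vals), suv$spacing_mm, ctr, rep(radius, 3)) <= 1
  mean(vals[sphere])
}

#' Quantify every truth lesion of a phantom on its (noisy) PET volume
#'
#' Runs [region_stats()], [metabolic_volume()] and [suv_peak()] on each
#' lesion support mask of a generated phantom, plus the reference-region
#' mean and the active-lesion classification.
#'
#' @param phantom Result of [generate_phantom()].
#' @param ... Passed to [metabolic_volume()].
#' @return A tibble with one row per lesion: SUV statistics, metabolic
#'   volume (ml), CT volume and mean HU over the support mask, and
#'   `is_active` per the 3x-reference rule.
#' @export
quantify_phantom <- function(phantom, ...) {
  suv <- to_suv(phantom$pet)
  ref_mean <- region_stats(suv, phantom$reference_mask)$suv_mean
  rows <- purrr::map_dfr(seq_len(nrow(phantom$truth)), function(i) {
    m <- phantom$truth$mask[[i]]
    st <- region_stats(suv, m)
    mv <- metabolic_volume(suv, m, ...)
    ctv <- phantom$ct$values[m]
    tibble(lesion_id = phantom$truth$lesion_id[i],
           suv_max = st$suv_max, suv_mean = st$suv_mean,
           suv_peak = suv_peak(suv, m),
           metabolic_volume_ml = mv$volume_ml,
           ct_volume_ml = sum(m) * voxel_volume_ml(suv),
           mean_hu = mean(ctv),
           reference_suv_mean = ref_mean,
           is_active = classify_active(st$suv_max, ref_mean))
  })
  if (!nrow(rows)) {
    rows <- tibble(lesion_id = integer(), suv_max = numeric(), suv_mean = numeric(),
                   suv_peak = numeric(), metabolic_volume_ml = numeric(),
                   ct_volume_ml = numeric(), mean_hu = numeric(),
                   reference_suv_mean = numeric(), is_active = logical())
  }
  rows
}
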