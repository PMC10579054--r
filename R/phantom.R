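#' Specify a synthetic lesion
#'
#' Describes one focal uptake lesion painted into a phantom: either an
#' isotropic 3D Gaussian uptake profile (exercises the 40%-of-SUVmax
#' threshold nontrivially) or a hard ellipsoid of uniform uptake.
#'
#' @param center_voxel Integer length-3 voxel index of the lesion center.
#' @param peak_suv SUV at the lesion center (>= 0), on top of background.
#' @param shape `"gaussian"` or `"ellipsoid"`.
#' @param sigma_mm Gaussian profile standard deviation in mm (shape
#'   `"gaussian"`); the lesion support mask extends to 3 sigma.
#' @param radii_mm Length-3 ellipsoid radii in mm (shape `"ellipsoid"`).
#' @param mean_hu CT density painted inside the lesion support, HU.
#' @param appears_at_week First visit week at which the lesion exists.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center_voxel, peak_suv, shape = c("gaussian", "ellipsoid"),
                        sigma_mm = 8, radii_mm = c(10, 10, 10),
                        mean_hu = 300, appears_at_week = 0) {
  shape <- match.arg(shape)
  if (peak_suv < 0) abort("`peak_suv` must be >= 0")
  if (shape == "gaussian" && sigma_mm <= 0) abort("`sigma_mm` must be > 0")
  if (shape == "ellipsoid" && any(radii_mm <= 0)) abort("`radii_mm` must be > 0")
  structure(list(center_voxel = as.integer(center_voxel), peak_suv = peak_suv,
                 shape = shape, sigma_mm = sigma_mm, radii_mm = radii_mm,
                 mean_hu = mean_hu, appears_at_week = appears_at_week),
            class = "lesion_spec")
}

#' Specify a synthetic PET-CT phantom
#'
#' Defines the voxel grid, soft-tissue background, skeletal reference region
#' (an ellipsoid standing in for the supra-acetabular region used to judge
#' lesion activity), the lesions, and the PET noise level.
#'
#' Defaults give a 64 x 64 x 96 grid at 4 mm isotropic spacing, which
#' quantifies in well under a second.
#'
#' @param grid_shape Integer length-3 voxel counts per axis.
#' @param voxel_spacing_mm Numeric length-3 spacing in mm.
#' @param lesions List of [lesion_spec()] objects.
#' @param reference_center_voxel,reference_radii_mm Ellipsoidal reference
#'   region (center voxel and radii in mm).
#' @param background_suv Soft-tissue background SUV.
#' @param reference_suv Mean SUV painted inside the reference region
#'   (normotopic bone takes up more NaF than soft tissue).
#' @param soft_tissue_hu,skeleton_hu CT levels for background and the
#'   reference bone region, HU.
#' @param pet_noise_sd SD of additive Gaussian PET noise, SUV units (>= 0).
#' @param seed Integer RNG seed used by [generate_phantom()].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 96), voxel_spacing_mm = c(4, 4, 4),
                         lesions = list(),
                         reference_center_voxel = c(32, 32, 24),
                         reference_radii_mm = c(16, 16, 16),
                         background_suv = 0.5, reference_suv = 2,
                         soft_tissue_hu = 50, skeleton_hu = 800,
                         pet_noise_sd = 0.05, seed = 1L) {
  if (any(grid_shape < 1)) abort("`grid_shape` must be positive")
  if (any(voxel_spacing_mm <= 0)) abort("`voxel_spacing_mm` must be > 0")
  if (pet_noise_sd < 0) abort("`pet_noise_sd` must be >= 0")
  if (background_suv < 0) abort("`background_suv` must be >= 0")
  ok <- vapply(lesions, inherits, logical(1), what = "lesion_spec")
  if (length(lesions) && !all(ok)) abort("`lesions` must be a list of lesion_spec objects")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 lesions = lesions,
                 reference_center_voxel = as.integer(reference_center_voxel),
                 reference_radii_mm = as.numeric(reference_radii_mm),
                 background_suv = background_suv, reference_suv = reference_suv,
                 soft_tissue_hu = soft_tissue_hu, skeleton_hu = skeleton_hu,
                 pet_noise_sd = pet_noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared Mahalanobis-style distance grids in physical mm from a center voxel
physical_dist2 <- function(grid_shape, spacing, center, scale) {
  ax <- lapply(1:3, function(k) (((seq_len(grid_shape[k]) - center[k]) * spacing[k]) / scale[k])^2)
  d2 <- array(0, grid_shape)
  d2 <- d2 + ax[[1]]
  d2 <- d2 + rep(ax[[2]], each = grid_shape[1])
  d2 <- d2 + rep(ax[[3]], each = grid_shape[1] * grid_shape[2])
  d2
}

ellipsoid_mask <- function(grid_shape, spacing, center, radii_mm) {
  physical_dist2(grid_shape, spacing, center, radii_mm) <= 1
}

lesion_support_mask <- function(les, grid_shape, spacing) {
  if (les$shape == "gaussian") {
    ellipsoid_mask(grid_shape, spacing, les$center_voxel, rep(3 * les$sigma_mm, 3))
  } else {
    ellipsoid_mask(grid_shape, spacing, les$center_voxel, les$radii_mm)
  }
}

lesion_profile <- function(les, grid_shape, spacing) {
  if (les$shape == "gaussian") {
    d2 <- physical_dist2(grid_shape, spacing, les$center_voxel, rep(les$sigma_mm, 3))
    prof <- les$peak_suv * exp(-d2 / 2)
    prof[!lesion_support_mask(les, grid_shape, spacing)] <- 0
    prof
  } else {
    les$peak_suv * ellipsoid_mask(grid_shape, spacing, les$center_voxel, les$radii_mm)
  }
}

lesion_extent_ok <- function(les, grid_shape, spacing) {
  r_mm <- if (les$shape == "gaussian") rep(3 * les$sigma_mm, 3) else les$radii_mm
  r_vox <- r_mm / spacing
  all(les$center_voxel - r_vox >= 1) && all(les$center_voxel + r_vox <= grid_shape)
}

#' Generate a synthetic PET-CT phantom
#'
#' Builds a PET SUV volume as soft-tissue background plus lesion uptake
#' profiles plus additive Gaussian noise (clipped at zero), a co-registered
#' CT volume with soft tissue, a skeletal reference region and the lesions
#' painted at their HU levels, and a truth table carrying each lesion's
#' exact support mask and its noise-free SUV statistics. Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `pet` ([pet_volume()]), `ct` ([ct_volume()]),
#'   `reference_mask` (logical array), and `truth` — a tibble with one row
#'   per lesion: `lesion_id`, `appears_at_week`, `peak_suv`, `mean_hu`,
#'   noise-free `suv_max`/`suv_mean`, `metabolic_volume_ml` (computed on the
#'   noise-free volume), `support_volume_ml` and a list column `mask`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   grid_shape = c(24, 24, 24), lesions = list(lesion_spec(c(12, 12, 12), 8)),
#'   reference_center_voxel = c(6, 6, 6), reference_radii_mm = c(8, 8, 8)
#' ))
#' ph$truth[, c("lesion_id", "suv_max", "metabolic_volume_ml")]
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  for (i in seq_along(spec$lesions)) {
    if (!lesion_extent_ok(spec$lesions[[i]], gs, sp)) {
      abort(sprintf("lesion %d extends outside the %s grid", i,
                    paste(gs, collapse = "x")))
    }
  }

  clean <- array(spec$background_suv, gs)
  ref_mask <- ellipsoid_mask(gs, sp, spec$reference_center_voxel, spec$reference_radii_mm)
  clean[ref_mask] <- spec$reference_suv
  ct_vals <- array(spec$soft_tissue_hu, gs)
  ct_vals[ref_mask] <- spec$skeleton_hu

  masks <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    clean <- clean + lesion_profile(les, gs, sp)
    masks[[i]] <- lesion_support_mask(les, gs, sp)
    ct_vals[masks[[i]]] <- les$mean_hu
  }

  withr_seed <- spec$seed
  noisy <- clean
  if (spec$pet_noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(withr_seed)
    noisy <- clean + array(rnorm(prod(gs), 0, spec$pet_noise_sd), gs)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  noisy <- pmax(noisy, 0)

  pet <- pet_volume(noisy, sp, units = "SUV")
  clean_pet <- pet_volume(clean, sp, units = "SUV")
  ct <- ct_volume(ct_vals, sp)

  truth <- purrr::map_dfr(seq_along(spec$lesions), function(i) {
    les <- spec$lesions[[i]]
    st <- region_stats(clean_pet, masks[[i]])
    mv <- metabolic_volume(clean_pet, masks[[i]])
    tibble(lesion_id = i, appears_at_week = les$appears_at_week,
           peak_suv = les$peak_suv, mean_hu = les$mean_hu,
           suv_max = st$suv_max, suv_mean = st$suv_mean,
           metabolic_volume_ml = mv$volume_ml,
           support_volume_ml = sum(masks[[i]]) * prod(sp) / 1000)
  })
  if (nrow(truth)) truth$mask <- masks else truth <- tibble(
    lesion_id = integer(), appears_at_week = numeric(), peak_suv = numeric(),
    mean_hu = numeric(), suv_max = numeric(), suv_mean = numeric(),
    metabolic_volume_ml = numeric(), support_volume_ml = numeric(), mask = list())

  list(pet = pet, ct = ct, reference_mask = ref_mask, truth = truth)
}
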