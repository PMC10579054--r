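#' PET volume objects
#'
#' A `pet_volume` is a 3D voxel grid of either decay-corrected activity
#' concentration (kBq/ml) or standardized uptake values (SUV, unitless),
#' together with the voxel spacing and — when the grid is in activity units —
#' the acquisition metadata needed to convert to SUV: the injected dose
#' \eqn{A_0} (kBq) and the body mass \eqn{M_0} (g).
#'
#' @param values Numeric 3D array of voxel values.
#' @param spacing_mm Numeric length-3 vector of voxel spacing in mm.
#' @param units Either `"SUV"` or `"kBq/ml"`.
#' @param injected_dose_kbq Injected radioactivity dose \eqn{A_0} in kBq
#'   (required to convert activity to SUV).
#' @param body_mass_g Body mass \eqn{M_0} in g.
#' @return A `pet_volume` object.
#' @seealso [to_suv()], [region_stats()], [ct_volume()]
#' @export
#' @examples
#' v <- pet_volume(array(1, c(4, 4, 4)), spacing_mm = c(4, 4, 4))
#' v
pet_volume <- function(values, spacing_mm = c(4, 4, 4), units = c("SUV", "kBq/ml"),
                       injected_dose_kbq = NULL, body_mass_g = NULL) {
  units <- match.arg(units)
  values <- validate_volume_array(values, spacing_mm)
  if (units == "kBq/ml") {
    if (is.null(injected_dose_kbq) || is.null(body_mass_g)) {
      abort("activity-unit PET volumes need `injected_dose_kbq` and `body_mass_g` to be convertible to SUV")
    }
    if (injected_dose_kbq <= 0) abort("`injected_dose_kbq` must be > 0")
    if (body_mass_g <= 0) abort("`body_mass_g` must be > 0")
  }
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm), units = units,
         injected_dose_kbq = injected_dose_kbq, body_mass_g = body_mass_g),
    class = c("pet_volume", "ho_volume")
  )
}

#' CT volume objects
#'
#' A 3D grid of Hounsfield units co-registered with (same shape and spacing
#' as) its paired PET volume.
#'
#' @param values Numeric 3D array of HU values.
#' @param spacing_mm Numeric length-3 voxel spacing in mm.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(values, spacing_mm = c(4, 4, 4)) {
  values <- validate_volume_array(values, spacing_mm)
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm)),
            class = c("ct_volume", "ho_volume"))
}

validate_volume_array <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L) abort("volume `values` must be a 3D array")
  if (!all(is.finite(values))) abort("volume `values` must be finite")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 positive numbers")
  }
  values
}

#' @export
print.ho_volume <- function(x, ...) {
  kind <- if (inherits(x, "pet_volume")) sprintf("PET volume [%s]", x$units) else "CT volume [HU]"
  cat(sprintf("<%s> %s voxels @ %s mm\n", kind,
              paste(dim(x$values), collapse = " x "),
              paste(format(x$spacing_mm), collapse = " x ")))
  cat(sprintf("  range %.3g .. %.3g\n", min(x$values), max(x$values)))
  invisible(x)
}

# volume of one voxel in ml (1 ml == 1000 mm^3)
voxel_volume_ml <- function(vol) prod(vol$spacing_mm) / 1000

#' Write a phantom to NIfTI with a JSON truth sidecar
#'
#' Writes `pet.nii.gz`, `ct.nii.gz` and `truth.json` (per-lesion noise-free
#' statistics; voxel masks are not serialized) into `dir`.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pix <- phantom$pet$spacing_mm
  pet_img <- RNifti::asNifti(phantom$pet$values, pixdim = pix)
  ct_img <- RNifti::asNifti(phantom$ct$values, pixdim = pix)
  RNifti::writeNifti(pet_img, file.path(dir, "pet.nii.gz"))
  RNifti::writeNifti(ct_img, file.path(dir, "ct.nii.gz"))
  truth <- phantom$truth
  truth$mask <- NULL
  meta <- list(
    units = phantom$pet$units,
    injected_dose_kbq = phantom$pet$injected_dose_kbq,
    body_mass_g = phantom$pet$body_mass_g,
    spacing_mm = pix,
    lesions = truth
  )
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a phantom written by [write_phantom_nifti()]
#'
#' @param dir Directory containing `pet.nii.gz`, `ct.nii.gz`, `truth.json`.
#' @return A list with `pet`, `ct` (volume objects) and `truth` (a tibble).
#' @export
read_phantom_nifti <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  pet_img <- RNifti::readNifti(file.path(dir, "pet.nii.gz"))
  ct_img <- RNifti::readNifti(file.path(dir, "ct.nii.gz"))
  spacing <- as.numeric(meta$spacing_mm)
  pet <- pet_volume(array(as.numeric(pet_img), dim = dim(pet_img)), spacing,
                    units = meta$units,
                    injected_dose_kbq = meta$injected_dose_kbq,
                    body_mass_g = meta$body_mass_g)
  ct <- ct_volume(array(as.numeric(ct_img), dim = dim(ct_img)), spacing)
  list(pet = pet, ct = ct, truth = as_tibble(meta$lesions))
}

#' Plot an axial slice of a PET or CT volume
#'
#' @param object A `pet_volume` or `ct_volume`.
#' @param slice Index along the third axis (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster of the slice, in physical mm coordinates.
#' @export
autoplot.ho_volume <- function(object, slice = NULL, ...) {
  dims <- dim(object$values)
  slice <- slice %||% ceiling(dims[3] / 2)
  df <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  df$value <- as.vector(object$values[, , slice])
  df$x_mm <- (df$x - 1) * object$spacing_mm[1]
  df$y_mm <- (df$y - 1) * object$spacing_mm[2]
  lab <- if (inherits(object, "pet_volume")) object$units else "HU"
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = if (lab == "HU") "mako" else "inferno",
                                  name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice %d", slice)) +
    ggplot2::theme_minimal()
}
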