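#' Construct a CT volume
#'
#' A CT volume is a 3-D grid of attenuation values in Hounsfield Units (HU;
#' air about -1000, water 0) together with its voxel geometry. Arrays are
#' indexed `(y, x, z)` with the longitudinal stem axis third.
#'
#' @param voxels numeric 3-D array of HU values, dim `(y, x, z)`.
#' @param pixel_spacing in-plane voxel size in mm, `c(y, x)`; a single value
#'   is recycled.
#' @param slice_thickness longitudinal voxel size in mm.
#' @param meta named list of free-form metadata (scanner, kVp, batch id).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_thickness, meta = list()) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  slice_thickness <- as.numeric(slice_thickness)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0)
    stop("voxel spacing must be positive")
  structure(list(voxels = voxels, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels (y, x, z)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing %.3g x %.3g mm, slice thickness %.3g mm\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_thickness))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# voxel volume in mm^3
voxel_volume_mm3 <- function(x) {
  prod(x$pixel_spacing) * x$slice_thickness
}

#' Intensity normalization parameters
#'
#' Offset correction and scaling used before the decay classifier: a
#' normalized value is `clip((HU + offset_hu) / factor_hu, 0, 1)`. The
#' defaults (offset +1000 HU so air maps to 0, factor 2500 HU) make the
#' upper bound 1 correspond to 1500 HU, i.e. 250% of water attenuation.
#'
#' @param offset_hu HU added before scaling (default +1000, air -> 0).
#' @param factor_hu positive divisor in HU (default 2500).
#' @return An object of class `normalization_params`.
#' @export
normalization_params <- function(offset_hu = 1000, factor_hu = 2500) {
  if (factor_hu <= 0) stop("factor_hu must be positive")
  structure(list(offset_hu = offset_hu, factor_hu = factor_hu),
            class = "normalization_params")
}

#' Normalize a CT volume to [0, 1]
#'
#' @param vol a [ct_volume()].
#' @param params a [normalization_params()].
#' @return An object of class `normalized_volume`: list with `values`
#'   (array in \[0, 1\]), `params`, and the voxel geometry of `vol`.
#' @export
normalize_volume <- function(vol, params = normalization_params()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(params, "normalization_params"))
  v <- (vol$voxels + params$offset_hu) / params$factor_hu
  v[v < 0] <- 0
  v[v > 1] <- 1
  structure(list(values = v, params = params,
                 pixel_spacing = vol$pixel_spacing,
                 slice_thickness = vol$slice_thickness),
            class = "normalized_volume")
}

#' Invert the normalization back to Hounsfield Units
#'
#' Exact inside the unclipped HU range `[-offset, factor - offset]`.
#'
#' @param norm a `normalized_volume` (or plain numeric values with `params`).
#' @param params normalization parameters; taken from `norm` when missing.
#' @return HU values with the shape of the input.
#' @export
denormalize <- function(norm, params = NULL) {
  if (inherits(norm, "normalized_volume")) {
    params <- norm$params
    norm <- norm$values
  }
  if (is.null(params)) stop("params required for plain numeric input")
  norm * params$factor_hu - params$offset_hu
}

#' Relative attenuation as percent of water
#'
#' Converts a normalized value back to HU and then to attenuation relative
#' to water: `100 * (1 + HU / 1000)`. With default parameters the upper
#' bound 1.0 corresponds to 250% of water attenuation and 0.0 to air (0%).
#'
#' @param norm_value normalized value(s) in \[0, 1\].
#' @param params a [normalization_params()].
#' @return percent of water attenuation.
#' @export
relative_attenuation_percent <- function(norm_value,
                                         params = normalization_params()) {
  if (any(norm_value < 0 | norm_value > 1))
    stop("norm_value must lie in [0, 1]")
  hu <- norm_value * params$factor_hu - params$offset_hu
  100 * (1 + hu / 1000)
}

#' Remove the scanner bed from a CT volume
#'
#' The bearing area (patient table) of a CT scanner appears as a horizontal
#' high-opacity band below the log, constant across slices. It is located on
#' the slice-averaged image as the topmost image row in which a large
#' fraction of pixels exceeds a characteristic opacity level; that row and
#' everything below it is replaced by air. Rows are indexed top-to-bottom,
#' so "below" means larger row index.
#'
#' @param vol a [ct_volume()].
#' @param air_hu HU value used for replacement (default -1000).
#' @param opacity_hu opacity level characteristic of the synthetic table
#'   surface (default 200 HU, well above any wood).
#' @param min_coverage minimum fraction of columns in a row that must exceed
#'   `opacity_hu` for the row to count as table (default 0.5).
#' @return A `ct_volume`; unchanged (with a message) when no table is found.
#' @export
remove_table <- function(vol, air_hu = -1000, opacity_hu = 200,
                         min_coverage = 0.5) {
  stopifnot(inherits(vol, "ct_volume"))
  avg <- apply(vol$voxels, c(1L, 2L), mean)
  coverage <- rowMeans(avg > opacity_hu)
  hit <- which(coverage >= min_coverage)
  if (length(hit) == 0L) {
    message("remove_table: no table detected, volume unchanged")
    return(vol)
  }
  r <- min(hit)
  vol$voxels[r:dim(vol$voxels)[1L], , ] <- air_hu
  vol$meta$table_row <- r
  vol
}
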