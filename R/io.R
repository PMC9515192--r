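#' Read a CT volume
#'
#' Supported containers: a DICOM series directory (uncompressed explicit-VR
#' little-endian, one file per slice), NIfTI (`.nii`/`.nii.gz`), or a
#' multi-page TIFF stack with a JSON sidecar (`<file>.json`) holding
#' `pixel_spacing_mm`, `slice_thickness_mm` and the affine HU scaling.
#' Rescale slope/intercept are applied so returned values are Hounsfield
#' Units.
#'
#' @param path file or directory path.
#' @param format one of `"auto"`, `"dicom_dir"`, `"nifti"`, `"tiff_stack"`.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path, format = c("auto", "dicom_dir", "nifti",
                                            "tiff_stack")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto") format <- .guess_format(path)
  switch(format,
    dicom_dir = read_dicom_dir(path),
    nifti = .read_nifti_volume(path),
    tiff_stack = .read_tiff_stack(path)
  )
}

#' Write a CT volume
#'
#' @param vol a [ct_volume()].
#' @param path output file (NIfTI, TIFF) or directory (DICOM series).
#' @param format one of `"nifti"`, `"tiff_stack"`, `"dicom_dir"`.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path,
                            format = c("nifti", "tiff_stack", "dicom_dir")) {
  stopifnot(inherits(vol, "ct_volume"))
  format <- match.arg(format)
  switch(format,
    nifti = .write_nifti(vol$voxels, path, vol$pixel_spacing,
                         vol$slice_thickness),
    tiff_stack = .write_tiff_stack(vol, path),
    dicom_dir = write_dicom_dir(vol, path)
  )
  invisible(path)
}

.guess_format <- function(path) {
  if (dir.exists(path)) return("dicom_dir")
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  if (grepl("\\.tiff?$", path)) return("tiff_stack")
  stop("cannot guess format of ", path, "; pass format explicitly")
}

# NIfTI stores (i, j, k) = (x, y, z); internal arrays are (y, x, z).
.write_nifti <- function(arr, path, pixel_spacing, slice_thickness,
                         datatype = "double") {
  img <- RNifti::asNifti(aperm(arr, c(2L, 1L, 3L)))
  RNifti::pixdim(img) <- c(pixel_spacing[2L], pixel_spacing[1L],
                           slice_thickness)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

.read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  vox <- aperm(as.array(img), c(2L, 1L, 3L))
  ct_volume(vox, pixel_spacing = c(pd[2L], pd[1L]), slice_thickness = pd[3L],
            meta = list(format = "nifti"))
}

.read_nifti_array <- function(path) {
  aperm(as.array(RNifti::readNifti(path)), c(2L, 1L, 3L))
}

.sidecar_path <- function(path) paste0(path, ".json")

# TIFF pages hold 32-bit floats in [0, 1]; the affine back to HU lives in
# the sidecar.
.write_tiff_stack <- function(vol, path) {
  lo <- min(vol$voxels)
  rng <- max(vol$voxels) - lo
  if (rng == 0) rng <- 1
  pages <- lapply(seq_len(dim(vol$voxels)[3L]), function(k) {
    (vol$voxels[, , k] - lo) / rng
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_spacing_mm = vol$pixel_spacing,
         slice_thickness_mm = vol$slice_thickness,
         hu_offset = lo, hu_range = rng),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_tiff_stack <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side))
    stop("tiff_stack requires a spacing sidecar at ", side)
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vox <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]]
  vox <- vox * sc$hu_range + sc$hu_offset
  ct_volume(vox, pixel_spacing = sc$pixel_spacing_mm,
            slice_thickness = sc$slice_thickness_mm,
            meta = list(format = "tiff_stack"))
}

#' Write a label volume
#'
#' Stores the integer class grid as NIfTI (int16) plus a JSON code map next
#' to it (`<file>.codes.json`).
#'
#' @param labels a `label_volume` (see [generate_phantom()]).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  .write_nifti(labels$classes, path, labels$pixel_spacing,
               labels$slice_thickness, datatype = "int16")
  jsonlite::write_json(as.list(label_codes()), paste0(path, ".codes.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#' @param path the `.nii`/`.nii.gz` path.
#' @return A `label_volume`.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(2L, 1L, 3L))
  storage.mode(arr) <- "integer"
  label_volume(arr, pixel_spacing = c(pd[2L], pd[1L]),
               slice_thickness = pd[3L])
}
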