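# Thin R wrappers around the compiled voxel kernels. All take/return logical
# or numeric arrays with dim (y, x, z); connectivity is 26/6 in 3-D and 8/4
# within a slice.

label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 6L, 8L, 26L))
  d <- dim3(mask)
  lab <- cc_label_cpp(as.logical(mask), d, as.integer(connectivity))
  array(lab, dim = d)
}

binary_dilate <- function(mask, radius) {
  d <- dim3(mask)
  radius <- rep_len(as.integer(radius), 3L)
  array(box_dilate_cpp(as.logical(mask), d, radius), dim = d)
}

binary_erode <- function(mask, radius) {
  !binary_dilate(!mask, radius)
}

binary_open <- function(mask, radius) {
  binary_dilate(binary_erode(mask, radius), radius)
}

binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

# Exact in-plane Euclidean distance (voxel units) of TRUE voxels to the
# nearest FALSE voxel, computed per slice.
edt_slicewise <- function(mask) {
  d <- dim3(mask)
  array(sqrt(edt2d_slicewise_cpp(as.logical(mask), d)), dim = d)
}

# Fill in-plane holes: background components (4-connected, per slice) not
# touching the slice border are converted to foreground.
fill_holes_slicewise <- function(mask) {
  d <- dim3(mask)
  lab <- label_components(!mask, connectivity = 4L)
  border <- array(FALSE, d)
  border[c(1L, d[1L]), , ] <- TRUE
  border[, c(1L, d[2L]), ] <- TRUE
  outside <- unique(lab[border & !mask])
  hole <- !mask & !(lab %in% outside)
  mask | hole
}

# Two-threshold hysteresis. Bright mode keeps voxels >= low connected to a
# seed >= high; dark mode keeps voxels <= high connected to a seed <= low.
hysteresis_mask <- function(values, low, high, dark = FALSE,
                            connectivity = 26L) {
  stopifnot(low < high)
  if (dark) {
    keep <- values <= high
    seed <- values <= low
  } else {
    keep <- values >= low
    seed <- values >= high
  }
  if (!any(seed)) return(array(FALSE, dim3(values)))
  lab <- label_components(keep, connectivity)
  hit <- unique(lab[seed])
  hit <- hit[hit > 0L]
  array(lab %in% hit, dim = dim3(values))
}

dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) d <- c(d, 1L)
  as.integer(d)
}
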