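# Minimal DICOM support: explicit-VR little-endian, uncompressed,
# single-frame 16-bit CT slices, one file per slice. This covers
# scanner-style series export/import for this package's volumes; it is not
# a general DICOM implementation (no sequences, no compressed transfer
# syntaxes, no implicit VR).

.dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dicom_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.dicom_element <- function(group, elem, vr, value_bytes) {
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% .dicom_long_vrs) {
    c(hdr, as.raw(c(0, 0)), .u32(length(value_bytes)), value_bytes)
  } else {
    c(hdr, .u16(length(value_bytes)), value_bytes)
  }
}

.dicom_str <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  .dicom_element(group, elem, vr, .dicom_pad(charToRaw(s), pad))
}

.dicom_us <- function(group, elem, v) .dicom_element(group, elem, "US", .u16(v))

write_dicom_slice <- function(path, pixels, instance, pixel_spacing,
                              slice_thickness, z_pos) {
  # pixels: integer matrix (y rows, x cols) of HU; stored row-major as int16
  stopifnot(all(pixels >= -32768 & pixels <= 32767))
  pix <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  body <- c(
    .dicom_str(0x0008, 0x0060, "CS", "CT"),
    .dicom_str(0x0018, 0x0050, "DS", format(slice_thickness)),
    .dicom_str(0x0020, 0x0013, "IS", format(instance)),
    .dicom_str(0x0020, 0x1041, "DS", format(z_pos)),
    .dicom_us(0x0028, 0x0002, 1L),
    .dicom_us(0x0028, 0x0010, nrow(pixels)),
    .dicom_us(0x0028, 0x0011, ncol(pixels)),
    .dicom_str(0x0028, 0x0030, "DS",
               paste(format(pixel_spacing[1]), format(pixel_spacing[2]),
                     sep = "\\")),
    .dicom_us(0x0028, 0x0100, 16L),
    .dicom_us(0x0028, 0x0101, 16L),
    .dicom_us(0x0028, 0x0102, 15L),
    .dicom_us(0x0028, 0x0103, 1L),
    .dicom_str(0x0028, 0x1052, "DS", "0"),
    .dicom_str(0x0028, 0x1053, "DS", "1"),
    .dicom_element(0x7FE0, 0x0010, "OW", pix)
  )
  meta <- .dicom_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(.dicom_element(0x0002, 0x0000, "UL", .u32(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_dicom_slice <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  p <- 133L
  rd16 <- function(at) as.integer(r[at]) + 256L * as.integer(r[at + 1L])
  rd32 <- function(at) {
    sum(as.numeric(r[at + 0:3]) * c(1, 256, 65536, 16777216))
  }
  tags <- list()
  while (p + 7L <= length(r)) {
    group <- rd16(p); elem <- rd16(p + 2L)
    vr <- rawToChar(r[(p + 4L):(p + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt DICOM not supported: ", path)
    if (vr %in% .dicom_long_vrs) {
      len <- rd32(p + 8L); vstart <- p + 12L
    } else {
      len <- rd16(p + 6L); vstart <- p + 8L
    }
    val <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, bytes = val)
    p <- vstart + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  getstr <- function(key) {
    if (is.null(tags[[key]])) return(NA_character_)
    b <- tags[[key]]$bytes
    trimws(rawToChar(b[b != as.raw(0)]))
  }
  getus <- function(key) {
    b <- tags[[key]]$bytes
    as.integer(b[1]) + 256L * as.integer(b[2])
  }
  rows <- getus("0028,0010"); cols <- getus("0028,0011")
  slope <- as.numeric(getstr("0028,1053"))
  intercept <- as.numeric(getstr("0028,1052"))
  spacing <- as.numeric(strsplit(getstr("0028,0030"), "\\\\")[[1]])
  pix <- readBin(tags[["7FE0,0010"]]$bytes, "integer", n = rows * cols,
                 size = 2, signed = TRUE, endian = "little")
  m <- t(matrix(pix, nrow = cols, ncol = rows))
  list(pixels = m * slope + intercept,
       instance = as.integer(getstr("0020,0013")),
       pixel_spacing = spacing,
       slice_thickness = as.numeric(getstr("0018,0050")))
}

read_dicom_dir <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", path)
  slices <- lapply(files, read_dicom_slice)
  ord <- order(vapply(slices, `[[`, integer(1), "instance"))
  slices <- slices[ord]
  shapes <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice geometry in DICOM series")
  sp <- slices[[1]]$pixel_spacing
  vox <- array(0, dim = c(shapes[1, 1], shapes[2, 1], length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$pixels
  ct_volume(vox, pixel_spacing = sp,
            slice_thickness = slices[[1]]$slice_thickness,
            meta = list(format = "dicom_dir", n_files = length(slices)))
}

write_dicom_dir <- function(vol, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  vox <- round(vol$voxels)
  nz <- dim(vox)[3L]
  for (k in seq_len(nz)) {
    write_dicom_slice(file.path(path, sprintf("slice_%04d.dcm", k)),
                      vox[, , k], instance = k,
                      pixel_spacing = vol$pixel_spacing,
                      slice_thickness = vol$slice_thickness,
                      z_pos = (k - 1) * vol$slice_thickness)
  }
  invisible(path)
}
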