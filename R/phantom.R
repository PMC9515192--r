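#' Voxel class codes
#'
#' Integer codes used in label volumes, covering the tissue classes, the
#' insect-generated cavities, the two main false-positive sources
#' (shrinkage cracks, drill holes from increment sampling), larvae, and
#' fungal decay.
#'
#' @return Named integer vector.
#' @export
label_codes <- function() {
  c(background = 0L, bark = 1L, wood = 2L, tunnel_bark = 3L,
    tunnel_wood = 4L, crack = 5L, drilling = 6L, larva = 7L, decay = 8L)
}

#' Construct a label volume
#'
#' @param classes integer 3-D array of class codes (see [label_codes()]).
#' @param pixel_spacing in-plane voxel size in mm, `c(y, x)`.
#' @param slice_thickness longitudinal voxel size in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(classes, pixel_spacing, slice_thickness) {
  if (length(dim(classes)) != 3L) stop("classes must be a 3-D array")
  if (!all(classes %in% label_codes())) stop("unknown class codes present")
  storage.mode(classes) <- "integer"
  structure(list(classes = classes,
                 pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
                 slice_thickness = as.numeric(slice_thickness)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$classes)
  cat(sprintf("label_volume: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- table(factor(x$classes, levels = label_codes(),
                      labels = names(label_codes())))
  print(tab[tab > 0])
  invisible(x)
}

#' Parameters of a synthetic log phantom
#'
#' Describes a cylindrical Norway-spruce-like log: bark annulus, concentric
#' early/latewood growth rings, tortuous air-filled beetle galleries,
#' radial shrinkage cracks, straight drill holes, bright larvae attached to
#' galleries, and fungal-decay regions that are darker or brighter than
#' sound wood, optionally with the perpendicular (cuboidal) crack systems
#' typical of brown rot. Only the ordering of the HU palette is meaningful
#' (air < dark decay < earlywood < latewood < larva); the absolute defaults
#' are plausible for moist spruce deadwood.
#'
#' @param length_slices number of axial slices.
#' @param radius_mm outer log radius (bark included).
#' @param bark_thickness_mm bark annulus thickness; 0 for no bark.
#' @param ring_period_mm growth-ring period.
#' @param latewood_fraction fraction of each ring that is dense latewood.
#' @param hu_earlywood,hu_latewood,hu_bark,hu_air,hu_larva HU palette.
#' @param pixel_spacing_mm,slice_thickness_mm voxel geometry.
#' @param margin_mm air margin around the log.
#' @param tunnel_count number of beetle galleries.
#' @param tunnel_radius_mm length-2 range of gallery radii.
#' @param tunnel_length_mm length-2 range of gallery arc lengths.
#' @param tunnel_tortuosity direction-noise weight of the correlated random
#'   walk in (0, 1); larger is more tortuous.
#' @param tunnel_zone `"wood"` (wood-borer style, penetrates sapwood),
#'   `"bark"` (bark-beetle style, confined to the bark/cambium shell) or
#'   `"mixed"`.
#' @param crack_count number of radial shrinkage cracks.
#' @param crack_max_depth maximum crack depth as a fraction of the radius.
#' @param drilling_count number of straight drill holes (e.g. increment
#'   borer samples), perpendicular to the stem axis.
#' @param drilling_radius_mm drill hole radius (8 mm auger -> 4 mm).
#' @param larva_count number of larvae, each attached to a gallery.
#' @param larva_length_mm larva length along its gallery.
#' @param decay_patch_count number of fungal decay regions.
#' @param decay_contrast_hu signed HU contrasts sampled per patch; negative
#'   values give darker (degraded) wood, positive brighter (moist) wood.
#' @param decay_crack_system add perpendicular brown-rot crack systems
#'   inside decay regions.
#' @param decay_radius_mm length-2 range of in-plane decay patch semi-axes.
#' @param noise_sigma_hu standard deviation of additive Gaussian HU noise.
#' @return An object of class `log_phantom_spec`.
#' @export
log_phantom_spec <- function(length_slices = 60,
                             radius_mm = 80,
                             bark_thickness_mm = 6,
                             ring_period_mm = 3,
                             latewood_fraction = 0.3,
                             hu_earlywood = -400,
                             hu_latewood = -100,
                             hu_bark = -500,
                             hu_air = -1000,
                             hu_larva = 60,
                             pixel_spacing_mm = 0.75,
                             slice_thickness_mm = 2,
                             margin_mm = 10,
                             tunnel_count = 3,
                             tunnel_radius_mm = c(1.5, 3),
                             tunnel_length_mm = c(80, 160),
                             tunnel_tortuosity = 0.4,
                             tunnel_zone = c("wood", "bark", "mixed"),
                             crack_count = 0,
                             crack_max_depth = 0.6,
                             drilling_count = 0,
                             drilling_radius_mm = 4,
                             larva_count = 0,
                             larva_length_mm = 18,
                             decay_patch_count = 0,
                             decay_contrast_hu = c(-150, 150),
                             decay_crack_system = TRUE,
                             decay_radius_mm = c(6, 16),
                             noise_sigma_hu = 10) {
  tunnel_zone <- match.arg(tunnel_zone)
  spec <- as.list(environment())
  if (radius_mm <= 0 || bark_thickness_mm < 0 || ring_period_mm <= 0)
    stop("radii and thicknesses must be positive")
  if (bark_thickness_mm >= radius_mm)
    stop("bark_thickness_mm must be smaller than radius_mm")
  if (any(c(tunnel_count, crack_count, drilling_count, larva_count,
            decay_patch_count) < 0))
    stop("structure counts must be non-negative")
  if (max(tunnel_radius_mm) >= radius_mm)
    stop("tunnel radius must be smaller than the log radius")
  class(spec) <- "log_phantom_spec"
  spec
}

# ---------------------------------------------------------------------------
# generator
# ---------------------------------------------------------------------------

#' Generate a synthetic labeled log phantom
#'
#' Carves the structures described by a [log_phantom_spec()] into a HU
#' volume and records every structure in a paired label volume before noise
#' is added. Deterministic given `(spec, seed)`.
#'
#' @param spec a [log_phantom_spec()].
#' @param seed integer seed.
#' @return List with `volume` (a [ct_volume()]) and `labels`
#'   (a `label_volume`).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "log_phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sp <- spec$pixel_spacing_mm
  st <- spec$slice_thickness_mm
  half <- ceiling((spec$radius_mm + spec$margin_mm) / sp)
  ny <- nx <- 2L * half + 1L
  nz <- as.integer(spec$length_slices)
  cy <- cx <- half + 1L
  codes <- label_codes()

  yy <- matrix(seq_len(ny) - cy, ny, nx)
  xx <- matrix(rep(seq_len(nx) - cx, each = ny), ny, nx)
  rmm <- sqrt(yy^2 + xx^2) * sp
  theta <- atan2(yy, xx) %% (2 * pi)

  R <- spec$radius_mm
  bt <- spec$bark_thickness_mm
  lab2 <- matrix(codes["background"], ny, nx)
  lab2[rmm <= R] <- codes["bark"]
  lab2[rmm <= R - bt] <- codes["wood"]
  hu2 <- matrix(spec$hu_air, ny, nx)
  hu2[lab2 == codes["bark"]] <- spec$hu_bark
  inwood <- lab2 == codes["wood"]
  phase <- ((R - bt - rmm) %% spec$ring_period_mm) / spec$ring_period_mm
  late <- inwood & phase >= (1 - spec$latewood_fraction)
  hu2[inwood] <- spec$hu_earlywood
  hu2[late] <- spec$hu_latewood

  vox <- array(rep(hu2, nz), dim = c(ny, nx, nz))
  lab <- array(rep(lab2, nz), dim = c(ny, nx, nz))
  storage.mode(lab) <- "integer"
  lin <- function(y, x, z) y + ny * (x - 1L) + ny * nx * (z - 1L)

  # --- fungal decay regions -------------------------------------------------
  for (i in seq_len(spec$decay_patch_count)) {
    contrast <- sample(spec$decay_contrast_hu, 1L)
    a <- runif(2, spec$decay_radius_mm[1], spec$decay_radius_mm[2])
    az <- runif(1, 1.2, 2.5) * max(a)            # fungi spread longitudinally
    rc <- runif(1, 0, max(R - bt - max(a) - 2, 1))
    tc <- runif(1, 0, 2 * pi)
    y0 <- cy + rc * sin(tc) / sp
    x0 <- cx + rc * cos(tc) / sp
    z0 <- runif(1, 1, nz)
    ys <- pmax(1L, floor(y0 - a[1] / sp)):pmin(ny, ceiling(y0 + a[1] / sp))
    xs <- pmax(1L, floor(x0 - a[2] / sp)):pmin(nx, ceiling(x0 + a[2] / sp))
    zs <- pmax(1L, floor(z0 - az / st)):pmin(nz, ceiling(z0 + az / st))
    gy <- ((ys - y0) * sp / a[1])^2
    gx <- ((xs - x0) * sp / a[2])^2
    gz <- ((zs - z0) * st / az)^2
    inside <- outer(outer(gy, gx, `+`), gz, `+`) <= 1
    sub <- lab[ys, xs, zs]
    sel <- inside & sub == codes["wood"]
    vsub <- vox[ys, xs, zs]
    vsub[sel] <- vsub[sel] + contrast
    if (isTRUE(spec$decay_crack_system)) {
      # perpendicular (cuboidal) crack planes typical of brown rot
      step <- max(3L, round(6 / sp * 0.75))
      gyi <- slice.index(inside, 1L); gxi <- slice.index(inside, 2L)
      planes <- (gyi %% step == 0L) | (gxi %% step == 0L)
      vsub[sel & planes] <- spec$hu_air
    }
    sub[sel] <- codes["decay"]
    vox[ys, xs, zs] <- vsub
    lab[ys, xs, zs] <- sub
  }

  # --- beetle galleries -----------------------------------------------------
  tunnel_ends <- list()
  for (i in seq_len(spec$tunnel_count)) {
    rt <- runif(1, spec$tunnel_radius_mm[1], spec$tunnel_radius_mm[2])
    len <- runif(1, spec$tunnel_length_mm[1], spec$tunnel_length_mm[2])
    zone <- spec$tunnel_zone
    if (zone == "bark") rt <- min(rt, max(bt / 2 - sp, sp))
    path <- .tunnel_walk(len, rt, zone, R, bt, nz, sp, st, spec$tunnel_tortuosity)
    idx <- .carve_tube(path, rt, ny, nx, nz, cy, cx, sp, st)
    if (length(idx)) {
      old_lab <- lab[idx]
      keep <- old_lab != codes["background"]
      idx <- idx[keep]; old_lab <- old_lab[keep]
      vox[idx] <- spec$hu_air
      lab[idx] <- ifelse(old_lab == codes["bark"] |
                           old_lab == codes["tunnel_bark"],
                         codes["tunnel_bark"], codes["tunnel_wood"])
      tunnel_ends[[length(tunnel_ends) + 1L]] <-
        list(pos = path[nrow(path), ], dir = path[nrow(path), ] -
               path[max(1L, nrow(path) - 5L), ])
    }
  }

  # --- larvae (bright, touching a gallery) ----------------------------------
  if (spec$larva_count > 0 && length(tunnel_ends) > 0) {
    for (i in seq_len(spec$larva_count)) {
      end <- tunnel_ends[[1L + (i - 1L) %% length(tunnel_ends)]]
      axis <- which.max(abs(end$dir[1:2]))      # in-plane long axis
      semi <- c(2.5, 2.5, 2.5)
      semi[axis] <- spec$larva_length_mm / 2
      idx <- .carve_ellipsoid(end$pos, semi, ny, nx, nz, sp, st)
      if (length(idx)) {
        keep <- lab[idx] != codes["background"]
        idx <- idx[keep]
        vox[idx] <- spec$hu_larva
        lab[idx] <- codes["larva"]
      }
    }
  }

  # --- radial shrinkage cracks ----------------------------------------------
  for (i in seq_len(spec$crack_count)) {
    tc <- runif(1, 0, 2 * pi)
    depth <- runif(1, 0.25, spec$crack_max_depth)
    wmm <- runif(1, 1, 2) * sp
    z0 <- sample.int(nz, 1L)
    zlen <- max(3L, round(runif(1, 0.3, 0.8) * nz))
    zs <- z0:min(nz, z0 + zlen - 1L)
    dang <- (theta - tc + pi) %% (2 * pi) - pi
    sel2 <- abs(rmm * sin(dang)) <= wmm / 2 & abs(dang) < pi / 2 &
      rmm <= R & rmm >= R * (1 - depth)
    idx2 <- which(sel2)
    if (length(idx2)) {
      for (z in zs) {
        idx <- idx2 + ny * nx * (z - 1L)
        keep <- lab[idx] %in% codes[c("bark", "wood", "decay")]
        vox[idx[keep]] <- spec$hu_air
        lab[idx[keep]] <- codes["crack"]
      }
    }
  }

  # --- drill holes (straight, perpendicular to the stem axis) ---------------
  for (i in seq_len(spec$drilling_count)) {
    tc <- runif(1, 0, 2 * pi)
    z0 <- sample.int(nz, 1L)
    depth <- runif(1, 0.4, 0.7) * R
    rd <- spec$drilling_radius_mm
    ey <- R * sin(tc) / sp; ex <- R * cos(tc) / sp   # entry point (voxels)
    uy <- -sin(tc); ux <- -cos(tc)                    # inward direction
    py <- (yy - ey) * sp; px <- (xx - ex) * sp
    t_ <- py * uy + px * ux
    perp2 <- (py - t_ * uy)^2 + (px - t_ * ux)^2
    zs <- max(1L, z0 - ceiling(rd / st)):min(nz, z0 + ceiling(rd / st))
    for (z in zs) {
      dz2 <- ((z - z0) * st)^2
      sel2 <- t_ >= 0 & t_ <= depth & (perp2 + dz2) <= rd^2
      idx <- which(sel2) + ny * nx * (z - 1L)
      keep <- lab[idx] %in% codes[c("bark", "wood", "decay")]
      vox[idx[keep]] <- spec$hu_air
      lab[idx[keep]] <- codes["drilling"]
    }
  }

  if (spec$noise_sigma_hu > 0)
    vox <- vox + array(rnorm(length(vox), 0, spec$noise_sigma_hu), dim(vox))

  list(volume = ct_volume(vox, pixel_spacing = sp, slice_thickness = st,
                          meta = list(phantom_seed = seed)),
       labels = label_volume(lab, pixel_spacing = sp, slice_thickness = st))
}

# correlated random walk gallery centerline; returns matrix of voxel coords
# (y, x, z), one row per step of ~1 in-plane voxel
.tunnel_walk <- function(length_mm, radius_mm, zone, R, bt, nz, sp, st,
                         tortuosity) {
  n <- max(10L, round(length_mm / sp))
  t0 <- runif(1, 0, 2 * pi)
  if (zone == "bark") {
    r0 <- R - bt / 2
  } else {
    r0 <- R - bt - radius_mm - sp      # just under the bark
  }
  pos <- c(r0 * sin(t0), r0 * cos(t0), runif(1, 0.2, 0.8) * nz * st)
  d <- c(-sin(t0), -cos(t0), 0) + rnorm(3, 0, 0.2)
  d <- d / sqrt(sum(d^2))
  out <- matrix(0, n, 3)
  rmin <- radius_mm + sp
  for (k in seq_len(n)) {
    d <- (1 - tortuosity) * d + tortuosity * rnorm(3)
    d <- d / sqrt(sum(d^2))
    cand <- pos + d * sp
    r <- sqrt(cand[1]^2 + cand[2]^2)
    if (zone == "bark") {
      lo <- R - bt + radius_mm; hi <- R - radius_mm
      if (r < lo || r > hi) {            # reflect radially into the shell
        u <- cand[1:2] / max(r, 1e-9)
        rr <- min(max(r, lo), hi)
        cand[1:2] <- u * rr
        d <- d - 2 * sum(d[1:2] * u) * c(u, 0)[1:3][1:3]
        d <- d / sqrt(sum(d^2))
      }
    } else {
      hi <- if (zone == "mixed") R - radius_mm else R - bt - radius_mm
      if (r > hi || r < rmin) {
        u <- cand[1:2] / max(r, 1e-9)
        cand[1:2] <- u * min(max(r, rmin), hi)
        d[1:2] <- d[1:2] - 2 * sum(d[1:2] * u) * u
        d <- d / sqrt(sum(d^2))
      }
    }
    cand[3] <- min(max(cand[3], radius_mm + st), nz * st - radius_mm - st)
    pos <- cand
    out[k, ] <- pos
  }
  out
}

# mark all voxels within radius_mm of any path point; path in mm (y, x, z
# relative to axis center), returns linear indices
.carve_tube <- function(path, radius_mm, ny, nx, nz, cy, cx, sp, st) {
  oy <- seq(-ceiling(radius_mm / sp), ceiling(radius_mm / sp))
  oz <- seq(-ceiling(radius_mm / st), ceiling(radius_mm / st))
  off <- expand.grid(dy = oy, dx = oy, dz = oz)
  off <- off[(off$dy * sp)^2 + (off$dx * sp)^2 + (off$dz * st)^2 <=
               radius_mm^2, , drop = FALSE]
  py <- round(path[, 1] / sp) + cy
  px <- round(path[, 2] / sp) + cx
  pz <- round(path[, 3] / st)
  y <- rep(py, each = nrow(off)) + off$dy
  x <- rep(px, each = nrow(off)) + off$dx
  z <- rep(pz, each = nrow(off)) + off$dz
  ok <- y >= 1 & y <= ny & x >= 1 & x <= nx & z >= 1 & z <= nz
  unique(y[ok] + ny * (x[ok] - 1) + ny * nx * (z[ok] - 1))
}

.carve_ellipsoid <- function(center_mm, semi_mm, ny, nx, nz, sp, st) {
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  y0 <- center_mm[1] / sp + cy
  x0 <- center_mm[2] / sp + cx
  z0 <- center_mm[3] / st
  ys <- max(1, floor(y0 - semi_mm[1] / sp)):min(ny, ceiling(y0 + semi_mm[1] / sp))
  xs <- max(1, floor(x0 - semi_mm[2] / sp)):min(nx, ceiling(x0 + semi_mm[2] / sp))
  zs <- max(1, floor(z0 - semi_mm[3] / st)):min(nz, ceiling(z0 + semi_mm[3] / st))
  g <- expand.grid(y = ys, x = xs, z = zs)
  d <- ((g$y - y0) * sp / semi_mm[1])^2 + ((g$x - x0) * sp / semi_mm[2])^2 +
    ((g$z - z0) * st / semi_mm[3])^2
  g <- g[d <= 1, , drop = FALSE]
  g$y + ny * (g$x - 1) + ny * nx * (g$z - 1)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---------------------------------------------------------------------------
# ground truth bookkeeping
# ---------------------------------------------------------------------------

#' Exact volume summary from a label volume
#'
#' The ground-truth twin of [quantify_tunnel_volume()]: voxel counts per
#' class and relative volumes. Relative tunnel volume uses the denominator
#' bark + wood + tunnel voxels (+ larvae when counted); decay is relative
#' to wood + decay voxels.
#'
#' @param labels a `label_volume`.
#' @param include_larvae count larva voxels toward tunnel volume (larvae
#'   occupy excavated space); default `TRUE`.
#' @return An object of class `volume_summary`: list with `counts` (named
#'   voxel counts), `tunnel` (data.frame with compartments bark/wood/total:
#'   voxels, mm3, percent), `decay_percent`, `voxel_volume_mm3`.
#' @export
true_volume_summary <- function(labels, include_larvae = TRUE) {
  stopifnot(inherits(labels, "label_volume"))
  codes <- label_codes()
  counts <- vapply(codes, function(cd) sum(labels$classes == cd), numeric(1))
  names(counts) <- names(codes)
  vv <- prod(labels$pixel_spacing) * labels$slice_thickness
  .volume_summary_from_counts(counts, vv, include_larvae,
                              larva_compartment = "wood")
}

# shared between ground truth and pipeline output; larva_compartment says
# where larva voxels are credited when include_larvae
.volume_summary_from_counts <- function(counts, voxel_volume_mm3,
                                        include_larvae = TRUE,
                                        larva_compartment = "wood") {
  tb <- counts[["tunnel_bark"]]
  tw <- counts[["tunnel_wood"]]
  if (include_larvae) {
    if (larva_compartment == "bark") tb <- tb + counts[["larva"]]
    else tw <- tw + counts[["larva"]]
  }
  denom <- counts[["bark"]] + counts[["wood"]] + tb + tw
  pct <- function(x) if (denom > 0) 100 * x / denom else 0
  tunnel <- data.frame(
    compartment = c("bark", "wood", "total"),
    voxels = c(tb, tw, tb + tw),
    mm3 = c(tb, tw, tb + tw) * voxel_volume_mm3,
    percent = c(pct(tb), pct(tw), pct(tb + tw)),
    row.names = NULL)
  wood_denom <- counts[["wood"]] + counts[["decay"]]
  decay_percent <- if (wood_denom > 0) 100 * counts[["decay"]] / wood_denom else 0
  structure(list(counts = counts, tunnel = tunnel,
                 decay_percent = decay_percent,
                 voxel_volume_mm3 = voxel_volume_mm3),
            class = "volume_summary")
}

#' @export
print.volume_summary <- function(x, ...) {
  cat("volume_summary (voxel volume", format(x$voxel_volume_mm3),
      "mm^3)\n")
  print(x$tunnel, row.names = FALSE)
  cat(sprintf("decay: %.2f%% of wood\n", x$decay_percent))
  invisible(x)
}

#' Add a synthetic scanner bed to a phantom volume
#'
#' Inserts a horizontal high-opacity band (the "patient table") below the
#' log, constant across slices, for exercising [remove_table()].
#'
#' @param vol a [ct_volume()].
#' @param top_row first image row (from the top) occupied by the table.
#' @param thickness_vox table thickness in voxels.
#' @param table_hu opacity of the synthetic table surface.
#' @return The modified `ct_volume`.
#' @export
add_scanner_table <- function(vol, top_row, thickness_vox = 4L,
                              table_hu = 400) {
  stopifnot(inherits(vol, "ct_volume"))
  rows <- top_row:min(dim(vol$voxels)[1L], top_row + thickness_vox - 1L)
  vol$voxels[rows, , ] <- table_hu
  vol
}
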