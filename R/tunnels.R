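#' Hysteresis threshold parameters
#'
#' Two-threshold segmentation: voxels past the strong threshold seed the
#' mask, voxels past the weak threshold are kept only when 26-connected to
#' a seed. Thresholds are on the normalized \[0, 1\] scale (air 0,
#' water 0.4 with default normalization).
#'
#' @param low,high weak/strong thresholds, `0 <= low < high <= 1`.
#' @param closing_radius_vox radius of the binary closing applied after
#'   thresholding (0 disables).
#' @param min_component_vox components smaller than this are discarded.
#' @return An object of class `hysteresis_params`.
#' @export
hysteresis_params <- function(low = 0.12, high = 0.20,
                              closing_radius_vox = 1L,
                              min_component_vox = 64L) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("need 0 <= low < high <= 1")
  structure(list(low = low, high = high,
                 closing_radius_vox = as.integer(closing_radius_vox),
                 min_component_vox = as.integer(min_component_vox)),
            class = "hysteresis_params")
}

#' Geometry rules separating cracks and drill holes from beetle tunnels
#'
#' Connected cavity components are classified from shape descriptors:
#' shrinkage cracks are thin radially-aligned sheets reaching the log
#' surface; drill holes are straight tubes in a known radius band;
#' everything else is tagged as beetle tunnel.
#'
#' @param crack_planarity_min minimum sheet-likeness (ratio of the second
#'   to third principal axis length).
#' @param crack_alignment_min minimum |cos| between the sheet normal and
#'   the tangential direction (radial sheets have tangential normals).
#' @param drill_straightness_min minimum end-to-end / arc-length ratio of
#'   the component centerline for whole isolated components.
#' @param drill_core_straightness_min straightness gate applied to the
#'   deep-eroded core in the drill pre-pass (the core of a straight drill
#'   stays straight even when a gallery touches the hole; tortuous gallery
#'   cores fall well below this).
#' @param drill_core_min_vox minimum eroded-core size considered.
#' @param drill_min_length_mm minimum core length; drill holes run tens of
#'   mm into the log, eroded gallery fragments are short.
#' @param drill_radius_mm admissible drill radius band in mm.
#' @param open_radius_vox opening radius used to split thin sheets from
#'   thick tubes before component analysis.
#' @return An object of class `cavity_rules`.
#' @export
cavity_rules <- function(crack_planarity_min = 2.5,
                         crack_alignment_min = 0.6,
                         drill_straightness_min = 0.92,
                         drill_core_straightness_min = 0.85,
                         drill_core_min_vox = 50L,
                         drill_min_length_mm = 12,
                         drill_radius_mm = c(2.5, 6),
                         open_radius_vox = 1L) {
  structure(as.list(environment()), class = "cavity_rules")
}

#' Full configuration of the tunnel segmentation pipeline
#'
#' @param solid [hysteresis_params()] for wood/bark detection (bright).
#' @param dark `c(low, high)` hysteresis thresholds for air-filled
#'   cavities: seeds `<= low`, kept `<= high`.
#' @param hull_closing_vox in-plane closing radius used to span cavity and
#'   crack openings when building the solid hull.
#' @param bark_max_depth_mm deepest plausible bark, in mm.
#' @param bark_min_contrast minimum normalized intensity separation between
#'   the outer shell and the inner wood for a bark shell to be accepted
#'   (default 0.05, i.e. 125 HU — bark is about 190 HU darker than the
#'   early/latewood mix, growth-ring artifacts stay below 0.04).
#' @param larva_band normalized intensity band of larvae (moist tissue).
#' @param larva_size_vox admissible larva size range in voxels.
#' @param rules a [cavity_rules()].
#' @param include_larvae count larva voxels toward tunnel volume.
#' @return A list, class `tunnel_config`.
#' @export
tunnel_config <- function(solid = hysteresis_params(),
                          dark = c(low = 0.06, high = 0.12),
                          hull_closing_vox = 6L,
                          bark_max_depth_mm = 25,
                          bark_min_contrast = 0.05,
                          larva_band = c(0.40, 0.60),
                          larva_size_vox = c(30, 8000),
                          rules = cavity_rules(),
                          include_larvae = TRUE) {
  structure(as.list(environment()), class = "tunnel_config")
}

# ---------------------------------------------------------------------------

#' Detect the solid log (bark + wood)
#'
#' Hysteresis thresholding on the normalized volume, followed by a binary
#' closing and removal of small components.
#'
#' @param norm a `normalized_volume`.
#' @param params a [hysteresis_params()].
#' @return Logical 3-D mask.
#' @export
detect_solid <- function(norm, params = hysteresis_params()) {
  stopifnot(inherits(norm, "normalized_volume"))
  mask <- hysteresis_mask(norm$values, params$low, params$high)
  if (!any(mask)) stop("no log found")
  if (params$closing_radius_vox > 0)
    mask <- binary_close(mask, params$closing_radius_vox)
  if (params$min_component_vox > 1) {
    lab <- label_components(mask)
    sz <- tabulate(lab)
    keep <- which(sz >= params$min_component_vox)
    mask <- array(lab %in% keep, dim(mask))
  }
  if (!any(mask)) stop("no log found")
  mask
}

#' Split the solid into bark shell and inner wood
#'
#' The bark is the outer shell of the solid. Per slice, the in-plane
#' Euclidean depth from the log surface is computed on the hole-filled
#' hull; the radial intensity profile by depth is scanned for its largest
#' upward jump (bark is less attenuating than moist sapwood), which fixes
#' the shell depth; the boundary layer is then refined by intensity
#' (closer to the bark or the wood median).
#'
#' @param solid logical mask from [detect_solid()].
#' @param norm the `normalized_volume` it came from.
#' @param config a [tunnel_config()] (hull closing, bark depth/contrast).
#' @return An object of class `tissue_masks`: logical masks `background`,
#'   `bark`, `wood`, plus `hull`, `depth` (in-plane voxel depth),
#'   `region_bark`/`region_wood` (hull partition used for compartment
#'   assignment), per-slice `center` and `bark_depth_vox`.
#' @export
split_bark_wood <- function(solid, norm, config = tunnel_config()) {
  d <- dim(solid)
  sp <- norm$pixel_spacing[1L]
  h <- config$hull_closing_vox
  hull <- fill_holes_slicewise(binary_close(solid, c(h, h, 0L)))
  depth <- edt_slicewise(hull)
  maxd <- max(2L, ceiling(config$bark_max_depth_mm / sp))

  nz <- d[3L]
  zidx <- slice.index(solid, 3L)
  db <- ceiling(depth)
  sel <- solid & db >= 1 & db <= maxd
  grp <- db[sel] + (maxd + 1) * (zidx[sel] - 1)
  sums <- rowsum(norm$values[sel], grp)
  cnts <- rowsum(rep(1, sum(sel)), grp)
  prof <- matrix(NA_real_, maxd, nz)
  gid <- as.integer(rownames(sums))
  prof[cbind((gid - 1) %% (maxd + 1) + 1, (gid - 1) %/% (maxd + 1) + 1)] <-
    sums / cnts

  # change point maximizing the separation between the outer (bark) and
  # inner (wood) mean intensity; robust against growth-ring oscillation
  bark_depth <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    p <- prof[, z]
    ok <- which(!is.na(p))
    if (length(ok) < 4) next
    p <- p[seq_len(max(ok))]
    len <- length(p)
    score <- vapply(seq_len(len - 2L), function(dd) {
      mean(p[(dd + 1L):len], na.rm = TRUE) - mean(p[seq_len(dd)], na.rm = TRUE)
    }, numeric(1))
    j <- which.max(score)
    if (length(j) && !is.na(score[j]) && score[j] >= config$bark_min_contrast)
      bark_depth[z] <- j
  }

  ds <- bark_depth
  ds[is.na(ds)] <- 0
  thr <- array(rep(ds, each = d[1L] * d[2L]), d)
  region_bark <- hull & depth <= thr & thr > 0
  region_wood <- hull & !region_bark
  bark <- solid & region_bark
  wood <- solid & !bark

  # intensity refinement of the boundary layer
  if (any(bark) && any(wood)) {
    mb <- median(norm$values[bark])
    mw <- median(norm$values[wood])
    if (mw > mb) {
      edge <- solid & depth > pmax(thr - 1, 0) & depth <= thr + 1 & thr > 0
      to_bark <- edge & norm$values <= (mb + mw) / 2
      bark <- (bark & !edge) | to_bark
      wood <- solid & !bark
    }
  }

  # per-slice hull centroid
  n_per <- rowsum(as.numeric(hull), as.vector(zidx))
  cy <- rowsum(as.numeric(slice.index(hull, 1L) * hull), as.vector(zidx)) / pmax(n_per, 1)
  cx <- rowsum(as.numeric(slice.index(hull, 2L) * hull), as.vector(zidx)) / pmax(n_per, 1)

  structure(list(background = !hull, bark = bark, wood = wood, hull = hull,
                 depth = depth, region_bark = region_bark,
                 region_wood = region_wood,
                 center = cbind(y = as.numeric(cy), x = as.numeric(cx)),
                 bark_depth_vox = ds,
                 pixel_spacing = norm$pixel_spacing,
                 slice_thickness = norm$slice_thickness),
            class = "tissue_masks")
}

#' Detect air-filled cavities inside the log
#'
#' Dark-voxel hysteresis restricted to the solid hull (the hole-filled,
#' closed log silhouette), so exterior air is excluded.
#'
#' @param norm a `normalized_volume`.
#' @param tissues [split_bark_wood()] output.
#' @param dark `c(low, high)`: seeds `<= low`, kept `<= high`.
#' @return Logical cavity mask.
#' @export
detect_cavities <- function(norm, tissues, dark = c(low = 0.06, high = 0.12)) {
  stopifnot(inherits(tissues, "tissue_masks"))
  cav <- hysteresis_mask(norm$values, dark[[1L]], dark[[2L]], dark = TRUE)
  cav & tissues$hull
}

#' Classify cavity components as tunnel, crack, or drill hole
#'
#' Thin sheets are first split from thick tubes by a binary opening; each
#' 26-connected component is then classified from its shape descriptors
#' (see [cavity_rules()]). Remaining cavities are tagged as beetle tunnels
#' and assigned to bark or wood by majority compartment.
#'
#' @param cavities logical mask from [detect_cavities()].
#' @param tissues [split_bark_wood()] output.
#' @param rules a [cavity_rules()].
#' @return List with `classes` (integer array: 0 outside cavities,
#'   otherwise codes tunnel_bark/tunnel_wood/crack/drilling) and
#'   `components` (one row per component with all descriptors).
#' @export
classify_cavities <- function(cavities, tissues, rules = cavity_rules()) {
  codes <- label_codes()
  d <- dim(cavities)
  out <- array(0L, d)
  comps <- list()
  if (!any(cavities)) {
    return(list(classes = out,
                components = .empty_components_df()))
  }
  r <- rules$open_radius_vox
  outside_d <- binary_dilate(!tissues$hull, 1L)
  spacing <- c(tissues$pixel_spacing, tissues$slice_thickness)

  # drill holes first: they are thicker than galleries, so a deep in-plane
  # erosion isolates their cores even when a gallery touches the hole; the
  # core is grown back inside the cavity mask and tested as a straight
  # cylinder in the drill radius band
  remaining <- cavities
  er <- max(2L, floor(rules$drill_radius_mm[1L] / tissues$pixel_spacing[1L]) - 1L)
  dcore <- binary_erode(cavities, c(er, er, 0L))
  if (any(dcore)) {
    dl <- label_components(dcore)
    sizes <- tabulate(dl)
    for (key in which(sizes >= rules$drill_core_min_vox)) {
      core_idx <- which(dl == key)
      cd <- .component_descriptors(core_idx, d, spacing, tissues, outside_d)
      if (cd$straightness < rules$drill_core_straightness_min ||
          cd$length_mm < rules$drill_min_length_mm) next
      rc <- binary_dilate(dl == key, c(er + 1L, er + 1L, 1L)) & cavities
      idx <- which(rc)
      desc <- .component_descriptors(idx, d, spacing, tissues, outside_d)
      if (desc$mean_radius_mm >= rules$drill_radius_mm[1L] &&
          desc$mean_radius_mm <= rules$drill_radius_mm[2L]) {
        out[idx] <- codes[["drilling"]]
        remaining <- remaining & !rc
        desc$class <- "drilling"
        comps[[length(comps) + 1L]] <- desc
      }
    }
  }

  opened <- binary_open(remaining, r)
  core <- remaining & binary_dilate(opened, r)
  thin <- remaining & !core

  for (part in list(core, thin)) {
    if (!any(part)) next
    lab <- label_components(part)
    nmax <- max(lab)
    idx_by <- split(which(part), lab[part])
    for (key in names(idx_by)) {
      idx <- idx_by[[key]]
      desc <- .component_descriptors(idx, d, spacing, tissues, outside_d)
      cls <- .classify_component(desc, rules)
      code <- switch(cls,
                     crack = codes[["crack"]],
                     drilling = codes[["drilling"]],
                     tunnel = if (desc$compartment == "bark")
                       codes[["tunnel_bark"]] else codes[["tunnel_wood"]])
      out[idx] <- code
      desc$class <- cls
      comps[[length(comps) + 1L]] <- desc
    }
  }
  components <- do.call(rbind, lapply(comps, function(dsc)
    data.frame(voxels = dsc$voxels, planarity = dsc$planarity,
               elongation = dsc$elongation,
               radial_alignment = dsc$radial_alignment,
               straightness = dsc$straightness,
               mean_radius_mm = dsc$mean_radius_mm,
               touches_surface = dsc$touches_surface,
               compartment = dsc$compartment, class = dsc$class)))
  components$id <- seq_len(nrow(components))
  list(classes = out, components = components)
}

.empty_components_df <- function() {
  data.frame(voxels = integer(0), planarity = numeric(0),
             elongation = numeric(0), radial_alignment = numeric(0),
             straightness = numeric(0), mean_radius_mm = numeric(0),
             touches_surface = logical(0), compartment = character(0),
             class = character(0), id = integer(0))
}

.component_descriptors <- function(idx, d, spacing, tissues, outside_d) {
  ny <- d[1L]; nx <- d[2L]
  z <- (idx - 1L) %/% (ny * nx) + 1L
  rem <- (idx - 1L) %% (ny * nx)
  x <- rem %/% ny + 1L
  y <- rem %% ny + 1L
  pts <- cbind(y * spacing[1L], x * spacing[2L], z * spacing[3L])
  n <- length(idx)
  voxvol <- prod(spacing)

  planarity <- 1; elongation <- 1; straightness <- 1
  radial_alignment <- 0; mean_radius_mm <- (3 * n * voxvol / (4 * pi))^(1 / 3)
  length_mm <- max(spacing)
  if (n >= 8L) {
    cv <- stats::cov(pts)
    eg <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-9) + (spacing[1L] / 4)^2  # voxel-size ridge
    planarity <- sqrt(ev[2L] / ev[3L])
    elongation <- sqrt(ev[1L] / ev[2L])
    # radial alignment: sheet normal vs tangential direction at centroid
    zc <- round(mean(z)); zc <- min(max(zc, 1L), d[3L])
    cyx <- tissues$center[zc, ]
    vy <- mean(y) - cyx[1L]; vx <- mean(x) - cyx[2L]
    rr <- sqrt(vy^2 + vx^2)
    if (rr > 1e-6) {
      tang <- c(vx, -vy, 0) / rr
      nrm <- eg$vectors[, 3L]
      radial_alignment <- abs(sum(nrm * tang))
    }
    # centerline straightness along the first principal axis
    s <- as.vector((pts - rep(colMeans(pts), each = n)) %*% eg$vectors[, 1L])
    nb <- min(20L, max(3L, floor(n / 8)))
    bins <- cut(s, nb, labels = FALSE)
    cl <- rowsum(pts, bins) / as.vector(table(bins))
    if (nrow(cl) >= 2L) {
      seg <- sqrt(rowSums(diff(cl)^2))
      arc <- sum(seg)
      ee <- sqrt(sum((cl[nrow(cl), ] - cl[1L, ])^2))
      if (arc > 0) straightness <- min(ee / arc, 1)
    }
    len <- max(s) - min(s) + spacing[1L]
    mean_radius_mm <- sqrt(n * voxvol / (pi * len))
    length_mm <- len
  }
  bark_frac <- mean(tissues$region_bark[idx])
  list(voxels = n, planarity = planarity, elongation = elongation,
       radial_alignment = radial_alignment, straightness = straightness,
       mean_radius_mm = mean_radius_mm, length_mm = length_mm,
       touches_surface = any(outside_d[idx]),
       compartment = if (bark_frac > 0.5) "bark" else "wood",
       idx = NULL)
}

.classify_component <- function(desc, rules) {
  if (desc$planarity >= rules$crack_planarity_min &&
      desc$radial_alignment >= rules$crack_alignment_min &&
      desc$touches_surface)
    return("crack")
  if (desc$straightness >= rules$drill_straightness_min &&
      desc$mean_radius_mm >= rules$drill_radius_mm[1L] &&
      desc$mean_radius_mm <= rules$drill_radius_mm[2L] &&
      desc$elongation >= 1.5)
    return("drilling")
  "tunnel"
}

#' Detect beetle larvae
#'
#' Larvae are moist and appear bright. Components in the larva intensity
#' band are kept only when 26-connected to a detected cavity and of
#' plausible size, which avoids classifying other moisture-containing wood
#' as larvae.
#'
#' @param norm a `normalized_volume`.
#' @param cavity_mask logical mask of detected cavities/tunnels.
#' @param band normalized intensity band `c(lo, hi)`.
#' @param size_range_vox admissible component size `c(min, max)` in voxels.
#' @return Logical larva mask.
#' @export
detect_larvae <- function(norm, cavity_mask, band = c(0.40, 0.60),
                          size_range_vox = c(30, 8000)) {
  bright <- norm$values >= band[1L] & norm$values <= band[2L]
  if (!any(bright)) return(array(FALSE, dim(norm$values)))
  near_cav <- binary_dilate(cavity_mask, 1L)
  lab <- label_components(bright)
  sz <- tabulate(lab)
  touching <- unique(lab[near_cav & bright])
  touching <- touching[touching > 0L]
  keep <- touching[sz[touching] >= size_range_vox[1L] &
                     sz[touching] <= size_range_vox[2L]]
  array(lab %in% keep, dim(norm$values))
}

#' Quantify tunnel volume per compartment
#'
#' Counts voxels per class and reports absolute (mm^3) and relative (%)
#' tunnel volumes for bark, wood and the complete log; relative volume is
#' tunnel / (bark + wood + tunnel) voxels.
#'
#' @param labels a `label_volume` (pipeline output or ground truth).
#' @param tissues optional [split_bark_wood()] output, used to credit larva
#'   voxels to the right compartment.
#' @param include_larvae count larvae toward tunnel volume (default `TRUE`;
#'   larvae occupy excavated space).
#' @return A `volume_summary` (see [true_volume_summary()]).
#' @export
quantify_tunnel_volume <- function(labels, tissues = NULL,
                                   include_larvae = TRUE) {
  stopifnot(inherits(labels, "label_volume"))
  codes <- label_codes()
  counts <- vapply(codes, function(cd) sum(labels$classes == cd), numeric(1))
  names(counts) <- names(codes)
  larva_comp <- "wood"
  if (!is.null(tissues) && counts[["larva"]] > 0) {
    lv <- labels$classes == codes[["larva"]]
    if (mean(tissues$region_bark[lv]) > 0.5) larva_comp <- "bark"
  }
  vv <- prod(labels$pixel_spacing) * labels$slice_thickness
  .volume_summary_from_counts(counts, vv, include_larvae, larva_comp)
}

#' Virtually unroll the bark shell
#'
#' Samples the bark shell along radial rays for every slice and angle,
#' giving a radial view of the log surface: rows are slices (longitudinal
#' stem axis), columns span the circumference.
#'
#' @param x a `label_volume` (class-priority projection) or a
#'   `normalized_volume`/[ct_volume()] (min-intensity projection, so
#'   air-filled galleries stand out).
#' @param tissues [split_bark_wood()] output.
#' @param angular_samples number of circumference samples.
#' @return Matrix `(slices x angles)`, class `unrolled_bark`; class codes
#'   or intensities depending on input.
#' @export
unroll_bark <- function(x, tissues, angular_samples = 360L) {
  stopifnot(inherits(tissues, "tissue_masks"))
  codes <- label_codes()
  is_label <- inherits(x, "label_volume")
  arr <- if (is_label) x$classes else if (inherits(x, "normalized_volume"))
    x$values else if (inherits(x, "ct_volume")) x$voxels else x
  d <- dim(arr)
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  A <- as.integer(angular_samples)
  ang <- (seq_len(A) - 1) / A * 2 * pi
  # class priority: cavities > larva > bark > wood > background
  prio <- c(background = 0, wood = 1, bark = 2, decay = 3, drilling = 4,
            crack = 5, larva = 6, tunnel_wood = 7, tunnel_bark = 8)
  code2prio <- integer(max(codes) + 1L)
  code2prio[codes + 1L] <- prio[names(codes)]

  out <- matrix(if (is_label) codes[["background"]] else NA_real_, nz, A)
  hull <- tissues$hull
  for (z in seq_len(nz)) {
    hz <- hull[, , z]
    if (!any(hz)) next
    cy <- tissues$center[z, 1L]; cx <- tissues$center[z, 2L]
    idx <- which(hz)
    yy <- (idx - 1L) %% ny + 1L
    xx <- (idx - 1L) %/% ny + 1L
    rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
    th <- atan2(yy - cy, xx - cx) %% (2 * pi)
    bin <- pmin(floor(th / (2 * pi) * A) + 1L, A)
    rmax <- rep(NA_real_, A)
    agg <- tapply(rr, bin, max)
    rmax[as.integer(names(agg))] <- agg
    # interpolate missing angular bins from neighbors
    if (anyNA(rmax)) {
      ok <- which(!is.na(rmax))
      if (length(ok) == 0L) next
      rmax[is.na(rmax)] <- stats::approx(ok, rmax[ok], xout = which(is.na(rmax)),
                                         rule = 2)$y
    }
    depth_max <- max(tissues$bark_depth_vox[z], 2) + 1
    steps <- seq(0, depth_max, by = 0.5)
    sy <- round(rep(cy, A * length(steps)) +
                  rep(rmax - rep(steps, each = A), 1) * sin(rep(ang, length(steps))))
    sx <- round(rep(cx, A * length(steps)) +
                  rep(rmax - rep(steps, each = A), 1) * cos(rep(ang, length(steps))))
    okm <- sy >= 1 & sy <= ny & sx >= 1 & sx <= nx
    vals <- rep(if (is_label) codes[["background"]] else NA_real_,
                A * length(steps))
    lin <- sy[okm] + ny * (sx[okm] - 1L)
    slice <- arr[, , z]
    vals[okm] <- slice[lin]
    vm <- matrix(vals, nrow = A)
    if (is_label) {
      pm <- matrix(code2prio[vm + 1L], nrow = A)
      best <- max.col(pm, ties.method = "first")
      out[z, ] <- vm[cbind(seq_len(A), best)]
    } else {
      out[z, ] <- apply(vm, 1L, min, na.rm = TRUE)
    }
  }
  structure(out, class = c("unrolled_bark", class(out)))
}

#' Segment beetle tunnels in a CT volume
#'
#' The full classical pipeline: normalization, solid detection, bark/wood
#' separation, cavity detection, geometric crack/drill discrimination,
#' larva detection, and per-compartment tunnel volume quantification.
#'
#' @param vol a [ct_volume()] (or an already `normalized_volume`).
#' @param config a [tunnel_config()].
#' @param params [normalization_params()] applied when `vol` is a raw
#'   `ct_volume`.
#' @return List with `labels` (a `label_volume`), `tissues`, `components`
#'   (descriptor table), and `summary` (a `volume_summary`).
#' @export
segment_tunnels <- function(vol, config = tunnel_config(),
                            params = normalization_params()) {
  norm <- if (inherits(vol, "normalized_volume")) vol
          else normalize_volume(vol, params)
  solid <- detect_solid(norm, config$solid)
  tissues <- split_bark_wood(solid, norm, config)
  cav <- detect_cavities(norm, tissues, config$dark)
  cls <- classify_cavities(cav, tissues, config$rules)
  larvae <- detect_larvae(norm, cav | cls$classes > 0L, config$larva_band,
                          config$larva_size_vox)
  codes <- label_codes()
  lab <- array(codes[["background"]], dim(solid))
  lab[tissues$wood] <- codes[["wood"]]
  lab[tissues$bark] <- codes[["bark"]]
  sel <- cls$classes > 0L
  lab[sel] <- cls$classes[sel]
  lab[larvae] <- codes[["larva"]]
  labels <- label_volume(lab, pixel_spacing = norm$pixel_spacing,
                         slice_thickness = norm$slice_thickness)
  summary <- quantify_tunnel_volume(labels, tissues,
                                    include_larvae = config$include_larvae)
  list(labels = labels, tissues = tissues, components = cls$components,
       summary = summary, config = config)
}

#' Export tunnel voxels as a coordinate table
#'
#' Writes one row per tunnel (and larva) voxel with its class — the raw
#' material for 3-D gallery visualizations.
#'
#' @param labels a `label_volume`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tunnel_voxels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  codes <- label_codes()
  sel <- labels$classes %in% codes[c("tunnel_bark", "tunnel_wood", "larva")]
  idx <- which(sel)
  d <- dim(labels$classes)
  z <- (idx - 1L) %/% (d[1L] * d[2L]) + 1L
  rem <- (idx - 1L) %% (d[1L] * d[2L])
  df <- data.frame(y = rem %% d[1L] + 1L, x = rem %/% d[1L] + 1L, z = z,
                   class = names(codes)[match(labels$classes[idx], codes)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
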