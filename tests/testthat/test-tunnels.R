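test_that("solid detection matches the label-derived solid on a noiseless phantom", {
  fx <- std_phantom()
  norm <- normalize_volume(fx$ph$volume)
  solid <- detect_solid(norm)
  codes <- label_codes()
  truth <- fx$ph$labels$classes %in% codes[c("bark", "wood", "larva", "decay")]
  disagree <- mean(xor(solid, array(truth, dim(solid))))
  expect_lt(disagree, 0.01)
  expect_error(detect_solid(normalize_volume(
    ct_volume(array(-1000, c(12, 12, 3)), c(1, 1), 1))), "no log found")
})

test_that("solid detection is robust to 20 HU of noise", {
  fx <- std_phantom()
  noisy_spec <- fx$spec
  noisy_spec$noise_sigma_hu <- 20
  noisy <- generate_phantom(noisy_spec, seed = 11)   # same structures
  m0 <- detect_solid(normalize_volume(fx$ph$volume))
  m1 <- detect_solid(normalize_volume(noisy$volume))
  expect_lt(mean(xor(m0, m1)), 0.02)
})

test_that("bark/wood split partitions the solid and recovers bark thickness", {
  fx <- std_phantom()
  seg <- std_segmentation()
  tis <- seg$tissues
  norm <- normalize_volume(fx$ph$volume)
  solid <- detect_solid(norm)
  expect_false(any(tis$bark & tis$wood))
  expect_equal(tis$bark | tis$wood, solid)
  # 6 mm bark at 0.75 mm spacing = 8 voxels, within +-1
  sp <- fx$spec$pixel_spacing_mm
  expect_true(all(abs(tis$bark_depth_vox - fx$spec$bark_thickness_mm / sp) <= 1))
})

test_that("a barkless log yields an empty bark mask", {
  spec <- log_phantom_spec(length_slices = 8, radius_mm = 30,
                           bark_thickness_mm = 0, pixel_spacing_mm = 1,
                           tunnel_count = 0, noise_sigma_hu = 0)
  ph <- generate_phantom(spec, seed = 4)
  norm <- normalize_volume(ph$volume)
  tis <- split_bark_wood(detect_solid(norm), norm)
  expect_equal(sum(tis$bark), 0L)
  expect_gt(sum(tis$wood), 0L)
})

test_that("cavity detection recovers >=95% of true tunnel voxels", {
  fx <- std_phantom()
  seg <- std_segmentation()
  norm <- normalize_volume(fx$ph$volume)
  cav <- detect_cavities(norm, seg$tissues)
  codes <- label_codes()
  truth <- fx$ph$labels$classes %in% codes[c("tunnel_bark", "tunnel_wood")]
  expect_gt(sum(cav & truth) / sum(truth), 0.95)
  # exclusivity in the assembled labels: cavity voxels never stay tissue
  lab <- seg$labels$classes
  expect_false(any(lab[cav] %in% codes[c("bark", "wood")]))
  expect_true(all(lab[seg$tissues$background] == codes[["background"]]))
  # empty log has no cavities
  spec0 <- log_phantom_spec(length_slices = 6, radius_mm = 20,
                            pixel_spacing_mm = 1, tunnel_count = 0,
                            noise_sigma_hu = 0)
  ph0 <- generate_phantom(spec0, seed = 2)
  n0 <- normalize_volume(ph0$volume)
  t0 <- split_bark_wood(detect_solid(n0), n0)
  expect_equal(sum(detect_cavities(n0, t0)), 0L)
})

test_that("component classification separates tunnels, cracks and drillings", {
  fx <- std_phantom()
  seg <- std_segmentation()
  codes <- label_codes()
  truth <- fx$ph$labels$classes
  est <- seg$labels$classes
  cavity_classes <- codes[c("tunnel_bark", "tunnel_wood", "crack", "drilling")]
  both <- truth %in% cavity_classes & est %in% cavity_classes
  # collapse tunnel_bark/tunnel_wood to "tunnel" for the class accuracy
  collapse <- function(x) ifelse(x %in% codes[c("tunnel_bark", "tunnel_wood")],
                                 99L, x)
  acc <- mean(collapse(truth[both]) == collapse(est[both]))
  expect_gt(acc, 0.90)
  expect_setequal(unique(seg$components$class),
                  c("tunnel", "crack", "drilling"))
  # no cavities -> empty classification
  empty <- classify_cavities(array(FALSE, dim(est)), seg$tissues)
  expect_equal(nrow(empty$components), 0L)
  expect_true(all(empty$classes == 0L))
})

test_that("classification is invariant to translation and 90-degree rotation", {
  spec <- log_phantom_spec(length_slices = 14, radius_mm = 30,
                           pixel_spacing_mm = 1, margin_mm = 14,
                           tunnel_count = 2, crack_count = 2,
                           noise_sigma_hu = 0)
  ph <- generate_phantom(spec, seed = 6)
  count_by_class <- function(vox) {
    seg <- segment_tunnels(ct_volume(vox, c(1, 1), 2))
    vapply(split(seg$components$voxels, seg$components$class), sum,
           numeric(1))
  }
  base <- count_by_class(ph$volume$voxels)
  # translate by (4, 6) voxels, padding with air
  v <- ph$volume$voxels
  d <- dim(v)
  shifted <- array(-1000, d)
  shifted[5:d[1], 7:d[2], ] <- v[1:(d[1] - 4), 1:(d[2] - 6), ]
  expect_equal(count_by_class(shifted), base)
  expect_equal(count_by_class(rotate90(v)), base)
})

test_that("larvae are kept only when connected to a tunnel and sized plausibly", {
  fx <- std_phantom()
  seg <- std_segmentation()
  codes <- label_codes()
  truth_larva <- fx$ph$labels$classes == codes[["larva"]]
  est_larva <- seg$labels$classes == codes[["larva"]]
  expect_gt(sum(est_larva & truth_larva) / sum(truth_larva), 0.8)

  # identical bright blob far from any tunnel is rejected
  norm <- normalize_volume(fx$ph$volume)
  cav <- array(seg$labels$classes %in% codes[c("tunnel_bark", "tunnel_wood",
                                               "crack", "drilling")],
               dim(seg$labels$classes))
  vals <- norm$values
  ctr <- round(dim(vals) / 2)
  decoy <- deadwoodCT:::.carve_ellipsoid(
    c(10, 10, ctr[3] * fx$ph$volume$slice_thickness), c(6, 2.5, 2.5),
    dim(vals)[1], dim(vals)[2], dim(vals)[3],
    fx$ph$volume$pixel_spacing[1], fx$ph$volume$slice_thickness)
  vals2 <- vals
  vals2[decoy] <- 0.424                      # larva-band intensity, in wood
  norm2 <- norm; norm2$values <- vals2
  lv <- detect_larvae(norm2, cav)
  expect_gt(sum(lv & truth_larva) / sum(truth_larva), 0.8)
  expect_equal(sum(lv[decoy]), 0L)
  # size gate: a 2-voxel speck touching a tunnel is rejected
  lv2 <- detect_larvae(norm, cav, size_range_vox = c(1e5, 2e5))
  expect_equal(sum(lv2), 0L)
  # no bright voxels at all
  flat <- norm; flat$values <- array(0.2, dim(vals))
  expect_equal(sum(detect_larvae(flat, cav)), 0L)
})

test_that("estimated tunnel volume matches ground truth within tolerance", {
  fx <- std_phantom()
  seg <- std_segmentation()
  ts <- true_volume_summary(fx$ph$labels)
  for (comp in c("wood", "total")) {
    est <- seg$summary$tunnel$percent[seg$summary$tunnel$compartment == comp]
    tru <- ts$tunnel$percent[ts$tunnel$compartment == comp]
    expect_lt(abs(est - tru), 0.1 * tru + 0.05)
  }
  # class counts are conserved through assembly
  expect_equal(sum(seg$summary$counts), length(seg$labels$classes))
})

test_that("more tunnels never means less estimated tunnel volume", {
  est_pct <- function(n_tunnels, seed) {
    spec <- log_phantom_spec(length_slices = 12, radius_mm = 30,
                             pixel_spacing_mm = 1, tunnel_count = n_tunnels,
                             tunnel_radius_mm = c(2, 2.5),
                             tunnel_length_mm = c(40, 60),
                             noise_sigma_hu = 0)
    seg <- segment_tunnels(generate_phantom(spec, seed = seed)$volume)
    seg$summary$tunnel$percent[seg$summary$tunnel$compartment == "total"]
  }
  for (seed in c(3, 17)) {
    expect_lte(est_pct(2, seed), est_pct(4, seed))
  }
})

test_that("crack-only control phantoms stay below 1% spurious tunnel volume", {
  spec <- log_phantom_spec(length_slices = 24, radius_mm = 45,
                           bark_thickness_mm = 6, pixel_spacing_mm = 0.75,
                           slice_thickness_mm = 2, tunnel_count = 0,
                           crack_count = 6, noise_sigma_hu = 10)
  seg <- segment_tunnels(generate_phantom(spec, seed = 13)$volume)
  fp <- seg$summary$tunnel$percent[seg$summary$tunnel$compartment == "total"]
  expect_lt(fp, 1)
})

test_that("unrolled bark localizes a bark gallery at its true angles", {
  spec <- log_phantom_spec(length_slices = 20, radius_mm = 40,
                           bark_thickness_mm = 7, pixel_spacing_mm = 0.75,
                           slice_thickness_mm = 2, tunnel_count = 1,
                           tunnel_zone = "bark", tunnel_radius_mm = c(1.4, 1.7),
                           tunnel_length_mm = c(50, 60), noise_sigma_hu = 0)
  ph <- generate_phantom(spec, seed = 8)
  seg <- segment_tunnels(ph$volume)
  A <- 180L
  unr <- unroll_bark(seg$labels, seg$tissues, angular_samples = A)
  expect_equal(nrow(unr), dim(ph$volume$voxels)[3])
  codes <- label_codes()
  got <- which(apply(unr == codes[["tunnel_bark"]], 2, any))
  # true angular bins of bark-tunnel voxels
  lab <- ph$labels$classes
  idx <- which(lab == codes[["tunnel_bark"]])
  d <- dim(lab)
  yy <- (idx - 1) %% d[1] + 1
  xx <- ((idx - 1) %/% d[1]) %% d[2] + 1
  ctr <- (d[1] + 1) / 2
  th <- atan2(yy - ctr, xx - ctr) %% (2 * pi)
  want <- unique(pmin(floor(th / (2 * pi) * A) + 1, A))
  expect_gt(length(intersect(got, want)) / length(union(got, want)), 0.7)
  miss <- setdiff(got, c(want, want + 1, want - 1, 1, A))
  expect_lt(length(miss) / max(length(got), 1), 0.1)
})

test_that("an empty log unrolls to pure bark", {
  spec <- log_phantom_spec(length_slices = 8, radius_mm = 25,
                           pixel_spacing_mm = 1, tunnel_count = 0,
                           noise_sigma_hu = 0)
  ph <- generate_phantom(spec, seed = 3)
  seg <- segment_tunnels(ph$volume)
  unr <- unroll_bark(seg$labels, seg$tissues, angular_samples = 90)
  expect_true(all(unr == label_codes()[["bark"]]))
})

test_that("unrolled tunnel area tracks true bark-tunnel volume across seeds", {
  areas <- truths <- numeric(0)
  for (seed in 1:6) {
    spec <- log_phantom_spec(length_slices = 12, radius_mm = 30,
                             bark_thickness_mm = 7, pixel_spacing_mm = 1,
                             tunnel_count = 1 + seed %% 3,
                             tunnel_zone = "bark",
                             tunnel_radius_mm = c(1.4, 1.8),
                             tunnel_length_mm = c(30, 60),
                             noise_sigma_hu = 0)
    ph <- generate_phantom(spec, seed = 100 + seed)
    seg <- segment_tunnels(ph$volume)
    unr <- unroll_bark(seg$labels, seg$tissues, angular_samples = 180)
    areas <- c(areas, sum(unr == label_codes()[["tunnel_bark"]]))
    truths <- c(truths, sum(ph$labels$classes == label_codes()[["tunnel_bark"]]))
  }
  expect_gt(spearman_test(areas, truths)$rho, 0.9)
})
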