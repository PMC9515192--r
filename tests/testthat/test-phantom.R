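test_that("generation is deterministic given spec and seed", {
  spec <- log_phantom_spec(length_slices = 8, radius_mm = 20,
                           pixel_spacing_mm = 1, tunnel_count = 2,
                           crack_count = 1, decay_patch_count = 1)
  a <- generate_phantom(spec, seed = 9)
  b <- generate_phantom(spec, seed = 9)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$labels$classes, b$labels$classes)
  c <- generate_phantom(spec, seed = 10)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("an empty log contains only background, bark and wood", {
  spec <- log_phantom_spec(length_slices = 6, radius_mm = 20,
                           pixel_spacing_mm = 1, tunnel_count = 0,
                           noise_sigma_hu = 0)
  ph <- generate_phantom(spec, seed = 1)
  codes <- label_codes()
  expect_true(all(ph$labels$classes %in% codes[c("background", "bark", "wood")]))
  ts <- true_volume_summary(ph$labels)
  expect_equal(ts$tunnel$percent, c(0, 0, 0))
  expect_equal(ts$decay_percent, 0)
})

test_that("a straight tunnel's labeled volume matches the analytic cylinder", {
  r_mm <- 2.5; len_mm <- 30
  spec <- log_phantom_spec(length_slices = 60, radius_mm = 45,
                           bark_thickness_mm = 4, pixel_spacing_mm = 0.5,
                           slice_thickness_mm = 0.5, margin_mm = 6,
                           tunnel_count = 1, tunnel_radius_mm = c(r_mm, r_mm),
                           tunnel_length_mm = c(len_mm, len_mm),
                           tunnel_tortuosity = 0, noise_sigma_hu = 0)
  ph <- generate_phantom(spec, seed = 21)
  vox_vol <- prod(ph$labels$pixel_spacing) * ph$labels$slice_thickness
  n_tunnel <- sum(ph$labels$classes %in% label_codes()[c("tunnel_wood",
                                                         "tunnel_bark")])
  analytic <- (pi * r_mm^2 * len_mm + 4 / 3 * pi * r_mm^3) / vox_vol
  expect_lt(abs(n_tunnel - analytic) / analytic, 0.10)
})

test_that("ground-truth summary is additive and exact by construction", {
  ph <- std_phantom()$ph
  ts <- true_volume_summary(ph$labels)
  expect_equal(sum(ts$counts), length(ph$labels$classes))
  tot <- ts$tunnel$voxels[ts$tunnel$compartment == "total"]
  expect_equal(tot, sum(ts$tunnel$voxels[ts$tunnel$compartment != "total"]))
  # painting exactly 5% of wood voxels as decay gives decay fraction 5%
  lab <- ph$labels
  wood_idx <- which(lab$classes == label_codes()[["wood"]])
  n_wood <- length(wood_idx)
  k <- round(0.05 * n_wood)
  lab$classes[wood_idx[seq_len(k)]] <- label_codes()[["decay"]]
  ts2 <- true_volume_summary(lab)
  expect_equal(ts2$decay_percent, 100 * k / n_wood, tolerance = 1e-12)
})

test_that("the noiseless HU palette is ordered air < dark decay < wood < larva", {
  spec <- log_phantom_spec(length_slices = 16, radius_mm = 35,
                           pixel_spacing_mm = 1, tunnel_count = 2,
                           larva_count = 1, decay_patch_count = 2,
                           decay_contrast_hu = -150,
                           decay_crack_system = FALSE, noise_sigma_hu = 0)
  ph <- generate_phantom(spec, seed = 5)
  codes <- label_codes()
  v <- ph$volume$voxels; l <- ph$labels$classes
  m <- function(cls) mean(v[l == codes[[cls]]])
  expect_lt(m("tunnel_wood"), m("decay"))
  expect_lt(m("decay"), m("wood"))
  expect_lt(m("wood"), m("larva"))
  expect_equal(m("tunnel_wood"), -1000)
})

test_that("impossible structures are rejected", {
  expect_error(log_phantom_spec(tunnel_radius_mm = c(90, 100), radius_mm = 80),
               "tunnel radius")
  expect_error(log_phantom_spec(bark_thickness_mm = 90, radius_mm = 80),
               "bark_thickness")
  expect_error(log_phantom_spec(tunnel_count = -1), "non-negative")
})

test_that("the simulated experiment reproduces the field design bookkeeping", {
  sim <- simulate_experiment(seed = 2)
  expect_equal(nrow(sim$logs), 122L)
  expect_equal(max(sim$logs$mesocosm), 61L)
  per_meso <- table(sim$logs$mesocosm)
  expect_true(all(per_meso == 2))
  trt <- table(sim$logs$treatment[!duplicated(sim$logs$mesocosm)])
  expect_equal(as.integer(trt[c("control", "bark_beetles", "wood_borers")]),
               c(26L, 20L, 15L))
  # deterministic
  sim2 <- simulate_experiment(seed = 2)
  expect_identical(sim$logs, sim2$logs)
})

test_that("zero effect and zero noise collapse the simulation as designed", {
  eff <- guild_effects(control = list(tunnel_fraction = 0, bark_share = 0))
  quiet <- experiment_noise(moisture_sd = 0, massloss_extra_sd = 0,
                            mass_resolution_g = 0,
                            decay_fraction_mean = c(batch1 = 0, batch2 = 0))
  sim <- simulate_experiment(effects = eff, noise = quiet, seed = 3)
  ctrl <- sim$logs[sim$logs$treatment == "control", ]
  expect_true(all(ctrl$true_tunnel_fraction == 0))
  # without measurement noise, mass loss ranks exactly with tunnel fraction
  m0_hat <- estimate_log_dry_mass(sim$logs$fresh_mass_log,
                                  sim$logs$fresh_mass_disc,
                                  sim$logs$dry_mass_disc)
  loss <- round(relative_mass_loss(m0_hat, sim$logs$dry_mass_final), 9)
  expect_gt(cor(rank(sim$logs$true_tunnel_fraction), rank(loss)), 0.999)
})
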