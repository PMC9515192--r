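#' Mesocosm experiment design
#'
#' Treatment allocation of the simulated decomposition experiment. The
#' default is the field design: 26 control mesocosms without beetles, 20
#' with bark beetles, 15 with wood-boring beetles, two logs per mesocosm
#' (122 logs in 61 mesocosms); one log per mesocosm is harvested early
#' (batch 1, beetle-focused) and one late (batch 2, fungus-focused).
#'
#' @param control,bark_beetles,wood_borers mesocosm counts per treatment.
#' @param logs_per_mesocosm logs in each mesocosm.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(control = 26L, bark_beetles = 20L,
                              wood_borers = 15L, logs_per_mesocosm = 2L) {
  if (any(c(control, bark_beetles, wood_borers, logs_per_mesocosm) < 0))
    stop("counts must be non-negative")
  structure(list(control = as.integer(control),
                 bark_beetles = as.integer(bark_beetles),
                 wood_borers = as.integer(wood_borers),
                 logs_per_mesocosm = as.integer(logs_per_mesocosm)),
            class = "experiment_design")
}

#' Per-guild effect sizes
#'
#' Mean true tunnel fraction of the log volume and the share of that
#' fraction excavated inside the bark compartment. Bark beetles work the
#' bark/cambium shell almost exclusively; wood-borers excavate several-fold
#' more and penetrate the sapwood.
#'
#' @param control,bark_beetles,wood_borers lists with `tunnel_fraction`
#'   (mean, of log volume) and `bark_share` (fraction of tunnel volume in
#'   bark).
#' @param cv lognormal coefficient of variation of per-log tunnel fractions.
#' @return An object of class `guild_effects`.
#' @export
guild_effects <- function(control = list(tunnel_fraction = 0, bark_share = 0),
                          bark_beetles = list(tunnel_fraction = 0.004,
                                              bark_share = 0.9),
                          wood_borers = list(tunnel_fraction = 0.02,
                                             bark_share = 0.3),
                          cv = 0.4) {
  eff <- list(control = control, bark_beetles = bark_beetles,
              wood_borers = wood_borers, cv = cv)
  for (g in c("control", "bark_beetles", "wood_borers"))
    if (eff[[g]]$tunnel_fraction < 0) stop("effect sizes must be >= 0")
  structure(eff, class = "guild_effects")
}

#' Noise model of the simulated experiment
#'
#' @param moisture_mean mean fresh/dry mass excess (fresh = dry * (1 + m)).
#' @param moisture_sd within-log heterogeneity of the fresh/dry mass ratio
#'   between the disc and the rest of the log; drives the disc estimator's
#'   error. The default 0.02 yields a moderate rank correlation (about 0.5)
#'   between tunnel fraction and apparent mass loss, the regime observed in
#'   field data. 0 disables it.
#' @param massloss_extra_sd additive noise on the true mass-loss fraction.
#' @param mass_resolution_g balance resolution: recorded masses are rounded
#'   to this many grams (0.1 g in the field protocol; 0 disables rounding).
#' @param decay_fraction_mean mean true decay fraction per batch (named
#'   `batch1`, `batch2`); fungal decay is minor after 1.5 years and around
#'   20% of the wood after 3.5 years.
#' @param decay_density_loss relative density loss of decayed wood.
#' @return A list of noise parameters.
#' @export
experiment_noise <- function(moisture_mean = 0.8, moisture_sd = 0.02,
                             massloss_extra_sd = 0.002,
                             mass_resolution_g = 0.1,
                             decay_fraction_mean = c(batch1 = 0.03,
                                                     batch2 = 0.2),
                             decay_density_loss = 0.3) {
  list(moisture_mean = moisture_mean, moisture_sd = moisture_sd,
       massloss_extra_sd = massloss_extra_sd,
       mass_resolution_g = mass_resolution_g,
       decay_fraction_mean = decay_fraction_mean,
       decay_density_loss = decay_density_loss)
}

#' Simulate a mesocosm decomposition experiment
#'
#' Draws per-log true tunnel fractions (per compartment) from the guild
#' effect distributions, true decay fractions per batch, and fresh/dry
#' masses for each log and its cut disc. Mass loss is constructed to be
#' positively driven by tunnel and decay fractions (voxel mass is
#' proportional to HU + 1000, so excavated volume is lost mass), while the
#' disc-based dry-mass estimator inherits error from within-log moisture
#' heterogeneity — including occasional negative apparent mass loss.
#'
#' @param design an [experiment_design()].
#' @param effects a [guild_effects()].
#' @param noise an [experiment_noise()] list.
#' @param seed integer seed.
#' @return An object of class `simulated_experiment`: list with `design`,
#'   `logs` (one row per log: treatment, batch, geometry, true fractions,
#'   masses) and `effects`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                effects = guild_effects(),
                                noise = experiment_noise(),
                                seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(effects, "guild_effects"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  trt <- rep(c("control", "bark_beetles", "wood_borers"),
             times = c(design$control, design$bark_beetles,
                       design$wood_borers))
  n_meso <- length(trt)
  meso <- rep(seq_len(n_meso), each = design$logs_per_mesocosm)
  batch <- rep(seq_len(design$logs_per_mesocosm), times = n_meso)
  n_logs <- length(meso)
  treatment <- trt[meso]

  radius_mm <- runif(n_logs, 80, 100)           # 16-20 cm diameter
  length_mm <- rep(500, n_logs)
  bark_mm <- runif(n_logs, 5, 8)

  sigma <- sqrt(log(1 + effects$cv^2))
  frac <- vapply(seq_len(n_logs), function(i) {
    mu <- effects[[treatment[i]]]$tunnel_fraction
    if (mu == 0) 0 else rlnorm(1, log(mu) - sigma^2 / 2, sigma)
  }, numeric(1))
  share <- vapply(treatment, function(g) effects[[g]]$bark_share, numeric(1))
  frac_bark <- frac * share
  frac_wood <- frac - frac_bark

  dmean <- noise$decay_fraction_mean
  decay_frac <- ifelse(batch == 1L,
                       pmin(1, rlnorm(n_logs, log(pmax(dmean[["batch1"]], 1e-6)) - 0.125, 0.5)),
                       pmin(1, rlnorm(n_logs, log(pmax(dmean[["batch2"]], 1e-6)) - 0.125, 0.5)))
  if (all(dmean == 0)) decay_frac <- rep(0, n_logs)

  d0 <- rnorm(n_logs, 0.43, 0.04)               # g/cm^3, fresh spruce
  vol_log_cm3 <- pi * (radius_mm / 10)^2 * (length_mm / 10)
  vol_disc_cm3 <- pi * (radius_mm / 10)^2 * 3
  m0 <- d0 * vol_log_cm3                        # true initial dry mass, g
  theta_log <- noise$moisture_mean + rnorm(n_logs, 0, 0.05)
  theta_disc <- theta_log + rnorm(n_logs, 0, noise$moisture_sd)
  dry_disc <- d0 * vol_disc_cm3
  fresh_disc <- dry_disc * (1 + theta_disc)
  fresh_log <- m0 * (1 + theta_log)

  loss_frac <- frac + decay_frac * noise$decay_density_loss +
    rnorm(n_logs, 0, noise$massloss_extra_sd)
  loss_frac <- pmin(pmax(loss_frac, 0), 0.95)
  dry_final <- m0 * (1 - loss_frac)

  rec <- function(x) {
    if (is.null(noise$mass_resolution_g) || noise$mass_resolution_g <= 0) x
    else round(x / noise$mass_resolution_g) * noise$mass_resolution_g
  }
  logs <- data.frame(
    log_id = seq_len(n_logs),
    mesocosm = meso,
    treatment = treatment,
    batch = batch,
    radius_mm = radius_mm,
    bark_mm = bark_mm,
    length_mm = length_mm,
    true_tunnel_fraction = frac,
    true_tunnel_fraction_bark = frac_bark,
    true_tunnel_fraction_wood = frac_wood,
    true_decay_fraction = decay_frac,
    dry_mass_initial_true = rec(m0),
    fresh_mass_log = rec(fresh_log),
    fresh_mass_disc = rec(fresh_disc),
    dry_mass_disc = rec(dry_disc),
    dry_mass_final = rec(dry_final),
    stringsAsFactors = FALSE)

  structure(list(design = design, effects = effects, noise = noise,
                 seed = seed, logs = logs),
            class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("simulated_experiment: %d logs in %d mesocosms\n",
              nrow(x$logs), max(x$logs$mesocosm)))
  print(table(x$logs$treatment, x$logs$batch))
  invisible(x)
}

#' Render a simulated log as a CT phantom section
#'
#' Builds a [log_phantom_spec()] for one log of a [simulate_experiment()]
#' output and voxelizes a section of it. Tunnel counts are derived from the
#' log's true tunnel fractions; the zone follows the guild (bark beetles in
#' the bark shell, wood-borers into the sapwood). Rendering a section
#' rather than the full 50 cm log keeps volumes small; fractions are
#' volume-relative and therefore comparable.
#'
#' @param sim a `simulated_experiment`.
#' @param log_id which log to render.
#' @param length_slices section length in slices.
#' @param pixel_spacing_mm,slice_thickness_mm rendering resolution.
#' @param crack_count shrinkage cracks per rendered section (drying
#'   deadwood always cracks; this is the main false-positive source).
#' @param seed integer seed (combined with `log_id`).
#' @param ... overrides passed on to [log_phantom_spec()].
#' @return As [generate_phantom()], plus element `spec`.
#' @export
render_log_phantom <- function(sim, log_id, length_slices = 40,
                               pixel_spacing_mm = 1, slice_thickness_mm = 2,
                               crack_count = 3, seed = 1L, ...) {
  stopifnot(inherits(sim, "simulated_experiment"))
  row <- sim$logs[sim$logs$log_id == log_id, ]
  if (nrow(row) != 1L) stop("unknown log_id")
  zone <- switch(row$treatment, control = "wood", bark_beetles = "bark",
                 wood_borers = "mixed")
  sec_vol <- pi * row$radius_mm^2 * length_slices * slice_thickness_mm
  mean_tunnel_r <- if (zone == "bark") 1.5 else 2.2
  mean_len <- 120
  vtun <- pi * mean_tunnel_r^2 * mean_len
  n_tun <- round(row$true_tunnel_fraction * sec_vol / vtun)
  spec <- log_phantom_spec(
    length_slices = length_slices,
    radius_mm = row$radius_mm,
    bark_thickness_mm = row$bark_mm,
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    tunnel_count = n_tun,
    tunnel_radius_mm = if (zone == "bark") c(1.2, 1.8) else c(1.8, 2.6),
    tunnel_length_mm = c(90, 150),
    tunnel_zone = zone,
    crack_count = crack_count,
    ...)
  out <- generate_phantom(spec, seed = seed + 1000L * log_id)
  out$spec <- spec
  out
}

#' Export tidy per-log summaries
#'
#' Writes the per-log table of a simulated (or measured) experiment to CSV,
#' ready for external statistical software (e.g. beta regression of
#' relative volumes on treatment).
#'
#' @param logs data.frame of per-log results.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_log_summary <- function(logs, path) {
  write.csv(logs, path, row.names = FALSE)
  invisible(path)
}
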