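# Shared fixtures, built once per test run. All synthetic, generated in code.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A mid-sized noiseless phantom with all structure types; tunnels >= 2
# voxels in radius so the cavity detector sees them.
std_phantom <- function() fixture("std_phantom", function() {
  spec <- log_phantom_spec(
    length_slices = 30, radius_mm = 50, bark_thickness_mm = 6,
    pixel_spacing_mm = 0.75, slice_thickness_mm = 2, margin_mm = 10,
    tunnel_count = 3, tunnel_radius_mm = c(1.6, 2.6),
    crack_count = 4, drilling_count = 1, larva_count = 1,
    noise_sigma_hu = 0)
  list(spec = spec, ph = generate_phantom(spec, seed = 11))
})

std_segmentation <- function() fixture("std_segmentation", function() {
  segment_tunnels(std_phantom()$ph$volume)
})

# in-plane 90 degree rotation of a (y, x, z) array (square slices)
rotate90 <- function(arr) {
  d <- dim(arr)
  out <- array(arr[1], d)
  for (z in seq_len(d[3])) {
    m <- arr[, , z]
    out[, , z] <- t(m)[, d[1]:1]
  }
  out
}
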