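# Shared fixture builders. Everything is generated in code; no binary data.

# A constant-colour frame.
flat_frame <- function(rgb, h = 8, w = 8, time = 0, pixel_size = NA_real_) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  image_frame(px, time = time, pixel_size = pixel_size)
}

# A frame with a centred red disk of radius r_px on black background.
disk_frame <- function(r_px, n = 160, time = 0, pixel_size = 0.4, value = 200) {
  px <- array(0, dim = c(n, n, 3))
  ctr <- (n + 1) / 2
  d2 <- outer(seq_len(n), seq_len(n), function(i, j) (i - ctr)^2 + (j - ctr)^2)
  red <- px[, , 1]
  red[d2 <= r_px^2] <- value
  px[, , 1] <- red
  image_frame(px, time = time, pixel_size = pixel_size)
}

# A small, fast release run: 40 um cube at 32^3, D large enough that the
# release runs to near-complete depletion (plateau) inside 3000 min.
fast_release_sequence <- function(seed = 11, noise_sd = 2, extinction = 0.03) {
  g <- crystal_geometry(40, 1.25)
  simulate_sequence(g, diffusion_params(2e-14),
                    optics_model(extinction = extinction, noise_sd = noise_sd,
                                 seed = seed),
                    mode = "release",
                    sample_times = c(15, 30, 60, 100, 200, 300, 500,
                                     1000, 1600, 2350, 3000))
}

# Occupancy-fraction trace (interior voxels) from an uptake run, wrapped as
# an intensity trace on a 0-100 scale so rate estimators apply unchanged.
uptake_fraction_trace <- function(geometry, D, sample_times) {
  fl <- simulate_diffusion(geometry, diffusion_params(D), "uptake", sample_times)
  cap <- sum(!mofdiff:::clamped_voxels(geometry))
  frac <- vapply(fl, function(f)
    total_occupancy(f, geometry, exclude_clamped = TRUE), numeric(1)) / cap
  tr <- data.frame(time_min = c(0, sample_times),
                   mean_intensity = c(0, frac) * 100,
                   mask_area = cap)
  class(tr) <- c("intensity_trace", "data.frame")
  tr
}

# Exact remaining-fraction of a Dirichlet slab (series solution), and the
# cube fraction via the separable product form.
slab_remaining <- function(t_s, D_um, L) {
  n <- seq(1, 199, by = 2)
  (8 / pi^2) * sum(exp(-n^2 * pi^2 * D_um * t_s / L^2) / n^2)
}
cube_fraction <- function(t_s, D_um, L) 1 - slab_remaining(t_s, D_um, L)^3

# Seeded RNG scope for fixtures (the package's internal scoped-RNG helper).
with_seed_test <- function(seed, code) mofdiff:::with_seed(seed, code)
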