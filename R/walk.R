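#' Simulate an ensemble of Brownian particles
#'
#' Free isotropic Brownian motion in 1, 2 or 3 dimensions: each step adds
#' independent Gaussian increments with per-axis variance `2 * D * dt`, so
#' after time `t` the ensemble mean-square displacement is `q_i * D * t`
#' with `q_i = 2 * dim`. Used to validate the MSD estimator against a known
#' ground-truth diffusivity.
#'
#' @param dim spatial dimensionality, 1, 2 or 3.
#' @param true_D ground-truth diffusivity in m^2/s.
#' @param n_particles number of independent particles (>= 1).
#' @param total_time elapsed time in seconds (0 gives an unmoved ensemble).
#' @param dt step length in seconds.
#' @param seed mandatory random seed.
#' @return object of class `walk_ensemble` with `positions`
#'   (`n_particles x dim`, micrometres), `dim`, `true_D`, `elapsed`, `seed`.
#' @export
simulate_walk <- function(dim, true_D, n_particles, total_time, dt, seed) {
  if (!dim %in% 1:3) stop("dim must be 1, 2 or 3")
  if (true_D <= 0) stop("true_D must be positive")
  if (n_particles < 1) stop("need at least one particle")
  if (dt <= 0) stop("dt must be positive")
  if (total_time < 0) stop("total_time must be non-negative")
  if (missing(seed) || is.null(seed)) stop("simulate_walk requires a seed")
  D_um <- convert_unit(true_D, "m2/s", "um2/s")
  pos <- matrix(0, nrow = n_particles, ncol = dim)
  if (total_time > 0) {
    n_full <- floor(total_time / dt)
    rem <- total_time - n_full * dt
    pos <- with_seed(seed, {
      p <- pos
      for (k in seq_len(n_full))
        p <- p + matrix(stats::rnorm(n_particles * dim, 0, sqrt(2 * D_um * dt)),
                        n_particles, dim)
      if (rem > 1e-12)
        p <- p + matrix(stats::rnorm(n_particles * dim, 0, sqrt(2 * D_um * rem)),
                        n_particles, dim)
      p
    })
  }
  structure(list(positions = pos, dim = as.integer(dim), true_D = true_D,
                 elapsed = total_time, seed = seed),
            class = "walk_ensemble")
}

#' Ensemble mean-square displacement
#'
#' @param ensemble a [simulate_walk()] result.
#' @return mean of squared displacement from the origin, in um^2.
#' @export
msd <- function(ensemble) {
  stopifnot(inherits(ensemble, "walk_ensemble"))
  mean(rowSums(ensemble$positions^2))
}
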