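# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Optical model for rendering concentration fields
#'
#' Rendering mimics bright-field transmission microscopy of a crystal whose
#' guest is an intensely red chromophore: per pixel, the occupancy is
#' path-integrated along the view axis and converted to a Beer-Lambert
#' absorbance `A = extinction * channel_weight * path_integral`. The green
#' and blue channels are attenuated strongly (the crystal reddens as it
#' loads); the red channel is attenuated weakly but measurably, since the
#' chromophore absorbs across the visible band, which is what gives the
#' red-channel differential trace its signal.
#'
#' @param view_axis projection axis (1, 2 or 3).
#' @param extinction absorbance per unit occupancy per micrometre of path.
#' @param background_rgb 8-bit colour of the empty field of view.
#' @param channel_weights relative extinction per channel (red, green,
#'   blue).
#' @param noise_sd additive Gaussian pixel noise, in 8-bit counts; requires
#'   `seed` when positive.
#' @param pad background margin around the projected crystal, in pixels.
#' @param seed random seed for the noise stream. Stochastic rendering with
#'   no seed is an error, so every run is reproducible.
#' @return object of class `optics_model`.
#' @export
optics_model <- function(view_axis = 3, extinction = 0.03,
                         background_rgb = c(235, 235, 235),
                         channel_weights = c(red = 0.25, green = 1, blue = 1),
                         noise_sd = 2, pad = 8, seed = NULL) {
  stopifnot(view_axis %in% 1:3, length(background_rgb) == 3,
            length(channel_weights) == 3)
  if (extinction < 0) stop("extinction must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(background_rgb < 0) || any(background_rgb > 255))
    stop("background channels must be in [0, 255]")
  if (pad < 0) stop("pad must be >= 0")
  structure(list(view_axis = as.integer(view_axis), extinction = extinction,
                 background_rgb = as.numeric(background_rgb),
                 channel_weights = as.numeric(channel_weights),
                 noise_sd = noise_sd, pad = as.integer(pad),
                 bit_depth = 8L, seed = seed),
            class = "optics_model")
}

#' Render a concentration field into a microscopy-like RGB frame
#'
#' @param field a `concentration_field`.
#' @param geometry the matching [crystal_geometry()].
#' @param optics an [optics_model()].
#' @param seed overrides `optics$seed` for this frame (used to give each
#'   frame of a sequence its own noise realisation).
#' @return an [image_frame()] with 8-bit pixels, timestamped from the field.
#' @export
render_frame <- function(field, geometry, optics, seed = optics$seed) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(optics, "optics_model"))
  if (anyNA(field$occupancy) || any(!is.finite(field$occupancy)))
    stop("field must be finite")
  ax <- optics$view_axis
  keep <- setdiff(1:3, ax)
  path <- apply(field$occupancy, keep, sum) * geometry$voxel_pitch  # um
  nr <- nrow(path); nc <- ncol(path)
  pad <- optics$pad
  H <- nr + 2L * pad; W <- nc + 2L * pad
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    bg <- optics$background_rgb[ch]
    plane <- matrix(bg, H, W)
    A <- optics$extinction * optics$channel_weights[ch] * path
    plane[pad + seq_len(nr), pad + seq_len(nc)] <- bg * exp(-A)
    px[, , ch] <- plane
  }
  if (optics$noise_sd > 0) {
    if (is.null(seed))
      stop("stochastic rendering requires an explicit seed (noise_sd > 0)")
    px <- px + with_seed(seed, array(stats::rnorm(H * W * 3, 0, optics$noise_sd),
                                     dim = c(H, W, 3)))
  }
  px <- round(pmin(pmax(px, 0), 255))
  image_frame(px, time = field$time, pixel_size = geometry$voxel_pitch)
}

#' Simulate a crystal and render the whole image sequence
#'
#' Composes [simulate_diffusion()] and [render_frame()]: the reference
#' frame (time 0, the untouched starting crystal) is rendered first, then
#' one frame per sample time. Frame `k` uses noise seed `seed + k - 1` so
#' noise is independent across frames yet fully reproducible.
#'
#' @inheritParams simulate_diffusion
#' @param optics an [optics_model()]; its `seed` is the sequence seed and is
#'   mandatory when `noise_sd > 0`.
#' @return an [image_sequence()] of `length(sample_times) + 1` frames.
#' @export
simulate_sequence <- function(geometry, params, optics,
                              mode = c("uptake", "release"),
                              sample_times) {
  mode <- match.arg(mode)
  if (optics$noise_sd > 0 && is.null(optics$seed))
    stop("simulate_sequence with noise requires optics$seed")
  fields <- simulate_diffusion(geometry, params, mode, sample_times)
  ref <- build_field(geometry, if (mode == "uptake") 0 else 1)
  all_fields <- c(list(ref), fields)
  frames <- lapply(seq_along(all_fields), function(k) {
    s <- if (is.null(optics$seed)) NULL else optics$seed + k - 1L
    render_frame(all_fields[[k]], geometry, optics, seed = s)
  })
  image_sequence(frames)
}
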