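#' An 8-bit RGB microscopy frame
#'
#' @param pixels `H x W x 3` numeric array of intensities in `[0, 255]`
#'   (RGB order).
#' @param time acquisition time in minutes.
#' @param pixel_size micrometres per pixel (may be `NA` for fixtures that
#'   never reach physical measurements).
#' @return object of class `image_frame`.
#' @export
image_frame <- function(pixels, time = 0, pixel_size = NA_real_) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be an H x W x 3 array")
  if (any(dim(pixels)[1:2] < 1)) stop("frame must have at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must be in [0, 255]")
  if (time < 0) stop("time must be >= 0")
  structure(list(pixels = pixels, time = as.numeric(time),
                 pixel_size = as.numeric(pixel_size)),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_frame: %d x %d px, t = %.4g min, %.4g um/px\n",
              d[1], d[2], x$time, x$pixel_size))
  invisible(x)
}

#' An ordered, time-stamped sequence of frames
#'
#' The first frame is the reference against which every later frame is
#' differenced. Frames must share shape and pixel size, and timestamps must
#' be strictly increasing.
#'
#' @param frames list of [image_frame()] objects.
#' @return object of class `image_sequence`.
#' @export
image_sequence <- function(frames) {
  if (!length(frames)) stop("empty sequence")
  if (!all(vapply(frames, inherits, TRUE, "image_frame")))
    stop("frames must all be image_frame objects")
  dims <- vapply(frames, function(f) dim(f$pixels)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same shape")
  ps <- vapply(frames, function(f) f$pixel_size, numeric(1))
  if (length(unique(ps[!is.na(ps)])) > 1)
    stop("all frames must share the same pixel size")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(frames = frames), class = "image_sequence")
}

#' @export
length.image_sequence <- function(x) length(x$frames)

#' @export
print.image_sequence <- function(x, ...) {
  t <- sequence_times(x)
  cat(sprintf("image_sequence: %d frames, t = %.4g .. %.4g min\n",
              length(t), min(t), max(t)))
  invisible(x)
}

sequence_times <- function(seq) vapply(seq$frames, function(f) f$time, numeric(1))

#' Reference subtraction
#'
#' Per-channel absolute difference against the reference frame, clamped to
#' the 8-bit range. The absolute difference keeps infusion (colour
#' appearing) and release (colour fading) on the same code path, and makes
#' the result invariant to any offset shared by both frames.
#'
#' @param frame,reference [image_frame()] objects of identical shape.
#' @return an [image_frame()] holding the differential image, timestamped
#'   from `frame`.
#' @export
subtract_reference <- function(frame, reference) {
  stopifnot(inherits(frame, "image_frame"), inherits(reference, "image_frame"))
  if (!identical(dim(frame$pixels), dim(reference$pixels)))
    stop("frame and reference shapes differ")
  d <- abs(frame$pixels - reference$pixels)
  image_frame(pmin(d, 255), time = frame$time, pixel_size = frame$pixel_size)
}

#' Red-channel extraction
#'
#' The guest chromophore is red, so the red plane of the differential image
#' carries the concentration signal; it is copied verbatim as an 8-bit
#' grayscale image (no luminance weighting).
#'
#' @param diff a 3-channel [image_frame()] (normally a differential frame).
#' @return object of class `differential_frame` with fields `red_gray`
#'   (`H x W` matrix) and `time`.
#' @export
extract_red_gray <- function(diff) {
  stopifnot(inherits(diff, "image_frame"))
  if (dim(diff$pixels)[3] != 3) stop("expected a 3-channel frame")
  structure(list(red_gray = diff$pixels[, , 1], time = diff$time,
                 pixel_size = diff$pixel_size),
            class = "differential_frame")
}

#' Mean histogram intensity of a grayscale frame
#'
#' @param gray a [extract_red_gray()] result (or any object with a
#'   `red_gray` matrix).
#' @param mask optional logical matrix selecting the pixels to average;
#'   default is the full frame.
#' @return arithmetic mean on the 0-255 scale.
#' @export
mean_intensity <- function(gray, mask = NULL) {
  g <- gray$red_gray
  if (is.null(mask)) return(mean(g))
  if (!identical(dim(mask), dim(g))) stop("mask shape must match frame")
  if (!any(mask)) stop("empty mask")
  mean(g[mask])
}

#' Crystal mask from a reference frame
#'
#' The projected crystal is darker than the background in the green/blue
#' channels (it absorbs them); thresholding their mean at the midpoint of
#' its range segments crystal from background. Useful because full-frame
#' means dilute the differential signal with background pixels.
#'
#' @param reference an [image_frame()].
#' @return logical `H x W` matrix, `TRUE` on crystal pixels.
#' @export
crystal_mask <- function(reference) {
  stopifnot(inherits(reference, "image_frame"))
  gb <- (reference$pixels[, , 2] + reference$pixels[, , 3]) / 2
  gb < (max(gb) + min(gb)) / 2
}

#' Mean differential red intensity vs. time
#'
#' The pipeline's kinetic observable: every frame after the first is
#' differenced against the reference, reduced to its red plane, and
#' averaged. The reference contributes a zero at its own timestamp.
#'
#' @param seq an [image_sequence()] of at least two frames.
#' @param mask `NULL` (full frame), the string `"crystal"` (threshold the
#'   reference via [crystal_mask()]), or a logical matrix.
#' @return object of class `intensity_trace`: a data frame with columns
#'   `time_min`, `mean_intensity`, `mask_area`.
#' @export
build_trace <- function(seq, mask = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  if (length(seq) < 2) stop("need at least two frames (reference + one)")
  ref <- seq$frames[[1]]
  if (identical(mask, "crystal")) mask <- crystal_mask(ref)
  area <- if (is.null(mask)) prod(dim(ref$pixels)[1:2]) else sum(mask)
  vals <- vapply(seq$frames[-1], function(f) {
    mean_intensity(extract_red_gray(subtract_reference(f, ref)), mask)
  }, numeric(1))
  tr <- data.frame(time_min = sequence_times(seq),
                   mean_intensity = c(0, vals),
                   mask_area = area)
  class(tr) <- c("intensity_trace", "data.frame")
  tr
}

# 3 x 3 median filter with edge replication; knocks out single-pixel noise
# spikes before any maximum/threshold is taken.
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 2) return(m)
  ri <- cbind(c(1, seq_len(nr - 1)), seq_len(nr), c(seq_len(nr - 1) + 1, nr))
  ci <- cbind(c(1, seq_len(nc - 1)), seq_len(nc), c(seq_len(nc - 1) + 1, nc))
  stack <- array(NA_real_, dim = c(nr, nc, 9))
  k <- 0
  for (dr in 1:3) for (dc in 1:3) {
    k <- k + 1
    stack[, , k] <- m[ri[, dr], ci[, dc]]
  }
  apply(stack, c(1, 2), stats::median)
}

# Hydraulic diameter (4 * area / perimeter) of a logical pixel region, in
# micrometres. The perimeter is the Crofton-corrected pixel-edge count
# (pi/4 * exposed 4-neighbour edges), which makes the measure equal the
# ordinary diameter for a digital disk. For a band of depth d along the
# crystal rim it equals ~2d, the diffusion penetration scale.
hydraulic_diameter <- function(region, pixel_size) {
  area <- sum(region)
  nr <- nrow(region); nc <- ncol(region)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- region
  edges <- sum(pad & !rbind(pad[-1, ], FALSE)) +
           sum(pad & !rbind(FALSE, pad[-(nr + 2L), ])) +
           sum(pad & !cbind(pad[, -1], FALSE)) +
           sum(pad & !cbind(FALSE, pad[, -(nc + 2L)]))
  perim <- (pi / 4) * edges
  4 * area / perim * pixel_size
}

#' Linear growth of the released (or infused) spot
#'
#' Measures the spot-change length `omega` used by the FRAP-style
#' diffusion-coefficient formula: in the first post-reference frame and in
#' the frame nearest `t_D`, the differential red image is median-filtered
#' (3 x 3) and thresholded at half its maximum; `omega` is the change in
#' the thresholded region's linear size between those two frames, in
#' micrometres.
#'
#' The region's linear size is its hydraulic diameter, `4 * area /
#' perimeter`: for a compact disk-like spot this is exactly the spot
#' diameter, while for the annular spot a crystal releases from all its
#' faces it is twice the band depth -- in both cases the diffusion
#' penetration scale the FRAP-style formula expects, rather than an area
#' statistic that saturates at the crystal size. The perimeter uses the
#' Crofton correction (pi/4 times the exposed pixel-edge count), and the
#' 3 x 3 median filter removes single-pixel noise spikes that would
#' otherwise define the frame maximum.
#'
#' @param seq an [image_sequence()]; its `pixel_size` must be known.
#' @param t_D characteristic half-intensity time in minutes (from
#'   [fit_release()]).
#' @param threshold fraction of the frame maximum defining the spot region.
#' @return `omega` in micrometres, with attribute `details` (frame times,
#'   threshold and the two diameters used).
#' @export
measure_spot_change <- function(seq, t_D, threshold = 0.5) {
  stopifnot(inherits(seq, "image_sequence"))
  if (length(seq) < 3) stop("need a reference and at least two frames")
  if (t_D <= 0) stop("t_D must be positive")
  ps <- seq$frames[[1]]$pixel_size
  if (is.na(ps)) stop("pixel size unknown; omega needs a physical scale")
  ref <- seq$frames[[1]]
  times <- sequence_times(seq)[-1]
  k_near <- which.min(abs(times - t_D)) + 1L
  pick <- c(2L, k_near)
  diam <- vapply(pick, function(k) {
    g <- median3x3(extract_red_gray(subtract_reference(seq$frames[[k]], ref))$red_gray)
    m <- max(g)
    if (m <= 0) stop("empty thresholded region: frame shows no differential signal")
    hydraulic_diameter(g >= threshold * m, ps)
  }, numeric(1))
  omega <- diam[2] - diam[1]
  attr(omega, "details") <- list(
    t_first = times[1], t_near = times[k_near - 1L], threshold = threshold,
    measure = "hydraulic diameter (4A/P, Crofton perimeter)",
    diameter_first_um = diam[1], diameter_tD_um = diam[2])
  omega
}
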