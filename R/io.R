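#' Write an image sequence as PNG frames plus a manifest
#'
#' The manifest CSV (`filename`, `time_min`, `pixel_size_um`) is the single
#' source of timing truth; frames in real experiments come at irregular
#' intervals and filename conventions are fragile.
#'
#' @param seq an [image_sequence()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the manifest path.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "image_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  times <- sequence_times(seq)
  files <- sprintf("%s_%04d.png", prefix, seq_along(times))
  for (k in seq_along(times)) {
    png::writePNG(seq$frames[[k]]$pixels / 255, file.path(dir, files[k]))
  }
  ps <- seq$frames[[1]]$pixel_size
  manifest <- data.frame(filename = files, time_min = times,
                         pixel_size_um = ps)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = , tiff = {
                 if (!requireNamespace("tiff", quietly = TRUE))
                   stop("reading TIFF frames requires the 'tiff' package")
                 tiff::readTIFF(path)
               },
               stop("unsupported frame format: ", ext))
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  round(px * 255)
}

#' Read an image sequence from a manifest CSV
#'
#' Frames are ordered by `time_min` (with a warning if the manifest rows
#' were not already sorted); duplicate timestamps and missing files are
#' errors, and all frames must agree in shape and pixel size.
#'
#' @param manifest_path path to a manifest CSV with columns `filename`,
#'   `time_min`, `pixel_size_um`.
#' @return an [image_sequence()].
#' @export
read_sequence <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("filename", "time_min", "pixel_size_um")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$time_min)) stop("duplicate timestamp in manifest")
  if (is.unsorted(man$time_min)) {
    warning("manifest rows not sorted by time; sorting on load")
    man <- man[order(man$time_min), , drop = FALSE]
  }
  if (length(unique(man$pixel_size_um)) > 1)
    stop("a sequence must have a single pixel size")
  root <- dirname(manifest_path)
  paths <- file.path(root, man$filename)
  missing <- !file.exists(paths)
  if (any(missing)) stop("missing frame file(s): ",
                         paste(man$filename[missing], collapse = ", "))
  frames <- lapply(seq_len(nrow(man)), function(k) {
    image_frame(read_frame_file(paths[k]), time = man$time_min[k],
                pixel_size = man$pixel_size_um[k])
  })
  image_sequence(frames)
}

#' Write / read an intensity trace as CSV
#'
#' CSV round-trips losslessly at full double precision. An optional JSON
#' sidecar (`<path>.json`) records the pipeline settings used to produce
#' the trace.
#'
#' @param trace an [build_trace()] result; must be non-empty.
#' @param path output CSV path.
#' @param settings optional list of pipeline settings for the sidecar.
#' @return invisibly, `path`.
#' @export
write_trace <- function(trace, path, settings = NULL) {
  if (is.null(trace) || !nrow(trace)) stop("refusing to write an empty trace")
  df <- as.data.frame(trace)
  df$time_min <- sprintf("%.17g", df$time_min)
  df$mean_intensity <- sprintf("%.17g", df$mean_intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(settings))
    jsonlite::write_json(settings, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  class(tr) <- c("intensity_trace", "data.frame")
  tr
}

# Deterministic provenance block: config hash + seed + package version.
provenance <- function(seed = NULL, config = NULL) {
  hash <- NULL
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
    hash <- unname(tools::md5sum(tmp))
  }
  Filter(Negate(is.null),
         list(package = "mofdiff",
              version = as.character(utils::packageVersion("mofdiff")),
              seed = seed, config_md5 = hash))
}

#' Serialize analysis results as JSON
#'
#' Diffusion estimates and release fits are written with their echoed
#' inputs and a provenance block (package version, seed, config hash) so a
#' result file is self-describing. Numbers are written at full precision.
#'
#' @param x a `diffusion_estimate`, `release_fit`, or plain list.
#' @param path output JSON path.
#' @param seed,config optional provenance inputs.
#' @return invisibly, `path`.
#' @export
write_results <- function(x, path, seed = NULL, config = NULL) {
  payload <- if (inherits(x, "diffusion_estimate")) {
    echo <- x$inputs_echo
    fit <- echo$fit
    list(D_m2_per_s = x$D, method = x$method,
         omega_um = echo$omega_um, t_D_min = echo$t_D_min,
         q_i = echo$q_i, msd_um2 = echo$msd_um2, elapsed_s = echo$elapsed_s,
         fit = if (!is.null(fit)) list(A = fit$A, tau = fit$tau,
                                       plateau = fit$plateau, rmse = fit$rmse,
                                       model = fit$model))
  } else if (inherits(x, "release_fit")) {
    list(fit = list(A = x$A, tau = x$tau, plateau = x$plateau,
                    t_D_min = x$t_D, rmse = x$rmse, model = x$model))
  } else {
    x
  }
  payload <- Filter(Negate(is.null), payload)
  payload$provenance <- provenance(seed, config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' A run configuration binds the simulator, optics and pipeline settings:
#' `geometry` (`extents`, `voxel_pitch`, optional `exposed_faces`),
#' `params` (`D`, optional `dt`), `optics` (optional overrides of
#' [optics_model()] fields), `mode`, `sample_times_min`, and a mandatory
#' `seed` (any stochastic stage without a seed is a configuration error).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return a validated list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  need <- c("geometry", "params", "mode", "sample_times_min", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  if (!all(c("extents", "voxel_pitch") %in% names(cfg$geometry)))
    stop("config geometry needs extents and voxel_pitch")
  if (!"D" %in% names(cfg$params)) stop("config params needs D (m^2/s)")
  if (!cfg$mode %in% c("uptake", "release")) stop("mode must be uptake or release")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config needs a single integer seed")
  class(cfg) <- c("run_config", "list")
  cfg
}

# Materialise the S3 objects a config describes.
config_objects <- function(cfg) {
  geo <- crystal_geometry(
    extents = cfg$geometry$extents,
    voxel_pitch = cfg$geometry$voxel_pitch,
    exposed_faces = cfg$geometry$exposed_faces %||% ALL_FACES)
  D <- cfg$params$D
  if (!is.null(names(D))) D <- unlist(D)
  par <- diffusion_params(D_face = D, dt = cfg$params$dt %||% NULL)
  oc <- cfg$optics %||% list()
  opt <- optics_model(
    view_axis = oc$view_axis %||% 3,
    extinction = oc$extinction %||% 0.03,
    background_rgb = oc$background_rgb %||% c(235, 235, 235),
    channel_weights = oc$channel_weights %||% c(0.25, 1, 1),
    noise_sd = oc$noise_sd %||% 2,
    pad = oc$pad %||% 8,
    seed = cfg$seed)
  list(geometry = geo, params = par, optics = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
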