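#' Literature constants for MOF colorimetric sensing design
#'
#' Loads the versioned JSON file of cited constants shipped with the
#' package: maximum guest load per mg of MOF, initial uptake rate,
#' spectroscopic detection limit, cage and window diameters, and the
#' guest-molecule box dimensions. These are stored constants with their
#' provenance notes; they are never used to calibrate the simulator.
#'
#' @return a named list; each entry has `value`, `units` and `note`.
#' @export
sensing_constants <- function() {
  path <- system.file("extdata", "sensing_constants.json", package = "mofdiff")
  if (path == "") stop("sensing_constants.json not found")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Guest capacity of a MOF mass at saturation
#'
#' Linear in mass: `capacity = mass * max_load_ratio`. In a sensing system
#' this sets the maximum detectable amount.
#'
#' @param mass_mg MOF mass in mg (>= 0).
#' @param max_load_ratio mg guest per mg MOF.
#' @return guest mass at saturation, in mg.
#' @examples
#' capacity(1)   # 0.33 mg
#' @export
capacity <- function(mass_mg, max_load_ratio = sensing_constants()$max_load_ratio$value) {
  if (any(mass_mg < 0)) stop("mass must be >= 0")
  mass_mg * max_load_ratio
}

#' Can a rigid box-shaped molecule pass a circular pore window?
#'
#' A molecule presents its two smallest axes to the aperture, so the
#' criterion is `max(two smallest dims) <= window_diameter` (inclusive at
#' equality). This is the minimal geometric rule consistent with a
#' 1.41 x 1.83 x 1.14 nm guest demonstrably entering through <= 1.7 nm
#' windows while 1.3 nm windows are sub-molecular.
#'
#' @param molecule_dims three positive box dimensions in nm (any order).
#' @param window_diameter circular aperture diameter in nm.
#' @return `TRUE` if the molecule can pass.
#' @examples
#' window_accessibility(c(1.41, 1.83, 1.14), 1.7)  # TRUE
#' window_accessibility(c(1.41, 1.83, 1.14), 1.3)  # FALSE
#' @export
window_accessibility <- function(molecule_dims, window_diameter) {
  if (length(molecule_dims) != 3 || any(molecule_dims <= 0))
    stop("molecule_dims must be three positive lengths")
  if (window_diameter <= 0) stop("window_diameter must be positive")
  d <- sort(molecule_dims, decreasing = TRUE)
  d[2] <= window_diameter + 1e-12
}

#' Initial uptake rate from an intensity trace
#'
#' Fits a least-squares line to the trace points inside the early window
#' (where uptake is close to linear, being a short section of a sqrt-law),
#' and expresses the slope as a fraction of the saturation intensity per
#' hour -- the quantity quoted as "% per hour" in uptake studies.
#'
#' @param trace an [build_trace()] result from an uptake run.
#' @param window_min use points with `time_min <= window_min` (>= 3 points
#'   required).
#' @param saturation saturation intensity (counts). Defaults to the trace
#'   maximum, which is only honest if the trace actually saturates.
#' @return rate as fraction of saturation per hour.
#' @export
initial_uptake_rate <- function(trace, window_min,
                                saturation = max(trace$mean_intensity)) {
  sel <- trace$time_min <= window_min
  if (sum(sel) < 3) stop("need at least 3 trace points inside the window")
  if (max(trace$time_min) < window_min) stop("window extends beyond the trace")
  if (saturation <= 0) stop("saturation must be positive")
  fit <- stats::lm(mean_intensity ~ time_min, data = trace[sel, , drop = FALSE])
  slope_per_min <- unname(stats::coef(fit)[2])
  slope_per_min * 60 / saturation
}

# Canonical probe voxel indices, one voxel inside the Dirichlet-held
# surface layer (surface voxels are pinned to the bath occupancy and would
# all tie at t50 = 0). A probe is reported only when every face it presses
# against is exposed; the body centre is always reported.
probe_indices <- function(geometry) {
  n <- geometry$grid
  exp_f <- geometry$exposed_faces
  mid <- pmax(1L, as.integer(ceiling(n / 2)))
  near <- function(ax) {
    if (paste0(c("x", "y", "z")[ax], "-") %in% exp_f) return(2L)
    if (paste0(c("x", "y", "z")[ax], "+") %in% exp_f) return(n[ax] - 1L)
    NA_integer_
  }
  nn <- vapply(1:3, near, integer(1))
  avail <- which(!is.na(nn))
  probes <- list(body_center = mid)
  if (length(avail) >= 1) {
    p <- mid; p[avail[1]] <- nn[avail[1]]
    probes$face_center <- p
  }
  if (length(avail) >= 2) {
    p <- mid; p[avail[1:2]] <- nn[avail[1:2]]
    probes$edge_midpoint <- p
  }
  if (length(avail) == 3) probes$corner <- nn
  probes[intersect(c("corner", "edge_midpoint", "face_center", "body_center"),
                   names(probes))]
}

#' Half-saturation times at corner, edge, face and centre probes
#'
#' For an uptake run, extracts the occupancy time series at canonical probe
#' voxels -- corner, edge midpoint, face centre (each one voxel inside the
#' exposed surface) and body centre -- and linearly interpolates the time at
#' which each first reaches 50% occupancy. Diffusion reaches a corner from
#' three faces at once, an edge from two and a face centre from one, so on
#' an all-faces-exposed crystal the half-saturation times must order
#' corner < edge < face centre < body centre. Probes whose faces are sealed
#' are excluded.
#'
#' @param fields list of `concentration_field` snapshots from an uptake run
#'   covering saturation (e.g. [simulate_diffusion()] output).
#' @param geometry the matching [crystal_geometry()].
#' @return object of class `saturation_ordering`: list with `t50` (named
#'   vector, minutes) and `ordered` (`TRUE` if the available probes are
#'   strictly ordered corner < edge < face < centre; `NA` when the input is
#'   already saturated so every t50 is 0).
#' @export
saturation_ordering <- function(fields, geometry) {
  stopifnot(length(fields) >= 2, inherits(geometry, "crystal_geometry"))
  times <- vapply(fields, function(f) f$time, numeric(1))
  probes <- probe_indices(geometry)
  t50 <- vapply(names(probes), function(nm) {
    idx <- probes[[nm]]
    u <- vapply(fields, function(f) f$occupancy[idx[1], idx[2], idx[3]], numeric(1))
    if (u[1] >= 0.5) return(0)
    k <- which(u >= 0.5)[1]
    if (is.na(k)) stop("probe '", nm, "' never reaches half saturation; extend the run")
    t0 <- if (k == 1) 0 else times[k - 1]
    u0 <- if (k == 1) u[1] else u[k - 1]
    t0 + (0.5 - u0) / (u[k] - u0) * (times[k] - t0)
  }, numeric(1))
  ordered <- if (all(t50 == 0)) NA else all(diff(t50) > 0)
  structure(list(t50 = t50, ordered = ordered), class = "saturation_ordering")
}

#' @export
print.saturation_ordering <- function(x, ...) {
  cat("half-saturation times (min):\n")
  print(round(x$t50, 2))
  cat("strictly ordered corner < edge < face < centre:", x$ordered, "\n")
  invisible(x)
}
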