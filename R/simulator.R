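#' Create a uniform concentration field over a crystal
#'
#' @param geometry a [crystal_geometry()].
#' @param initial_occupancy fractional guest occupancy in `[0, 1]` applied to
#'   every voxel; 0 is an empty (colourless) crystal, 1 a fully infused one.
#' @return an object of class `concentration_field` with fields `occupancy`
#'   (3D array) and `time` (elapsed minutes, starts at 0).
#' @export
build_field <- function(geometry, initial_occupancy = 0) {
  stopifnot(inherits(geometry, "crystal_geometry"))
  if (!is.numeric(initial_occupancy) || length(initial_occupancy) != 1 ||
      is.na(initial_occupancy) ||
      initial_occupancy < 0 || initial_occupancy > 1)
    stop("initial_occupancy must be a single value in [0, 1]")
  structure(
    list(occupancy = array(initial_occupancy, dim = geometry$grid), time = 0),
    class = "concentration_field"
  )
}

#' @export
print.concentration_field <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("concentration_field: %d x %d x %d voxels, t = %.4g min, mean occupancy %.4g\n",
              d[1], d[2], d[3], x$time, mean(x$occupancy)))
  invisible(x)
}

#' Diffusion parameters for a crystal simulation
#'
#' @param D_face diffusivity in m^2/s; either a single value used everywhere
#'   or a named vector with entries for faces `"x-"`, ..., `"z+"` to model
#'   face-dependent ingress speed.
#' @param boundary_occupancy fractional surface concentration imposed by the
#'   bath: 1 for uptake from a saturated solution, 0 for release into pure
#'   solvent.
#' @param dt explicit time step in seconds, or `NULL` to choose
#'   automatically just inside the stability bound.
#' @return object of class `diffusion_params`.
#' @export
diffusion_params <- function(D_face, boundary_occupancy = 1, dt = NULL) {
  if (!is.numeric(D_face) || any(D_face < 0)) stop("D_face must be >= 0")
  if (length(D_face) > 1 && is.null(names(D_face)))
    stop("multiple D_face values must be named by face")
  if (!is.null(names(D_face)) && !all(names(D_face) %in% ALL_FACES))
    stop("unknown face name in D_face")
  if (boundary_occupancy < 0 || boundary_occupancy > 1)
    stop("boundary_occupancy must be in [0, 1]")
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  structure(list(D_face = D_face, boundary_occupancy = boundary_occupancy,
                 dt = dt),
            class = "diffusion_params")
}

#' Largest stable explicit time step
#'
#' The solver is a forward-time centred-space (FTCS) scheme; on an isotropic
#' grid of pitch `h` it is monotone (keeps occupancy in `[0, 1]`) only for
#' `dt <= h^2 / (6 * max(D))`. The solver refuses larger steps rather than
#' produce out-of-range occupancies.
#'
#' @param geometry a [crystal_geometry()].
#' @param params a [diffusion_params()].
#' @return the bound in seconds.
#' @export
stability_dt <- function(geometry, params) {
  D_um <- convert_unit(max(params$D_face), "m2/s", "um2/s")
  if (D_um == 0) return(Inf)
  geometry$voxel_pitch^2 / (6 * D_um)
}

resolve_dt <- function(geometry, params) {
  bound <- stability_dt(geometry, params)
  dt <- if (is.null(params$dt)) 0.99 * bound else params$dt
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %.4g s violates the FTCS stability bound %.4g s", dt, bound))
  if (!is.finite(dt)) stop("dt must be finite (set dt explicitly when D = 0)")
  dt
}

# Extract / overwrite a slab of a 3D array along one axis.
get_slab <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

set_slab <- function(a, axis, idx, value) {
  switch(axis,
         a[idx, , ] <- value,
         a[, idx, ] <- value,
         a[, , idx] <- value)
  a
}

# Voxel diffusivity map in um^2/s. Interior voxels use max(D_face); a
# two-voxel layer under each exposed face uses that face's value, the
# minimal mechanism for face-dependent ingress speed (well-defined infused
# layers behind fast faces). Overlapping layers at edges/corners take the
# larger of the competing face values.
diffusivity_field <- function(geometry, params) {
  n <- geometry$grid
  D <- params$D_face
  if (length(D) == 1 && is.null(names(D))) D <- stats::setNames(rep(D, 6), ALL_FACES)
  Dmax_um <- convert_unit(max(D), "m2/s", "um2/s")
  arr <- array(Dmax_um, dim = n)
  layer <- array(-Inf, dim = n)
  depth <- 2L
  for (f in geometry$exposed_faces) {
    if (!f %in% names(D)) next
    Df_um <- convert_unit(unname(D[[f]]), "m2/s", "um2/s")
    ax <- match(substr(f, 1, 1), c("x", "y", "z"))
    idx <- if (substr(f, 2, 2) == "-") seq_len(min(depth, n[ax]))
           else seq(max(1L, n[ax] - depth + 1L), n[ax])
    layer <- set_slab(layer, ax, idx, pmax(get_slab(layer, ax, idx), Df_um))
  }
  sel <- is.finite(layer)
  arr[sel] <- layer[sel]
  arr
}

# Precompute everything reusable across steps; returns a closure that
# advances the grid by n conservative FTCS steps via the compiled kernel.
diffusion_stepper <- function(geometry, params) {
  n <- geometry$grid
  h <- geometry$voxel_pitch
  Dvox <- diffusivity_field(geometry, params)
  clamp <- which(clamped_voxels(geometry))
  b <- params$boundary_occupancy
  function(u, dt, n_steps = 1L) {
    out <- step_ftcs_cpp(as.vector(u), as.vector(Dvox), n,
                         as.integer(clamp), b, dt / h^2, as.integer(n_steps))
    array(out, dim = n)
  }
}

#' Advance a concentration field by explicit finite differences
#'
#' One or more forward-time centred-space (FTCS) steps of the diffusion
#' equation in conservative (flux) form, with spatially varying diffusivity.
#' Exposed faces are Dirichlet boundaries: their outermost voxel layer (and
#' any defect voxels) is held at the bath occupancy. Sealed faces are
#' zero-flux, so a fully sealed crystal conserves total occupancy up to
#' floating-point rounding.
#'
#' @param field a [build_field()] result.
#' @param geometry a [crystal_geometry()]; must match the field's grid.
#' @param params a [diffusion_params()]; `params$dt` (or the automatic step)
#'   must satisfy [stability_dt()].
#' @param n_steps number of steps to take.
#' @return the advanced `concentration_field`; `time` moves by
#'   `n_steps * dt`.
#' @export
step_diffusion <- function(field, geometry, params, n_steps = 1L) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(geometry, "crystal_geometry"),
            inherits(params, "diffusion_params"))
  if (!identical(dim(field$occupancy), geometry$grid))
    stop("field grid does not match geometry")
  dt <- resolve_dt(geometry, params)
  step <- diffusion_stepper(geometry, params)
  u <- step(field$occupancy, dt, n_steps)
  if (anyNA(u) || any(!is.finite(u))) stop("NaN in concentration field")
  field$occupancy <- u
  field$time <- field$time + convert_unit(n_steps * dt, "s", "min")
  field
}

#' Total guest occupancy of a field
#'
#' @param field a `concentration_field`.
#' @param geometry the matching [crystal_geometry()]; needed when
#'   `exclude_clamped = TRUE`.
#' @param exclude_clamped drop the Dirichlet-held surface voxels, leaving
#'   the flux-driven interior uptake (the quantity with clean `sqrt(t)`
#'   short-time scaling).
#' @return sum of voxel occupancies.
#' @export
total_occupancy <- function(field, geometry = NULL, exclude_clamped = FALSE) {
  if (!exclude_clamped) return(sum(field$occupancy))
  stopifnot(inherits(geometry, "crystal_geometry"))
  sum(field$occupancy[!clamped_voxels(geometry)])
}

#' Simulate guest uptake or release and return field snapshots
#'
#' Uptake starts from an empty crystal with the bath at saturation
#' (boundary occupancy 1); release starts from a fully infused crystal with
#' the bath at zero (pure solvent). The solver advances in stable explicit
#' steps, shortening the final step to land exactly on each requested
#' sample time.
#'
#' @param geometry a [crystal_geometry()].
#' @param params a [diffusion_params()]; its `boundary_occupancy` is
#'   overridden by `mode` unless `override_boundary = FALSE`.
#' @param mode `"uptake"` or `"release"`.
#' @param sample_times strictly increasing snapshot times in minutes.
#' @param override_boundary set `FALSE` to keep `params$boundary_occupancy`
#'   (e.g. a partially loaded bath).
#' @return a list of `concentration_field` snapshots, one per sample time.
#' @export
simulate_diffusion <- function(geometry, params,
                               mode = c("uptake", "release"),
                               sample_times,
                               override_boundary = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(sample_times), length(sample_times) >= 1)
  if (any(diff(sample_times) <= 0) || any(sample_times < 0))
    stop("sample_times must be non-negative and strictly increasing")
  if (override_boundary)
    params$boundary_occupancy <- if (mode == "uptake") 1 else 0
  init <- if (mode == "uptake") 0 else 1
  field <- build_field(geometry, init)
  dt <- resolve_dt(geometry, params)
  step <- diffusion_stepper(geometry, params)
  u <- field$occupancy
  out <- vector("list", length(sample_times))
  t_s <- 0
  for (k in seq_along(sample_times)) {
    target <- convert_unit(sample_times[k], "min", "s")
    n_full <- max(0L, floor((target - t_s) / dt - 1e-12))
    if (n_full > 0) {
      u <- step(u, dt, n_full)
      t_s <- t_s + n_full * dt
    }
    if (target - t_s > 1e-9) {
      u <- step(u, target - t_s, 1L)
      t_s <- target
    }
    if (anyNA(u) || any(!is.finite(u))) stop("NaN in concentration field")
    snap <- field
    snap$occupancy <- u
    snap$time <- sample_times[k]
    out[[k]] <- snap
  }
  out
}
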