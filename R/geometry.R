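ALL_FACES <- c("x-", "x+", "y-", "y+", "z-", "z+")

#' Describe a faceted crystal as a voxel grid
#'
#' A crystal is modelled as an axis-aligned box of physical size `extents`
#' (micrometres per axis) discretised into isotropic cubic voxels of edge
#' `voxel_pitch`. The box is half-open, `[0, extent)` per axis; voxel `i`
#' (1-based) spans `[(i-1)*pitch, i*pitch)`. A subset of the six faces is in
#' contact with the surrounding solution (`exposed_faces`); the rest are
#' sealed (resting on the dish, or masked). Surface defects -- chips, bumps,
#' scratches that admit guest molecules from several directions at once --
#' are listed as sets of surface voxels that behave as extra exposed surface.
#'
#' @param extents physical size per axis in micrometres; a scalar is
#'   recycled to a cube.
#' @param voxel_pitch voxel edge length in micrometres (isotropic).
#' @param exposed_faces character vector, subset of
#'   `c("x-","x+","y-","y+","z-","z+")`. An empty vector seals the crystal
#'   completely -- physically a crystal out of solution, used for
#'   mass-conservation validation of the solver.
#' @param defects list of integer matrices with three columns (1-based voxel
#'   indices); every listed voxel must lie on the crystal surface.
#' @return an object of class `crystal_geometry` with fields `extents`,
#'   `voxel_pitch`, `grid` (voxel counts per axis), `exposed_faces`,
#'   `defects`.
#' @examples
#' g <- crystal_geometry(100, 2)   # 100 um cube, 50^3 voxels
#' g$grid
#' @export
crystal_geometry <- function(extents, voxel_pitch,
                             exposed_faces = ALL_FACES,
                             defects = list()) {
  if (length(extents) == 1) extents <- rep(extents, 3)
  stopifnot(length(extents) == 3, is.numeric(extents), is.numeric(voxel_pitch))
  if (any(extents <= 0)) stop("extents must be positive")
  if (voxel_pitch <= 0) stop("voxel_pitch must be positive")
  grid <- as.integer(floor(extents / voxel_pitch + 1e-9))
  if (any(grid < 1))
    stop("voxel_pitch larger than extents: grid degenerates to zero voxels")
  exposed_faces <- unique(exposed_faces)
  if (!all(exposed_faces %in% ALL_FACES))
    stop("unknown face name; use ", paste(ALL_FACES, collapse = ", "))
  defects <- lapply(defects, function(d) {
    d <- as.matrix(d)
    storage.mode(d) <- "integer"
    if (ncol(d) != 3) stop("defect voxel sets need three index columns")
    if (any(d < 1) || any(sweep(d, 2, grid, ">")))
      stop("defect voxel outside the grid")
    on_surface <- rowSums(d == 1 | sweep(d, 2, grid, "==")) > 0
    if (!all(on_surface)) stop("every defect voxel must lie on the crystal surface")
    d
  })
  structure(
    list(extents = as.numeric(extents), voxel_pitch = as.numeric(voxel_pitch),
         grid = grid, exposed_faces = exposed_faces, defects = defects),
    class = "crystal_geometry"
  )
}

#' @export
print.crystal_geometry <- function(x, ...) {
  cat(sprintf("crystal_geometry: %.4g x %.4g x %.4g um, pitch %.4g um (%d x %d x %d voxels)\n",
              x$extents[1], x$extents[2], x$extents[3], x$voxel_pitch,
              x$grid[1], x$grid[2], x$grid[3]))
  cat("  exposed faces:", paste(x$exposed_faces, collapse = " "), "\n")
  if (length(x$defects))
    cat("  defects:", length(x$defects), "surface region(s)\n")
  invisible(x)
}

# Logical mask of voxels held at the bath occupancy: the outermost voxel
# layer of every exposed face, plus all defect voxels.
clamped_voxels <- function(geometry) {
  n <- geometry$grid
  m <- array(FALSE, dim = n)
  for (f in geometry$exposed_faces) {
    ax <- match(substr(f, 1, 1), c("x", "y", "z"))
    idx <- if (substr(f, 2, 2) == "-") 1L else n[ax]
    if (ax == 1) m[idx, , ] <- TRUE
    else if (ax == 2) m[, idx, ] <- TRUE
    else m[, , idx] <- TRUE
  }
  for (d in geometry$defects) m[d] <- TRUE
  m
}
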