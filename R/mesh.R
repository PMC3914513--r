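#' Cylindrical sample geometry
#'
#' @param radius cylinder radius in metres.
#' @param length electrode-to-electrode gap in metres.
#' @return An object of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(radius = 0.010, length = 0.20) {
  if (!is.finite(radius) || radius <= 0) stop("cylinder_geometry: radius must be > 0")
  if (!is.finite(length) || length <= 0) stop("cylinder_geometry: length must be > 0")
  structure(list(radius = radius, length = length), class = "cylinder_geometry")
}

#' Build a structured axisymmetric mesh of a cylinder
#'
#' Discretises the (r, z) half-section of the cylinder into `nr` x `nz`
#' uniform cells. Because the geometry, electrical loading and boundary
#' conditions are all rotationally symmetric, the full 3-D field is recovered
#' from this 2-D section; each cell represents an annulus of volume
#' 2 pi r dr dz (exact for a mid-point radius). Cells are stored
#' column-major: cell (i, j) -> index (j-1)*nr + i, with i the radial and j
#' the axial index.
#'
#' Exterior boundaries are tagged `electrode_bottom` (z = 0),
#' `electrode_top` (z = L) and `lateral` (r = R); the axis r = 0 is a
#' symmetry line carrying zero flux (its radial face area is zero).
#'
#' @param geom a [cylinder_geometry()].
#' @param nr number of radial cells (>= 2).
#' @param nz number of axial cells (>= 2).
#' @return An object of class `axisym_mesh`.
#' @export
build_mesh <- function(geom, nr = 16L, nz = 16L) {
  stopifnot(inherits(geom, "cylinder_geometry"))
  nr <- as.integer(nr); nz <- as.integer(nz)
  if (is.na(nr) || nr < 2L || is.na(nz) || nz < 2L)
    stop("build_mesh: nr and nz must be integers >= 2")
  R <- geom$radius; L <- geom$length
  dr <- R / nr; dz <- L / nz
  r <- (seq_len(nr) - 0.5) * dr          # cell-centre radii
  z <- (seq_len(nz) - 0.5) * dz          # cell-centre axial positions
  r_face <- seq(0, R, length.out = nr + 1L)
  z_face <- seq(0, L, length.out = nz + 1L)
  cell_r <- rep(r, times = nz)
  cell_z <- rep(z, each = nr)
  volume <- 2 * pi * cell_r * dr * dz    # exact annular volume
  structure(list(
    nr = nr, nz = nz, dr = dr, dz = dz,
    r = r, z = z, r_face = r_face, z_face = z_face,
    cell_r = cell_r, cell_z = cell_z, volume = volume,
    # radial face area at face k (k = 1 is the axis, area 0): 2 pi r_face dz
    area_r_face = 2 * pi * r_face * dz,
    # axial face area of radial ring i (same at every z level): 2 pi r_i dr
    area_z_face = 2 * pi * r * dr,
    radius = R, length = L, ncell = nr * nz,
    geometry = geom), class = "axisym_mesh")
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric mesh: %d x %d cells (r x z), R = %g m, L = %g m\n",
              x$nr, x$nz, x$radius, x$length))
  cat(sprintf("  dr = %g m, dz = %g m, total volume = %g m^3\n",
              x$dr, x$dz, sum(x$volume)))
  invisible(x)
}

#' Linear cell index from (i, j) grid indices
#'
#' @param mesh an `axisym_mesh`.
#' @param i radial index (1 = on axis, nr = outermost ring).
#' @param j axial index (1 = bottom electrode layer, nz = top).
#' @return Integer index into cell-ordered vectors.
#' @export
mesh_index <- function(mesh, i, j) {
  stopifnot(inherits(mesh, "axisym_mesh"))
  (as.integer(j) - 1L) * mesh$nr + as.integer(i)
}

#' (i, j) grid indices from a linear cell index
#'
#' @param mesh an `axisym_mesh`.
#' @param idx linear cell index.
#' @return A list with integer vectors `i` and `j`.
#' @export
mesh_ij <- function(mesh, idx) {
  stopifnot(inherits(mesh, "axisym_mesh"))
  idx <- as.integer(idx)
  i <- (idx - 1L) %% mesh$nr + 1L
  j <- (idx - 1L) %/% mesh$nr + 1L
  list(i = i, j = j)
}

#' Exterior boundary faces with tags
#'
#' Enumerates every exterior face of the mesh with its cell, tag and area.
#' The axis (r = 0) is not listed: it is a symmetry line with zero radial
#' face area, not a physical boundary.
#'
#' @param mesh an `axisym_mesh`.
#' @return A data.frame with columns `cell`, `i`, `j`, `tag`, `area_m2` and
#'   `dist_m` (cell centre to face distance).
#' @export
boundary_faces <- function(mesh) {
  stopifnot(inherits(mesh, "axisym_mesh"))
  nr <- mesh$nr; nz <- mesh$nz
  bottom <- data.frame(cell = mesh_index(mesh, seq_len(nr), 1L),
                       i = seq_len(nr), j = 1L, tag = "electrode_bottom",
                       area_m2 = mesh$area_z_face, dist_m = mesh$dz / 2)
  top <- data.frame(cell = mesh_index(mesh, seq_len(nr), nz),
                    i = seq_len(nr), j = nz, tag = "electrode_top",
                    area_m2 = mesh$area_z_face, dist_m = mesh$dz / 2)
  lateral <- data.frame(cell = mesh_index(mesh, nr, seq_len(nz)),
                        i = nr, j = seq_len(nz), tag = "lateral",
                        area_m2 = rep(mesh$area_r_face[nr + 1L], nz),
                        dist_m = mesh$dr / 2)
  rbind(bottom, top, lateral)
}

#' Reshape a cell-ordered field to an (nr x nz) matrix
#'
#' @param mesh an `axisym_mesh`.
#' @param x numeric vector of length `mesh$ncell`.
#' @return A matrix with `nr` rows (radius) and `nz` columns (axial position).
#' @export
field_matrix <- function(mesh, x) {
  stopifnot(inherits(mesh, "axisym_mesh"), length(x) == mesh$ncell)
  matrix(x, nrow = mesh$nr, ncol = mesh$nz)
}
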