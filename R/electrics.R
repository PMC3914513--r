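#' Electrical boundary specification
#'
#' One electrode (z = L) is held at the applied voltage, the other (z = 0) is
#' grounded; the lateral surface and the axis carry no normal current. In
#' `constant_power` drive the applied voltage is rescaled over time so the
#' total dissipated power stays at a set point (see
#' [rescale_for_constant_power()]); the voltage given here is then the value
#' at which the run starts.
#'
#' @param applied_voltage potential difference between the electrodes, volts
#'   (> 0). Interpreted as the effective (RMS) value entering the Joule term.
#' @param drive_mode `"constant_voltage"` or `"constant_power"`.
#' @return An object of class `electric_bc`.
#' @export
electric_bc <- function(applied_voltage = 100,
                        drive_mode = c("constant_voltage", "constant_power")) {
  drive_mode <- match.arg(drive_mode)
  if (!is.finite(applied_voltage) || applied_voltage <= 0)
    stop("electric_bc: applied_voltage must be > 0")
  structure(list(applied_voltage = applied_voltage, drive_mode = drive_mode),
            class = "electric_bc")
}

# Harmonic-mean face conductances G = k_f * A / d for every internal face.
# The harmonic mean preserves flux continuity across jumps in the coefficient,
# and makes the scheme exact for piecewise-constant 1-D profiles.
# Returns parallel vectors p, q (cell indices across each face) and G.
.face_conductances <- function(mesh, k) {
  nr <- mesh$nr; nz <- mesh$nz
  K <- matrix(k, nr, nz)
  # radial faces between rings i and i+1 (face radius r_face[i+1])
  kh_r <- 2 * K[-nr, , drop = FALSE] * K[-1, , drop = FALSE] /
    (K[-nr, , drop = FALSE] + K[-1, , drop = FALSE])
  G_r <- kh_r * (mesh$area_r_face[2:nr] / mesh$dr)
  i_r <- rep(seq_len(nr - 1L), times = nz)
  j_r <- rep(seq_len(nz), each = nr - 1L)
  p_r <- (j_r - 1L) * nr + i_r
  # axial faces between levels j and j+1
  kh_z <- 2 * K[, -nz, drop = FALSE] * K[, -1, drop = FALSE] /
    (K[, -nz, drop = FALSE] + K[, -1, drop = FALSE])
  G_z <- kh_z * (mesh$area_z_face / mesh$dz)
  i_z <- rep(seq_len(nr), times = nz - 1L)
  j_z <- rep(seq_len(nz - 1L), each = nr)
  p_z <- (j_z - 1L) * nr + i_z
  list(p = c(p_r, p_z), q = c(p_r + 1L, p_z + nr),
       G = c(as.vector(G_r), as.vector(G_z)))
}

# Half-cell Dirichlet conductances at the two electrode layers.
.electrode_conductances <- function(mesh, k) {
  nr <- mesh$nr; nz <- mesh$nz
  K <- matrix(k, nr, nz)
  Gd <- mesh$area_z_face / (mesh$dz / 2)
  list(bottom = list(cell = seq_len(nr), G = K[, 1] * Gd),
       top = list(cell = (nz - 1L) * nr + seq_len(nr), G = K[, nz] * Gd))
}

.accumulate_at <- function(n, idx, val) {
  out <- numeric(n)
  s <- rowsum(val, group = idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Solve the quasistatic potential equation
#'
#' Finite-volume solution of `div(sigma grad V) = 0` on the axisymmetric mesh
#' with Dirichlet values V = 0 on the bottom electrode and
#' V = `applied_voltage` on the top electrode, and zero normal current on the
#' lateral surface and the axis. Face conductivities are harmonic means of
#' the adjacent cells; the symmetric positive-definite system is solved with
#' a direct sparse factorisation.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param sigma_field electrical conductivity per cell, S m^-1, all > 0.
#' @param bc an [electric_bc()].
#' @return Numeric vector of cell potentials (V) with the applied voltage
#'   attached as attribute `applied_voltage`. The discrete maximum principle
#'   guarantees 0 <= V <= applied_voltage.
#' @export
solve_potential <- function(mesh, sigma_field, bc) {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(bc, "electric_bc"))
  n <- mesh$ncell
  if (length(sigma_field) != n)
    stop("solve_potential: sigma_field length does not match the mesh")
  if (any(!is.finite(sigma_field)) || any(sigma_field <= 0))
    stop("solve_potential: sigma must be finite and strictly positive everywhere")
  V0 <- bc$applied_voltage
  fc <- .face_conductances(mesh, sigma_field)
  el <- .electrode_conductances(mesh, sigma_field)
  diag_add <- .accumulate_at(n, c(fc$p, fc$q), c(fc$G, fc$G))
  diag_add[el$bottom$cell] <- diag_add[el$bottom$cell] + el$bottom$G
  diag_add[el$top$cell] <- diag_add[el$top$cell] + el$top$G
  A <- Matrix::sparseMatrix(
    i = c(fc$p, fc$q, seq_len(n)),
    j = c(fc$q, fc$p, seq_len(n)),
    x = c(-fc$G, -fc$G, diag_add), dims = c(n, n))
  b <- numeric(n)
  b[el$top$cell] <- el$top$G * V0
  V <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop(
                  "solve_potential: singular system (degenerate conductivity ",
                  "or broken boundary tags): ", conditionMessage(e)))
  if (any(!is.finite(V)))
    stop("solve_potential: non-finite solution (singular system)")
  attr(V, "applied_voltage") <- V0
  V
}

#' Joule heat source from a potential solution
#'
#' Computes the volumetric power density Q = sigma |grad V|^2 per cell. The
#' squared gradient is reconstructed from the discrete face fluxes with the
#' energy-consistent splitting: each internal face contributes half of
#' G (dV)^2 to both adjacent cells and each electrode face contributes its
#' full half-cell dissipation, so that the volume integral of Q equals the
#' electrical power V0 * I delivered through the electrodes exactly (to
#' solver precision).
#'
#' @param mesh the mesh the potential was solved on.
#' @param sigma_field conductivity per cell used in the solve.
#' @param potential result of [solve_potential()].
#' @param applied_voltage optional; defaults to the attribute carried by
#'   `potential`.
#' @return Volumetric heat source per cell, W m^-3 (>= 0).
#' @export
joule_source <- function(mesh, sigma_field, potential, applied_voltage = NULL) {
  stopifnot(inherits(mesh, "axisym_mesh"))
  n <- mesh$ncell
  if (length(potential) != n || length(sigma_field) != n)
    stop("joule_source: field lengths do not match the mesh")
  if (is.null(applied_voltage))
    applied_voltage <- attr(potential, "applied_voltage")
  if (is.null(applied_voltage))
    stop("joule_source: applied_voltage missing (pass it or use solve_potential output)")
  fc <- .face_conductances(mesh, sigma_field)
  el <- .electrode_conductances(mesh, sigma_field)
  dv2 <- (potential[fc$q] - potential[fc$p])^2
  acc <- .accumulate_at(n, c(fc$p, fc$q), rep(0.5 * fc$G * dv2, 2L))
  acc[el$bottom$cell] <- acc[el$bottom$cell] +
    el$bottom$G * potential[el$bottom$cell]^2
  acc[el$top$cell] <- acc[el$top$cell] +
    el$top$G * (applied_voltage - potential[el$top$cell])^2
  acc / mesh$volume
}

#' Current through an electrode
#'
#' Discrete flux integral of sigma dV/dn over one electrode. Current
#' conservation requires the two electrodes to carry equal current.
#'
#' @param mesh,sigma_field,potential as in [joule_source()].
#' @param which `"top"` or `"bottom"`.
#' @param applied_voltage optional, see [joule_source()].
#' @return Current in amperes (positive for current flowing through the
#'   sample from the live to the grounded electrode).
#' @export
electrode_current <- function(mesh, sigma_field, potential,
                              which = c("top", "bottom"),
                              applied_voltage = NULL) {
  which <- match.arg(which)
  if (is.null(applied_voltage))
    applied_voltage <- attr(potential, "applied_voltage")
  el <- .electrode_conductances(mesh, sigma_field)
  if (which == "top")
    sum(el$top$G * (applied_voltage - potential[el$top$cell]))
  else
    sum(el$bottom$G * potential[el$bottom$cell])
}

#' Total dissipated power
#'
#' Volume-weighted integral of the Joule source over the sample.
#'
#' @param mesh the mesh.
#' @param Q volumetric source per cell, W m^-3.
#' @return Power in watts.
#' @export
total_power <- function(mesh, Q) {
  stopifnot(inherits(mesh, "axisym_mesh"), length(Q) == mesh$ncell)
  sum(Q * mesh$volume)
}
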