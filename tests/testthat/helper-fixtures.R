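# Shared fixtures: small meshes, a constant-property table, and an
# independent 1-D finite-difference oracle for the axial potential problem.

tab5 <- default_property_table()

# Constant-property table: same value at every tabulated temperature, so
# interpolation returns exactly these constants at any T.
const_table <- function(lambda = 0.5, vhc = 3.4e6, sigma = 2.0) {
  property_table(c(0, 100), rep(lambda, 2), rep(vhc, 2) / 1e6 * 1e6,
                 rep(sigma, 2))
}

small_mesh <- function(nr = 8, nz = 8, R = 0.01, L = 0.2)
  build_mesh(cylinder_geometry(R, L), nr, nz)

# Independent oracle: 1-D cell-centred finite-volume solve of
# d/dz (sigma dV/dz) = 0 between plates at 0 and V0, dense solve.
# sigma_z: one conductivity per axial layer.
oracle_potential_1d <- function(sigma_z, L, V0) {
  nz <- length(sigma_z)
  dz <- L / nz
  harm <- function(a, b) 2 * a * b / (a + b)
  A <- matrix(0, nz, nz)
  b <- numeric(nz)
  for (j in seq_len(nz)) {
    if (j > 1) {
      g <- harm(sigma_z[j - 1], sigma_z[j]) / dz
      A[j, j] <- A[j, j] + g; A[j, j - 1] <- A[j, j - 1] - g
    } else {
      g <- sigma_z[1] / (dz / 2)
      A[j, j] <- A[j, j] + g            # V = 0 at z = 0
    }
    if (j < nz) {
      g <- harm(sigma_z[j], sigma_z[j + 1]) / dz
      A[j, j] <- A[j, j] + g; A[j, j + 1] <- A[j, j + 1] - g
    } else {
      g <- sigma_z[nz] / (dz / 2)
      A[j, j] <- A[j, j] + g; b[j] <- b[j] + g * V0
    }
  }
  as.numeric(solve(A, b))
}

# Expand a per-layer axial profile to the full cell ordering of a mesh.
axial_profile <- function(mesh, values_z) rep(values_z, each = mesh$nr)
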