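# Homogeneous incompressible elastic-solid model.
#
# The boundary deformation field u_k is extrapolated linearly along radii
# to zero at the centre of mass, giving a displacement field on the polar
# mesh induced by angular remeshing: mesh node (m, k) sits at rho_m * b_k,
# rho_m = m/M, and carries u = rho_m * u_k. In-plane displacement
# gradients are computed by finite differences on the (rho, theta) grid
# (central in theta, periodic; second-order one-sided at the inner and
# boundary rings in rho) and mapped to Cartesian derivatives through the
# mesh Jacobian. The z direction is closed by incompressibility:
# eps_zz = -(eps_xx + eps_yy); eps_xz = eps_yz = 0 at the central plane.
# Because u is linear in rho, the resulting stress is constant along each
# spoke - the radial-stress constancy this model is known for.

# ---- finite-difference stencils (isolated for replacement) ----

# d/drho on an M x n array, drho spacing; central inside, second-order
# one-sided at the first and last ring.
#' @keywords internal
fd_rho <- function(A, drho) {
  M <- nrow(A)
  if (M < 3) stopf("mesh too coarse: need at least 3 radial rings")
  out <- A
  out[2:(M - 1), ] <- (A[3:M, ] - A[1:(M - 2), ]) / (2 * drho)
  out[1, ] <- (-3 * A[1, ] + 4 * A[2, ] - A[3, ]) / (2 * drho)
  out[M, ] <- (3 * A[M, ] - 4 * A[M - 1, ] + A[M - 2, ]) / (2 * drho)
  out
}

# d/dtheta on an M x n array, periodic central differences over columns.
#' @keywords internal
fd_theta <- function(A, dtheta) {
  n <- ncol(A)
  (A[, c(2:n, 1), drop = FALSE] - A[, c(n, 1:(n - 1)), drop = FALSE]) / (2 * dtheta)
}

# Strain components from the displacement-gradient components.
#' @keywords internal
strain_from_gradients <- function(L11, L12, L21, L22, q) {
  exx <- L11 + q * (L11^2 + L21^2)
  eyy <- L22 + q * (L12^2 + L22^2)
  exy <- 0.5 * (L12 + L21) + q * (L11 * L12 + L21 * L22)
  list(exx = exx, eyy = eyy, exy = exy, ezz = -(exx + eyy))
}

#' Strain field of the solid model
#'
#' Evaluates the (nonlinear) strain tensor of the linear-radial interior
#' deformation on a polar mesh of `rings` radial rings by n angular
#' points, n taken from the mapping. The quadratic displacement-gradient
#' term follows `params$strain_convention` (see [elastic_params()]).
#'
#' @param mapping an [point_mapping()]; the initial contour must be
#'   remeshed by angle about its centroid and centred at the origin
#' @param params [elastic_params()]
#' @param rings number of radial rings (>= 3, default 20)
#' @return object of class `nt_strain` holding `rings` x n matrices
#'   `exx`, `eyy`, `exy`, `ezz` (symmetric tensor, `exz = eyz = 0` at the
#'   central plane) and the mesh (`x`, `y`, `detJ`, `rho`)
#' @export
solid_strain <- function(mapping, params = elastic_params(), rings = 20) {
  if (!inherits(mapping, "nt_mapping")) stopf("mapping must be an nt_mapping")
  if (rings < 3) stopf("mesh too coarse: need at least 3 radial rings")
  check_centred(mapping$initial)
  b <- mapping$initial; u <- mapping$u
  n <- mapping$n
  M <- as.integer(rings)
  rho <- seq_len(M) / M
  drho <- 1 / M
  dtheta <- 2 * pi / n
  Xx <- outer(rho, b[, 1]); Xy <- outer(rho, b[, 2])
  Ux <- outer(rho, u[, 1]); Uy <- outer(rho, u[, 2])
  J11 <- fd_rho(Xx, drho); J12 <- fd_theta(Xx, dtheta)
  J21 <- fd_rho(Xy, drho); J22 <- fd_theta(Xy, dtheta)
  det <- J11 * J22 - J12 * J21
  if (any(abs(det) < 1e-14 * max(abs(b))^2))
    stopf("degenerate mesh Jacobian (collinear spokes?)")
  Uxr <- fd_rho(Ux, drho); Uxt <- fd_theta(Ux, dtheta)
  Uyr <- fd_rho(Uy, drho); Uyt <- fd_theta(Uy, dtheta)
  L11 <- (Uxr * J22 - Uxt * J21) / det   # dux/dx
  L12 <- (-Uxr * J12 + Uxt * J11) / det  # dux/dy
  L21 <- (Uyr * J22 - Uyt * J21) / det   # duy/dx
  L22 <- (-Uyr * J12 + Uyt * J11) / det  # duy/dy
  eps <- strain_from_gradients(L11, L12, L21, L22, params$quad_coef)
  structure(c(eps, list(basis = "cartesian",
                        convention = params$strain_convention,
                        mesh = list(x = Xx, y = Xy, detJ = det, rho = rho,
                                    n = n, rings = M, drho = drho,
                                    dtheta = dtheta))),
            class = "nt_strain")
}

#' Stress from strain (Hooke's law)
#'
#' \deqn{\sigma_{ij} = \frac{E}{1+\nu}\left(\epsilon_{ij} +
#'   \frac{\nu}{1-2\nu}\epsilon_{kk}\delta_{ij}\right)}
#' At \eqn{\nu = 0.5} the \eqn{(1-2\nu)^{-1}} term is never evaluated:
#' incompressibility makes \eqn{\epsilon_{kk} = 0}, and the law reduces
#' exactly to \eqn{\sigma_{ij} = \frac{2E}{3}\epsilon_{ij}}. The trace is
#' asserted to vanish (|trace| < 1e-9) in that branch.
#'
#' @param strain an `nt_strain` from [solid_strain()]
#' @param params [elastic_params()]
#' @return object of class `nt_stress` with matrices `sxx`, `syy`, `sxy`,
#'   `szz` (Pa)
#' @export
stress_from_strain <- function(strain, params = elastic_params()) {
  if (!inherits(strain, "nt_strain") || strain$basis != "cartesian")
    stopf("stress_from_strain expects a Cartesian nt_strain")
  tr <- strain$exx + strain$eyy + strain$ezz
  if (params$nu == 0.5) {
    if (max(abs(tr)) >= 1e-9)
      stopf("incompressibility violation: |eps_kk| = %.3g >= 1e-9 with nu = 0.5",
            max(abs(tr)))
    k <- 2 * params$E / 3
    out <- list(sxx = k * strain$exx, syy = k * strain$eyy,
                sxy = k * strain$exy, szz = k * strain$ezz)
  } else {
    a <- params$E / (1 + params$nu)
    bterm <- a * params$nu / (1 - 2 * params$nu) * tr
    out <- list(sxx = a * strain$exx + bterm, syy = a * strain$eyy + bterm,
                sxy = a * strain$exy, szz = a * strain$ezz + bterm)
  }
  structure(c(out, list(basis = "cartesian", mesh = strain$mesh)),
            class = "nt_stress")
}

#' Free energy density
#'
#' \eqn{f = \frac{1}{2}\sigma_{ij}\epsilon_{ij}} pointwise (J/m^3 = Pa),
#' including the zz contribution; xz and yz components vanish at the
#' central plane.
#'
#' @param strain,stress matched fields from [solid_strain()] and
#'   [stress_from_strain()]
#' @return matrix of energy densities on the mesh
#' @export
energy_density <- function(strain, stress) {
  if (!identical(dim(strain$exx), dim(stress$sxx)))
    stopf("strain and stress fields have mismatched sizes")
  0.5 * (stress$sxx * strain$exx + stress$syy * strain$eyy +
           stress$szz * strain$ezz + 2 * stress$sxy * strain$exy)
}

# Channel height at position x: scalar height, or a channel_geometry with
# the constriction occupying 0 <= x <= length.
#' @keywords internal
height_at <- function(x, height) {
  if (inherits(height, "nt_channel_geometry"))
    ifelse(x >= 0 & x <= height$constriction_length,
           height$constriction_height, height$channel_height)
  else height + 0 * x
}

#' Total deformation energy of the solid model
#'
#' Integrates the free energy density over the mesh volume: cell area
#' (from the mesh Jacobian) times the channel height at that x.
#'
#' @inheritParams solid_strain
#' @param height channel height in um (scalar) or a [channel_geometry()]
#' @return energy in J (um^3 Pa x 1e-18; reported in Pa um^3)
#' @export
total_energy <- function(mapping, params = elastic_params(), rings = 20,
                         height = 4.7) {
  eps <- solid_strain(mapping, params, rings)
  sig <- stress_from_strain(eps, params)
  f <- energy_density(eps, sig)
  m <- eps$mesh
  w <- abs(m$detJ) * m$drho * m$dtheta * height_at(m$x, height)
  sum(f * w)
}

#' Surface traction of the solid model
#'
#' Evaluates stress at the boundary ring and projects it on the outward
#' normal, \eqn{t_i = \sigma_{ij} n_j}, using in-plane components only
#' (the outline normal is perpendicular to z, so \eqn{\sigma_{zz}} does
#' not contribute).
#'
#' @inheritParams total_energy
#' @param frames optional precomputed [contour_frames()] of the initial
#'   contour
#' @return a `nt_traction` data frame: `s1_um`, `x_um`, `y_um`, `tx_Pa`,
#'   `ty_Pa`, `tmag_Pa`, `f_J_per_m3`, `model`
#' @export
solid_traction <- function(mapping, params = elastic_params(), rings = 20,
                           frames = NULL) {
  eps <- solid_strain(mapping, params, rings)
  sig <- stress_from_strain(eps, params)
  f <- energy_density(eps, sig)
  fr <- frames %||% contour_frames(contour(mapping$initial, validate = FALSE))
  M <- eps$mesh$rings
  traction_profile(sxx = sig$sxx[M, ], syy = sig$syy[M, ], sxy = sig$sxy[M, ],
                   frames = fr, f = f[M, ], model = "solid")
}

# Shared traction assembly: t = sigma . n with unit outward normals.
#' @keywords internal
traction_profile <- function(sxx, syy, sxy, frames, f, model) {
  nx <- frames$nx; ny <- frames$ny
  nlen <- sqrt(nx^2 + ny^2)
  if (any(abs(nlen - 1) > 1e-9)) stopf("non-unit normal in frames")
  tx <- sxx * nx + sxy * ny
  ty <- sxy * nx + syy * ny
  out <- data.frame(s1_um = frames$s1, x_um = frames$x, y_um = frames$y,
                    tx_Pa = tx, ty_Pa = ty, tmag_Pa = sqrt(tx^2 + ty^2),
                    f_J_per_m3 = f, model = model,
                    stringsAsFactors = FALSE)
  class(out) <- c("nt_traction", "data.frame")
  out
}

#' Write a traction profile to CSV
#' @param profile an `nt_traction` data frame
#' @param path file path
#' @export
write_traction_csv <- function(profile, path) {
  write_csv_det(profile, path)
}
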