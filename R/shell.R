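# Thin elastic shell (Love-Kirchhoff) model of the nuclear lamina.
#
# The interior offers no resistance; only the ~100 nm lamina deforms
# elastically. Displacements are rotated into the surface basis
# (n, s1, s2) - outward normal, in-plane tangent, out-of-plane tangent
# (z) - where the thin-shell assumptions hold: constant thickness,
# normals remain normal, no strain in the normal direction. On a curved
# outline the derivative of the basis vectors along the surface couples
# tangential displacement to strain through the single nonzero curvature
# component C_s1s1 (C_s2s2 = 0 by the flat-z channel assumption):
#
#   D1s = du_s1/ds1 + C u_n     (tangential stretch)
#   D1n = du_n/ds1  - C u_s1    (tilt of the surface element)
#
# eps_s1s1 = D1s + q (D1s^2 + D1n^2) with q the quadratic-term
# coefficient of the active strain convention; eps_s2s2 = -eps_s1s1
# closes the tensor trace-free (constant thickness + constant enclosed
# volume); eps_nn = 0. The tilt enters as the shear eps_ns1 = D1n / 2
# (the normal derivative of u_s1 is unconstrained by the resistance-free
# interior and is taken as zero). Because eps_nn = 0 and the material is
# incompressible, sigma_nn = 0, so the traction t = sigma . n is exactly
# tangential - the shell model's signature.

#' Surface strain of the shell model
#'
#' @param mapping an [point_mapping()] (aligned pair)
#' @param frames [contour_frames()] of the *initial* (reference) contour;
#'   computed if omitted. Curvature coupling is evaluated on the
#'   reference configuration, consistent with small incremental steps.
#' @param params [elastic_params()]
#' @return object of class `nt_strain` with `basis = "surface"`: vectors
#'   `ess` (eps_s1s1), `ens` (eps_ns1), `es2s2` per boundary point, plus
#'   the frames
#' @export
shell_strain <- function(mapping, frames = NULL, params = elastic_params()) {
  if (!inherits(mapping, "nt_mapping")) stopf("mapping must be an nt_mapping")
  fr <- frames %||% contour_frames(contour(mapping$initial, validate = FALSE))
  if (nrow(fr) != mapping$n)
    stopf("frames (%d) and mapping (%d) lengths differ", nrow(fr), mapping$n)
  u <- mapping$u
  un <- fr$nx * u[, 1] + fr$ny * u[, 2]   # R_phi u: normal component
  us <- fr$tx * u[, 1] + fr$ty * u[, 2]   # tangential component
  # central difference along arclength with nonuniform spacing
  dds <- function(g) (vec_shift(g, 1) - vec_shift(g, -1)) / (2 * fr$ds)
  D1s <- dds(us) + fr$curvature * un
  D1n <- dds(un) - fr$curvature * us
  q <- params$quad_coef
  ess <- D1s + q * (D1s^2 + D1n^2)
  structure(list(ess = ess, ens = 0.5 * D1n, es2s2 = -ess,
                 basis = "surface", convention = params$strain_convention,
                 frames = fr),
            class = "nt_strain")
}

# Surface-basis stress of the incompressible shell (Eq 1, nu = 1/2 branch;
# the trace is zero by the es2s2 closure, so sigma = (2E/3) eps).
#' @keywords internal
shell_stress <- function(strain, params) {
  if (params$nu != 0.5)
    stopf("the shell model is implemented for the incompressible case nu = 0.5")
  k <- 2 * params$E / 3
  list(sss = k * strain$ess, sns = k * strain$ens, ss2 = k * strain$es2s2)
}

#' Surface traction of the shell model
#'
#' Stress via Hooke's law (incompressible branch) in surface coordinates,
#' rotated back to Cartesian by \eqn{R_\phi^T}, then \eqn{t_i =
#' \sigma_{ij} n_j}. The normal-normal stress vanishes by construction,
#' so the traction is tangential: \eqn{t = \sigma_{n s_1}\,\hat{s}_1}.
#' Tractions are reported in Pa at the mid-surface; the shell thickness
#' `h` enters only the total-energy integral.
#'
#' @param strain an [shell_strain()] result (or an [point_mapping()], in
#'   which case the strain is computed first)
#' @param frames frames of the initial contour (taken from the strain if
#'   omitted)
#' @param params [elastic_params()]
#' @param rupture_tension optional threshold (Pa): traction magnitudes
#'   above it are flagged in a `flag_rupture` column (off by default;
#'   rupture itself is not modelled)
#' @return a `nt_traction` data frame as in [solid_traction()], with
#'   `model = "shell"`
#' @export
shell_traction <- function(strain, frames = NULL, params = elastic_params(),
                           rupture_tension = NULL) {
  if (inherits(strain, "nt_mapping"))
    strain <- shell_strain(strain, frames, params)
  if (!inherits(strain, "nt_strain") || strain$basis != "surface")
    stopf("shell_traction expects a surface nt_strain")
  fr <- frames %||% strain$frames
  sig <- shell_stress(strain, params)
  # sigma_cart = R^T sigma_surf R; t = sigma_cart n = sigma_ns1 s1_hat
  tx <- sig$sns * fr$tx
  ty <- sig$sns * fr$ty
  f <- 0.5 * (sig$sss * strain$ess + sig$ss2 * strain$es2s2 +
                2 * sig$sns * strain$ens)
  out <- data.frame(s1_um = fr$s1, x_um = fr$x, y_um = fr$y,
                    tx_Pa = tx, ty_Pa = ty, tmag_Pa = sqrt(tx^2 + ty^2),
                    f_J_per_m3 = f, model = "shell",
                    stringsAsFactors = FALSE)
  if (!is.null(rupture_tension))
    out$flag_rupture <- out$tmag_Pa > rupture_tension
  class(out) <- c("nt_traction", "data.frame")
  out
}

#' Total deformation energy of the shell model
#'
#' Integrates the surface energy density over the shell volume: per-point
#' density x shell thickness `h` x arclength weight x out-of-plane extent
#' (the channel height at that x).
#'
#' @inheritParams shell_strain
#' @param height channel height (um) or [channel_geometry()]
#' @return energy in Pa um^3
#' @export
shell_energy <- function(mapping, frames = NULL, params = elastic_params(),
                         height = 4.7) {
  eps <- shell_strain(mapping, frames, params)
  fr <- eps$frames
  sig <- shell_stress(eps, params)
  f <- 0.5 * (sig$sss * eps$ess + sig$ss2 * eps$es2s2 + 2 * sig$sns * eps$ens)
  sum(f * params$h * fr$ds * height_at(fr$x, height))
}
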