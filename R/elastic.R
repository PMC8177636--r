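# Elastic parameters and boundary point mappings.

#' Elastic parameters of the nucleus
#'
#' @param E Young's modulus in Pa (default 5000). Stress, traction and
#'   energy scale linearly in `E`; force directions are independent of it.
#' @param nu Poisson ratio; `0.5` (the default) is the incompressible case
#'   and is handled by an exact branch, never by a near-0.5 approximation.
#' @param h shell thickness in um (default 0.1, the ~100 nm nuclear
#'   lamina); used only by the shell model's total-energy integral.
#' @param strain_convention `"as-printed"` keeps an extra factor 1/2 on
#'   the quadratic displacement-gradient term, i.e.
#'   \eqn{\epsilon_{ij} = \frac{1}{2}(\partial_i u_j + \partial_j u_i +
#'   \frac{1}{2}\partial_i u_k \partial_j u_k)};
#'   `"green-lagrange"` uses the standard finite-strain tensor (quadratic
#'   coefficient 1/2 instead of 1/4), which is exactly invariant under
#'   rigid rotations. Both are exposed because the printed form is not
#'   rotation invariant; neither is chosen silently.
#' @return object of class `nt_elastic_params`
#' @export
elastic_params <- function(E = 5000, nu = 0.5, h = 0.1,
                           strain_convention = c("as-printed", "green-lagrange")) {
  strain_convention <- match.arg(strain_convention)
  if (!is.numeric(E) || E <= 0) stopf("E must be positive")
  if (!is.numeric(nu) || nu <= 0 || nu > 0.5) stopf("nu must be in (0, 0.5]")
  if (!is.numeric(h) || h <= 0) stopf("h must be positive")
  structure(list(E = E, nu = nu, h = h,
                 strain_convention = strain_convention,
                 quad_coef = if (strain_convention == "as-printed") 0.25 else 0.5),
            class = "nt_elastic_params")
}

#' Boundary correspondence between two outlines
#'
#' A point mapping is the sampled deformation field u: point k of the
#' initial outline maps to point k of the target, u_k = target_k -
#' initial_k. Both outlines must have the same point count and preserve
#' anticlockwise order. The solid model additionally assumes the initial
#' centroid is at the origin (zero deformation at the centre of mass).
#'
#' @param initial,target [contour()] objects (or plain matrices) with
#'   equal point counts
#' @param validate check invariants
#' @return object of class `nt_mapping`: list with `initial`, `target`
#'   (n x 2 matrices), `u` (target - initial) and `n`
#' @export
point_mapping <- function(initial, target, validate = TRUE) {
  ip <- if (is_contour(initial)) as_points(initial) else as.matrix(initial)
  tp <- if (is_contour(target)) as_points(target) else as.matrix(target)
  if (nrow(ip) != nrow(tp))
    stopf("initial and target must have equal point counts (%d vs %d)",
          nrow(ip), nrow(tp))
  if (validate) {
    if (shoelace_area(ip) <= 0 || shoelace_area(tp) <= 0)
      stopf("mapping endpoints must both be anticlockwise")
  }
  structure(list(initial = ip, target = tp, u = tp - ip, n = nrow(ip)),
            class = "nt_mapping")
}

#' @export
print.nt_mapping <- function(x, ...) {
  um <- sqrt(rowSums(x$u^2))
  cat(sprintf("<nt_mapping> %d points, |u| mean %.4g um, max %.4g um\n",
              x$n, mean(um), max(um)))
  invisible(x)
}

#' Linearly interpolated interior deformation of the solid model
#'
#' The deformation inside the nucleus decreases linearly along each spoke
#' from its boundary value to zero at the centre of mass: at a fraction
#' `f` of the way from the origin to boundary point k the displacement is
#' `f * u_k`.
#'
#' @param mapping an [point_mapping()] whose initial centroid is at the
#'   origin
#' @param radial_fraction scalar in \[0, 1\]
#' @return n x 2 matrix of interior displacements (um)
#' @export
interior_deformation <- function(mapping, radial_fraction) {
  if (!inherits(mapping, "nt_mapping")) stopf("mapping must be an nt_mapping")
  if (!is.numeric(radial_fraction) || radial_fraction < 0 || radial_fraction > 1)
    stopf("radial_fraction must be in [0, 1]")
  check_centred(mapping$initial)
  radial_fraction * mapping$u
}

#' @keywords internal
check_centred <- function(pts, tol = 1e-6) {
  cen <- polygon_centroid(pts)
  scale <- max(abs(pts), 1)
  if (sqrt(sum(cen^2)) > tol * scale)
    stopf("solid model requires the initial contour centred at its centroid (offset %.3g um); align the pair first",
          sqrt(sum(cen^2)))
  invisible(TRUE)
}
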