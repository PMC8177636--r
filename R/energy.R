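# Model-agnostic deformation energy, plus lean evaluators for the
# annealer's inner loop. The factories precompute everything that depends
# only on the (fixed) initial contour so that a proposal costs a handful
# of vectorised operations; they are verified against total_energy() /
# shell_energy() in the test suite.

#' Deformation free energy of a mapping
#'
#' Total free energy of the boundary deformation under the chosen
#' mechanical model. This is the objective the annealer minimises; the
#' annealing temperature carries the same (energy) units, with k_B
#' absorbed.
#'
#' @param mapping an [point_mapping()]
#' @param model `"solid"` or `"shell"`
#' @param params [elastic_params()]
#' @param rings solid-model radial mesh resolution
#' @param height channel height (um) or [channel_geometry()]
#' @return scalar energy (Pa um^3)
#' @export
deformation_energy <- function(mapping, model = c("solid", "shell"),
                               params = elastic_params(), rings = 20,
                               height = 4.7) {
  model <- match.arg(model)
  if (model == "solid") total_energy(mapping, params, rings, height)
  else shell_energy(mapping, NULL, params, height)
}

# Factory: returns function(target_matrix) -> energy for a fixed initial
# contour. For the solid model the stress is constant along each spoke
# (u linear in rho), so the volume integral reduces to boundary values
# times precomputed spoke-volume weights.
#' @keywords internal
energy_fn_factory <- function(initial, model, params, rings = 20,
                              height = 4.7) {
  b <- if (is_contour(initial)) as_points(initial) else as.matrix(initial)
  n <- nrow(b)
  if (model == "solid") {
    check_centred(b)
    dtheta <- 2 * pi / n
    Dbx <- (vec_shift(b[, 1], 1) - vec_shift(b[, 1], -1)) / (2 * dtheta)
    Dby <- (vec_shift(b[, 2], 1) - vec_shift(b[, 2], -1)) / (2 * dtheta)
    det1 <- b[, 1] * Dby - b[, 2] * Dbx
    if (any(abs(det1) < 1e-14 * max(abs(b))^2))
      stopf("degenerate mesh Jacobian for the solid energy")
    M <- as.integer(rings)
    rho <- seq_len(M) / M
    # spoke-volume weights: sum_m |det J| drho dtheta h(x_mk)
    W <- colSums(outer(rho, abs(det1)) * (1 / M) * dtheta *
                   matrix(height_at(outer(rho, b[, 1]), height), M, n))
    q <- params$quad_coef
    if (params$nu == 0.5) {
      kfac <- 2 * params$E / 3
      function(tp) {
        ux <- tp[, 1] - b[, 1]; uy <- tp[, 2] - b[, 2]
        Dux <- (vec_shift(ux, 1) - vec_shift(ux, -1)) / (2 * dtheta)
        Duy <- (vec_shift(uy, 1) - vec_shift(uy, -1)) / (2 * dtheta)
        L11 <- (ux * Dby - Dux * b[, 2]) / det1
        L12 <- (-ux * Dbx + Dux * b[, 1]) / det1
        L21 <- (uy * Dby - Duy * b[, 2]) / det1
        L22 <- (-uy * Dbx + Duy * b[, 1]) / det1
        exx <- L11 + q * (L11^2 + L21^2)
        eyy <- L22 + q * (L12^2 + L22^2)
        exy <- 0.5 * (L12 + L21) + q * (L11 * L12 + L21 * L22)
        # f = 1/2 sigma:eps with sigma = (2E/3) eps and ezz = -(exx+eyy)
        f <- 0.5 * kfac * (exx^2 + eyy^2 + (exx + eyy)^2 + 2 * exy^2)
        sum(f * W)
      }
    } else {
      function(tp) {
        mp <- point_mapping(b, tp, validate = FALSE)
        total_energy(mp, params, rings, height)
      }
    }
  } else {
    fr <- contour_frames(contour(b, validate = FALSE))
    kfac <- 2 * params$E / 3
    q <- params$quad_coef
    wgt <- params$h * fr$ds * height_at(fr$x, height)
    nx <- fr$nx; ny <- fr$ny; tx <- fr$tx; ty <- fr$ty
    curv <- fr$curvature; ds2 <- 2 * fr$ds
    function(tp) {
      ux <- tp[, 1] - b[, 1]; uy <- tp[, 2] - b[, 2]
      un <- nx * ux + ny * uy
      us <- tx * ux + ty * uy
      D1s <- (vec_shift(us, 1) - vec_shift(us, -1)) / ds2 + curv * un
      D1n <- (vec_shift(un, 1) - vec_shift(un, -1)) / ds2 - curv * us
      ess <- D1s + q * (D1s^2 + D1n^2)
      ens <- 0.5 * D1n
      f <- kfac * (ess^2 + ens^2)
      sum(f * wgt)
    }
  }
}
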