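# Metropolis simulated annealing of the boundary correspondence.
#
# The mapping between two outlines is not unique; the physical deformation
# is taken to be the one minimising the deformation free energy of the
# chosen mechanical model. Starting from the equal-angle correspondence,
# single mapped points are perturbed a fraction of the way towards one of
# their two neighbours; downhill moves are always accepted, uphill moves
# with probability exp(-dE/T); T starts at a value giving ~20% overall
# acceptance and decays geometrically per sweep. Proposals that would
# break the sequential boundary order (the multi-valued-surface failure
# mode) are rejected before any energy evaluation.

#' Annealing configuration
#'
#' @param seed integer RNG seed; two runs with the same seed are
#'   bit-identical
#' @param initial_acceptance target overall acceptance fraction used to
#'   calibrate the starting temperature (default 0.2)
#' @param cooling_factor geometric per-sweep temperature multiplier in
#'   (0, 1) (default 0.95)
#' @param sweeps_max maximum number of sweeps; one sweep is n proposals
#'   (default 500)
#' @param stall_sweeps terminate after this many sweeps with relative
#'   best-energy improvement below `stall_tol` (default 25)
#' @param stall_tol relative improvement threshold (default 1e-6)
#' @param move_fraction step size towards a neighbour in (0, 1)
#'   (default 0.1: "a tenth of the way")
#' @param temperature optional explicit starting temperature (energy
#'   units, k_B absorbed); `NULL` means calibrate
#' @param reproject if `TRUE`, proposed positions are re-projected onto
#'   the target outline (off by default: moves slide along straight
#'   chords between the current neighbours)
#' @return object of class `nt_anneal_config`
#' @export
anneal_config <- function(seed = 1L, initial_acceptance = 0.2,
                          cooling_factor = 0.95, sweeps_max = 500L,
                          stall_sweeps = 25L, stall_tol = 1e-6,
                          move_fraction = 0.1, temperature = NULL,
                          reproject = FALSE) {
  if (move_fraction <= 0 || move_fraction >= 1)
    stopf("move_fraction must be in (0, 1)")
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stopf("cooling_factor must be in (0, 1)")
  if (initial_acceptance <= 0 || initial_acceptance >= 1)
    stopf("initial_acceptance must be in (0, 1)")
  structure(list(seed = as.integer(seed),
                 initial_acceptance = initial_acceptance,
                 cooling_factor = cooling_factor,
                 sweeps_max = as.integer(sweeps_max),
                 stall_sweeps = as.integer(stall_sweeps),
                 stall_tol = stall_tol,
                 move_fraction = move_fraction,
                 temperature = temperature,
                 reproject = isTRUE(reproject)),
            class = "nt_anneal_config")
}

#' Equal-angle starting correspondence
#'
#' Remeshes both (aligned) contours about the origin of the common frame
#' to the target's point count at equal angles; point k of the initial
#' maps to point k of the target.
#'
#' @param initial,target aligned [contour()] objects (initial centred at
#'   the origin), both star-shaped about the origin
#' @param n number of correspondence points; default the target's point
#'   count
#' @return an [point_mapping()]
#' @export
initial_mapping <- function(initial, target, n = NULL) {
  n <- n %||% nrow(target)
  ri <- as_points(remesh_by_angle(initial, n, origin = c(0, 0)))
  rt <- as_points(remesh_by_angle(target, n, origin = c(0, 0)))
  # remeshing onto chords drifts the centroid by O(1/n^2); shift both
  # endpoints by the same vector so the initial is exactly centred (the
  # solid-model anchor) without touching the deformation field
  cen <- polygon_centroid(ri)
  point_mapping(sweep(ri, 2, cen), sweep(rt, 2, cen))
}

#' Metropolis acceptance rule
#'
#' Accept if the free energy decreases (`dE <= 0`); otherwise accept with
#' probability `exp(-dE / T)` against a uniform draw in \[0, 1). `dE = 0`
#' is always accepted (exp(0) = 1 exceeds any draw). Downhill moves do
#' not consume a random number.
#'
#' @param dE energy change of the proposal
#' @param T temperature (> 0), energy units
#' @return logical
#' @export
metropolis_accept <- function(dE, T) {
  if (!is.finite(T) || T <= 0) stopf("temperature must be positive")
  if (dE <= 0) return(TRUE)
  stats::runif(1) < exp(-dE / T)
}

#' Propose a single-point move
#'
#' Picks one mapped point uniformly at random and moves it
#' `config$move_fraction` of the way towards one of its two neighbours
#' (chosen uniformly), evaluating the energy change under the given
#' model. A proposal that would break the sequential (anticlockwise)
#' order of the mapped points is rejected outright (`ok = FALSE`) without
#' an energy evaluation. A point coincident with its chosen neighbour
#' yields a no-op with `dE = 0`.
#'
#' @param mapping current [point_mapping()]
#' @param config [anneal_config()]
#' @param energy_fn function(target matrix) -> energy; built via the
#'   model factories by [anneal()] (exposed here for testing)
#' @param energy_current current energy (recomputed if `NULL`)
#' @param project_to optional closed polyline (n x 2 matrix): with
#'   `config$reproject`, proposed positions are snapped to the nearest
#'   point of this outline
#' @return list `(k, position, dE, ok, target)`
#' @export
propose_move <- function(mapping, config = anneal_config(),
                         energy_fn, energy_current = NULL,
                         project_to = NULL) {
  n <- mapping$n
  tp <- mapping$target
  k <- sample.int(n, 1L)
  side <- if (stats::runif(1) < 0.5) -1L else 1L
  nb <- tp[((k - 1L + side) %% n) + 1L, ]
  pos <- tp[k, ] + config$move_fraction * (nb - tp[k, ])
  if (config$reproject && !is.null(project_to))
    pos <- project_to_polyline(pos, project_to)
  if (all(pos == tp[k, ]))
    return(list(k = k, position = pos, dE = 0, ok = TRUE, target = tp))
  cand <- tp
  cand[k, ] <- pos
  if (!order_preserved(cand, k))
    return(list(k = k, position = pos, dE = NA_real_, ok = FALSE, target = tp))
  e0 <- energy_current %||% energy_fn(tp)
  e1 <- energy_fn(cand)
  list(k = k, position = pos, dE = e1 - e0, ok = TRUE, target = cand)
}

# Nearest point of a closed polyline to p.
#' @keywords internal
project_to_polyline <- function(p, pts) {
  a <- pts
  b <- row_shift(pts, 1)
  e <- b - a
  ee <- rowSums(e * e)
  t <- ((p[1] - a[, 1]) * e[, 1] + (p[2] - a[, 2]) * e[, 2]) / pmax(ee, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  px <- a[, 1] + t * e[, 1]; py <- a[, 2] + t * e[, 2]
  d2 <- (px - p[1])^2 + (py - p[2])^2
  i <- which.min(d2)
  c(px[i], py[i])
}

# Sequential-order guard: mapped point k must stay between its neighbours
# in polar angle about the origin (local check; the full mapping is kept
# monotone by induction).
#' @keywords internal
order_preserved <- function(tp, k) {
  n <- nrow(tp)
  km <- ((k - 2L) %% n) + 1L
  kp <- (k %% n) + 1L
  a <- tp[km, ]; b <- tp[k, ]; c <- tp[kp, ]
  # anticlockwise order about origin: cross products a x b and b x c
  # must both be positive (angles strictly increasing)
  (a[1] * b[2] - a[2] * b[1]) > 0 && (b[1] * c[2] - b[2] * c[1]) > 0
}

#' Sample proposal energy changes from a fixed mapping
#'
#' Draws `n_samples` single-point proposals from `mapping` (without
#' accepting any) and returns their energy changes. Used to calibrate the
#' starting temperature.
#'
#' @inheritParams propose_move
#' @param n_samples number of proposals (>= 500 recommended)
#' @return numeric vector of dE values (order-violating proposals are
#'   skipped)
#' @export
sample_proposal_dE <- function(mapping, config = anneal_config(),
                               energy_fn, n_samples = 500L) {
  e0 <- energy_fn(mapping$target)
  out <- numeric(0)
  for (i in seq_len(n_samples)) {
    pr <- propose_move(mapping, config, energy_fn, energy_current = e0)
    if (pr$ok) out <- c(out, pr$dE)
  }
  out
}

#' Calibrate the starting temperature
#'
#' Finds T such that the expected overall acceptance of the sampled
#' proposals, `mean(dE <= 0) + mean over uphill of exp(-dE/T)`, matches
#' `target` within `tol` (bisection on log T; acceptance is monotone in
#' T). If the downhill fraction alone already reaches the target, no
#' finite T can be that cold: the smallest probed T is returned with a
#' warning.
#'
#' @param dE numeric vector of proposal energy changes (see
#'   [sample_proposal_dE()])
#' @param target target acceptance fraction (default 0.2)
#' @param tol calibration tolerance on the acceptance fraction
#' @return temperature T0 (energy units)
#' @export
calibrate_temperature <- function(dE, target = 0.2, tol = 0.02) {
  dE <- dE[is.finite(dE)]
  if (!length(dE)) stopf("no proposal samples to calibrate from")
  up <- dE[dE > 0]
  p_down <- mean(dE <= 0)
  acc <- function(T) p_down + sum(exp(-up / T)) / length(dE)
  scale <- if (length(up)) stats::median(up) else 1
  if (!length(up) || p_down >= target) {
    T_min <- 1e-8 * max(scale, 1e-300)
    warnf("all proposals downhill at the target acceptance (downhill fraction %.3f >= %.3f); returning smallest probed temperature",
          p_down, target)
    return(T_min)
  }
  lo <- 1e-12 * scale; hi <- 1e12 * scale
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (acc(mid) < target) lo <- mid else hi <- mid
    if (abs(acc(mid) - target) <= tol / 10) return(mid)
  }
  sqrt(lo * hi)
}

#' Anneal the boundary correspondence
#'
#' Minimises the deformation free energy of the mapping between two
#' aligned outlines by Metropolis simulated annealing. One sweep is n
#' proposals; the temperature is multiplied by `cooling_factor` per
#' sweep; the best-so-far mapping is tracked (its energy trace is
#' non-increasing by construction) and returned. Terminates at
#' `sweeps_max` or after `stall_sweeps` sweeps with relative best-energy
#' improvement below `stall_tol`. Fully reproducible given
#' `config$seed`.
#'
#' @param initial,target aligned [contour()] objects (initial centred at
#'   the origin) or an `nt_mapping` as `initial` (then `target` is
#'   ignored)
#' @param model `"solid"` or `"shell"`
#' @param params [elastic_params()]
#' @param config [anneal_config()]
#' @param rings solid-model mesh resolution
#' @param height channel height (um) or [channel_geometry()]
#' @param n correspondence point count (default: target's count)
#' @return object of class `nt_anneal`: list with the best `mapping`, its
#'   `energy`, the starting temperature `T0`, and `trace` (a data frame
#'   `sweep, temperature, current_energy, best_energy, acceptance_rate`)
#' @export
anneal <- function(initial, target = NULL, model = c("solid", "shell"),
                   params = elastic_params(), config = anneal_config(),
                   rings = 20, height = 4.7, n = NULL) {
  model <- match.arg(model)
  mapping <- if (inherits(initial, "nt_mapping")) initial
             else initial_mapping(initial, target, n)
  energy_fn <- energy_fn_factory(mapping$initial, model, params, rings, height)
  with_seed(config$seed, {
    tp <- mapping$target
    e_cur <- energy_fn(tp)
    if (!is.finite(e_cur)) stopf("non-finite energy of the starting mapping")
    T0 <- config$temperature %||% {
      dE <- sample_proposal_dE(mapping, config, energy_fn, 500L)
      suppressWarnings(calibrate_temperature(dE, config$initial_acceptance))
    }
    Tk <- T0
    best_tp <- tp; e_best <- e_cur
    n_pts <- mapping$n
    trace <- vector("list", config$sweeps_max)
    stall <- 0L
    mapping_cur <- mapping
    for (sw in seq_len(config$sweeps_max)) {
      acc_n <- 0L
      e_best_prev <- e_best
      for (i in seq_len(n_pts)) {
        pr <- propose_move(mapping_cur, config, energy_fn,
                           energy_current = e_cur,
                           project_to = if (config$reproject) mapping$target)
        if (!pr$ok) next
        if (!is.finite(pr$dE))
          stopf("non-finite energy at proposal for point %d", pr$k)
        if (metropolis_accept(pr$dE, Tk)) {
          mapping_cur$target <- pr$target
          mapping_cur$u <- pr$target - mapping_cur$initial
          e_cur <- e_cur + pr$dE
          acc_n <- acc_n + 1L
          if (e_cur < e_best) { e_best <- e_cur; best_tp <- pr$target }
        }
      }
      trace[[sw]] <- data.frame(sweep = sw, temperature = Tk,
                                current_energy = e_cur, best_energy = e_best,
                                acceptance_rate = acc_n / n_pts)
      stopifnot(e_best <= e_best_prev + 1e-300)
      rel_impr <- if (e_best_prev > 0) (e_best_prev - e_best) / e_best_prev
                  else e_best_prev - e_best
      stall <- if (rel_impr < config$stall_tol) stall + 1L else 0L
      Tk <- Tk * config$cooling_factor
      if (stall >= config$stall_sweeps) break
    }
    best <- point_mapping(mapping$initial, best_tp, validate = FALSE)
    structure(list(mapping = best, energy = e_best, T0 = T0,
                   model = model,
                   trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)])),
              class = "nt_anneal")
  })
}

#' @export
print.nt_anneal <- function(x, ...) {
  cat(sprintf("<nt_anneal> %s model, %d sweeps, T0 = %.4g, best energy = %.6g\n",
              x$model, nrow(x$trace), x$T0, x$energy))
  invisible(x)
}

#' Write the annealing energy trace to CSV
#' @param result an `nt_anneal` object
#' @param path file path
#' @export
write_energy_trace_csv <- function(result, path) {
  write_csv_det(result$trace, path)
}
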