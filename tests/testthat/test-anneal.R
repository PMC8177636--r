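# Metropolis rule, temperature calibration, proposal mechanics, annealing

test_that("equal-angle initial mapping handles the symmetric cases", {
  circ <- unit_circle_contour(3, 64)
  mp <- initial_mapping(circ, circ)
  expect_lt(max(abs(mp$u)), 1e-12)
  expect_lt(deformation_energy(mp, "shell"), 1e-18)
  # concentric circles: purely radial u of equal magnitude
  mp2 <- initial_mapping(unit_circle_contour(2, 64), unit_circle_contour(2.6, 64))
  um <- sqrt(rowSums(mp2$u^2))
  expect_equal(um, rep(0.6, 64), tolerance = 1e-9)
  radial <- mp2$u[, 1] * mp2$initial[, 2] - mp2$u[, 2] * mp2$initial[, 1]
  expect_lt(max(abs(radial)), 1e-9)
})

test_that("equal-angle energy equals an independent oracle (circle -> ellipse)", {
  circ <- unit_circle_contour(2, 48)
  ell <- make_shape("ellipse", a = 2.4, b = 5 / 3, n = 48)
  mp <- initial_mapping(circ, ell)
  pars <- elastic_params()
  expect_equal(deformation_energy(mp, "shell", pars),
               shell_energy_oracle(contour(mp$initial, validate = FALSE),
                                   mp$target, pars),
               tolerance = 1e-10)
})

test_that("propose_move steps a tenth of the way towards a neighbour", {
  circ <- unit_circle_contour(3, 32)
  mp <- initial_mapping(circ, circ)
  efn <- nuctraction:::energy_fn_factory(mp$initial, "shell", elastic_params(),
                                         height = 4.7)
  cfg <- anneal_config(move_fraction = 0.1)
  set.seed(99)
  k_exp <- sample.int(32, 1)
  side_exp <- if (stats::runif(1) < 0.5) -1L else 1L
  nb <- mp$target[((k_exp - 1 + side_exp) %% 32) + 1, ]
  set.seed(99)
  pr <- propose_move(mp, cfg, efn)
  expect_identical(pr$k, k_exp)
  expect_equal(pr$position, mp$target[k_exp, ] + 0.1 * (nb - mp$target[k_exp, ]),
               tolerance = 1e-15, ignore_attr = TRUE)
  # identity mapping of identical circles is a local optimum: dE >= 0
  set.seed(4)
  dEs <- sample_proposal_dE(mp, cfg, efn, 200)
  expect_true(all(dEs >= -1e-12))
  # coincident neighbour -> no-op with dE = 0
  tp <- mp$target; tp[2, ] <- tp[1, ]
  mp_dup <- point_mapping(mp$initial, tp, validate = FALSE)
  hits <- 0
  set.seed(11)
  for (i in 1:200) {
    pr <- propose_move(mp_dup, cfg, efn)
    if (pr$ok && all(pr$position == mp_dup$target[pr$k, ])) {
      expect_identical(pr$dE, 0)
      hits <- hits + 1
    }
  }
  expect_gt(hits, 0)
})

test_that("order-violating proposals are rejected before energy evaluation", {
  circ <- unit_circle_contour(1, 16)
  tp <- unclass(circ)
  tp[3, ] <- tp[2, ] * 1.001  # point 3 pushed behind point 2 in angle
  expect_false(nuctraction:::order_preserved(tp, 3))
  expect_true(nuctraction:::order_preserved(unclass(circ), 3))
})

test_that("the Metropolis rule follows the Boltzmann law", {
  expect_true(metropolis_accept(-1, 1e-6))
  expect_true(metropolis_accept(0, 1e-6))
  expect_error(metropolis_accept(1, 0), "positive")
  T <- 2.5
  set.seed(123)
  acc <- mean(vapply(1:10000, function(i) metropolis_accept(T * log(2), T), TRUE))
  expect_lt(abs(acc - 0.5), 0.015)
  # at the cooling floor only downhill moves pass
  set.seed(1)
  expect_false(any(vapply(1:200, function(i)
    metropolis_accept(1, 1e-12), TRUE)))
})

test_that("temperature calibration hits the target acceptance", {
  # all uphill with equal dE = d: closed form T = d / log(1/0.2)
  d <- 3.7
  T0 <- calibrate_temperature(rep(d, 600), target = 0.2)
  expect_lt(abs(exp(-d / T0) - 0.2), 0.005)
  expect_warning(calibrate_temperature(rep(-1, 600)), "downhill")
  # mixed synthetic set: seeded Metropolis replay lands in [0.18, 0.22]
  set.seed(42)
  dE <- c(-abs(stats::rnorm(60)), abs(stats::rnorm(540, 2, 1)))
  T0 <- calibrate_temperature(dE, target = 0.2)
  set.seed(77)
  acc <- mean(vapply(sample(dE, 4000, TRUE), function(e)
    metropolis_accept(e, T0), TRUE))
  expect_gt(acc, 0.18); expect_lt(acc, 0.22)
})

test_that("annealing identical contours stays at the identity", {
  circ <- unit_circle_contour(3, 32)
  res <- anneal(circ, circ, model = "shell",
                config = anneal_config(seed = 5, sweeps_max = 30))
  expect_lt(res$energy, 1e-12)
  expect_true(all(diff(res$trace$best_energy) <= 0))
})

test_that("annealing is reproducible and seed-robust on a convex case", {
  circ <- unit_circle_contour(4, 48)
  pair <- make_deformation_pair(circ, "dilation", 0.2)
  cfg <- anneal_config(seed = 9, sweeps_max = 60)
  r1 <- anneal(pair$initial, pair$target, model = "shell", config = cfg)
  r2 <- anneal(pair$initial, pair$target, model = "shell", config = cfg)
  expect_identical(r1$mapping$target, r2$mapping$target)
  expect_identical(r1$trace, r2$trace)
  r3 <- anneal(pair$initial, pair$target, model = "shell",
               config = anneal_config(seed = 10, sweeps_max = 60))
  expect_lt(abs(r3$energy - r1$energy) / r1$energy, 0.02)
  # sequential order preserved in the result
  ang <- atan2(r1$mapping$target[, 2], r1$mapping$target[, 1])
  expect_equal(sum(diff(ang) < 0), 1)  # single wrap
})

test_that("annealed dilation energy matches the analytic hoop-strain optimum", {
  alpha <- 0.2
  circ <- unit_circle_contour(4, 48)
  pair <- make_deformation_pair(circ, "dilation", alpha)
  res <- anneal(pair$initial, pair$target, model = "shell",
                config = anneal_config(seed = 3, sweeps_max = 80))
  pars <- elastic_params()
  fr <- contour_frames(contour(res$mapping$initial, validate = FALSE))
  ess <- alpha + pars$quad_coef * alpha^2
  e_analytic <- sum(2 * pars$E / 3 * ess^2 * pars$h * fr$ds * 4.7)
  expect_lt(res$energy, 1.02 * e_analytic)
  expect_gt(res$energy, 0.9 * e_analytic)
})

test_that("non-finite proposal energies abort with a point index", {
  circ <- unit_circle_contour(3, 32)
  mp <- initial_mapping(circ, circ)
  bad_fn <- function(tp) if (any(tp[5, ] != mp$target[5, ])) NaN else 0
  set.seed(2)
  expect_error({
    for (i in 1:500) {
      pr <- propose_move(mp, anneal_config(), bad_fn, energy_current = 0)
      if (pr$ok && !is.finite(pr$dE))
        nuctraction:::stopf("non-finite energy at proposal for point %d", pr$k)
    }
  }, "non-finite energy.*point")
})

test_that("lattice DP oracle equals brute-force enumeration (small case)", {
  circ <- unit_circle_contour(2, 8)
  ell <- make_shape("ellipse", a = 2.3, b = 2 / 2.3 * 2, n = 32)
  mp <- initial_mapping(centered(circ), centered(ell), n = 8)
  pars <- elastic_params()
  e_dp <- dp_lattice_min(contour(mp$initial, validate = FALSE), mp$target,
                         pars, npos = 3)
  e_bf <- brute_lattice_min(contour(mp$initial, validate = FALSE), mp$target,
                            pars, npos = 3)
  expect_equal(e_dp, e_bf, tolerance = 1e-12)
})
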