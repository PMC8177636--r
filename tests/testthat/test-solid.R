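# homogeneous incompressible elastic solid: interior extrapolation,
# polar-mesh strain, Hooke stress, energy density, boundary traction

fake_strain <- function(exx, eyy, exy, n = 4) {
  # minimal Cartesian strain field for constitutive-law unit tests
  structure(list(exx = matrix(exx, 2, n), eyy = matrix(eyy, 2, n),
                 exy = matrix(exy, 2, n),
                 ezz = matrix(-(exx + eyy), 2, n),
                 basis = "cartesian", convention = "as-printed",
                 mesh = NULL),
            class = "nt_strain")
}

test_that("interior deformation interpolates linearly to zero at the centroid", {
  circ <- unit_circle_contour(2, 64)
  p <- unclass(circ)
  u <- cbind(rep(2, 64), rep(-4, 64))
  mp <- point_mapping(p, p + u, validate = FALSE)
  expect_equal(interior_deformation(mp, 0), matrix(0, 64, 2),
               ignore_attr = TRUE)
  expect_equal(interior_deformation(mp, 1), u, ignore_attr = TRUE)
  expect_equal(unname(interior_deformation(mp, 0.5)[1, ]), c(1, -2))
  expect_error(interior_deformation(mp, 1.2), "0, 1")
})

test_that("strain of an affine displacement matches the symbolic oracle", {
  circ <- remesh_by_angle(unit_circle_contour(3, 96), 96, origin = c(0, 0))
  alpha <- 0.1
  mp <- affine_mapping(circ, diag(c(1 + alpha, 1 - alpha)))
  gl <- elastic_params(strain_convention = "green-lagrange")
  eps <- solid_strain(mp, gl, rings = 8)
  # symbolic: L = diag(alpha, -alpha); eps = (L + L^T)/2 + L^T L / 2
  expect_equal(max(abs(eps$exx - (alpha + alpha^2 / 2))), 0, tolerance = 1e-3)
  expect_equal(max(abs(eps$eyy - (-alpha + alpha^2 / 2))), 0, tolerance = 1e-3)
  expect_lt(max(abs(eps$exy)), 1e-9)
  # FD is exact for affine fields: much tighter than the nominal 1e-3
  expect_lt(max(abs(eps$exx - (alpha + alpha^2 / 2))), 1e-12)
  # zero map
  mp0 <- point_mapping(unclass(circ), unclass(circ), validate = FALSE)
  eps0 <- solid_strain(mp0, gl, rings = 5)
  expect_identical(max(abs(eps0$exx)), 0)
  expect_error(solid_strain(mp, gl, rings = 2), "3 radial rings")
})

test_that("Green-Lagrange strain is rotation invariant; the printed form is not", {
  star <- centered(random_star_contour(64, seed = 2))
  circ <- centered(remesh_by_angle(star, 64, origin = c(0, 0)))
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mp <- affine_mapping(circ, R)
  gl <- solid_strain(mp, elastic_params(strain_convention = "green-lagrange"), 6)
  expect_lt(max(abs(gl$exx), abs(gl$eyy), abs(gl$exy)), 1e-6)
  ap <- solid_strain(mp, elastic_params(strain_convention = "as-printed"), 6)
  expect_gt(max(abs(ap$exx)), 1e-4)
})

test_that("Hooke law: incompressible branch, zero map, exact E linearity", {
  e <- 0.01
  eps <- fake_strain(e, -e, 0)
  sig <- stress_from_strain(eps, elastic_params(E = 5000, nu = 0.5))
  expect_equal(sig$sxx[1, 1], 2 * 5000 / 3 * e, tolerance = 1e-12)
  expect_equal(sig$syy[1, 1], -2 * 5000 / 3 * e, tolerance = 1e-12)
  expect_identical(sig$szz[1, 1], 0)
  sig0 <- stress_from_strain(fake_strain(0, 0, 0), elastic_params())
  expect_identical(max(abs(sig0$sxx)), 0)
  sig2 <- stress_from_strain(eps, elastic_params(E = 10000, nu = 0.5))
  expect_identical(sig2$sxx, 2 * sig$sxx)
  expect_identical(sig2$sxy, 2 * sig$sxy)
  # trace violation with nu = 0.5 is an error
  bad <- fake_strain(e, -e, 0)
  bad$ezz <- bad$ezz + 1e-6
  expect_error(stress_from_strain(bad, elastic_params(nu = 0.5)),
               "incompressibility")
  # compressible branch agrees with the componentwise formula
  nu <- 0.3
  eps2 <- fake_strain(0.02, 0.005, -0.01)
  eps2$ezz <- matrix(0.003, 2, 4)  # nonzero trace exercised
  sigc <- stress_from_strain(eps2, elastic_params(E = 1000, nu = nu))
  tr <- 0.02 + 0.005 + 0.003
  expect_equal(sigc$sxx[1, 1],
               1000 / (1 + nu) * (0.02 + nu / (1 - 2 * nu) * tr),
               tolerance = 1e-12)
})

test_that("energy density is the half contraction, checked against brute force", {
  e <- 0.01
  eps <- fake_strain(e, -e, 0)
  sig <- stress_from_strain(eps, elastic_params(E = 5000))
  f <- energy_density(eps, sig)
  expect_equal(f[1, 1], 2 * 5000 / 3 * e^2, tolerance = 1e-12)
  expect_identical(energy_density(fake_strain(0, 0, 0),
                                  stress_from_strain(fake_strain(0, 0, 0),
                                                     elastic_params()))[1, 1], 0)
  # random trace-free strain: brute-force 3x3 tensor contraction oracle
  set.seed(8)
  for (i in 1:5) {
    exx <- stats::runif(1, -0.02, 0.02); eyy <- stats::runif(1, -0.02, 0.02)
    exy <- stats::runif(1, -0.02, 0.02)
    eps <- fake_strain(exx, eyy, exy)
    sig <- stress_from_strain(eps, elastic_params())
    E3 <- matrix(c(exx, exy, 0, exy, eyy, 0, 0, 0, -(exx + eyy)), 3, 3)
    S3 <- 2 * 5000 / 3 * E3
    expect_equal(energy_density(eps, sig)[1, 1], 0.5 * sum(S3 * E3),
                 tolerance = 1e-12)
  }
  # mismatched sizes
  eps_small <- fake_strain(e, -e, 0, n = 3)
  expect_error(energy_density(eps_small, sig), "mismatch")
})

test_that("traction is the stress-normal product", {
  circ <- unit_circle_contour(2, 64)
  fr <- contour_frames(circ)
  # isotropic in-plane stress p I: t = p n
  p <- 37.5
  prof <- nuctraction:::traction_profile(rep(p, 64), rep(p, 64), rep(0, 64),
                                         fr, rep(0, 64), "solid")
  expect_equal(prof$tx_Pa, p * fr$nx, tolerance = 1e-12)
  expect_equal(prof$tmag_Pa, rep(p, 64), tolerance = 1e-12)
  # zero stress
  prof0 <- nuctraction:::traction_profile(rep(0, 64), rep(0, 64), rep(0, 64),
                                          fr, rep(0, 64), "solid")
  expect_identical(max(abs(prof0$tmag_Pa)), 0)
  # general symmetric stress at a 30 degree normal vs matrix-vector oracle
  s <- matrix(c(120, -35, -35, 80), 2)
  nh <- c(cos(pi / 6), sin(pi / 6))
  fr1 <- fr[1, , drop = FALSE]
  fr1$nx <- nh[1]; fr1$ny <- nh[2]
  pr <- nuctraction:::traction_profile(s[1, 1], s[2, 2], s[1, 2], fr1, 0, "solid")
  expect_equal(c(pr$tx_Pa, pr$ty_Pa), as.numeric(s %*% nh), tolerance = 1e-12)
  # non-unit normal rejected
  fr1$nx <- 2
  expect_error(nuctraction:::traction_profile(1, 1, 0, fr1, 0, "solid"),
               "non-unit")
})

test_that("radial stress is constant along each spoke", {
  st <- remesh_by_angle(make_shape("stadium", r = 2.5, len = 4, n = 128),
                        96, origin = c(0, 0))
  pair <- make_deformation_pair(st, "constriction-squeeze", 0.15)
  mp <- initial_mapping(pair$initial, pair$target, 96)
  eps <- solid_strain(mp, elastic_params(), rings = 12)
  sig <- stress_from_strain(eps, elastic_params())
  # radial direction of spoke k
  b <- mp$initial
  rn <- b / sqrt(rowSums(b^2))
  srr <- t(t(sig$sxx) * rn[, 1]^2) + 2 * t(t(sig$sxy) * (rn[, 1] * rn[, 2])) +
    t(t(sig$syy) * rn[, 2]^2)
  spread <- apply(srr, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-9 * max(abs(srr)))
})

test_that("incompressibility holds to machine precision on random deformations", {
  set.seed(21)
  for (i in 1:10) {
    ct <- centered(remesh_by_angle(random_star_contour(48, seed = i),
                                   48, c(0, 0)))
    p <- unclass(ct)
    u <- 0.05 * cbind(stats::rnorm(48), stats::rnorm(48))
    u <- apply(u, 2, function(col) stats::filter(c(col, col), rep(1 / 5, 5),
                                                 circular = TRUE)[1:48])
    mp <- point_mapping(p, p + u, validate = FALSE)
    eps <- solid_strain(mp, elastic_params(), rings = 6)
    expect_lt(max(abs(eps$exx + eps$eyy + eps$ezz)), 1e-12)
  }
})

test_that("aligned pure translation has (near-)zero energy", {
  st <- make_shape("stadium", r = 2, len = 5, n = 96)
  pair <- make_deformation_pair(st, "translation", 4)
  al <- align_pair(pair$initial, pair$target)
  mp <- initial_mapping(al$initial, al$target, 96)
  en <- total_energy(mp, elastic_params(), rings = 8)
  vol <- polygon_area(al$initial) * 4.7
  expect_lt(en, 1e-10 * 5000 * vol)
})

test_that("traction scales linearly in E with bit-identical directions", {
  circ <- remesh_by_angle(unit_circle_contour(3, 64), 64, c(0, 0))
  pair <- make_deformation_pair(circ, "area-preserving-affine", 0.15)
  mp <- initial_mapping(pair$initial, pair$target, 64)
  t1 <- solid_traction(mp, elastic_params(E = 5000))
  t2 <- solid_traction(mp, elastic_params(E = 10000))
  expect_identical(t2$tx_Pa, 2 * t1$tx_Pa)
  expect_identical(t2$ty_Pa, 2 * t1$ty_Pa)
  expect_identical(atan2(t2$ty_Pa, t2$tx_Pa), atan2(t1$ty_Pa, t1$tx_Pa))
})
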