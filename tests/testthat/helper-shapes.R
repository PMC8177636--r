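# Shared fixtures and independent oracles. Oracles deliberately re-derive
# quantities from definitions (triangulation, brute-force contraction,
# exhaustive scans) rather than calling the code paths they check.

# regular n-gon on a circle, first vertex at angle -pi (rear)
unit_circle_contour <- function(r = 1, n = 200, center = c(0, 0)) {
  th <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# star-shaped polygon with seeded random radii
random_star_contour <- function(n = 10, seed = 1, r_range = c(1, 3)) {
  set.seed(seed)
  th <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
  r <- stats::runif(n, r_range[1], r_range[2])
  contour(cbind(r * cos(th), r * sin(th)))
}

# re-centre a contour at its centroid (solid-model precondition)
centered <- function(ct) {
  contour(sweep(unclass(ct), 2, polygon_centroid(ct)), validate = FALSE)
}

# mapping whose target is an exact affine image of the initial points
# (no remeshing, so displacement gradients are spatially constant)
affine_mapping <- function(initial, A, t = c(0, 0)) {
  p <- unclass(initial); attr(p, "class") <- NULL
  point_mapping(p, p %*% t(A) + matrix(t, nrow(p), 2, byrow = TRUE),
                validate = FALSE)
}

# fan-triangulation centroid oracle
centroid_triangulation_oracle <- function(pts) {
  n <- nrow(pts)
  acc <- c(0, 0); atot <- 0
  for (i in 2:(n - 1)) {
    a <- pts[1, ]; b <- pts[i, ]; c <- pts[i + 1, ]
    ar <- ((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
    acc <- acc + ar * (a + b + c) / 3
    atot <- atot + ar
  }
  acc / atot
}

# exhaustive Otsu oracle: minimise intra-class variance over every split
# of the sorted distinct values (definition-level, not histogram code)
otsu_oracle_split <- function(v) {
  u <- sort(unique(v))
  best <- Inf; best_i <- NA
  for (i in seq_len(length(u) - 1)) {
    g1 <- v[v <= u[i]]; g2 <- v[v > u[i]]
    w <- (length(g1) * pvar(g1) + length(g2) * pvar(g2)) / length(v)
    if (w < best - 1e-12 * max(abs(w), 1)) { best <- w; best_i <- i }
  }
  u[best_i]  # upper edge of class 1
}
pvar <- function(x) if (length(x) < 2) 0 else mean((x - mean(x))^2)

# per-point shell energy contribution: depends on the mapped positions of
# points k-1, k, k+1 only (independent re-derivation used by the DP and
# brute-force annealing oracles)
shell_point_energy <- function(fr, b, k, pm1, p0, pp1, params, height = 4.7) {
  n <- nrow(fr)
  km <- ((k - 2) %% n) + 1; kp <- (k %% n) + 1
  comp <- function(i, p) {
    u <- unname(p - b[i, ])
    c(un = fr$nx[i] * u[1] + fr$ny[i] * u[2],
      us = fr$tx[i] * u[1] + fr$ty[i] * u[2])
  }
  a <- comp(km, pm1); c0 <- comp(k, p0); cc <- comp(kp, pp1)
  D1s <- (cc["us"] - a["us"]) / (2 * fr$ds[k]) + fr$curvature[k] * c0["un"]
  D1n <- (cc["un"] - a["un"]) / (2 * fr$ds[k]) - fr$curvature[k] * c0["us"]
  q <- params$quad_coef
  ess <- D1s + q * (D1s^2 + D1n^2)
  ens <- 0.5 * D1n
  f <- (2 * params$E / 3) * (ess^2 + ens^2)
  unname(f * params$h * fr$ds[k] * height)
}

# total shell energy of a full configuration via the per-point oracle
shell_energy_oracle <- function(initial, target_pts, params, height = 4.7) {
  b <- unclass(initial); attr(b, "class") <- NULL
  fr <- contour_frames(initial)
  n <- nrow(b)
  sum(vapply(seq_len(n), function(k) {
    km <- ((k - 2) %% n) + 1; kp <- (k %% n) + 1
    shell_point_energy(fr, b, k, target_pts[km, ], target_pts[k, ],
                       target_pts[kp, ], params, height)
  }, 1))
}

# candidate lattice for the discretised-correspondence oracle: for each
# point, `npos` positions along the chord between its equal-angle
# neighbours on the target
chord_lattice <- function(target_pts, npos = 7) {
  n <- nrow(target_pts)
  lapply(seq_len(n), function(k) {
    km <- ((k - 2) %% n) + 1; kp <- (k %% n) + 1
    a <- target_pts[km, ]; c <- target_pts[kp, ]
    t(vapply(seq_len(npos) / (npos + 1),
             function(f) a + f * (c - a), c(0, 0)))
  })
}

# order constraint between adjacent lattice choices (anticlockwise polar
# angle about the origin must increase)
lattice_order_ok <- function(p, q) (p[1] * q[2] - p[2] * q[1]) > 0

# exact minimum over the order-constrained lattice by cyclic dynamic
# programming; the shell energy is 3-local in the mapped points so this
# equals exhaustive enumeration (cross-checked against brute force below)
dp_lattice_min <- function(initial, target_pts, params, npos = 7,
                           height = 4.7) {
  b <- unclass(initial); attr(b, "class") <- NULL
  fr <- contour_frames(initial)
  n <- nrow(b)
  lat <- chord_lattice(target_pts, npos)
  ek <- function(k, ia, ib, ic) {
    km <- ((k - 2) %% n) + 1; kp <- (k %% n) + 1
    shell_point_energy(fr, b, k, lat[[km]][ia, ], lat[[k]][ib, ],
                       lat[[kp]][ic, ], params, height)
  }
  best <- Inf
  for (i1 in seq_len(npos)) for (i2 in seq_len(npos)) {
    if (!lattice_order_ok(lat[[1]][i1, ], lat[[2]][i2, ])) next
    # dp[prev, cur] = min energy of e_2..e_{k-1} with c_{k-1}=prev, c_k=cur
    dp <- matrix(Inf, npos, npos)
    dp[i1, i2] <- 0
    for (k in 3:n) {
      dp2 <- matrix(Inf, npos, npos)
      for (ip in seq_len(npos)) for (ic in seq_len(npos)) {
        if (!is.finite(min(dp[, ip]))) next
        if (!lattice_order_ok(lat[[k - 1]][ip, ], lat[[k]][ic, ])) next
        cand <- dp[, ip] + vapply(seq_len(npos), function(ig)
          ek(k - 1, ig, ip, ic), 1)
        dp2[ip, ic] <- min(cand)
      }
      dp <- dp2
    }
    for (ipn in seq_len(npos)) for (icn in seq_len(npos)) {
      if (!is.finite(dp[ipn, icn])) next
      if (!lattice_order_ok(lat[[n]][icn, ], lat[[1]][i1, ])) next
      tot <- dp[ipn, icn] + ek(n, ipn, icn, i1) + ek(1, icn, i1, i2)
      if (tot < best) best <- tot
    }
  }
  best
}

# brute-force lattice minimum (small n / npos only)
brute_lattice_min <- function(initial, target_pts, params, npos = 3,
                              height = 4.7) {
  n <- nrow(target_pts)
  lat <- chord_lattice(target_pts, npos)
  grid <- do.call(expand.grid, rep(list(seq_len(npos)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    pts <- t(vapply(seq_len(n), function(k) lat[[k]][idx[k], ], c(0, 0)))
    ok <- all(vapply(seq_len(n), function(k)
      lattice_order_ok(pts[k, ], pts[(k %% n) + 1, ]), TRUE))
    if (!ok) next
    e <- shell_energy_oracle(initial, pts, params, height)
    if (e < best) best <- e
  }
  best
}
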