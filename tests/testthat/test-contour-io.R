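# contour container, CSV round trips, Otsu threshold, outline extraction,
# volume estimation, TIFF subset

test_that("contour constructor enforces the outline invariants", {
  expect_error(contour(cbind(1:3, 1:3)), "at least 8")
  # clockwise input is normalised to anticlockwise
  th <- seq(pi, -pi, length.out = 33)[-33]
  cw <- contour(cbind(cos(th), sin(th)))
  expect_gt(nuctraction:::shoelace_area(unclass(cw)), 0)
  # consecutive duplicates rejected
  p <- unclass(unit_circle_contour(1, 16))
  expect_error(contour(rbind(p, p[16, ])), "identical consecutive|simple")
  # self-intersecting bowtie rejected
  bow <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0.5, -0.5), c(0, 1),
               c(-0.2, 0.8), c(-0.3, 0.5), c(-0.2, 0.2))
  expect_error(contour(bow), "simple")
})

test_that("Otsu equals the exhaustive intra-class-variance minimiser", {
  # two equal-mass delta peaks: threshold strictly between, tie to lowest
  v <- c(rep(10, 50), rep(200, 50))
  th <- otsu_threshold(matrix(v, 10, 10))
  expect_gt(th, 10); expect_lt(th, 200)
  split <- otsu_oracle_split(v)
  expect_identical(split, 10)
  expect_error(otsu_threshold(matrix(5, 3, 3)), "degenerate")
  # bimodal Gaussian mixture, 256 bins: equals exhaustive-scan maximiser
  set.seed(42)
  v <- c(stats::rnorm(4000, 40, 6), stats::rnorm(2000, 170, 14))
  v <- pmax(v, 0)
  th <- otsu_threshold(v)
  # oracle: exhaustive scan over the same binned candidates by definition
  br <- seq(min(v), max(v), length.out = 257)
  idx <- findInterval(v, br, rightmost.closed = TRUE)
  centers <- (br[-1] + br[-257]) / 2
  rep_v <- centers[idx]
  split <- otsu_oracle_split(rep_v)
  uo <- sort(unique(rep_v))
  expect_gt(th, split - 1e-9)
  expect_lt(th, uo[match(split, uo) + 1] + 1e-9)
  # property: random histograms, package split == oracle split
  for (s in 1:20) {
    set.seed(s)
    vals <- sample(0:15, 400, replace = TRUE,
                   prob = stats::runif(16, 0.05, 1))
    if (length(unique(vals)) < 2) next
    th <- otsu_threshold(vals)
    split <- otsu_oracle_split(vals)
    u <- sort(unique(vals))
    expect_gt(th, split); expect_lt(th, u[match(split, u) + 1])
  }
})

test_that("extract_contour recovers known shapes at pixel-edge accuracy", {
  px <- matrix(0, 30, 30); px[6:25, 6:25] <- 255
  sq <- extract_contour(gray_image(px, 1), 100)
  expect_lt(abs(contour_perimeter(sq) - 80), 2)
  expect_lt(abs(polygon_area(sq) - 400) / 400, 0.05)
  nr <- 70; cc <- 35.5
  pxd <- outer(1:nr, 1:nr,
               function(r, c) ifelse((r - cc)^2 + (c - cc)^2 <= 900, 200, 10))
  disc <- extract_contour(gray_image(pxd, 1))
  expect_lt(abs(polygon_area(disc) - pi * 900) / (pi * 900), 0.03)
  # all-background: threshold above every pixel
  expect_error(extract_contour(gray_image(pxd, 1), 300), "no object")
  # border-touching component warns but proceeds
  pxb <- matrix(0, 20, 20); pxb[1:10, 5:15] <- 50
  expect_warning(extract_contour(gray_image(pxb, 1), 10), "border")
  # unit conversion is an exact scaling
  a <- extract_contour(gray_image(pxd, 1))
  b <- extract_contour(gray_image(pxd, 0.215))
  expect_identical(unclass(b), unclass(a) * 0.215)
})

test_that("contour CSV round trip is lossless and normalising", {
  ell <- make_shape("ellipse", a = 3.2, b = 1.7, n = 100)
  f <- tempfile(fileext = ".csv")
  write_contour_csv(ell, f)
  back <- read_contour_csv(f)
  expect_identical(unclass(back), unclass(ell))
  # clockwise file comes back anticlockwise with the same point set
  p <- unclass(ell)
  writeLines(c("x_um,y_um",
               paste(sprintf("%.17g", rev(p[, 1])),
                     sprintf("%.17g", rev(p[, 2])), sep = ",")), f)
  back2 <- read_contour_csv(f)
  expect_equal(sort(back2[, 1]), sort(p[, 1]))
  expect_gt(nuctraction:::shoelace_area(unclass(back2)), 0)
  writeLines(c("x_um,y_um", "1,2", "3,4", "5,6"), f)
  expect_error(read_contour_csv(f), "at least 8")
  writeLines(c("x_um,y_um", paste(1:9, 1:9, sep = ","), "oops"), f)
  expect_error(read_contour_csv(f), "line 11")
})

test_that("estimate_volume is area times (piecewise) height", {
  box <- contour(rect_points(7, 10, n = 40))
  expect_equal(estimate_volume(box, 4.7), 329, tolerance = 1e-12)
  unit <- contour(rect_points(1, 1, n = 12))
  expect_equal(estimate_volume(unit, 1), 1, tolerance = 1e-12)
  disc <- make_shape("circle", r = 5, n = 400)
  expect_equal(estimate_volume(disc, 3.4), pi * 25 * 3.4, tolerance = 1e-3)
  expect_error(estimate_volume(box, -1), "positive")
  # split across the constriction entrance: half at each height
  g <- channel_geometry()
  box2 <- contour(rect_points(4, 1.8, center = c(0, 0), n = 24))
  a <- polygon_area(box2)
  expect_equal(estimate_volume(box2, g),
               a / 2 * g$channel_height + a / 2 * g$constriction_height,
               tolerance = 1e-9)
})

test_that("TIFF subset round-trips 8- and 16-bit multi-page grayscale", {
  set.seed(7)
  a <- gray_image(matrix(sample(0:255, 12 * 9, TRUE), 12, 9), 0.5)
  b <- gray_image(matrix(sample(0:60000, 6 * 8, TRUE), 6, 8), 0.5)
  f <- tempfile(fileext = ".tif")
  write_tiff_gray(a, f, bits = 8)
  expect_identical(read_tiff_gray(f, 0.5)[[1]]$pixels, a$pixels)
  write_tiff_gray(list(b, b), f, bits = 16)
  back <- read_tiff_gray(f, 0.5)
  expect_length(back, 2)
  expect_identical(back[[2]]$pixels, b$pixels)
  fbad <- tempfile()
  writeBin(as.raw(1:64), fbad)
  expect_error(read_tiff_gray(fbad), "TIFF")
})
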