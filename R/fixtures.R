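# Synthetic contours, deformation pairs with known ground truth, and
# channel/constriction geometry. Everything in the pipeline is testable
# against these without any experimental data.
#
# The stage shapes emulate the migration sequence qualitatively: a
# channel-filling nucleus before the constriction, a tip protruding into
# the constriction mouth on entry, and a long narrow shape inside. Their
# default areas reproduce the measured mean nuclear volumes (242 um^3
# before and 231 um^3 inside) divided by the respective channel heights;
# no claim is made that they reproduce experimental average outlines,
# which are not available as coordinates.

#' Microchannel constriction geometry
#'
#' Cross-section dimensions (width x height): 7 x 4.7 um in the channel,
#' 2 x 3.4 um in the constriction; constriction length 20 um; entrance
#' taper 45 degrees. The constriction occupies `0 <= x <= length` in
#' pipeline coordinates.
#'
#' @param channel_width,channel_height channel cross section (um)
#' @param constriction_width,constriction_height constriction cross
#'   section (um); must be smaller than the channel's
#' @param constriction_length constriction length (um)
#' @param taper_deg entrance/exit taper angle (degrees)
#' @return object of class `nt_channel_geometry`
#' @export
channel_geometry <- function(channel_width = 7, channel_height = 4.7,
                             constriction_width = 2,
                             constriction_height = 3.4,
                             constriction_length = 20, taper_deg = 45) {
  if (constriction_width >= channel_width ||
      constriction_height >= channel_height)
    stopf("constriction dimensions must be smaller than channel dimensions")
  structure(list(channel_width = channel_width,
                 channel_height = channel_height,
                 constriction_width = constriction_width,
                 constriction_height = constriction_height,
                 constriction_length = constriction_length,
                 taper_deg = taper_deg),
            class = "nt_channel_geometry")
}

# Points along a circular arc, anticlockwise, endpoint excluded.
#' @keywords internal
arc_points <- function(center, r, from, to, n) {
  th <- seq(from, to, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Points along a straight segment, endpoint excluded.
#' @keywords internal
seg_points <- function(from, to, n) {
  t <- seq(0, 1, length.out = n + 1)[-(n + 1)]
  cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
}

# Distribute n points over pieces proportionally to their lengths.
#' @keywords internal
alloc_points <- function(lengths, n) {
  raw <- pmax(2L, round(n * lengths / sum(lengths)))
  raw
}

#' Generate a synthetic stage shape
#'
#' Kinds:
#' * `circle`: radius `r` (default 4), centred at `center`;
#' * `ellipse`: semi-axes `a`, `b`;
#' * `stadium`: rectangle of straight length `len` with semicircular caps
#'   of radius `r`;
#' * `pre-constriction`: channel-filling stadium (cap radius = channel
#'   half-width) with area `volume / channel_height`, rear of the shape
#'   at negative x, front at `x = front` (default just touching the
#'   constriction entrance taper);
#' * `entering`: the same body with a tapered tongue of constriction
#'   width protruding `tongue` um into the constriction (`x > 0`);
#' * `inside`: a stadium of constriction width with area
#'   `volume / constriction_height`, placed inside the constriction.
#'
#' All shapes are star-shaped closed contours; "entering" and "inside"
#' respect the channel geometry (flat sections at wall positions, width
#' at most the constriction width inside).
#'
#' @param kind shape kind (see above)
#' @param n number of boundary points (>= 32, default 200)
#' @param r,a,b,len,center kind-specific dimensional parameters (um)
#' @param geometry [channel_geometry()] for the stage shapes
#' @param volume nominal nuclear volume (um^3): 242 before / 231 inside,
#'   the measured stage means
#' @param tongue protrusion length of the "entering" tip (um, default 3)
#' @return an [contour()] object
#' @export
make_shape <- function(kind = c("circle", "ellipse", "stadium",
                                "pre-constriction", "entering", "inside"),
                       n = 200, r = 4, a = 2, b = 1, len = 4,
                       center = c(0, 0), geometry = channel_geometry(),
                       volume = NULL, tongue = 3) {
  kind <- match.arg(kind)
  if (n < 32) stopf("make_shape needs n >= 32 points")
  if (kind == "circle") {
    if (r <= 0) stopf("radius must be positive")
    return(contour(arc_points(center, r, -pi, pi, n), validate = FALSE))
  }
  if (kind == "ellipse") {
    if (a <= 0 || b <= 0) stopf("semi-axes must be positive")
    th <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
    return(contour(cbind(center[1] + a * cos(th), center[2] + b * sin(th)),
                   validate = FALSE))
  }
  if (kind == "stadium") {
    if (r <= 0 || len < 0) stopf("stadium needs r > 0, len >= 0")
    return(stadium_contour(r, len, center, n))
  }
  g <- geometry
  if (kind == "pre-constriction") {
    vol <- volume %||% 242
    rr <- g$channel_width / 2
    area <- vol / g$channel_height
    len0 <- (area - pi * rr^2) / g$channel_width
    if (len0 < 0)
      stopf("volume %.3g um^3 too small for a channel-filling stadium", vol)
    taper_len <- (g$channel_width - g$constriction_width) / 2 /
      tan(g$taper_deg * pi / 180)
    front <- -taper_len  # front face just reaches the taper start
    return(stadium_contour(rr, len0, c(front - len0 / 2 - rr, 0), n))
  }
  if (kind == "inside") {
    vol <- volume %||% 231
    rr <- g$constriction_width / 2
    area <- vol / g$constriction_height
    len0 <- (area - pi * rr^2) / g$constriction_width
    if (len0 < 0) stopf("volume too small for the constriction stadium")
    return(stadium_contour(rr, len0, c(g$constriction_length / 2, 0), n))
  }
  # entering: channel-filling body + tapered tongue into the constriction
  vol <- volume %||% 242
  R <- g$channel_width / 2
  w <- g$constriction_width / 2
  taper_len <- (R - w) / tan(g$taper_deg * pi / 180)
  if (tongue <= 0) stopf("tongue length must be positive")
  tip_r <- w
  tip_straight <- tongue - tip_r
  if (tip_straight <= 0)
    stopf("tongue must exceed the tip radius %.3g um", tip_r)
  # body straight length from the area budget
  area <- vol / g$channel_height
  area_caps <- pi * R^2 / 2                    # rear cap
  area_taper <- (R + w) * taper_len            # trapezoid (both sides)
  area_tongue <- 2 * w * tip_straight + pi * w^2 / 2
  body_len <- (area - area_caps - area_taper - area_tongue) / g$channel_width
  if (body_len < 0) stopf("volume too small for the entering shape")
  x_taper0 <- -taper_len                        # taper starts here
  x_rear <- x_taper0 - body_len                 # rear straight ends here
  per <- c(pi * R, body_len, sqrt(taper_len^2 + (R - w)^2), tip_straight,
           pi * w, tip_straight, sqrt(taper_len^2 + (R - w)^2), body_len)
  nn <- alloc_points(per, n)
  pts <- rbind(
    arc_points(c(x_rear, 0), R, pi / 2, 3 * pi / 2, nn[1]),      # rear cap
    seg_points(c(x_rear, -R), c(x_taper0, -R), nn[2]),           # lower wall
    seg_points(c(x_taper0, -R), c(0, -w), nn[3]),                # lower taper
    seg_points(c(0, -w), c(tip_straight, -w), nn[4]),            # lower tongue
    arc_points(c(tip_straight, 0), w, -pi / 2, pi / 2, nn[5]),   # tip cap
    seg_points(c(tip_straight, w), c(0, w), nn[6]),              # upper tongue
    seg_points(c(0, w), c(x_taper0, R), nn[7]),                  # upper taper
    seg_points(c(x_taper0, R), c(x_rear, R), nn[8]))             # upper wall
  contour(pts, validate = FALSE)
}

#' @keywords internal
stadium_contour <- function(r, len, center, n) {
  if (len < 1e-12)
    return(contour(arc_points(center, r, -pi, pi, n), validate = FALSE))
  x0 <- center[1] - len / 2; x1 <- center[1] + len / 2
  per <- c(pi * r, max(len, 1e-9), pi * r, max(len, 1e-9))
  nn <- alloc_points(per, n)
  pts <- rbind(
    arc_points(c(x1, center[2]), r, -pi / 2, pi / 2, nn[1]),  # right cap
    seg_points(c(x1, center[2] + r), c(x0, center[2] + r), nn[2]),
    arc_points(c(x0, center[2]), r, pi / 2, 3 * pi / 2, nn[3]),
    seg_points(c(x0, center[2] - r), c(x1, center[2] - r), nn[4]))
  contour(pts, validate = FALSE)
}

# Smoothstep ramp on [0, 1].
#' @keywords internal
sstep <- function(z) {
  z <- pmin(pmax(z, 0), 1)
  z * z * (3 - 2 * z)
}

#' Generate a deformation pair with known ground truth
#'
#' The target is the exact image of the (centroid-centred) initial
#' contour under the stated map, and the per-point ground-truth
#' displacement `u` is stored for recovery tests.
#'
#' Kinds: `translation` (u = (magnitude, 0), or a length-2 vector);
#' `dilation` (isotropic scaling by 1 + magnitude about the centroid);
#' `area-preserving-affine` (diag(lambda, 1/lambda), lambda = 1 +
#' magnitude: area preserved to machine precision); and
#' `constriction-squeeze` (y compressed by up to `magnitude` with a
#' smooth ramp towards the front, then x rescaled about the centroid to
#' restore the area exactly).
#'
#' @param contour initial outline
#' @param map_kind see above
#' @param magnitude deformation amplitude (dimensionless except for
#'   translation, where it is um)
#' @return list with `initial` (centred [contour()]), `target`
#'   ([contour()]), and `u` (n x 2 ground-truth displacement matrix)
#' @export
make_deformation_pair <- function(contour,
                                  map_kind = c("translation", "dilation",
                                               "area-preserving-affine",
                                               "constriction-squeeze"),
                                  magnitude = 0.1) {
  map_kind <- match.arg(map_kind)
  cen <- polygon_centroid(contour)
  p <- sweep(as_points(contour), 2, cen)
  init <- nuctraction::contour(p, validate = FALSE)
  tp <- switch(map_kind,
    "translation" = {
      d <- if (length(magnitude) == 2) magnitude else c(magnitude, 0)
      sweep(p, 2, -d)
    },
    "dilation" = (1 + magnitude) * p,
    "area-preserving-affine" = {
      lam <- 1 + magnitude
      cbind(lam * p[, 1], p[, 2] / lam)
    },
    "constriction-squeeze" = {
      x0 <- min(p[, 1]); x1 <- max(p[, 1])
      g <- 1 - magnitude * sstep((p[, 1] - x0) / (x1 - x0))
      q <- cbind(p[, 1], p[, 2] * g)
      a0 <- abs(shoelace_area(p)); a1 <- abs(shoelace_area(q))
      cbind(q[, 1] * a0 / a1, q[, 2])
    })
  targ <- tryCatch(nuctraction::contour(tp, validate = TRUE),
                   error = function(e)
                     stopf("deformed target is not a valid simple contour: %s",
                           conditionMessage(e)))
  list(initial = init, target = targ, u = tp - p)
}

#' Rasterise a contour into a grayscale image
#'
#' Fills the polygon at `fg` intensity over a `bg` background on a pixel
#' grid with `margin` pixels of clearance, optionally adding seeded
#' Gaussian noise (clamped at zero). Closes the loop for segmentation
#' tests: `extract_contour(rasterize_contour(x))` recovers `x` up to
#' pixelisation.
#'
#' @param contour outline (um)
#' @param pixel_size um per pixel (default 0.215)
#' @param noise_sd Gaussian noise standard deviation (intensity units)
#' @param margin clearance around the shape in pixels (>= 2)
#' @param fg,bg foreground/background intensities
#' @param seed RNG seed for the noise
#' @return an [gray_image()]
#' @export
rasterize_contour <- function(contour, pixel_size = 0.215, noise_sd = 0,
                              margin = 3, fg = 200, bg = 10, seed = 1L) {
  pts <- as_points(contour)
  if (margin < 2) stopf("margin must be at least 2 px")
  w_um <- diff(range(pts[, 1])); h_um <- diff(range(pts[, 2]))
  if (w_um < pixel_size || h_um < pixel_size)
    stopf("contour smaller than one pixel; nothing to rasterise")
  x0 <- min(pts[, 1]) - margin * pixel_size
  y1 <- max(pts[, 2]) + margin * pixel_size
  nc <- ceiling(w_um / pixel_size) + 2 * margin
  nr <- ceiling(h_um / pixel_size) + 2 * margin
  # pixel (r, c) centre in um
  cx <- x0 + (seq_len(nc) - 0.5) * pixel_size
  cy <- y1 - (seq_len(nr) - 0.5) * pixel_size
  inside <- point_in_polygon(cx, cy, pts)
  px <- matrix(bg, nr, nc)
  px[inside] <- fg
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
    px <- pmax(px + noise, 0)
  }
  gray_image(px, pixel_size)
}

# Even-odd crossing test for the grid (cx across columns, cy down rows).
#' @keywords internal
point_in_polygon <- function(cx, cy, pts) {
  nr <- length(cy); nc <- length(cx)
  X <- matrix(cx, nr, nc, byrow = TRUE)
  Y <- matrix(cy, nr, nc)
  inside <- matrix(FALSE, nr, nc)
  n <- nrow(pts)
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    xj <- pts[j, 1]; yj <- pts[j, 2]
    cross <- ((yi > Y) != (yj > Y)) &
      (X < (xj - xi) * (Y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
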