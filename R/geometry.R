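# Geometric primitives on closed contours.
#
# Conventions used throughout:
#  * contours are anticlockwise, so shoelace area is positive and the
#    outward unit normal is the unit tangent rotated by -pi/2;
#  * the arclength coordinate s1 starts at the rearmost vertex (minimum x)
#    and increases anticlockwise, so profiles start at the rear of the
#    nucleus, run along negative y to the front, and return along
#    positive y;
#  * curvature is the discrete turning angle per unit arclength, positive
#    where the outline is locally convex.

#' Polygon area (shoelace formula)
#'
#' @param contour an [contour()] object (or plain two-column matrix)
#' @return area in um^2 (positive; contours are anticlockwise)
#' @export
polygon_area <- function(contour) {
  pts <- if (is_contour(contour)) as_points(contour) else as.matrix(contour)
  abs(shoelace_area(pts))
}

#' Polygon centroid
#'
#' Area-weighted centre of a simple closed polygon, with the closing wrap
#' (vertex N connects to vertex 1):
#' \deqn{x_c = \frac{1}{6A}\sum_i (x_i y_{i+1} - x_{i+1} y_i)(x_i + x_{i+1})}
#' and likewise for \eqn{y_c}. Independent of the starting vertex. This is
#' the zero-deformation anchor of the solid model.
#'
#' @param contour an [contour()] object (or plain two-column matrix)
#' @return length-2 numeric `c(x, y)` in um
#' @export
polygon_centroid <- function(contour) {
  pts <- if (is_contour(contour)) as_points(contour) else as.matrix(contour)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- vec_shift(x, 1); yn <- vec_shift(y, 1)
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(abs(pts), 1)^2)
    stopf("cannot compute centroid of a zero-area polygon")
  c(x = sum(cr * (x + xn)) / (6 * a), y = sum(cr * (y + yn)) / (6 * a))
}

#' Remesh a contour by equal angular spokes
#'
#' Casts `n` rays from `origin` at angles \eqn{\theta_k = -\pi + 2\pi k/n}
#' (k = 0, ..., n-1) and returns the intersection of each ray with the
#' piecewise-linear boundary. Requires the contour to be star-shaped about
#' `origin`: every ray must cross the boundary exactly once. The first
#' output point lies on the ray pointing in -x, i.e. towards the rear of a
#' nucleus centred at `origin`.
#'
#' @param contour an [contour()] object
#' @param n number of output points (>= 8)
#' @param origin spoke origin, default the polygon centroid
#' @return an anticlockwise [contour()] with `n` points
#' @export
remesh_by_angle <- function(contour, n, origin = polygon_centroid(contour)) {
  pts <- as_points(contour)
  if (n < 8) stopf("remesh needs n >= 8, got %d", n)
  r <- spoke_radii(pts, n, origin)
  th <- spoke_angles(n)
  contour(cbind(origin[1] + r * cos(th), origin[2] + r * sin(th)),
          validate = FALSE)
}

#' @keywords internal
spoke_angles <- function(n) -pi + 2 * pi * (seq_len(n) - 1) / n

# Radii of the single boundary crossing of each spoke; errors if any ray
# has 0 or >= 2 crossings (not star-shaped about origin).
#' @keywords internal
spoke_radii <- function(pts, n, origin) {
  a <- cbind(pts[, 1] - origin[1], pts[, 2] - origin[2])
  b <- row_shift(a, 1)
  e <- b - a
  th <- spoke_angles(n)
  scale <- max(abs(a))
  r_out <- numeric(n)
  for (k in seq_len(n)) {
    d <- c(cos(th[k]), sin(th[k]))
    # solve a + s e = t d ; cross with d: s (e x d) = -(a x d)
    exd <- e[, 1] * d[2] - e[, 2] * d[1]
    axd <- a[, 1] * d[2] - a[, 2] * d[1]
    ok <- abs(exd) > 1e-14 * scale
    s <- ifelse(ok, -axd / exd, NA_real_)
    # tolerant window: a ray through a vertex hits both adjacent edges
    # (s ~ 0 and s ~ 1); the duplicates are collapsed by distance below
    hit <- ok & s >= -1e-9 & s <= 1 + 1e-9
    t <- (a[hit, 1] + s[hit] * e[hit, 1]) * d[1] +
         (a[hit, 2] + s[hit] * e[hit, 2]) * d[2]
    t <- sort(t[t > 1e-12 * scale])
    # collapse duplicate hits where a ray passes exactly through a vertex
    if (length(t) > 1) t <- t[c(TRUE, diff(t) > 1e-9 * max(scale, 1))]
    if (length(t) != 1)
      stopf("contour is not star-shaped about (%.3g, %.3g): ray at angle %.4f rad crosses the boundary %d times",
            origin[1], origin[2], th[k], length(t))
    r_out[k] <- t
  }
  r_out
}

#' Surface frames of a contour
#'
#' Per-vertex differential geometry of the outline: arclength `s1`
#' (anticlockwise, origin at the rearmost, minimum-x vertex), unit outward
#' normal, unit tangent, rotation angle `phi` between the normal and the
#' x axis, and the in-plane curvature `C_s1s1`.
#'
#' The tangent is the normalised central difference along the closed
#' polyline; the normal is the tangent rotated by -pi/2 (outward for
#' anticlockwise contours); the curvature is the turning angle between
#' successive edges divided by the mean adjacent edge length, positive on
#' locally convex sections. The out-of-plane curvature is zero by the
#' flat-z channel assumption, so `C_s1s1` is the only curvature component
#' carried around.
#'
#' @param contour an [contour()] object
#' @return object of class `nt_frames`: a data frame with columns
#'   `s1`, `x`, `y`, `nx`, `ny`, `tx`, `ty`, `phi`, `curvature`, `ds`
#'   (the arclength weight of each vertex), plus attributes `perimeter`
#'   and `rear_index`. Rows are in contour-vertex order; `s1` increases
#'   anticlockwise from the rearmost vertex.
#' @export
contour_frames <- function(contour) {
  pts <- as_points(contour)
  n <- nrow(pts)
  if (n < 8) stopf("frames need at least 8 points")
  e <- row_shift(pts, 1) - pts            # edge k: vertex k -> k+1
  len <- sqrt(rowSums(e * e))
  if (any(len == 0)) stopf("contour has duplicate consecutive points")
  e_prev <- row_shift(e, -1)              # edge into vertex k
  len_prev <- vec_shift(len, -1)
  tng <- row_shift(pts, 1) - row_shift(pts, -1)
  tlen <- sqrt(rowSums(tng * tng))
  if (any(tlen == 0)) stopf("degenerate tangent (coincident neighbours)")
  tng <- tng / tlen
  nrm <- cbind(tng[, 2], -tng[, 1])       # tangent rotated -pi/2: outward
  phi <- atan2(nrm[, 2], nrm[, 1])
  # turning angle at vertex k between incoming and outgoing edges
  dphi <- atan2(e_prev[, 1] * e[, 2] - e_prev[, 2] * e[, 1],
                e_prev[, 1] * e[, 1] + e_prev[, 2] * e[, 2])
  ds <- (len_prev + len) / 2
  curv <- dphi / ds
  cum <- cumsum(c(0, len))[seq_len(n)]    # arclength of vertex k from vertex 1
  per <- sum(len)
  i0 <- which.min(pts[, 1])
  s1 <- (cum - cum[i0]) %% per
  s1[i0] <- 0
  out <- data.frame(s1 = s1, x = pts[, 1], y = pts[, 2],
                    nx = nrm[, 1], ny = nrm[, 2],
                    tx = tng[, 1], ty = tng[, 2],
                    phi = phi, curvature = curv, ds = ds)
  attr(out, "perimeter") <- per
  attr(out, "rear_index") <- i0
  class(out) <- c("nt_frames", "data.frame")
  out
}

#' Export frames as CSV
#'
#' Columns: `s1_um, x_um, y_um, nx, ny, phi_rad, curvature_per_um`.
#' @param frames an [contour_frames()] object
#' @param path file path
#' @export
write_frames_csv <- function(frames, path) {
  df <- data.frame(s1_um = frames$s1, x_um = frames$x, y_um = frames$y,
                   nx = frames$nx, ny = frames$ny, phi_rad = frames$phi,
                   curvature_per_um = frames$curvature)
  write_csv_det(df, path)
}
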