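# Closed-outline container and its file format.
#
# A contour is the geometric substrate of the whole pipeline: an ordered,
# closed, simple polyline in physical units (micrometres), oriented
# anticlockwise so that the shoelace area is positive and the outward
# normal is the tangent rotated by -pi/2.

#' Closed nucleus outline
#'
#' Construct a contour: an ordered closed boundary polyline in physical
#' units (um). The polygon must be simple (non-self-intersecting, proper
#' crossings), have at least 8 vertices and no two identical consecutive
#' vertices. Orientation is normalised to anticlockwise (positive shoelace
#' area); clockwise input is silently reversed.
#'
#' @param points two-column numeric matrix (or data frame) of x, y vertex
#'   positions in um. The polygon is implicitly closed: the last vertex
#'   connects back to the first (do not repeat the first vertex).
#' @param validate check invariants (simplicity is O(n^2); disable only on
#'   contours produced by trusted internal code).
#' @return an object of class `nt_contour`: the vertex matrix with columns
#'   `x`, `y`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' circ <- contour(cbind(5 * cos(th), 5 * sin(th)))
#' polygon_area(circ)
#' @export
contour <- function(points, validate = TRUE) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2)
    stopf("contour points must be a two-column numeric matrix")
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  rownames(pts) <- NULL
  # drop an explicit closing vertex
  n <- nrow(pts)
  if (n >= 2 && all(pts[1, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  if (!all(is.finite(pts))) stopf("contour coordinates must be finite")
  if (nrow(pts) < 8) stopf("contour needs at least 8 points, got %d", nrow(pts))
  a <- shoelace_area(pts)
  if (abs(a) < .Machine$double.eps * max(abs(pts), 1)^2)
    stopf("degenerate contour: zero area")
  if (a < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  if (validate) {
    d <- pts - row_shift(pts, 1)
    if (any(rowSums(d * d) == 0))
      stopf("contour has identical consecutive points")
    if (!is_simple_polygon(pts))
      stopf("contour is not a simple polygon (self-intersection)")
  }
  structure(pts, class = c("nt_contour", "matrix", "array"))
}

#' @export
print.nt_contour <- function(x, ...) {
  cat(sprintf("<nt_contour> %d points, area %.4g um^2, perimeter %.4g um\n",
              nrow(x), polygon_area(x), contour_perimeter(x)))
  invisible(x)
}

#' Test for the contour class
#' @param x object
#' @export
is_contour <- function(x) inherits(x, "nt_contour")

#' @keywords internal
as_points <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}

#' Signed shoelace area of a vertex matrix (positive = anticlockwise)
#' @keywords internal
shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- vec_shift(x, 1); yn <- vec_shift(y, 1)
  sum(x * yn - xn * y) / 2
}

# Proper-crossing simplicity test. Segments sharing an endpoint (adjacent
# edges, or a vertex visited twice by a crack boundary) are not counted as
# intersections; only transversal crossings and collinear overlaps fail.
#' @keywords internal
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- row_shift(pts, 1)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # edge n is adjacent to edge 1
    if (!length(js)) next
    p <- a[i, ]; r <- b[i, ] - p
    q <- a[js, , drop = FALSE]
    s <- b[js, , drop = FALSE] - q
    qp <- cbind(q[, 1] - p[1], q[, 2] - p[2])
    rxs <- r[1] * s[, 2] - r[2] * s[, 1]
    qpxr <- qp[, 1] * r[2] - qp[, 2] * r[1]
    tol <- 1e-12 * max(abs(pts), 1)^2
    with_int <- abs(rxs) > tol
    if (any(with_int)) {
      t <- (qp[with_int, 1] * s[with_int, 2] - qp[with_int, 2] * s[with_int, 1]) / rxs[with_int]
      u <- qpxr[with_int] / rxs[with_int]
      eps <- 1e-12
      if (any(t > eps & t < 1 - eps & u > eps & u < 1 - eps)) return(FALSE)
    }
    col <- !with_int & abs(qpxr) <= tol
    if (any(col)) {
      # collinear: overlapping projection means a degenerate overlap
      rr <- sum(r * r)
      t0 <- (qp[col, 1] * r[1] + qp[col, 2] * r[2]) / rr
      t1 <- t0 + (s[col, 1] * r[1] + s[col, 2] * r[2]) / rr
      lo <- pmin(t0, t1); hi <- pmax(t0, t1)
      if (any(hi > 1e-9 & lo < 1 - 1e-9)) return(FALSE)
    }
  }
  TRUE
}

#' Contour perimeter
#' @param x contour
#' @return perimeter in um
#' @export
contour_perimeter <- function(x) {
  pts <- as_points(x)
  d <- row_shift(pts, 1) - pts
  sum(sqrt(rowSums(d * d)))
}

#' Read an outline from CSV
#'
#' Expects the two-column format written by [write_contour_csv()]: header
#' `x_um,y_um`, one vertex per line, implicit closure. Orientation is
#' normalised to anticlockwise on read.
#'
#' @param path file path
#' @return an [contour()] object
#' @export
read_contour_csv <- function(path) {
  if (!file.exists(path)) stopf("contour file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stopf("contour file %s is empty", path)
  body <- lines[-1]
  if (length(body) < 8)
    stopf("contour file %s has %d points; at least 8 required", path, length(body))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2)
  if (length(bad))
    stopf("malformed line %d in %s: expected two comma-separated values", bad[1] + 1L, path)
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stopf("malformed line %d in %s: non-numeric coordinate", bad[1] + 1L, path)
  contour(cbind(x, y))
}

#' Write an outline to CSV
#'
#' Full printed precision (17 significant digits) so that a write/read
#' round trip is lossless.
#'
#' @param contour an [contour()] object
#' @param path file path
#' @export
write_contour_csv <- function(contour, path) {
  pts <- as_points(contour)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("x_um,y_um",
               paste(fmt_full(pts[, 1]), fmt_full(pts[, 2]), sep = ",")),
             con, sep = "\n")
  invisible(path)
}

#' Nucleus volume from the mid-plane outline
#'
#' The nucleus fills the channel in z, so the volume is the outline area
#' times the local channel height. With a scalar `height` this is simply
#' area x height. With a [channel_geometry()] the polygon is split at the
#' constriction entrance (x = 0) and exit (x = length) and each region's
#' area is multiplied by that region's height.
#'
#' @param contour outline in um; for the geometry variant, in coordinates
#'   where the constriction occupies `0 <= x <= length`.
#' @param height channel height in um, or a [channel_geometry()] object
#' @return volume in um^3
#' @examples
#' sq <- contour(rect_points(7, 10))
#' estimate_volume(sq, 4.7) # 329
#' @export
estimate_volume <- function(contour, height) {
  pts <- as_points(contour)
  if (inherits(height, "nt_channel_geometry")) {
    g <- height
    mid <- clip_x_band(pts, 0, g$constriction_length)
    left <- clip_x_band(pts, -Inf, 0)
    right <- clip_x_band(pts, g$constriction_length, Inf)
    return(left * g$channel_height + mid * g$constriction_height +
             right * g$channel_height)
  }
  if (!is.numeric(height) || length(height) != 1 || height <= 0)
    stopf("height must be a positive scalar")
  abs(shoelace_area(pts)) * height
}

# Area of the part of polygon `pts` with x in [x0, x1]
# (Sutherland-Hodgman clip against the two vertical half-planes).
#' @keywords internal
clip_x_band <- function(pts, x0, x1) {
  p <- pts
  if (is.finite(x0)) p <- clip_halfplane(p, c(1, 0), x0, keep_ge = TRUE)
  if (is.finite(x1) && nrow(p) > 0) p <- clip_halfplane(p, c(1, 0), x1, keep_ge = FALSE)
  if (nrow(p) < 3) return(0)
  abs(shoelace_area(p))
}

# Clip polygon against a*x+b*y >= c (keep_ge) or <= c.
#' @keywords internal
clip_halfplane <- function(pts, ab, c, keep_ge = TRUE) {
  n <- nrow(pts)
  if (n == 0) return(pts)
  v <- pts[, 1] * ab[1] + pts[, 2] * ab[2] - c
  if (!keep_ge) v <- -v
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- v[i]; vj <- v[j]
    if (vi >= 0) { out_x <- c(out_x, pts[i, 1]); out_y <- c(out_y, pts[i, 2]) }
    if ((vi > 0 && vj < 0) || (vi < 0 && vj > 0)) {
      t <- vi / (vi - vj)
      out_x <- c(out_x, pts[i, 1] + t * (pts[j, 1] - pts[i, 1]))
      out_y <- c(out_y, pts[i, 2] + t * (pts[j, 2] - pts[i, 2]))
    }
  }
  cbind(out_x, out_y)
}

#' Axis-aligned rectangle vertex helper
#'
#' Convenience for examples and tests: vertices of a `w` x `h` rectangle
#' centred at `center`, anticlockwise, `n` points distributed over the
#' perimeter.
#' @param w,h side lengths (um)
#' @param center centre position
#' @param n total number of vertices (>= 8)
#' @export
rect_points <- function(w, h, center = c(0, 0), n = 40) {
  per <- 2 * (w + h)
  n_w <- max(2L, round(n * w / per)); n_h <- max(2L, round(n * h / per))
  xs <- seq(-w / 2, w / 2, length.out = n_w + 1)[-(n_w + 1)]
  ys <- seq(-h / 2, h / 2, length.out = n_h + 1)[-(n_h + 1)]
  xs2 <- seq(w / 2, -w / 2, length.out = n_w + 1)[-(n_w + 1)]
  ys2 <- seq(h / 2, -h / 2, length.out = n_h + 1)[-(n_h + 1)]
  pts <- rbind(cbind(xs, -h / 2),   # bottom, left to right
               cbind(w / 2, ys),    # right, bottom to top
               cbind(xs2, h / 2),   # top, right to left
               cbind(-w / 2, ys2))  # left, top to bottom
  sweep(pts, 2, -center)
}
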