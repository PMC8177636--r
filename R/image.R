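# Outline segmentation from grayscale images.
#
# The segmentation chain mirrors the usual manual workflow: global Otsu
# threshold, keep the largest 8-connected foreground component, fill its
# holes, trace the outer boundary, resample to points spaced one pixel
# apart, convert to micrometres with y increasing upward.
#
# The boundary is traced along pixel *edges* (crack following), so the
# traced polygon of an axis-aligned w x h pixel block has perimeter
# 2(w + h) px and area exactly equal to the pixel count.

#' Grayscale image container
#'
#' @param pixels numeric matrix of non-negative intensities, at least 2x2;
#'   rows are image rows (row 1 at the top, as stored in image files).
#' @param pixel_size physical size of one pixel in um (default 0.215).
#' @return object of class `nt_image`
#' @export
gray_image <- function(pixels, pixel_size = 0.215) {
  px <- as.matrix(pixels)
  if (!is.numeric(px)) stopf("pixels must be numeric")
  storage.mode(px) <- "double"
  if (nrow(px) < 2 || ncol(px) < 2) stopf("image must be at least 2x2")
  if (!all(is.finite(px))) stopf("image intensities must be finite")
  if (any(px < 0)) stopf("image intensities must be non-negative")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be positive")
  structure(list(pixels = px, pixel_size = pixel_size), class = "nt_image")
}

#' @export
print.nt_image <- function(x, ...) {
  cat(sprintf("<nt_image> %d x %d px, %.3g um/px, intensity range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Otsu intensity threshold
#'
#' Splits the intensity histogram into background and foreground so as to
#' minimise the intra-class variance (equivalently, maximise the
#' between-class variance). Images with more than `max_bins` distinct
#' intensities are binned; otherwise every distinct value is a candidate
#' split. Ties are broken to the lowest threshold attaining the maximum,
#' so the result is deterministic. The returned threshold lies strictly
#' between the two classes: foreground is `pixels > threshold`.
#'
#' @param image an [gray_image()] object or numeric matrix/vector
#' @param max_bins histogram resolution for continuous images (default 256)
#' @return scalar threshold
#' @export
otsu_threshold <- function(image, max_bins = 256) {
  v <- if (inherits(image, "nt_image")) as.vector(image$pixels) else as.vector(image)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2)
    stopf("degenerate image: needs at least 2 distinct intensity values")
  u <- sort(unique(v))
  if (length(u) > max_bins) {
    br <- seq(min(v), max(v), length.out = max_bins + 1)
    idx <- findInterval(v, br, rightmost.closed = TRUE)
    centers <- (br[-1] + br[-length(br)]) / 2
    cnt <- tabulate(idx, nbins = max_bins)
    keep <- cnt > 0
    u <- centers[keep]; cnt <- cnt[keep]
  } else {
    cnt <- tabulate(match(v, u), nbins = length(u))
  }
  m <- length(u)
  w <- cumsum(cnt)                       # class-1 mass for split after bin i
  mu <- cumsum(cnt * u)
  tot <- w[m]; mutot <- mu[m]
  i <- seq_len(m - 1)
  w1 <- w[i]; w2 <- tot - w1
  m1 <- mu[i] / w1; m2 <- (mutot - mu[i]) / w2
  sb <- w1 * w2 * (m1 - m2)^2            # between-class variance (x tot^2)
  best <- which.max(sb)                  # which.max returns first (lowest) maximiser
  (u[best] + u[best + 1]) / 2
}

#' Extract the nucleus outline from an image
#'
#' Binarises at `threshold` (foreground strictly above), keeps the largest
#' 8-connected component, fills interior holes, traces the outer boundary
#' along pixel edges, resamples to points spaced one pixel apart and
#' converts to um with the y axis flipped so y increases upward. An
#' optional periodic smoothing (truncation to `smooth_harmonics` Fourier
#' harmonics) can be applied before resampling; by default the traced
#' outline is only resampled, never smoothed.
#'
#' @param image an [gray_image()] object
#' @param threshold intensity threshold, default [otsu_threshold()]
#' @param smooth_harmonics number of Fourier harmonics to keep, or `NULL`
#'   (default) for no smoothing
#' @return an [contour()] object in um
#' @export
extract_contour <- function(image, threshold = otsu_threshold(image),
                            smooth_harmonics = NULL) {
  if (!inherits(image, "nt_image")) stopf("image must be an nt_image")
  mask <- image$pixels > threshold
  if (!any(mask)) stopf("no object: thresholded mask is empty")
  mask <- largest_component(mask)
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    warnf("foreground component touches the image border; outline may be clipped")
  mask <- fill_holes(mask)
  path <- trace_crack_boundary(mask)     # corner coords, px units, y up
  if (!is.null(smooth_harmonics))
    path <- fourier_smooth(path, smooth_harmonics)
  path <- resample_closed(path, spacing = 1)
  contour(path * image$pixel_size)
}

# Largest 8-connected foreground component (iterative BFS flood fill).
#' @keywords internal
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  sizes <- integer(0)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- integer(256); queue[1] <- start; qn <- 1L
    lab[start] <- cur
    size <- 0L
    while (qn > 0L) {
      p <- queue[qn]; qn <- qn - 1L
      size <- size + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (k in 1:8) {
        rr <- r + off_r[k]; c2 <- cc + off_c[k]
        if (rr >= 1L && rr <= nr && c2 >= 1L && c2 <= nc) {
          q <- (c2 - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            qn <- qn + 1L
            if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[qn] <- q
          }
        }
      }
    }
    sizes[cur] <- size
  }
  lab == which.max(sizes)
}

# Fill holes: background connected (4-conn) to the border stays background,
# any other non-foreground pixel is an interior hole.
#' @keywords internal
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  seeds <- c(which(!mask[, 1]) , (nc - 1L) * nr + which(!mask[, nc]),
             (which(!mask[1, ]) - 1L) * nr + 1L,
             (which(!mask[nr, ]) - 1L) * nr + nr)
  seeds <- unique(seeds)
  queue <- seeds; outside[seeds] <- TRUE
  off <- c(-1L, 1L, -nr, nr)
  while (length(queue)) {
    p <- queue[length(queue)]; queue <- queue[-length(queue)]
    r <- ((p - 1L) %% nr) + 1L
    for (k in 1:4) {
      q <- p + off[k]
      if (k == 1L && r == 1L) next
      if (k == 2L && r == nr) next
      if (q >= 1L && q <= nr * nc && !mask[q] && !outside[q]) {
        outside[q] <- TRUE
        queue <- c(queue, q)
      }
    }
  }
  mask | (!outside)
}

# Trace the outer boundary of the foreground along pixel edges ("cracks").
# Returns corner coordinates in pixel units with 0-based pixel centres and
# y flipped upward: pixel (r, c) has centre (c - 1, nrow - r), so corners
# sit at half-integer positions. The walk keeps foreground on one fixed
# side and stops on re-entering the start corner with the start direction
# (Jacob's criterion adapted to crack following).
#' @keywords internal
trace_crack_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  occ <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  # start at the topmost-then-leftmost foreground pixel, top-left corner,
  # moving along its top edge (foreground below, background above)
  rc <- which(mask, arr.ind = TRUE)
  r0 <- min(rc[, 1]); c0 <- min(rc[rc[, 1] == r0, 2])
  # corner grid: corner (i, j), i in 0..nr, j in 0..nc; crack moves R/D/L/U
  # direction codes: 1 = R (+j), 2 = D (+i), 3 = L (-j), 4 = U (-i)
  di <- c(0L, 1L, 0L, -1L); dj <- c(1L, 0L, -1L, 0L)
  # pixels (1-based) adjacent to the crack leaving corner (i, j) in dir d:
  # fg must sit on the rotated (+90 deg in image coords) side
  crack_ok <- function(i, j, d) {
    if (d == 1L) { fg <- occ(i + 1L, j + 1L); bg <- occ(i, j + 1L) }
    else if (d == 2L) { fg <- occ(i + 1L, j); bg <- occ(i + 1L, j + 1L) }
    else if (d == 3L) { fg <- occ(i, j); bg <- occ(i + 1L, j) }
    else { fg <- occ(i, j + 1L); bg <- occ(i, j) }
    fg && !bg
  }
  i <- r0 - 1L; j <- c0 - 1L; d <- 1L
  stopifnot(crack_ok(i, j, d))
  i_start <- i; j_start <- j; d_start <- d
  path_i <- integer(512); path_j <- integer(512); np <- 0L
  repeat {
    np <- np + 1L
    if (np > length(path_i)) {
      path_i <- c(path_i, integer(length(path_i)))
      path_j <- c(path_j, integer(length(path_j)))
    }
    path_i[np] <- i; path_j[np] <- j
    i <- i + di[d]; j <- j + dj[d]
    # choose next direction: prefer turning towards the foreground side
    # (right turn in image coords), then straight, then away
    cand <- c((d %% 4L) + 1L, d, ((d + 2L) %% 4L) + 1L)
    d_next <- 0L
    for (dn in cand) if (crack_ok(i, j, dn)) { d_next <- dn; break }
    if (d_next == 0L) stopf("boundary tracing failed at corner (%d, %d)", i, j)
    d <- d_next
    if (i == i_start && j == j_start && d == d_start) break
    if (np > 4L * (nr + 2L) * (nc + 2L)) stopf("boundary tracing did not close")
  }
  ii <- path_i[seq_len(np)]; jj <- path_j[seq_len(np)]
  cbind(x = jj - 0.5, y = (nr - ii) - 0.5)
}

# Resample a closed polyline to (near-)uniform spacing along arclength.
#' @keywords internal
resample_closed <- function(pts, spacing = 1, n_out = NULL) {
  # drop only *consecutive* duplicates (a crack path may legitimately
  # revisit a corner at a diagonal pinch)
  prev <- row_shift(pts, -1)
  keep1 <- rowSums((pts - prev)^2) > 0
  keep1[1] <- TRUE
  pts <- pts[keep1, , drop = FALSE]
  closed <- rbind(pts, pts[1, ])
  seg <- diff(closed)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  closed <- closed[c(TRUE, keep), , drop = FALSE]
  seg <- diff(closed); len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  n <- n_out %||% max(8L, round(total / spacing))
  s <- total * (seq_len(n) - 1) / n
  xi <- stats::approx(cum, closed[, 1], xout = s)$y
  yi <- stats::approx(cum, closed[, 2], xout = s)$y
  cbind(x = xi, y = yi)
}

# Periodic smoothing by truncating the Fourier series of x(t) + i y(t).
#' @keywords internal
fourier_smooth <- function(pts, harmonics) {
  n <- nrow(pts)
  z <- stats::fft(complex(real = pts[, 1], imaginary = pts[, 2]))
  keep <- rep(FALSE, n)
  idx <- c(1L, 1L + seq_len(min(harmonics, floor((n - 1) / 2))))
  keep[idx] <- TRUE
  keep[n + 2L - idx[-1]] <- TRUE
  z[!keep] <- 0
  z <- stats::fft(z, inverse = TRUE) / n
  cbind(x = Re(z), y = Im(z))
}
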