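# Ensemble averaging of outlines and translation removal.
#
# Outlines of many nuclei at the same migration stage are averaged by
# radial spokes about each outline's centroid; initial/target pairs are
# registered along the channel axis by a convex combination of the
# rear-anchored and front-anchored registrations, weighted so that the
# end that moved less anchors the fit.

#' Average outlines by radial spokes
#'
#' Each contour is centred at its own centroid; `n` spokes are cast at
#' equal angles and the spoke-intersection *coordinates* are averaged
#' arithmetically across contours. Averaging coordinates (not radii)
#' keeps the mean well defined independently of the common-centroid step.
#'
#' @param contours list of [contour()] objects, each star-shaped about its
#'   own centroid
#' @param n number of spokes; default the average vertex count of the
#'   inputs (rounded), at least 8
#' @return the average [contour()]
#' @export
average_contours <- function(contours, n = NULL) {
  if (!length(contours)) stopf("no contours to average")
  if (!all(vapply(contours, is_contour, TRUE)))
    stopf("average_contours expects a list of contours")
  n <- n %||% max(8L, round(mean(vapply(contours, nrow, 1L))))
  if (n < 8) stopf("averaging needs n >= 8 spokes")
  acc <- matrix(0, n, 2)
  for (i in seq_along(contours)) {
    ct <- contours[[i]]
    cen <- polygon_centroid(ct)
    pts <- sweep(as_points(ct), 2, cen)
    r <- tryCatch(spoke_radii(pts, n, c(0, 0)), error = function(e)
      stopf("contour %d is not star-shaped about its centroid: %s",
            i, conditionMessage(e)))
    th <- spoke_angles(n)
    acc <- acc + cbind(r * cos(th), r * sin(th))
  }
  contour(acc / length(contours), validate = FALSE)
}

# Registration shift from rear and front displacements (raw frames).
# The convex weight w = |dr| / (|dr| + |df|) places the registration
# nearer the end that moved less. Isolated here so an alternative
# proportionality rule is a one-line swap.
#' @keywords internal
alignment_shift <- function(dr, df) {
  denom <- abs(dr) + abs(df)
  if (denom == 0) return(0)
  w <- abs(dr) / denom
  w * df + (1 - w) * dr
}

#' Align a deformation pair along the channel axis
#'
#' Removes rigid translation between two outlines of the same nucleus.
#' The initial outline is centred at its centroid (the origin). The rear
#' (minimum-x) and front (maximum-x) displacements `dr`, `df` between the
#' raw frames give the x registration shift
#' `s = w * df + (1 - w) * dr`, `w = |dr| / (|dr| + |df|)`,
#' so a pure translation (`dr = df`) is removed exactly and a symmetric
#' dilation (`dr = -df`) reduces to centroid alignment. The aligned target
#' is the raw target shifted by `-s` in x relative to the initial centroid
#' frame; in y the target is centred at its own centroid (motion is along
#' the channel). If rear and front are both unchanged the pair is centroid
#' aligned with shift 0.
#'
#' @param initial,target [contour()] objects in a common raw frame,
#'   motion along +x
#' @param check if `TRUE`, verify that the weighted registration does not
#'   increase the mean boundary displacement relative to pure centroid
#'   alignment (logged via `message()`, never fatal)
#' @return list with elements `initial` (centred), `target` (aligned),
#'   `shift` (the applied x registration `s`, um) and
#'   `offset_from_centroid` (x offset of the aligned target relative to
#'   plain centroid alignment, um)
#' @export
align_pair <- function(initial, target, check = TRUE) {
  ci <- polygon_centroid(initial)
  ct <- polygon_centroid(target)
  ip <- as_points(initial); tp <- as_points(target)
  dr <- min(tp[, 1]) - min(ip[, 1])
  df <- max(tp[, 1]) - max(ip[, 1])
  scale <- max(abs(ip), abs(tp), 1)
  init_c <- contour(sweep(ip, 2, ci), validate = FALSE)
  if (abs(dr) + abs(df) < 1e-12 * scale) {
    targ_a <- contour(sweep(tp, 2, ct), validate = FALSE)
    return(list(initial = init_c, target = targ_a, shift = 0,
                offset_from_centroid = 0))
  }
  s <- unname(alignment_shift(dr, df))
  dc <- unname(ct[1] - ci[1])
  targ_a <- contour(cbind(tp[, 1] - ci[1] - s, tp[, 2] - ct[2]),
                    validate = FALSE)
  if (check) {
    resid <- function(tg) {
      nn <- min(64L, nrow(ip), nrow(tp))
      u <- tryCatch({
        bi <- spoke_radii(as_points(init_c), nn, c(0, 0))
        bt <- spoke_radii(as_points(tg), nn, c(0, 0))
        th <- spoke_angles(nn)
        cbind((bt - bi) * cos(th), (bt - bi) * sin(th))
      }, error = function(e) NULL)
      if (is.null(u)) NA_real_ else mean(sqrt(rowSums(u^2)))
    }
    m_w <- resid(targ_a)
    targ_c <- contour(sweep(tp, 2, ct), validate = FALSE)
    m_c <- resid(targ_c)
    if (is.finite(m_w) && is.finite(m_c) && m_w > m_c + 1e-12)
      message(sprintf(
        "align_pair: weighted registration gives mean |u| = %.4g um vs %.4g um for centroid alignment (rear/front bracketing configuration)",
        m_w, m_c))
  }
  list(initial = init_c, target = targ_a, shift = s,
       offset_from_centroid = dc - s)
}
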