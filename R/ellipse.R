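#' Moment-based ellipse fit of a filled pixel region
#'
#' The animal body is represented by the equivalent ellipse of its filled
#' component: the ellipse with the same centroid and second-order central
#' moments as the pixel set. For a solid ellipse of semi-axes (A, B) the
#' second moments along its axes are A^2/4 and B^2/4, so the semi-axes are
#' recovered as twice the square roots of the moment eigenvalues. The
#' orientation is the major-axis direction in image coordinates (x right,
#' y down), normalized to [0, 180) degrees; `a >= b` is enforced.
#'
#' @param pixel_coords Two-column matrix of 0-based (x, y) pixel
#'   coordinates of the filled region.
#' @return List with `xc`, `yc`, `a`, `b`, `theta_deg`, `size`.
#' @examples
#' px <- ellipse_pixels(50, 40, 10, 4, 30)
#' fit_ellipse(px)
#' @export
fit_ellipse <- function(pixel_coords) {
  pixel_coords <- as.matrix(pixel_coords)
  n <- nrow(pixel_coords)
  if (n < 5) stop_degenerate("ellipse fit needs at least 5 pixels, got ", n)
  x <- pixel_coords[, 1]; y <- pixel_coords[, 2]
  xc <- mean(x); yc <- mean(y)
  dx <- x - xc; dy <- y - yc
  mxx <- mean(dx * dx); myy <- mean(dy * dy); mxy <- mean(dx * dy)
  tr <- mxx + myy
  det2 <- mxx * myy - mxy * mxy
  disc <- sqrt(max((mxx - myy)^2 / 4 + mxy^2, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l2 <= 1e-9 || det2 <= 1e-12) {
    stop_degenerate("pixel set is collinear or too thin for an ellipse fit")
  }
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  list(xc = xc, yc = yc, a = 2 * sqrt(l1), b = 2 * sqrt(l2),
       theta_deg = theta %% 180, size = n)
}

#' Pixels of a filled ellipse
#'
#' Hard (non-anti-aliased) rasterization: a pixel belongs to the ellipse
#' when its centre satisfies the ellipse inequality. Used by the renderer
#' and by the merge-cost evaluation.
#'
#' @param xc,yc Centre, 0-based pixel coordinates.
#' @param a,b Semi-major and semi-minor axes in pixels.
#' @param theta_deg Major-axis orientation, degrees, image convention.
#' @param height,width Optional image bounds for clipping; unbounded if
#'   `NULL`.
#' @return Two-column matrix of (x, y) coordinates.
#' @export
ellipse_pixels <- function(xc, yc, a, b, theta_deg,
                           height = NULL, width = NULL) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ex <- sqrt((a * ct)^2 + (b * st)^2)
  ey <- sqrt((a * st)^2 + (b * ct)^2)
  x0 <- floor(xc - ex); x1 <- ceiling(xc + ex)
  y0 <- floor(yc - ey); y1 <- ceiling(yc + ey)
  if (!is.null(width)) { x0 <- max(x0, 0); x1 <- min(x1, width - 1) }
  if (!is.null(height)) { y0 <- max(y0, 0); y1 <- min(y1, height - 1) }
  if (x1 < x0 || y1 < y0) return(cbind(x = integer(), y = integer()))
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, times = x1 - x0 + 1)
  dx <- gx - xc; dy <- gy - yc
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  inside <- u * u + v * v <= 1
  cbind(x = gx[inside], y = gy[inside])
}

# membership test of points in an ellipse (vectorized)
inside_ellipse <- function(x, y, xc, yc, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  dx <- x - xc; dy <- y - yc
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  u * u + v * v <= 1
}

# axial angular distance between two orientations defined modulo 180 deg
axial_diff <- function(t1, t2) {
  d <- abs(t1 - t2) %% 180
  pmin(d, 180 - d)
}
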