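#' Terminal points of a tracked ellipse
#'
#' Each animal is reduced to three points: the ellipse centre CE and the
#' two terminal points at the ends of the major axis,
#' `TP1 = CE + a (cos t, sin t)` and `TP2 = CE - a (cos t, sin t)`.
#' The fitted orientation is only defined modulo 180 degrees, which would
#' let TP1 and TP2 swap arbitrarily between frames; `theta` is therefore
#' the continuity-resolved body direction (see [continuous_direction()]),
#' which keeps each terminal point attached to the same end of the body.
#'
#' @param xc,yc Ellipse centre.
#' @param a Semi-major axis.
#' @param theta_deg Body direction in degrees (continuity-resolved; any
#'   real value, not reduced modulo 180).
#' @return `data.frame` with columns `tx1`, `ty1`, `tx2`, `ty2`
#'   (vectorized over the inputs).
#' @export
terminal_points <- function(xc, yc, a, theta_deg) {
  stopifnot(all(a > 0))
  th <- theta_deg * pi / 180
  data.frame(tx1 = xc + a * cos(th), ty1 = yc + a * sin(th),
             tx2 = xc - a * cos(th), ty2 = yc - a * sin(th))
}

#' Temporally continuous body direction
#'
#' Lifts a sequence of axial orientations (degrees, defined modulo 180)
#' to a continuous direction series: each step takes the representative of
#' the new orientation closest to the previous direction, so the change
#' per frame always lies in (-90, 90]. The first frame keeps its raw
#' value. The result is unbounded (it accumulates full turns), which is
#' exactly what the angular-range computation of the inspection classifier
#' needs.
#'
#' @param theta_deg Numeric vector of orientations in degrees.
#' @return Numeric vector, same length.
#' @export
continuous_direction <- function(theta_deg) {
  n <- length(theta_deg)
  if (n <= 1) return(theta_deg)
  d <- diff(theta_deg)
  d <- ((d + 90) %% 180) - 90
  theta_deg[1] + cumsum(c(0, d))
}

#' Keep terminal-point labels consistent between frames
#'
#' Of the two possible labellings of the current frame's terminal points,
#' keep the one minimizing `|TP1_t - TP1_(t-1)| + |TP2_t - TP2_(t-1)|`.
#' Equivalent to lifting the orientation with [continuous_direction()];
#' exposed separately for use on pre-computed triplets.
#'
#' @param current,previous Lists (or one-row data.frames) with `tx1`,
#'   `ty1`, `tx2`, `ty2`.
#' @return `current`, possibly with TP1/TP2 swapped.
#' @export
resolve_tp_identity <- function(current, previous) {
  keep <- sqrt((current$tx1 - previous$tx1)^2 + (current$ty1 - previous$ty1)^2) +
    sqrt((current$tx2 - previous$tx2)^2 + (current$ty2 - previous$ty2)^2)
  swap <- sqrt((current$tx2 - previous$tx1)^2 + (current$ty2 - previous$ty1)^2) +
    sqrt((current$tx1 - previous$tx2)^2 + (current$ty1 - previous$ty2)^2)
  if (swap < keep) {
    current[c("tx1", "ty1", "tx2", "ty2")] <-
      current[c("tx2", "ty2", "tx1", "ty1")]
  }
  current
}

#' Extract dwell nodes from a time-ordered path
#'
#' Streaming single-pass clustering of a trajectory into *nodes*: a
#' running node accepts the next point while it lies within `dis_th`
#' pixels of the current node centre (the mean of all members, updated on
#' every insertion). A point beyond the radius finalizes the node if it
#' has accumulated more than `mn_th` members, otherwise the accumulated
#' points are discarded; either way a fresh node starts from the current
#' point. The trailing node at the end of the path is finalized under the
#' same membership test. Because membership is evaluated at insertion
#' time against the running centre, the procedure is order-dependent by
#' design; node members are always temporally consecutive.
#'
#' @param x,y Numeric coordinate vectors of the path, one entry per frame.
#' @param frames Optional frame indices (default `0:(n-1)`).
#' @param dis_th Node radius in pixels.
#' @param mn_th Minimum member count.
#' @param strict If `TRUE`, a node needs strictly more than `mn_th`
#'   members; if `FALSE`, `mn_th` members suffice.
#' @return `data.frame` with one row per node: `node_index`, `x`, `y`
#'   (final centre), `first_frame`, `last_frame`, `mn` (member count),
#'   `first_index`, `last_index` (1-based positions in the input series).
#' @export
extract_nodes <- function(x, y, frames = NULL, dis_th = 1.7, mn_th = 14,
                          strict = TRUE) {
  stopifnot(dis_th > 0, mn_th >= 1, length(x) == length(y))
  n <- length(x)
  empty <- data.frame(node_index = integer(), x = numeric(), y = numeric(),
                      first_frame = integer(), last_frame = integer(),
                      mn = integer(), first_index = integer(),
                      last_index = integer())
  if (n == 0) return(empty)
  if (is.null(frames)) frames <- 0:(n - 1)
  pass_mn <- if (strict) function(m) m > mn_th else function(m) m >= mn_th

  nodes <- list()
  cx <- x[1]; cy <- y[1]
  first <- 1L; mn <- 1L
  for (i in seq_len(n)[-1]) {
    dis <- sqrt((x[i] - cx)^2 + (y[i] - cy)^2)
    if (dis < dis_th) {
      # join: running centre becomes the member mean
      cx <- (cx * mn + x[i]) / (mn + 1)
      cy <- (cy * mn + y[i]) / (mn + 1)
      mn <- mn + 1L
    } else if (pass_mn(mn)) {
      nodes[[length(nodes) + 1L]] <-
        list(x = cx, y = cy, first = first, last = i - 1L, mn = mn)
      cx <- x[i]; cy <- y[i]; first <- i; mn <- 1L
    } else {
      cx <- x[i]; cy <- y[i]; first <- i; mn <- 1L
    }
  }
  if (pass_mn(mn)) {
    nodes[[length(nodes) + 1L]] <-
      list(x = cx, y = cy, first = first, last = n, mn = mn)
  }
  if (length(nodes) == 0) return(empty)
  data.frame(
    node_index = seq_along(nodes),
    x = vapply(nodes, `[[`, numeric(1), "x"),
    y = vapply(nodes, `[[`, numeric(1), "y"),
    first_frame = frames[vapply(nodes, `[[`, integer(1), "first")],
    last_frame = frames[vapply(nodes, `[[`, integer(1), "last")],
    mn = vapply(nodes, `[[`, integer(1), "mn"),
    first_index = vapply(nodes, `[[`, integer(1), "first"),
    last_index = vapply(nodes, `[[`, integer(1), "last")
  )
}

#' Three-point reduction of one animal's track
#'
#' Computes the continuity-resolved direction and the centre/terminal
#' paths for one animal's rows of a track table.
#'
#' @param track One animal's rows of [track_sequence()] output, in frame
#'   order.
#' @return `data.frame` with `frame`, `xc`, `yc`, `tx1`, `ty1`, `tx2`,
#'   `ty2`, `theta` (continuous degrees).
#' @export
point_triplets <- function(track) {
  stopifnot(!is.unsorted(track$frame))
  theta <- continuous_direction(track$theta_deg)
  tp <- terminal_points(track$xc, track$yc, track$a, theta)
  data.frame(frame = track$frame, xc = track$xc, yc = track$yc,
             tp, theta = theta)
}
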