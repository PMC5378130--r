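#' Label 8-connected foreground components
#'
#' Breadth-first flood fill over the foreground pixels only, so the cost is
#' proportional to the number of foreground pixels, not the image area.
#' 8-connectivity is used so that thin diagonal outlines of an animal do
#' not fragment into several components. Labels are assigned in raster
#' (column-major) order of each component's first pixel, starting at 1;
#' background pixels are 0.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @return Integer matrix of the same shape with component labels.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  # 8-neighbour offsets in (dr, dc)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  k <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    k <- k + 1L
    lab[seed] <- k
    frontier <- seed
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      cc <- ((frontier - 1L) %/% h) + 1L
      nr <- rep(r, each = 8L) + dr
      nc <- rep(cc, each = 8L) + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      nidx <- unique(nidx[mask[nidx] & lab[nidx] == 0L])
      lab[nidx] <- k
      frontier <- nidx
    }
  }
  lab
}

#' Centroid of a pixel set
#'
#' The centre point CE of a segment is the arithmetic mean of its pixel
#' coordinates; it is real-valued and never rounded.
#'
#' @param pixel_coords Two-column matrix of (x, y) pixel coordinates.
#' @return Numeric `c(x, y)`.
#' @export
compute_centroid <- function(pixel_coords) {
  pixel_coords <- as.matrix(pixel_coords)
  if (nrow(pixel_coords) == 0) stop_invalid("empty pixel set has no centroid")
  c(x = mean(pixel_coords[, 1]), y = mean(pixel_coords[, 2]))
}

#' Segment one frame against a background model
#'
#' Foreground pixels are those where `background - frame` exceeds
#' `bin_threshold` (animals are dark on a bright ground). The binary image
#' is labelled with 8-connectivity and components smaller than `min_area`
#' pixels are discarded. Each surviving segment carries its label, pixel
#' set, size and centroid.
#'
#' @param frame Grayscale matrix.
#' @param bg A `background_model` or a plain background matrix.
#' @param bin_threshold Foreground threshold on the intensity difference.
#' @param min_area Minimum component size in pixels.
#' @return List of segments; each is a list with `label`, `idx` (1-based
#'   column-major linear pixel indices), `coords` (0-based (x, y) matrix),
#'   `size` and `centroid`. The list carries the label matrix as attribute
#'   `"labels"`.
#' @export
segment_frame <- function(frame, bg, bin_threshold = 70, min_area = 5) {
  bgpix <- if (inherits(bg, "background_model")) bg$pixels else bg
  if (!identical(dim(frame), dim(bgpix))) {
    stop_invalid("frame and background shapes differ")
  }
  mask <- (bgpix - frame) > bin_threshold
  lab <- label_components(mask)
  segs <- segments_from_labels(lab, min_area)
  attr(segs, "labels") <- lab
  segs
}

# build segment records from a label matrix, dropping small components and
# renumbering survivors 1..K in order of first pixel
segments_from_labels <- function(lab, min_area) {
  h <- nrow(lab)
  fg <- which(lab != 0L)
  if (length(fg) == 0) return(list())
  groups <- split(fg, lab[fg])
  groups <- groups[order(as.integer(names(groups)))]
  groups <- groups[lengths(groups) >= min_area]
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    coords <- idx_to_xy(idx, h)
    out[[i]] <- list(label = i, idx = idx, coords = coords,
                     size = length(idx), centroid = compute_centroid(coords))
  }
  out
}

#' Tabulate segments of one frame
#'
#' @param segments Output of [segment_frame()].
#' @param frame Frame index stored in the table (0-based).
#' @return `data.frame` with columns frame, label, size, xc, yc.
#' @export
segment_table <- function(segments, frame = 0L) {
  if (length(segments) == 0) {
    return(data.frame(frame = integer(), label = integer(), size = integer(),
                      xc = numeric(), yc = numeric()))
  }
  data.frame(
    frame = frame,
    label = vapply(segments, `[[`, integer(1), "label"),
    size = vapply(segments, `[[`, integer(1), "size"),
    xc = vapply(segments, function(s) s$centroid[["x"]], numeric(1)),
    yc = vapply(segments, function(s) s$centroid[["y"]], numeric(1))
  )
}
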