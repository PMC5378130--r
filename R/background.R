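#' Build a static background model from an image sequence
#'
#' The animals are darker than the substratum, so the background can be
#' recovered by iterative brightening: start from the first frame, and on
#' every pass copy into the model any pixel of a later frame that is
#' brighter than the model by more than `diff_threshold`. Pixels once
#' covered by an animal are replaced as soon as the animal moves away, and
#' the procedure reaches a fixed point when a full pass over the sequence
#' changes no pixel.
#'
#' On any sequence in which every pixel is animal-free in at least one
#' frame and the animal/background contrast exceeds `diff_threshold`, the
#' fixed point equals the true background exactly.
#'
#' @param frames List of grayscale matrices (see [read_frames()]).
#' @param diff_threshold Intensity difference required to overwrite a
#'   model pixel.
#' @param max_passes Safety bound on the number of passes; if reached the
#'   model is returned with `converged = FALSE`.
#' @return A list of class `background_model` with elements `pixels`
#'   (matrix), `diff_threshold`, `converged` and `passes`.
#' @examples
#' f <- matrix(200, 20, 20)
#' g <- f; g[5:8, 5:8] <- 50   # dark blob, later absent
#' bg <- build_background(list(g, f))
#' bg$converged
#' @export
build_background <- function(frames, diff_threshold = 30, max_passes = 50) {
  check_frames(frames)
  if (length(frames) < 2) stop_invalid("need at least 2 frames")
  bg <- frames[[1]]
  passes <- 0L
  converged <- FALSE
  while (passes < max_passes) {
    passes <- passes + 1L
    changed <- FALSE
    for (t in 2:length(frames)) {
      brighter <- frames[[t]] - bg > diff_threshold
      if (any(brighter)) {
        bg[brighter] <- frames[[t]][brighter]
        changed <- TRUE
      }
    }
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  structure(list(pixels = bg, diff_threshold = diff_threshold,
                 converged = converged, passes = passes),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("background model %dx%d px, diff_threshold=%g, %s after %d pass(es)\n",
              d[2], d[1], x$diff_threshold,
              if (x$converged) "converged" else "NOT converged", x$passes))
  invisible(x)
}
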