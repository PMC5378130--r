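#' Reference validation script and fixtures
#'
#' `reference_script()` builds the scripted behaviour sequence used
#' throughout the package's validation: swimming, wide search, swimming,
#' close search, swimming, inspection. The inspection phase lasts 25 s by
#' default -- deliberately longer than the 20 s close-search member cap,
#' matching the observation that genuine inspection bouts run to minutes
#' -- so that it is not absorbed into a close-search chain.
#'
#' @param swim_s,wide_s,close_s,inspect_s Phase durations in seconds.
#' @return A [behaviour_script()].
#' @export
reference_script <- function(swim_s = 3, wide_s = 5, close_s = 6,
                             inspect_s = 25) {
  behaviour_script(
    script_phase("swimming", swim_s),
    script_phase("wide_search", wide_s),
    script_phase("swimming", swim_s),
    script_phase("close_search", close_s),
    script_phase("swimming", swim_s),
    script_phase("inspection", inspect_s)
  )
}

#' Standard desk-scale validation arena
#'
#' A 160 x 120 px arena with 7 x 3 px animals at 33 fps: a scaled-down
#' stand-in for the full acquisition geometry that preserves the
#' body-size-to-step ratios the classifier depends on.
#'
#' @param ... Overrides passed to [arena_spec()].
#' @export
reference_arena <- function(...) {
  args <- utils::modifyList(list(width = 160, height = 120, a = 7, b = 3,
                                 noise_sd = 2), list(...))
  do.call(arena_spec, args)
}

#' Render one randomized two-animal crossing event
#'
#' Two animals swim ballistically along straight headings that intersect
#' at an angle drawn from 30-150 degrees, with independently drawn
#' approach distances and speeds, so the fused-blob interval varies from
#' brief touches to deep pass-throughs.
#'
#' @param seed Integer seed (fixes geometry and rendering noise).
#' @param arena An [arena_spec()]; default 200 x 200 px.
#' @return [simulate_sequence()] output.
#' @export
crossing_sequence <- function(seed,
                              arena = arena_spec(width = 200, height = 200,
                                                 a = 7, b = 3, noise_sd = 2)) {
  geom <- with_seed(seed, function() {
    list(angle = stats::runif(1, 30, 150),
         d = stats::runif(2, 24, 36),
         speed = stats::runif(2, 1.8, 2.4),
         a1 = stats::runif(1, 0, 360))
  })
  ctr <- c(arena$width, arena$height) / 2
  headings <- c(geom$a1, geom$a1 + geom$angle)
  starts <- lapply(1:2, function(i) {
    ctr - geom$d[i] * dir_vec(headings[i])
  })
  scripts <- lapply(1:2, function(i) {
    behaviour_script(script_phase("swimming", 1.0, speed = geom$speed[i],
                                  heading_sd = 0))
  })
  simulate_sequence(scripts, arena, seed = seed, starts = starts,
                    headings = as.list(headings))
}

#' Did a crossing event preserve both identities?
#'
#' Maps every tracked identity to its nearest ground-truth animal at the
#' identity's first and last frame; the event counts as swapped when any
#' identity changes its ground-truth partner, or when the tracker did not
#' maintain exactly two identities.
#'
#' @param truth Ground-truth table from [simulate_sequence()].
#' @param track Track table from [track_sequence()].
#' @return `TRUE` if identities were lost or exchanged.
#' @export
identity_swapped <- function(truth, track) {
  ids <- sort(unique(track$cyprid_id))
  if (length(ids) != length(unique(truth$cyprid_id))) return(TRUE)
  for (id in ids) {
    s <- track[track$cyprid_id == id, ]
    for (end in c(1, nrow(s))) {
      t <- truth[truth$frame == s$frame[end], ]
      m <- t$cyprid_id[which.min((t$x - s$xc[end])^2 + (t$y - s$yc[end])^2)]
      if (end == 1) m0 <- m else if (m != m0) return(TRUE)
    }
  }
  FALSE
}

#' Frame-level and sequence-level behaviour recovery
#'
#' Compares the classified behaviour of the longest track against the
#' scripted ground truth of a single-animal run. Frames the tracker did
#' not cover count as misclassified.
#'
#' @param truth Ground-truth table (single animal).
#' @param track Track table.
#' @param classification [classify_track()] result for `track`.
#' @return List with `accuracy` (fraction of truth frames with the
#'   correct label), `sequence_match` (logical: does the run-length
#'   collapsed event sequence equal the scripted one), and `predicted`
#'   (per-frame labels aligned to truth frames, `NA` where uncovered).
#' @export
recovery_metrics <- function(truth, track, classification) {
  main <- as.integer(names(which.max(table(track$cyprid_id))))
  sub <- track[track$cyprid_id == main, ]
  lab <- classification$labels[[as.character(main)]]
  pred <- rep(NA_character_, nrow(truth))
  fidx <- truth$frame - min(sub$frame) + 1L
  ok <- fidx >= 1 & fidx <= length(lab)
  pred[ok] <- lab[fidx[ok]]
  ev <- classification$events
  seq_pred <- rle(ev$behaviour[ev$cyprid_id == main])$values
  seq_true <- rle(truth$behaviour)$values
  list(accuracy = mean(!is.na(pred) & pred == truth$behaviour),
       sequence_match = identical(seq_pred, seq_true),
       predicted = pred)
}
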