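#' Associate segments between consecutive frames
#'
#' An old and a new segment are associated when their pixel sets intersect
#' in at least one pixel. Grouping the resulting bipartite overlap graph
#' into connected components yields the five situations handled by the
#' tracker: `one_to_one`, `merge` (several old, one new), `split` (one
#' old, several new), `exit` (old with no new partner) and `entry` (new
#' with no old partner). A many-to-many component is reported as kind
#' `complex` and is resolved downstream by generalized assignment.
#'
#' @param prev List of segments in the previous frame (see
#'   [segment_frame()]).
#' @param curr List of segments in the current frame.
#' @return List of association cases; each has `kind`, `old_labels`,
#'   `new_labels`.
#' @export
associate_segments <- function(prev, curr) {
  np <- length(prev); nc <- length(curr)
  # overlap adjacency
  overlaps <- vector("list", np)
  matched_new <- logical(nc)
  for (i in seq_len(np)) {
    hit <- integer(0)
    for (j in seq_len(nc)) {
      if (any(match(curr[[j]]$idx, prev[[i]]$idx, nomatch = 0L) > 0L)) {
        hit <- c(hit, j)
        matched_new[j] <- TRUE
      }
    }
    overlaps[[i]] <- hit
  }
  cases <- list()
  seen_old <- logical(np)
  # connected components of the bipartite graph, seeded from each old
  rev_overlaps <- vector("list", nc)
  for (i in seq_len(np)) for (j in overlaps[[i]]) {
    rev_overlaps[[j]] <- c(rev_overlaps[[j]], i)
  }
  for (i in seq_len(np)) {
    if (seen_old[i]) next
    olds <- i; news <- integer(0)
    frontier_old <- i
    seen_old[i] <- TRUE
    repeat {
      frontier_new <- setdiff(unlist(overlaps[frontier_old]), news)
      news <- c(news, frontier_new)
      frontier_old <- setdiff(unlist(rev_overlaps[frontier_new]), olds)
      if (length(frontier_old) == 0) break
      olds <- c(olds, frontier_old)
      seen_old[frontier_old] <- TRUE
    }
    olds <- sort(olds); news <- sort(news)
    kind <- if (length(news) == 0) "exit"
    else if (length(olds) == 1 && length(news) == 1) "one_to_one"
    else if (length(olds) >= 2 && length(news) == 1) "merge"
    else if (length(olds) == 1 && length(news) >= 2) "split"
    else "complex"
    cases[[length(cases) + 1L]] <- list(
      kind = kind,
      old_labels = vapply(prev[olds], `[[`, integer(1), "label"),
      new_labels = vapply(curr[news], `[[`, integer(1), "label")
    )
  }
  for (j in which(!matched_new)) {
    cases[[length(cases) + 1L]] <- list(
      kind = "entry", old_labels = integer(0),
      new_labels = curr[[j]]$label
    )
  }
  cases
}
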