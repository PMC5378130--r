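#' Wide-search weights of centre-point nodes
#'
#' Walking animals pause between steps; the centre-point path then yields
#' a string of nodes whose consecutive distances are the step lengths SL.
#' A stretch qualifies as wide search when, over a window of four
#' consecutive steps, (1) the ratio of the standard deviation to the mean
#' of SL is below `ratio_threshold` (0.2) and (2) the maximum relative
#' deviation of SL from `step_factor * CL` (0.85 of the body length),
#' `MC = max |SL - 0.85 CL| / (0.85 CL)`, is below `mc_threshold` (0.3).
#' Each passing window flags the five nodes it spans.
#'
#' Only temporally adjacent nodes form a step: when the time gap between
#' two consecutive nodes exceeds `max_gap` frames (for instance across a
#' swimming bout) the pair is excluded from every window, since the
#' animal did not walk between those pauses.
#'
#' @param nodes Centre-point nodes from [extract_nodes()].
#' @param cl Body length CL in pixels (> 0).
#' @param ratio_threshold,mc_threshold,step_factor Classifier constants.
#' @param max_gap Maximum inter-node gap in frames for a step; `Inf`
#'   disables the gate.
#' @return Integer vector `W` (0/1), one entry per node. Fewer than five
#'   nodes yield all zeros.
#' @export
classify_wide_search <- function(nodes, cl, ratio_threshold = 0.2,
                                 mc_threshold = 0.3, step_factor = 0.85,
                                 max_gap = Inf) {
  stopifnot(cl > 0)
  n <- nrow(nodes)
  w <- integer(n)
  if (n < 5) return(w)
  sl <- sqrt(diff(nodes$x)^2 + diff(nodes$y)^2)
  gap_ok <- if (is.finite(max_gap) && !is.null(nodes$first_frame)) {
    nodes$first_frame[-1] - nodes$last_frame[-n] <= max_gap
  } else rep(TRUE, n - 1)
  ref <- step_factor * cl
  ch <- (sl - ref) / ref
  for (i in seq_len(n - 4)) {
    if (!all(gap_ok[i:(i + 3)])) next
    win <- sl[i:(i + 3)]
    st <- stats::sd(win)
    m <- mean(win)
    mc <- max(abs(ch[i:(i + 3)]))
    if (m > 0 && st / m < ratio_threshold && mc < mc_threshold) {
      w[i:(i + 4)] <- 1L
    }
  }
  w
}

# minimal circular arc (degrees) containing a set of directions
circular_range <- function(theta_deg) {
  if (length(theta_deg) < 2) return(0)
  a <- sort(theta_deg %% 360)
  gaps <- diff(c(a, a[1] + 360))
  360 - max(gaps)
}

#' Inspection weights of terminal-point nodes
#'
#' During inspection the animal stays attached at one point and swings
#' its body about it, so the attached terminal point forms a node while
#' the body direction sweeps a wide arc. A terminal-point node is flagged
#' as inspection when the angular range of the body direction over the
#' node's member span (first member S to last member E) strictly exceeds
#' `angle_threshold_deg` (30 degrees). The range is the minimal circular
#' arc containing the sampled directions.
#'
#' @param nodes Terminal-point nodes from [extract_nodes()].
#' @param theta Body-direction series (degrees, continuity-resolved),
#'   aligned with the point series the nodes were extracted from (indexed
#'   by the nodes' `first_index`/`last_index`).
#' @param angle_threshold_deg Angular-range threshold.
#' @return Integer vector `IW` (0/1), one entry per node.
#' @export
classify_inspection <- function(nodes, theta, angle_threshold_deg = 30) {
  n <- nrow(nodes)
  iw <- integer(n)
  for (k in seq_len(n)) {
    rng <- circular_range(theta[nodes$first_index[k]:nodes$last_index[k]])
    if (rng > angle_threshold_deg) iw[k] <- 1L
  }
  iw
}

#' Close-search weights from chained inspection nodes
#'
#' Close search looks like a series of brief inspection events scattered
#' over a small area: the animal pivots, walks one to four steps, and
#' pivots again. Inspection nodes are scanned in time order and chained
#' when consecutive ones lie closer than `chain_steps * step_factor * cl`
#' (four nominal steps) and each has fewer than `member_cap` members --
#' the cap keeps genuine, minutes-long inspection bouts out of the chain.
#' Nodes of chains with at least two members get `CSW = 1` and their
#' inspection weight is reset to 0, so the two labels never overlap.
#'
#' When `max_gap` is finite, two inspection nodes separated in time by
#' more than that many frames never chain, so spatial coincidence across
#' an intervening swimming bout cannot manufacture close search.
#'
#' @param nodes Terminal-point nodes.
#' @param iw Inspection weights for `nodes` (see [classify_inspection()]).
#' @param cl Body length in pixels.
#' @param member_cap Member-count cap above which a node cannot join a
#'   chain (in members, i.e. frames).
#' @param step_factor,chain_steps Chain distance gate constants.
#' @param max_gap Maximum inter-node time gap in frames for chaining.
#' @return List with `csw` (0/1 per node), `iw` (modified inspection
#'   weights) and `chains` (list of integer vectors of chained node
#'   indices).
#' @export
classify_close_search <- function(nodes, iw, cl, member_cap,
                                  step_factor = 0.85, chain_steps = 4,
                                  max_gap = Inf) {
  n <- nrow(nodes)
  csw <- integer(n)
  chains <- list()
  insp <- which(iw == 1L)
  if (length(insp) >= 2) {
    gate <- chain_steps * step_factor * cl
    eligible <- nodes$mn[insp] < member_cap
    # chainable gaps between consecutive inspection nodes
    current <- insp[1]
    for (k in seq_len(length(insp) - 1)) {
      i <- insp[k]; j <- insp[k + 1]
      d <- sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2)
      gap <- if (is.finite(max_gap) && !is.null(nodes$first_frame)) {
        nodes$first_frame[j] - nodes$last_frame[i]
      } else 0
      if (eligible[k] && eligible[k + 1] && d < gate && gap <= max_gap) {
        current <- c(current, j)
      } else {
        if (length(current) >= 2) chains[[length(chains) + 1L]] <- current
        current <- j
      }
    }
    if (length(current) >= 2) chains[[length(chains) + 1L]] <- current
    for (ch in chains) csw[ch] <- 1L
  }
  iw[csw == 1L] <- 0L
  list(csw = csw, iw = iw, chains = chains)
}

#' Behaviour events from frame labels
#'
#' Collapses a per-frame label vector into maximal runs. Events tile the
#' track exactly: consecutive events abut and their durations sum to the
#' track duration.
#'
#' @param labels Character vector of per-frame behaviour labels.
#' @param frame_rate Frames per second.
#' @param start_frame Frame index of `labels[1]`.
#' @return `data.frame` with `behaviour`, `start_frame`, `end_frame`,
#'   `duration_s = (end_frame - start_frame + 1) / frame_rate`.
#' @export
ethogram_events <- function(labels, frame_rate, start_frame = 0L) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    behaviour = r$values,
    start_frame = start_frame + starts - 1L,
    end_frame = start_frame + ends - 1L,
    duration_s = r$lengths / frame_rate
  )
}

#' Assemble the ethogram of one animal
#'
#' Maps node-level weights back to frame spans and labels every frame of
#' the track. A run of consecutive wide-search nodes labels the whole
#' stepped interval (first member of the first node to last member of the
#' last); an inspection node labels its member span; a close-search chain
#' labels the span from its first to its last node. Within a frame the
#' precedence is close search > inspection > wide search, and every frame
#' not claimed by these three is swimming. Adjacent same-label runs merge
#' into single events; wide-search events additionally report their step
#' count (number of inter-node intervals spanned).
#'
#' @param centre_nodes,w Centre-point nodes and their wide-search weights.
#' @param tp_results List (one per terminal-point path) of lists with
#'   `nodes`, `iw` (post-overlap-removal), `chains`.
#' @param start_frame,end_frame Frame range of the track (inclusive).
#' @param frame_rate Frames per second.
#' @return List with `events` (`data.frame`: behaviour, start_frame,
#'   end_frame, duration_s, step_count) and `labels` (per-frame vector).
#' @export
assemble_ethogram <- function(centre_nodes, w, tp_results,
                              start_frame, end_frame, frame_rate) {
  nf <- end_frame - start_frame + 1L
  lab <- rep("swimming", nf)
  at <- function(f) pmin(pmax(f - start_frame + 1L, 1L), nf)

  if (nrow(centre_nodes) > 0 && any(w == 1L)) {
    r <- rle(w == 1L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      f0 <- centre_nodes$first_frame[starts[k]]
      f1 <- centre_nodes$last_frame[ends[k]]
      lab[at(f0):at(f1)] <- "wide_search"
    }
  }
  for (tp in tp_results) {
    if (nrow(tp$nodes) == 0) next
    for (k in which(tp$iw == 1L)) {
      lab[at(tp$nodes$first_frame[k]):at(tp$nodes$last_frame[k])] <- "inspection"
    }
  }
  for (tp in tp_results) {
    for (ch in tp$chains) {
      f0 <- tp$nodes$first_frame[ch[1]]
      f1 <- tp$nodes$last_frame[ch[length(ch)]]
      lab[at(f0):at(f1)] <- "close_search"
    }
  }

  events <- ethogram_events(lab, frame_rate, start_frame)
  events$step_count <- NA_integer_
  if (nrow(centre_nodes) > 0) {
    for (r in which(events$behaviour == "wide_search")) {
      inside <- centre_nodes$first_frame >= events$start_frame[r] &
        centre_nodes$last_frame <= events$end_frame[r]
      events$step_count[r] <- max(sum(inside) - 1L, 0L)
    }
  }
  list(events = events, labels = lab)
}

#' Classify a track table into behaviour events
#'
#' Full classification pipeline for every animal in a track table:
#' continuity-resolved direction and terminal points, node extraction on
#' the centre and both terminal-point paths, wide-search / inspection /
#' close-search weights, and ethogram assembly. The body length CL of an
#' animal is estimated as twice the median semi-major axis over its
#' track.
#'
#' @param track A [track_sequence()]-style `data.frame`.
#' @param config A [run_config()].
#' @return List with `events` (all animals), `labels` (named list of
#'   per-frame label vectors keyed by animal id), `nodes` (all nodes with
#'   `cyprid_id`, `source` and weights), and `cl` (named vector of body
#'   lengths).
#' @export
classify_track <- function(track, config = run_config()) {
  needed <- c("frame", "cyprid_id", "xc", "yc", "a", "b", "theta_deg")
  miss <- setdiff(needed, names(track))
  if (length(miss)) {
    stop_invalid("track table lacks column(s): ", paste(miss, collapse = ", "))
  }
  cap <- ceiling(config$inspection_member_cap_s * config$frame_rate)
  ids <- sort(unique(track$cyprid_id))
  all_events <- list(); all_nodes <- list(); labels <- list()
  cls <- stats::setNames(numeric(length(ids)), ids)

  for (id in ids) {
    tr <- track[track$cyprid_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    pt <- point_triplets(tr)
    cl <- 2 * stats::median(tr$a)
    cls[as.character(id)] <- cl

    max_gap <- ceiling(config$max_step_gap_s * config$frame_rate)
    cn <- extract_nodes(pt$xc, pt$yc, pt$frame, config$dis_th, config$mn_th,
                        config$strict_mn)
    w <- classify_wide_search(cn, cl, config$ratio_threshold,
                              config$mc_threshold, config$step_factor,
                              max_gap = max_gap)
    # terminal-point nodes from both paths, merged in time order: the
    # attached end of the body can alternate between TP1 and TP2 across
    # consecutive pivots, and the close-search chain must see them all
    nd1 <- extract_nodes(pt$tx1, pt$ty1, pt$frame, config$dis_th,
                         config$mn_th, config$strict_mn)
    nd2 <- extract_nodes(pt$tx2, pt$ty2, pt$frame, config$dis_th,
                         config$mn_th, config$strict_mn)
    tn <- rbind(if (nrow(nd1)) cbind(nd1, source = "tp1"),
                if (nrow(nd2)) cbind(nd2, source = "tp2"))
    if (is.null(tn)) {
      tn <- cbind(nd1, source = character(0))
    } else {
      tn <- tn[order(tn$first_frame, tn$source), , drop = FALSE]
    }
    iw <- classify_inspection(tn, pt$theta, config$angle_threshold_deg)
    cs <- classify_close_search(tn, iw, cl, cap, config$step_factor,
                                config$chain_steps, max_gap = max_gap)
    tp_results <- list(list(nodes = tn, iw = cs$iw, csw = cs$csw,
                            chains = cs$chains))
    eth <- assemble_ethogram(cn, w, tp_results,
                             min(tr$frame), max(tr$frame), config$frame_rate)
    eth$events <- cbind(cyprid_id = id, eth$events)
    all_events[[as.character(id)]] <- eth$events
    labels[[as.character(id)]] <- eth$labels

    all_nodes[[as.character(id)]] <- rbind(
      node_table(cn, id, "centre", w = w),
      if (nrow(tn)) data.frame(cyprid_id = id, source = tn$source,
                               tn[, setdiff(names(tn), "source")],
                               w = NA_integer_, iw = cs$iw, csw = cs$csw)
    )
  }
  list(events = do.call(rbind, c(all_events, list(make.row.names = FALSE))),
       labels = labels,
       nodes = do.call(rbind, c(all_nodes, list(make.row.names = FALSE))),
       cl = cls)
}

node_table <- function(nodes, id, source, w = NULL, iw = NULL, csw = NULL) {
  if (nrow(nodes) == 0) {
    return(NULL)
  }
  data.frame(cyprid_id = id, source = source, nodes,
             w = if (is.null(w)) NA_integer_ else w,
             iw = if (is.null(iw)) NA_integer_ else iw,
             csw = if (is.null(csw)) NA_integer_ else csw)
}
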