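#' Resolve a merged segment into its constituent animals
#'
#' When several previously distinct animals touch, their blobs fuse into
#' one segment. The segment's pixels are partitioned into *remaining*
#' pixels -- those overlapping a particular animal's pixels in the
#' previous frame -- and *free* pixels overlapping none. For each animal a
#' small deterministic set of candidate ellipses is scored and the
#' candidate with minimal cost
#' \deqn{W = a_1 N_{black} + a_2 N_{white} - a_3 N_{cyprid}}
#' is kept, where `N_black` counts pixels inside the candidate ellipse
#' that are not part of the segment (background claimed by the ellipse),
#' `N_white` counts the animal's claimed pixels left outside the ellipse,
#' and `N_cyprid` counts the animal's remaining pixels captured inside.
#'
#' Candidate ellipses per animal: (i) the moment fit of the remaining
#' pixels alone, (ii) the moment fit of remaining plus all free pixels,
#' and (iii) an ellipse detected by deterministic fixed-point refinement
#' seeded from the animal's previous ellipse -- segment pixels lying
#' under the (slightly inflated) ellipse are selected and the moment fit
#' of that selection becomes the next ellipse, iterated a few times.
#' The refinement carries each animal's orientation through a crossing:
#' when two bodies pass through one another the fused blob is an X whose
#' arms continue the two body axes, and an ellipse seeded with an
#' animal's own axis locks onto its own arm. The animal's *claimed*
#' pixels (the `N_white` reference and the returned `support_idx`) are
#' the segment pixels nearest to its refined ellipse in normalized
#' elliptical distance, claims being disjoint across animals by
#' construction.
#'
#' @param new_segment Segment produced by a merge association.
#' @param prev_states List of previous per-animal states; each needs
#'   `cyprid_id`, `support_idx` (the animal's pixel indices in the
#'   previous frame), and geometry fields `xc`, `yc`, `a`, `b`,
#'   `theta_deg`, `size`.
#' @param weights Named numeric `c(a1, a2, a3)`, all positive.
#' @param height Image height in rows (needed to decode pixel indices).
#' @return List of resolved states, one per previous animal, each with the
#'   geometry fields, `provenance` (`"merge-resolved"`, or `"missed"` when
#'   the animal has no remaining pixels in the segment or its candidate
#'   sets are degenerate -- missed states keep the previous geometry), and
#'   `support_idx` (the animal's claimed pixels).
#' @export
resolve_merge <- function(new_segment, prev_states,
                          weights = c(a1 = 1, a2 = 1, a3 = 1),
                          height) {
  seg_idx <- new_segment$idx
  k <- length(prev_states)
  remaining <- lapply(prev_states, function(s) {
    seg_idx[match(seg_idx, s$support_idx, nomatch = 0L) > 0L]
  })
  free <- seg_idx[!seg_idx %in% unlist(remaining)]
  sxy <- idx_to_xy(seg_idx, height)
  live <- which(lengths(remaining) > 0)

  # per-animal ellipse detection: fixed-point refinement from the
  # previous ellipse against the segment pixels
  refined <- vector("list", k)
  for (i in live) {
    e <- prev_states[[i]]
    for (iter in 1:3) {
      d <- ellipse_dist2(sxy, e)
      sel <- d <= 1.44  # inflate by 20% to let the body advance
      if (sum(sel) < 5) break
      f <- tryCatch(fit_ellipse(sxy[sel, , drop = FALSE]),
                    error = function(err) NULL)
      if (is.null(f)) break
      e <- f
    }
    refined[[i]] <- e
  }
  # disjoint pixel claims by nearest refined ellipse
  claimed <- vector("list", k)
  if (length(live)) {
    dmat <- vapply(live, function(i) ellipse_dist2(sxy, refined[[i]]),
                   numeric(nrow(sxy)))
    dmat <- matrix(dmat, nrow = nrow(sxy))
    owner <- live[max.col(-dmat, ties.method = "first")]
    owner[dmat[cbind(seq_len(nrow(sxy)), max.col(-dmat, ties.method = "first"))] > 1.44] <- 0L
    for (i in live) claimed[[i]] <- seg_idx[owner == i]
  }

  out <- vector("list", k)
  for (i in seq_len(k)) {
    ps <- prev_states[[i]]
    if (length(remaining[[i]]) == 0) {
      out[[i]] <- missed_state(ps)
      next
    }
    ref <- if (length(claimed[[i]])) claimed[[i]] else remaining[[i]]
    cands <- list()
    for (cs in list(remaining[[i]], c(remaining[[i]], free))) {
      if (length(cs) < 5) next
      f <- tryCatch(fit_ellipse(idx_to_xy(cs, height)), error = function(e) NULL)
      if (!is.null(f)) cands[[length(cands) + 1L]] <- f
    }
    cands[[length(cands) + 1L]] <- refined[[i]]
    best <- NULL
    best_w <- Inf
    for (f in cands) {
      wv <- merge_cost(f, ref, remaining[[i]], seg_idx, weights, height)
      if (wv < best_w) {
        best_w <- wv
        best <- f
      }
    }
    if (is.null(best)) {
      out[[i]] <- missed_state(ps)
      next
    }
    out[[i]] <- list(cyprid_id = ps$cyprid_id, xc = best$xc, yc = best$yc,
                     a = best$a, b = best$b, theta_deg = best$theta_deg,
                     size = length(ref), provenance = "merge-resolved",
                     support_idx = ref)
  }
  out
}

# squared normalized elliptical distance of points to an ellipse state
# (list with xc, yc, a, b, theta_deg); 1 on the boundary
ellipse_dist2 <- function(xy, e) {
  th <- e$theta_deg * pi / 180
  dx <- xy[, 1] - e$xc
  dy <- xy[, 2] - e$yc
  u <- (dx * cos(th) + dy * sin(th)) / e$a
  v <- (-dx * sin(th) + dy * cos(th)) / e$b
  u * u + v * v
}

# cost of one candidate ellipse; own_idx is the animal's claimed pixel
# set, the reference for the N_white penalty
merge_cost <- function(fit, own_idx, remaining_idx, seg_idx, weights, height) {
  exy <- ellipse_pixels(fit$xc, fit$yc, fit$a, fit$b, fit$theta_deg)
  ok <- exy[, 1] >= 0 & exy[, 2] >= 0 & exy[, 2] < height
  eidx <- xy_to_idx(exy[ok, 1], exy[ok, 2], height)
  n_black <- sum(match(eidx, seg_idx, nomatch = 0L) == 0L)
  n_white <- sum(match(own_idx, eidx, nomatch = 0L) == 0L)
  n_cyprid <- sum(match(remaining_idx, eidx, nomatch = 0L) > 0L)
  unname(weights[1] * n_black + weights[2] * n_white - weights[3] * n_cyprid)
}

missed_state <- function(ps) {
  list(cyprid_id = ps$cyprid_id, xc = ps$xc, yc = ps$yc, a = ps$a, b = ps$b,
       theta_deg = ps$theta_deg, size = ps$size, provenance = "missed",
       support_idx = ps$support_idx)
}

#' Assign animals of a splitting segment to its fragments
#'
#' When a segment that carried several animals breaks apart, each animal
#' must be matched to the correct fragment. Every (animal i, fragment j)
#' pair is scored by
#' \deqn{Et_{ij} = w_1 Es_{ij} + w_2 Ed_{ij} + w_3 Ep_{ij}}
#' with the three error terms normalized to \[0, 1\]:
#' size `Es = |s_i - s_j| / max(s_i, s_j)`; direction `Ed = min(|d|, 180 -
#' |d|) / 90` with `d` the orientation difference (orientations live on
#' the 180-degree axial circle); shared pixels `Ep = 1 - N_shared /
#' min(s_i, s_j)`, where `N_shared` counts pixels common to the animal's
#' previous support and the fragment. The returned assignment minimizes
#' the total cost -- exhaustively over all injective assignments for up to
#' 4 animals, greedily beyond. Ties resolve to the lowest animal id taking
#' the lowest fragment label. Unassigned animals are reported as missed,
#' unassigned fragments as entries.
#'
#' @param new_segments List of >= 2 fragments (segments).
#' @param old_cyprids List of animal states sharing the parent segment
#'   (fields as in [resolve_merge()]).
#' @param weights Named numeric `c(w1, w2, w3)`.
#' @return List with `assignment` (data.frame cyprid_id, segment_label,
#'   cost), `missed_ids`, `entry_labels`, and the full `cost` matrix
#'   (animals x fragments).
#' @export
resolve_split <- function(new_segments, old_cyprids,
                          weights = c(w1 = 1, w2 = 1, w3 = 1)) {
  ids <- vapply(old_cyprids, `[[`, numeric(1), "cyprid_id")
  ord_c <- order(ids)
  old_cyprids <- old_cyprids[ord_c]
  labs <- vapply(new_segments, `[[`, integer(1), "label")
  ord_s <- order(labs)
  new_segments <- new_segments[ord_s]
  nc <- length(old_cyprids); ns <- length(new_segments)
  cost <- matrix(NA_real_, nc, ns,
                 dimnames = list(vapply(old_cyprids, `[[`, numeric(1), "cyprid_id"),
                                 vapply(new_segments, `[[`, integer(1), "label")))
  for (i in seq_len(nc)) {
    ci <- old_cyprids[[i]]
    for (j in seq_len(ns)) {
      sj <- new_segments[[j]]
      cost[i, j] <- split_cost(ci, sj, weights)
    }
  }
  pick <- best_assignment(cost, exhaustive_max = 4L)
  assigned <- which(!is.na(pick))
  assignment <- data.frame(
    cyprid_id = vapply(old_cyprids[assigned], `[[`, numeric(1), "cyprid_id"),
    segment_label = vapply(new_segments[pick[assigned]], `[[`, integer(1), "label"),
    cost = cost[cbind(assigned, pick[assigned])]
  )
  missed <- setdiff(seq_len(nc), assigned)
  entries <- setdiff(seq_len(ns), pick[assigned])
  list(assignment = assignment,
       missed_ids = vapply(old_cyprids[missed], `[[`, numeric(1), "cyprid_id"),
       entry_labels = vapply(new_segments[entries], `[[`, integer(1), "label"),
       cost = cost)
}

# Et for one (animal, fragment) pair
split_cost <- function(cyprid, segment, weights) {
  es <- abs(cyprid$size - segment$size) / max(cyprid$size, segment$size)
  ed <- axial_diff(cyprid$theta_deg, seg_theta(segment)) / 90
  n_shared <- sum(match(segment$idx, cyprid$support_idx, nomatch = 0L) > 0L)
  ep <- 1 - n_shared / min(cyprid$size, segment$size)
  unname(weights[1] * es + weights[2] * ed + weights[3] * ep)
}

# fragment orientation; degenerate fragments fall back to 0 with Ed then
# dominated by the other terms
seg_theta <- function(segment) {
  fit <- tryCatch(fit_ellipse(segment$coords), error = function(e) NULL)
  if (is.null(fit)) 0 else fit$theta_deg
}

# minimal-total-cost injective assignment of rows to columns.
# NA selections are allowed only through row surplus (nrow > ncol).
# Enumeration order is lexicographic in row-major choices, and strict
# improvement is required to replace the incumbent, so equal-cost ties
# resolve to the earliest assignment: lowest row takes lowest column.
best_assignment <- function(cost, exhaustive_max = 4L) {
  nr <- nrow(cost); ncol_ <- ncol(cost)
  if (nr <= exhaustive_max) {
    best <- NULL; best_cost <- Inf
    cols <- seq_len(ncol_)
    # choose which rows are assigned when rows exceed columns
    row_sets <- if (nr <= ncol_) list(seq_len(nr)) else
      utils::combn(seq_len(nr), ncol_, simplify = FALSE)
    for (rows in row_sets) {
      perms <- permutations(cols, length(rows))
      for (p in perms) {
        tot <- sum(cost[cbind(rows, p)])
        if (tot < best_cost - 1e-12) {
          best_cost <- tot
          best <- rep(NA_integer_, nr)
          best[rows] <- p
        }
      }
    }
    best
  } else {
    # greedy: repeatedly take the cheapest remaining pair
    pick <- rep(NA_integer_, nr)
    free_r <- seq_len(nr); free_c <- seq_len(ncol_)
    while (length(free_r) && length(free_c)) {
      sub <- cost[free_r, free_c, drop = FALSE]
      k <- which.min(sub)  # ties: first in column-major order
      ri <- ((k - 1) %% length(free_r)) + 1
      ci <- ((k - 1) %/% length(free_r)) + 1
      pick[free_r[ri]] <- free_c[ci]
      free_r <- free_r[-ri]; free_c <- free_c[-ci]
    }
    pick
  }
}

# all ordered selections of k elements from v, lexicographic order
permutations <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i], k - 1)) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}
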