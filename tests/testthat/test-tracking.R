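test_that("ellipse fitting recovers rendered parameters", {
  px <- ellipse_pixels(50, 40, 10, 4, 30)
  fit <- fit_ellipse(px)
  expect_lt(abs(fit$xc - 50), 0.5)
  expect_lt(abs(fit$yc - 40), 0.5)
  expect_lt(abs(fit$a - 10), 0.5)
  expect_lt(abs(fit$b - 4), 0.5)
  expect_lt(min(abs(fit$theta_deg - 30), 180 - abs(fit$theta_deg - 30)), 3)
})

test_that("a rasterized circle fits as a ~ b with free orientation", {
  fit <- fit_ellipse(ellipse_pixels(30, 30, 6, 6, 0))
  expect_lt(abs(fit$a - 6), 0.5)
  expect_lt(abs(fit$b - 6), 0.5)
  expect_lt(fit$a - fit$b, 0.2)
})

test_that("degenerate pixel sets are rejected", {
  expect_error(fit_ellipse(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "cypridtrack_degenerate_geometry")
  expect_error(fit_ellipse(cbind(0:9, 0:9)),
               class = "cypridtrack_degenerate_geometry")  # collinear
  expect_error(fit_ellipse(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))),
               class = "cypridtrack_degenerate_geometry")  # < 5 px
})

make_seg <- function(coords, label = 1L, h = 60) {
  coords <- as.matrix(coords)
  list(label = label, idx = coords[, 1] * h + coords[, 2] + 1L,
       coords = coords, size = nrow(coords),
       centroid = compute_centroid(coords))
}

test_that("identical segment sets associate one-to-one", {
  s1 <- make_seg(ellipse_pixels(10, 10, 5, 2, 0), 1L)
  s2 <- make_seg(ellipse_pixels(40, 30, 5, 2, 90), 2L)
  cases <- associate_segments(list(s1, s2), list(s1, s2))
  expect_equal(vapply(cases, `[[`, character(1), "kind"),
               c("one_to_one", "one_to_one"))
})

test_that("two old segments overlapping one new form a merge case", {
  a <- make_seg(ellipse_pixels(10, 10, 5, 2, 0), 1L)
  b <- make_seg(ellipse_pixels(20, 10, 5, 2, 0), 2L)
  fused <- make_seg(ellipse_pixels(15, 10, 10, 3, 0), 1L)
  cases <- associate_segments(list(a, b), list(fused))
  expect_length(cases, 1)
  expect_equal(cases[[1]]$kind, "merge")
  expect_equal(cases[[1]]$old_labels, c(1L, 2L))
})

test_that("unmatched segments become entry and exit cases", {
  a <- make_seg(ellipse_pixels(10, 10, 5, 2, 0), 1L)
  entry <- associate_segments(list(), list(a))
  expect_equal(entry[[1]]$kind, "entry")
  exit <- associate_segments(list(a), list())
  expect_equal(exit[[1]]$kind, "exit")
})

test_that("a single-animal merge degenerates to a whole-segment fit", {
  seg <- make_seg(ellipse_pixels(25, 20, 8, 3, 40), 1L)
  prev <- list(list(cyprid_id = 1L, xc = 24, yc = 19.5, a = 8, b = 3,
                    theta_deg = 40, size = seg$size, support_idx = seg$idx))
  res <- resolve_merge(seg, prev, height = 60)
  ref <- fit_ellipse(seg$coords)
  expect_equal(res[[1]]$provenance, "merge-resolved")
  expect_lt(abs(res[[1]]$xc - ref$xc), 0.5)
  expect_lt(abs(res[[1]]$yc - ref$yc), 0.5)
  expect_lt(min(abs(res[[1]]$theta_deg - ref$theta_deg),
                180 - abs(res[[1]]$theta_deg - ref$theta_deg)), 3)
})

test_that("touching animals resolve to their own sides of a fused blob", {
  h <- 60
  # two ellipses touching side by side, drifting slightly over 3 frames
  for (dx in c(0, 0.5, 1)) {
    pa <- ellipse_pixels(20 + dx, 20, 7, 3, 0)
    pb <- ellipse_pixels(33 + dx, 20, 7, 3, 0)
    seg <- make_seg(unique(rbind(pa, pb)), 1L, h)
    prev <- list(
      list(cyprid_id = 1L, xc = 19.5 + dx, yc = 20, a = 7, b = 3,
           theta_deg = 0, size = nrow(pa),
           support_idx = pa[, 1] * h + pa[, 2] + 1L),
      list(cyprid_id = 2L, xc = 32.5 + dx, yc = 20, a = 7, b = 3,
           theta_deg = 0, size = nrow(pb),
           support_idx = pb[, 1] * h + pb[, 2] + 1L)
    )
    res <- resolve_merge(seg, prev, height = h)
    # each resolved centre is nearer its own previous centre than the other's
    for (i in 1:2) {
      d_own <- abs(res[[i]]$xc - prev[[i]]$xc)
      d_other <- abs(res[[i]]$xc - prev[[3 - i]]$xc)
      expect_lt(d_own, d_other)
    }
  }
})

test_that("an animal with no remaining pixels is marked missed", {
  seg <- make_seg(ellipse_pixels(25, 20, 8, 3, 0), 1L)
  far <- ellipse_pixels(50, 50, 5, 2, 0)
  prev <- list(
    list(cyprid_id = 1L, xc = 25, yc = 20, a = 8, b = 3, theta_deg = 0,
         size = seg$size, support_idx = seg$idx),
    list(cyprid_id = 2L, xc = 50, yc = 50, a = 5, b = 2, theta_deg = 0,
         size = nrow(far), support_idx = far[, 1] * 60 + far[, 2] + 1L)
  )
  res <- resolve_merge(seg, prev, height = 60)
  expect_equal(res[[2]]$provenance, "missed")
  expect_equal(res[[2]]$xc, 50)  # last known geometry retained
})

# independent oracle: enumerate every injective assignment and minimize
brute_split <- function(cost) {
  nc <- nrow(cost); ns <- ncol(cost)
  best <- NULL; best_cost <- Inf
  perm_idx <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perm_idx(v[-i], k - 1), function(r) c(v[i], r))
    }), recursive = FALSE)
  }
  rows_sets <- if (nc <= ns) list(seq_len(nc)) else
    utils::combn(seq_len(nc), ns, simplify = FALSE)
  for (rows in rows_sets) {
    for (p in perm_idx(seq_len(ns), length(rows))) {
      tot <- sum(cost[cbind(rows, p)])
      if (tot < best_cost - 1e-12) {
        best_cost <- tot
        best <- rep(NA_integer_, nc); best[rows] <- p
      }
    }
  }
  list(pick = best, cost = best_cost)
}

split_fixture <- function(sizes_old, sizes_new, thetas_old, h = 80) {
  # non-overlapping supports so Ep carries no signal unless constructed
  old <- lapply(seq_along(sizes_old), function(i) {
    px <- ellipse_pixels(15 * i, 60, sqrt(sizes_old[i]), sqrt(sizes_old[i]) / 2,
                         thetas_old[i])
    list(cyprid_id = i, xc = 15 * i, yc = 60, a = sqrt(sizes_old[i]),
         b = sqrt(sizes_old[i]) / 2, theta_deg = thetas_old[i],
         size = sizes_old[i], support_idx = px[, 1] * h + px[, 2] + 1L)
  })
  new <- lapply(seq_along(sizes_new), function(j) {
    px <- ellipse_pixels(15 * j, 20, 4, 2, 0)
    seg <- make_seg(px, j, h)
    seg$size <- sizes_new[j]
    seg
  })
  list(old = old, new = new)
}

test_that("split assignment matches sizes when other terms are flat", {
  fx <- split_fixture(c(40, 90), c(42, 88), c(0, 0))
  res <- resolve_split(fx$new, fx$old)
  expect_equal(res$assignment$cyprid_id, c(1, 2))
  expect_equal(res$assignment$segment_label, c(1L, 2L))
  oracle <- brute_split(res$cost)
  expect_equal(res$assignment$segment_label, oracle$pick[!is.na(oracle$pick)])
})

test_that("a perfectly symmetric split ties to lowest id, lowest label", {
  fx <- split_fixture(c(50, 50), c(50, 50), c(0, 0))
  res <- resolve_split(fx$new, fx$old)
  expect_equal(res$assignment$cyprid_id, c(1, 2))
  expect_equal(res$assignment$segment_label, c(1L, 2L))
})

test_that("surplus fragments become entries, surplus animals missed", {
  fx <- split_fixture(c(40, 90), c(42, 88, 30), c(0, 0))
  res <- resolve_split(fx$new, fx$old)
  expect_equal(nrow(res$assignment), 2)
  expect_length(res$entry_labels, 1)
  fx2 <- split_fixture(c(40, 90, 60), c(42, 88), c(0, 0, 0))
  res2 <- resolve_split(fx2$new, fx2$old)
  expect_equal(nrow(res2$assignment), 2)
  expect_length(res2$missed_ids, 1)
})

test_that("a straight-moving animal keeps one identity end to end", {
  ar <- reference_arena(noise_sd = 0)
  sc <- behaviour_script(script_phase("swimming", 2, heading_sd = 0))
  tr <- generate_trajectory(sc, ar, seed = 5, start = c(30, 60), heading = 5)
  frames <- render_frames(tr, ar, seed = 5)
  trk <- track_sequence(frames, run_config())
  expect_equal(unique(trk$cyprid_id), 1L)
  expect_equal(nrow(trk), nrow(tr))
})

test_that("two crossing animals keep their identities", {
  sim <- crossing_sequence(7)
  trk <- track_sequence(sim$frames, run_config())
  expect_length(unique(trk$cyprid_id), 2)
  expect_false(identity_swapped(sim$truth, trk))
  expect_true(any(trk$provenance == "merge-resolved"))
})

test_that("an animal leaving the view is retired; re-entry is a new id", {
  ar <- arena_spec(width = 120, height = 80, a = 7, b = 3, noise_sd = 0)
  # hand-built trajectory: walks out of frame, comes back much later
  n1 <- 30; gap <- 25; n2 <- 20
  tr <- data.frame(
    frame = 0:(n1 + gap + n2 - 1),
    time_s = (0:(n1 + gap + n2 - 1)) / 33,
    x = c(seq(40, 40 - 3 * (n1 - 1), by = -3),      # exits left
          rep(-40, gap),                            # absent
          seq(-20, -20 + 3 * (n2 - 1), by = 3)),    # re-enters
    y = 40, theta = 0, behaviour = "swimming")
  frames <- render_frames(tr, ar, seed = 1)
  trk <- track_sequence(frames, run_config())
  ids <- unique(trk$cyprid_id)
  expect_gte(length(ids), 2)
  expect_lt(max(trk$frame[trk$cyprid_id == ids[1]]),
            min(trk$frame[trk$cyprid_id == ids[length(ids)]]))
})

test_that("identities are conserved when nothing exits or enters", {
  ar <- reference_arena(noise_sd = 1)
  sc <- behaviour_script(script_phase("swimming", 2))
  trajs <- list(generate_trajectory(sc, ar, seed = 21, start = c(40, 40)),
                generate_trajectory(sc, ar, seed = 22, start = c(120, 80)))
  frames <- render_frames(trajs, ar, seed = 21)
  trk <- track_sequence(frames, run_config())
  per_frame <- tapply(trk$cyprid_id, trk$frame, function(x) paste(sort(x), collapse = ","))
  expect_equal(unique(as.vector(per_frame)), "1,2")
})
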