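cl <- 14  # body length used throughout (2a with a = 7)

test_that("regular steps at 0.85 CL flag the whole stretch as wide search", {
  step <- 0.85 * cl
  nodes <- node_fixture(x = step * (0:5), y = rep(0, 6))
  expect_equal(classify_wide_search(nodes, cl), rep(1L, 6))
})

test_that("wildly alternating steps are not wide search", {
  xs <- cumsum(c(0, rep(c(0.3 * cl, 2 * cl), 3)))
  nodes <- node_fixture(x = xs, y = rep(0, 7))
  expect_equal(classify_wide_search(nodes, cl), rep(0L, 7))
})

test_that("fewer than five nodes can never form a wide-search window", {
  nodes <- node_fixture(x = 0.85 * cl * (0:3), y = rep(0, 4))
  expect_equal(classify_wide_search(nodes, cl), rep(0L, 4))
})

test_that("a long time gap between nodes breaks the step window", {
  step <- 0.85 * cl
  nodes <- node_fixture(x = step * (0:5), y = rep(0, 6))
  nodes$first_frame[4:6] <- nodes$first_frame[4:6] + 500L
  nodes$last_frame[4:6] <- nodes$last_frame[4:6] + 500L
  expect_equal(classify_wide_search(nodes, cl, max_gap = 66), rep(0L, 6))
  expect_equal(classify_wide_search(nodes, cl, max_gap = Inf), rep(1L, 6))
})

test_that("inspection needs an angular range beyond 30 degrees", {
  nodes <- node_fixture(x = 0, y = 0, dwell = 46)
  sweep45 <- seq(0, 45, by = 1)
  expect_equal(classify_inspection(nodes, sweep45), 1L)
  sweep10 <- seq(0, 10, length.out = 46)
  expect_equal(classify_inspection(nodes, sweep10), 0L)
})

test_that("angular range is the minimal circular arc", {
  nodes <- node_fixture(x = 0, y = 0, dwell = 31)
  wrap <- c(seq(350, 359, by = 1), seq(0, 20, by = 1))  # arc of exactly 30
  expect_equal(classify_inspection(nodes, wrap), 0L)    # strict >
  wrap31 <- c(wrap, 21)
  nodes31 <- node_fixture(x = 0, y = 0, dwell = 32)
  expect_equal(classify_inspection(nodes31, wrap31), 1L)
})

test_that("nearby short inspection nodes chain into close search", {
  nodes <- node_fixture(x = c(0, 2 * cl), y = c(0, 0), mn = 20)
  res <- classify_close_search(nodes, c(1L, 1L), cl, member_cap = 660)
  expect_equal(res$csw, c(1L, 1L))
  expect_equal(res$iw, c(0L, 0L))   # overlap removed
})

test_that("distant inspection nodes stay inspection", {
  nodes <- node_fixture(x = c(0, 10 * cl), y = c(0, 0), mn = 20)
  res <- classify_close_search(nodes, c(1L, 1L), cl, member_cap = 660)
  expect_equal(res$csw, c(0L, 0L))
  expect_equal(res$iw, c(1L, 1L))
})

test_that("a long dwell between short pivots stays inspection", {
  nodes <- node_fixture(x = c(0, 2 * cl, 4 * cl), y = c(0, 0, 0),
                        mn = c(20, 900, 20))
  res <- classify_close_search(nodes, c(1L, 1L, 1L), cl, member_cap = 660)
  expect_equal(res$csw[2], 0L)
  expect_equal(res$iw[2], 1L)
})

test_that("ethogram events tile the track and merge adjacent labels", {
  lab <- c(rep("swimming", 50), rep("close_search", 100),
           rep("close_search", 20), rep("inspection", 30))
  ev <- ethogram_events(lab, frame_rate = 33)
  expect_equal(nrow(ev), 3)   # the two close-search runs merge
  expect_equal(sum(ev$duration_s), length(lab) / 33)
  expect_equal(ev$start_frame[-1], ev$end_frame[-nrow(ev)] + 1L)
})

test_that("an all-quiet track is one long swimming event", {
  ar <- reference_arena()
  tr <- generate_trajectory(behaviour_script(script_phase("swimming", 4)),
                            ar, seed = 3)
  res <- classify_track(truth_track(tr, ar), run_config())
  expect_equal(res$events$behaviour, "swimming")
  expect_equal(nrow(res$events), 1)
})

test_that("scripted behaviours are recovered from a perfect track", {
  ar <- reference_arena()
  cfg <- run_config()
  for (seed in c(2, 5, 8)) {
    tr <- generate_trajectory(reference_script(), ar, seed = seed)
    res <- classify_track(truth_track(tr, ar), cfg)
    m <- mean(res$labels[["1"]] == tr$behaviour)
    expect_gt(m, 0.9)
    expect_equal(rle(res$events$behaviour)$values, rle(tr$behaviour)$values)
    # tiling invariant
    expect_equal(sum(res$events$duration_s), nrow(tr) / cfg$frame_rate)
    # swimming is the exact complement of the other three
    expect_equal(sum(res$labels[["1"]] == "swimming"),
                 nrow(tr) - sum(res$labels[["1"]] != "swimming"))
  }
})

test_that("raising the angle threshold never adds inspection events", {
  ar <- reference_arena()
  tr <- generate_trajectory(reference_script(), ar, seed = 17)
  trk <- truth_track(tr, ar)
  counts <- vapply(c(10, 30, 50, 80), function(th) {
    cfg <- run_config(angle_threshold_deg = th)
    ev <- classify_track(trk, cfg)$events
    sum(ev$behaviour == "inspection")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("wide-search events report their step counts", {
  ar <- reference_arena()
  tr <- generate_trajectory(
    behaviour_script(script_phase("wide_search", 6, jitter_sd = 0,
                                  heading_sd = 0)),
    ar, seed = 4)
  res <- classify_track(truth_track(tr, ar), run_config())
  ws <- res$events[res$events$behaviour == "wide_search", ]
  expect_equal(nrow(ws), 1)
  # 6 s at 33 fps with 16-frame dwells + 3-frame steps -> 10 full dwells
  expect_gte(ws$step_count, 8)
})

test_that("summaries reproduce the published averaging convention", {
  ev <- data.frame(
    cyprid_id = 1,
    behaviour = c(rep("inspection", 11), rep("close_search", 1)),
    duration_s = c(c(300, 250, 200, 180, 170, 160, 150, 149, 140, 130, 120), 101),
    step_count = NA_integer_)
  expect_equal(sum(ev$duration_s[ev$behaviour == "inspection"]), 1949)
  s <- summarize_events(ev)
  expect_equal(s$average[s$behaviour == "inspection"], 177)  # 1949 / 11 floored
  expect_equal(s$event_number[s$behaviour == "inspection"], 11)
  ev2 <- data.frame(cyprid_id = 1, behaviour = "inspection",
                    duration_s = c(23, 22), step_count = NA_integer_)
  s2 <- summarize_events(ev2)
  expect_equal(s2$average[s2$behaviour == "inspection"], 22)  # 45 / 2 floored
  # no events -> blank row, Table-style em-dash semantics
  expect_true(is.na(s2$total[s2$behaviour == "wide_search"]))
  expect_equal(s2$event_number[s2$behaviour == "wide_search"], 0)
})
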