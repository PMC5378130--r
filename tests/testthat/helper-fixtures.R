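# shared in-code fixtures: no files, everything built at test time

# uniform bright frame with optional dark rectangles (x0:x1, y0:y1, 0-based)
flat_frame <- function(h = 40, w = 60, value = 200) matrix(value, h, w)

add_rect <- function(frame, x0, x1, y0, y1, value = 50) {
  frame[(y0:y1) + 1, (x0:x1) + 1] <- value
  frame
}

# a perfect track table from a generated trajectory (bypasses imaging)
truth_track <- function(traj, arena) {
  data.frame(frame = traj$frame, time_s = traj$time_s, cyprid_id = 1L,
             xc = traj$x, yc = traj$y, a = arena$a, b = arena$b,
             theta_deg = traj$theta %% 180,
             size = nrow(ellipse_pixels(0, 0, arena$a, arena$b, 0)),
             provenance = "fitted")
}

# synthetic node table for classifier unit tests
node_fixture <- function(x, y, mn = 20, gap = 3, dwell = 16) {
  n <- length(x)
  first <- cumsum(c(0, rep(dwell + gap, n - 1)))
  data.frame(node_index = seq_len(n), x = x, y = y,
             first_frame = first, last_frame = first + dwell - 1L,
             mn = rep_len(mn, n),
             first_index = first + 1L, last_index = first + dwell)
}
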