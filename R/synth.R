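#' Arena specification for the synthetic renderer
#'
#' Describes the imaging conditions the generator emulates: a static
#' bright arena viewed by a fixed camera, dark elliptical animals, and
#' additive Gaussian pixel noise. Defaults mirror the acquisition set-up
#' the method was designed for: 1280 x 960 px at 33 frames per second,
#' with an animal long enough that its boundary spans well over five
#' pixels.
#'
#' @param width,height Image size in pixels.
#' @param background Background intensity (0-255).
#' @param blob Animal intensity; must be darker than the background.
#' @param a,b Animal semi-axes in pixels.
#' @param noise_sd Standard deviation of the additive pixel noise.
#' @param frame_rate Frames per second.
#' @return List of class `arena_spec`.
#' @export
arena_spec <- function(width = 1280, height = 960, background = 200,
                       blob = 60, a = 20, b = 8, noise_sd = 2,
                       frame_rate = 33) {
  stopifnot(blob < background, a >= b, b > 0, 2 * a >= 5)
  structure(list(width = width, height = height, background = background,
                 blob = blob, a = a, b = b, noise_sd = noise_sd,
                 frame_rate = frame_rate),
            class = "arena_spec")
}

#' One phase of a behaviour script
#'
#' @param behaviour One of `"swimming"`, `"wide_search"`,
#'   `"close_search"`, `"inspection"`.
#' @param duration_s Phase duration in seconds (> 0).
#' @param ... Behaviour-specific parameters overriding the defaults
#'   documented in [generate_trajectory()].
#' @return List describing the phase.
#' @export
script_phase <- function(behaviour, duration_s, ...) {
  behaviour <- match.arg(behaviour, c("swimming", "wide_search",
                                      "close_search", "inspection"))
  stopifnot(duration_s > 0)
  c(list(behaviour = behaviour, duration_s = duration_s), list(...))
}

#' A behaviour script
#'
#' @param ... Phases built with [script_phase()], in temporal order.
#' @return List of class `behaviour_script`.
#' @export
behaviour_script <- function(...) {
  phases <- list(...)
  stopifnot(length(phases) > 0)
  structure(phases, class = "behaviour_script")
}

# unit vector of a direction in degrees (image convention, y down)
dir_vec <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

# evaluate a function with a private RNG stream, leaving the global
# generator state untouched
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a ground-truth labelled trajectory
#'
#' Emits one animal's centre position and continuous body direction per
#' frame, following the behaviour script exactly: phase transitions occur
#' at the scripted times, so the frame-level ground-truth labels are
#' unambiguous. Given the same seed, script and arena the output is
#' bit-identical.
#'
#' Motion models and their per-phase parameters (all override-able via
#' [script_phase()]; CL denotes the body length `2a`):
#' \describe{
#'   \item{swimming}{ballistic motion, `speed` (default `0.35 * CL`
#'     px/frame) with heading noise `heading_sd` (3 deg/frame); reflects
#'     off the arena walls.}
#'   \item{wide_search}{stepped walking: dwell of `dwell_frames` (16)
#'     frames with positional jitter `jitter_sd` (0.25 px), then a step
#'     of `step_factor` (0.85) times CL over `transit_frames` (3) frames;
#'     heading drifts by `heading_sd` (12 deg) per step.}
#'   \item{close_search}{tortuous stepped walking: each dwell pivots the
#'     body about one terminal point, sweeping `sweep_deg` (60) degrees
#'     over `dwell_frames` (24) frames; steps of `step_factor_cs` (1.5)
#'     times CL with direction changes of sd `turn_sd` (70 deg).}
#'   \item{inspection}{fixed-point probing: one terminal point is pinned
#'     and the body direction oscillates sinusoidally with full range
#'     `amplitude_deg` (50) and period `period_s` (2 s).}
#' }
#'
#' @param script A [behaviour_script()].
#' @param arena An [arena_spec()].
#' @param seed Integer seed; fixes all randomness of the trajectory.
#' @param start,heading Optional initial centre `c(x, y)` and heading in
#'   degrees; randomized inside the arena when `NULL`.
#' @return `data.frame` with `frame` (0-based), `time_s`, `x`, `y`,
#'   `theta` (continuous degrees) and `behaviour`; the arena is attached
#'   as attribute `"arena"`.
#' @export
generate_trajectory <- function(script, arena = arena_spec(), seed = 1L,
                                start = NULL, heading = NULL) {
  stopifnot(inherits(script, "behaviour_script"), inherits(arena, "arena_spec"))
  with_seed(seed, function() {
    fr <- arena$frame_rate
    cl <- 2 * arena$a
    margin <- arena$a + 3
    lo <- c(margin, margin)
    hi <- c(arena$width - 1 - margin, arena$height - 1 - margin)
    pos <- if (is.null(start)) c(stats::runif(1, lo[1], hi[1]),
                                 stats::runif(1, lo[2], hi[2])) else start
    phi <- if (is.null(heading)) stats::runif(1, 0, 360) else heading

    xs <- numeric(0); ys <- numeric(0); ths <- numeric(0); beh <- character(0)
    emit <- function(p, th, b, n = 1) {
      xs <<- c(xs, rep(p[1], n)); ys <<- c(ys, rep(p[2], n))
      ths <<- c(ths, rep(th, n)); beh <<- c(beh, rep(b, n))
    }
    # steer the heading back into the arena when a step would leave it
    steer <- function(p, phi, dist) {
      for (try in 1:72) {
        q <- p + dist * dir_vec(phi)
        if (all(q >= lo) && all(q <= hi)) return(phi)
        phi <- phi + 25
      }
      phi
    }

    for (ph in unclass(script)) {
      nf <- max(1L, round(ph$duration_s * fr))
      par <- function(name, default) if (!is.null(ph[[name]])) ph[[name]] else default

      if (ph$behaviour == "swimming") {
        speed <- par("speed", 0.35 * cl)
        hsd <- par("heading_sd", 3)
        for (k in seq_len(nf)) {
          phi <- steer(pos, phi + stats::rnorm(1, 0, hsd), speed)
          pos <- pos + speed * dir_vec(phi)
          emit(pos, phi, "swimming")
        }
      } else if (ph$behaviour == "wide_search") {
        step <- par("step_factor", 0.85) * cl
        dwell <- par("dwell_frames", 16)
        transit <- par("transit_frames", 3)
        hsd <- par("heading_sd", 12)
        jit <- par("jitter_sd", 0.25)
        left <- nf
        while (left > 0) {
          nd <- min(dwell, left)
          for (k in seq_len(nd)) {
            emit(pos + stats::rnorm(2, 0, jit), phi + stats::rnorm(1, 0, 0.8),
                 "wide_search")
          }
          left <- left - nd
          if (left <= 0) break
          phi <- steer(pos, phi + stats::rnorm(1, 0, hsd), step)
          nt <- min(transit, left)
          tgt <- pos + step * dir_vec(phi)
          for (k in seq_len(nt)) {
            emit(pos + (tgt - pos) * k / transit, phi, "wide_search")
          }
          pos <- pos + (tgt - pos) * nt / transit  # stays continuous if cut short
          left <- left - nt
        }
      } else if (ph$behaviour == "close_search") {
        step <- par("step_factor_cs", 1.5) * cl
        dwell <- par("dwell_frames", 24)
        transit <- par("transit_frames", 4)
        sweep <- par("sweep_deg", 60)
        tsd <- par("turn_sd", 70)
        left <- nf
        while (left > 0) {
          anchor <- pos - arena$a * dir_vec(phi)
          nd <- min(dwell, left)
          sgn <- sample(c(-1, 1), 1)
          th <- phi
          for (k in seq_len(nd)) {
            th <- phi + sgn * sweep * ((k - 1) / max(dwell - 1, 1) - 0.5)
            p <- anchor + arena$a * dir_vec(th)
            emit(p, th, "close_search")
          }
          phi <- th  # body direction where the sweep actually stopped
          pos <- anchor + arena$a * dir_vec(phi)
          left <- left - nd
          if (left <= 0) break
          phi <- steer(pos, phi + stats::rnorm(1, 0, tsd), step)
          nt <- min(transit, left)
          tgt <- pos + step * dir_vec(phi)
          for (k in seq_len(nt)) {
            emit(pos + (tgt - pos) * k / transit, phi, "close_search")
          }
          pos <- pos + (tgt - pos) * nt / transit
          left <- left - nt
        }
      } else { # inspection
        amp <- par("amplitude_deg", 50)
        period <- par("period_s", 2)
        anchor <- pos - arena$a * dir_vec(phi)
        th <- phi
        for (k in seq_len(nf)) {
          th <- phi + (amp / 2) * sin(2 * pi * (k - 1) / (period * fr))
          p <- anchor + arena$a * dir_vec(th)
          emit(p, th, "inspection")
        }
        phi <- th
        pos <- anchor + arena$a * dir_vec(phi)
      }
    }
    n <- length(xs)
    out <- data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / fr,
                      x = xs, y = ys, theta = ths, behaviour = beh)
    attr(out, "arena") <- arena
    out
  })
}

#' Render trajectories into a grayscale frame sequence
#'
#' Each animal is drawn as a hard-rasterized (no anti-aliasing) filled
#' dark ellipse at its scripted centre and orientation, so segment sizes
#' are deterministic; overlapping animals naturally fuse into one dark
#' blob. Gaussian pixel noise is then added and intensities clipped to
#' 0-255.
#'
#' @param trajectories One trajectory `data.frame` or a list of them (all
#'   the same length).
#' @param arena An [arena_spec()].
#' @param seed Seed for the pixel noise.
#' @return List of frame matrices.
#' @export
render_frames <- function(trajectories, arena = arena_spec(), seed = 1L) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  nfs <- vapply(trajectories, nrow, integer(1))
  if (length(unique(nfs)) != 1) stop_invalid("trajectories differ in length")
  nf <- nfs[1]
  h <- arena$height; w <- arena$width
  with_seed(seed, function() {
    frames <- vector("list", nf)
    for (t in seq_len(nf)) {
      m <- matrix(arena$background, h, w)
      for (tr in trajectories) {
        px <- ellipse_pixels(tr$x[t], tr$y[t], arena$a, arena$b,
                             tr$theta[t] %% 180, height = h, width = w)
        if (nrow(px)) m[xy_to_idx(px[, 1], px[, 2], h)] <- arena$blob
      }
      if (arena$noise_sd > 0) {
        m <- m + matrix(stats::rnorm(h * w, 0, arena$noise_sd), h, w)
      }
      frames[[t]] <- pmin(pmax(round(m), 0), 255)
    }
    frames
  })
}

#' Simulate a complete labelled image sequence
#'
#' Generates one trajectory per script (seeds derived deterministically
#' from `seed`), renders them into frames, and returns the frames
#' together with the ground-truth table.
#'
#' @param scripts A [behaviour_script()] or list of them (one per animal).
#' @param arena An [arena_spec()].
#' @param seed Master seed.
#' @param starts,headings Optional lists of per-animal initial positions /
#'   headings.
#' @return List with `frames`, `truth` (`data.frame`: frame, cyprid_id,
#'   behaviour, x, y, theta) and `trajectories`.
#' @export
simulate_sequence <- function(scripts, arena = arena_spec(), seed = 1L,
                              starts = NULL, headings = NULL) {
  if (inherits(scripts, "behaviour_script")) scripts <- list(scripts)
  trajs <- vector("list", length(scripts))
  for (i in seq_along(scripts)) {
    trajs[[i]] <- generate_trajectory(
      scripts[[i]], arena, seed = seed + 7919L * i,
      start = if (is.null(starts)) NULL else starts[[i]],
      heading = if (is.null(headings)) NULL else headings[[i]]
    )
  }
  frames <- render_frames(trajs, arena, seed = seed)
  truth <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    data.frame(frame = trajs[[i]]$frame, cyprid_id = i,
               behaviour = trajs[[i]]$behaviour,
               x = trajs[[i]]$x, y = trajs[[i]]$y, theta = trajs[[i]]$theta)
  }))
  list(frames = frames, truth = truth, trajectories = trajs)
}
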