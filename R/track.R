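#' Track all animals through an image sequence
#'
#' Runs background subtraction and segmentation on every frame, associates
#' segments across consecutive frames, and maintains one stable identity
#' per animal. Merged blobs are resolved with [resolve_merge()], splitting
#' blobs with [resolve_split()]. An animal whose segment vanishes keeps
#' its last geometry with provenance `"missed"` for up to
#' `config$miss_patience` frames -- a missed animal's last pixel support
#' still takes part in association, so a brief detection dropout does not
#' break the identity -- after which the track is retired; a later
#' re-appearance mints a new identity. New identities are only minted on
#' entry. All iteration orders are deterministic (lowest id / lowest label
#' first), so the output is a pure function of frames and configuration.
#'
#' @param frames List of grayscale matrices in temporal order.
#' @param config A [run_config()] list.
#' @param bg Optional pre-built [build_background()] model; built from
#'   `frames` if `NULL`.
#' @return `data.frame` with one row per (frame, animal): `frame` (0-based),
#'   `time_s`, `cyprid_id`, `xc`, `yc`, `a`, `b`, `theta_deg` (in
#'   \[0, 180)), `size`, `provenance`.
#' @export
track_sequence <- function(frames, config = run_config(), bg = NULL) {
  check_frames(frames)
  if (is.null(bg)) {
    bg <- build_background(frames, config$diff_threshold, config$max_passes)
  }
  h <- nrow(frames[[1]])
  active <- list()      # by character id: state lists
  next_id <- 1L
  prev_segs <- NULL
  rows <- vector("list", length(frames))

  for (t in seq_along(frames)) {
    ft <- t - 1L
    segs <- tryCatch(
      segment_frame(frames[[t]], bg, config$bin_threshold, config$min_area),
      error = function(e) {
        warning("frame ", ft, " failed segmentation and was skipped: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(segs)) {
      active <- mark_all_missed(active)
      prev_segs <- list()
    } else {
      res <- step_tracker(active, next_id, prev_segs, segs, h, config)
      active <- res$active
      next_id <- res$next_id
      prev_segs <- segs
    }
    active <- retire_expired(active, config$miss_patience)
    rows[[t]] <- states_to_rows(active, ft, config$frame_rate)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(frame = integer(), time_s = numeric(),
                      cyprid_id = integer(), xc = numeric(), yc = numeric(),
                      a = numeric(), b = numeric(), theta_deg = numeric(),
                      size = integer(), provenance = character())
  }
  rownames(out) <- NULL
  attr(out, "background") <- bg
  out
}

# one association + resolution step; returns updated active set and id counter
step_tracker <- function(active, next_id, prev_segs, segs, h, config) {
  updated <- character(0)

  if (length(active)) {
    # old regions: previous segments that carried animals, plus the frozen
    # supports of currently missed animals
    regions <- list()
    region_cyprids <- list()
    if (length(prev_segs)) {
      for (s in prev_segs) {
        ids <- names(active)[vapply(active, function(a)
          identical(a$seg_label, s$label) && a$miss_count == 0L, logical(1))]
        if (length(ids)) {
          regions[[length(regions) + 1L]] <-
            list(label = length(regions) + 1L, idx = s$idx)
          region_cyprids[[length(regions)]] <- ids
        }
      }
    }
    for (id in names(active)) {
      if (active[[id]]$miss_count > 0L) {
        regions[[length(regions) + 1L]] <-
          list(label = length(regions) + 1L, idx = active[[id]]$support_idx)
        region_cyprids[[length(regions)]] <- id
      }
    }
    cases <- associate_segments(regions, segs)
  } else {
    cases <- if (length(segs)) {
      lapply(segs, function(s) list(kind = "entry", old_labels = integer(0),
                                    new_labels = s$label))
    } else list()
    region_cyprids <- list()
  }

  for (cs in cases) {
    ids <- sort(as.integer(unlist(region_cyprids[cs$old_labels])))
    states <- lapply(as.character(ids), function(i) active[[i]])
    new_here <- segs[match(cs$new_labels, vapply(segs, `[[`, integer(1), "label"))]

    if (cs$kind == "entry") {
      fit <- tryCatch(fit_ellipse(new_here[[1]]$coords), error = function(e) NULL)
      if (!is.null(fit)) {
        id <- next_id
        next_id <- next_id + 1L
        active[[as.character(id)]] <- new_state(id, fit, new_here[[1]])
        updated <- c(updated, as.character(id))
      }
    } else if (cs$kind == "exit") {
      # handled below as not-updated -> missed
    } else if (cs$kind %in% c("one_to_one", "merge") ||
               (cs$kind == "complex" && length(cs$new_labels) == 1)) {
      seg <- new_here[[1]]
      if (length(ids) == 1) {
        fit <- tryCatch(fit_ellipse(seg$coords), error = function(e) NULL)
        id <- as.character(ids)
        if (!is.null(fit)) {
          active[[id]] <- new_state(ids, fit, seg)
          updated <- c(updated, id)
        }
      } else {
        resolved <- resolve_merge(seg, states, config$merge_weights, h)
        for (st in resolved) {
          id <- as.character(st$cyprid_id)
          if (st$provenance != "missed") {
            st$miss_count <- 0L
            st$seg_label <- seg$label
            active[[id]] <- st
            updated <- c(updated, id)
          }
        }
      }
    } else {
      # split / complex with several fragments: injective assignment
      sp <- resolve_split(new_here, states, config$split_weights)
      for (r in seq_len(nrow(sp$assignment))) {
        id <- as.character(sp$assignment$cyprid_id[r])
        seg <- new_here[[match(sp$assignment$segment_label[r],
                               vapply(new_here, `[[`, integer(1), "label"))]]
        fit <- tryCatch(fit_ellipse(seg$coords), error = function(e) NULL)
        if (!is.null(fit)) {
          st <- new_state(sp$assignment$cyprid_id[r], fit, seg)
          st$provenance <- "split-assigned"
          active[[id]] <- st
          updated <- c(updated, id)
        }
      }
      for (lab in sp$entry_labels) {
        seg <- new_here[[match(lab, vapply(new_here, `[[`, integer(1), "label"))]]
        fit <- tryCatch(fit_ellipse(seg$coords), error = function(e) NULL)
        if (is.null(fit)) next
        # a leftover fragment first tries to reclaim a nearby missed animal
        # (an animal starved of pixels during the overlap re-emerges here)
        lost <- setdiff(names(active)[vapply(active, function(a)
          a$miss_count > 0L, logical(1))], updated)
        id <- NULL
        if (length(lost)) {
          dd <- vapply(lost, function(i) {
            a <- active[[i]]
            sqrt((a$xc - fit$xc)^2 + (a$yc - fit$yc)^2) /
              (4 * max(a$a, fit$a))
          }, numeric(1))
          cand <- lost[order(dd, as.integer(lost))]
          if (dd[cand[1]] <= 1) id <- as.integer(cand[1])  # within 2 body lengths
        }
        relinked <- !is.null(id)
        if (!relinked) {
          id <- next_id
          next_id <- next_id + 1L
        }
        st <- new_state(id, fit, seg)
        if (relinked) st$provenance <- "split-assigned"
        active[[as.character(id)]] <- st
        updated <- c(updated, as.character(id))
      }
    }
  }

  for (id in setdiff(names(active), updated)) {
    a <- active[[id]]
    a$miss_count <- a$miss_count + 1L
    a$provenance <- "missed"
    a$seg_label <- NA_integer_
    active[[id]] <- a
  }
  # keep deterministic id order
  active <- active[order(as.integer(names(active)))]
  list(active = active, next_id = next_id)
}

new_state <- function(id, fit, seg) {
  list(cyprid_id = as.integer(id), xc = fit$xc, yc = fit$yc, a = fit$a,
       b = fit$b, theta_deg = fit$theta_deg, size = seg$size,
       provenance = "fitted", support_idx = seg$idx,
       miss_count = 0L, seg_label = seg$label)
}

mark_all_missed <- function(active) {
  for (id in names(active)) {
    active[[id]]$miss_count <- active[[id]]$miss_count + 1L
    active[[id]]$provenance <- "missed"
    active[[id]]$seg_label <- NA_integer_
  }
  active
}

retire_expired <- function(active, patience) {
  keep <- vapply(active, function(a) a$miss_count <= patience, logical(1))
  active[keep]
}

states_to_rows <- function(active, frame, frame_rate) {
  if (length(active) == 0) return(NULL)
  data.frame(
    frame = frame,
    time_s = frame / frame_rate,
    cyprid_id = vapply(active, `[[`, integer(1), "cyprid_id"),
    xc = vapply(active, `[[`, numeric(1), "xc"),
    yc = vapply(active, `[[`, numeric(1), "yc"),
    a = vapply(active, `[[`, numeric(1), "a"),
    b = vapply(active, `[[`, numeric(1), "b"),
    theta_deg = vapply(active, `[[`, numeric(1), "theta_deg"),
    size = vapply(active, function(a)
      if (is.null(a$miss_count) || a$miss_count == 0L) as.integer(a$size)
      else as.integer(a$size), integer(1)),
    provenance = vapply(active, `[[`, character(1), "provenance"),
    row.names = NULL
  )
}

#' Track an on-disk image sequence
#'
#' Convenience wrapper: reads a frame directory (or multi-page TIFF),
#' builds the background, tracks, and optionally writes the track table
#' and background image.
#'
#' @param input Path passed to [read_frames()].
#' @param config A [run_config()].
#' @param track_csv,background_png Optional output paths.
#' @return The track `data.frame` (invisibly if outputs are written).
#' @export
track_images <- function(input, config = run_config(),
                         track_csv = NULL, background_png = NULL) {
  frames <- read_frames(input, invert = config$invert)
  trk <- track_sequence(frames, config)
  if (!is.null(background_png)) {
    write_background(attr(trk, "background"), background_png)
  }
  if (!is.null(track_csv)) {
    write_track(trk, track_csv)
    return(invisible(trk))
  }
  trk
}
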