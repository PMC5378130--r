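#' Read and write pipeline tables
#'
#' All tables are plain comma-separated files with a header row, `.`
#' decimal separator, UTF-8 encoding and LF line endings. Times are
#' seconds, coordinates pixels (0-based, x right, y down).
#'
#' @name table-io
NULL

write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname table-io
#' @param track Track table from [track_sequence()].
#' @param path Output/input file path.
#' @export
write_track <- function(track, path) {
  cols <- c("frame", "time_s", "cyprid_id", "xc", "yc", "a", "b",
            "theta_deg", "size", "provenance")
  write_csv_lf(track[, cols], path)
}

#' @rdname table-io
#' @return `read_track()` returns the track `data.frame`; a malformed
#'   file raises an error naming the missing column.
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame", "time_s", "cyprid_id", "xc", "yc", "a", "b",
              "theta_deg", "size", "provenance")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop_invalid("track table lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (col in setdiff(needed, "provenance")) {
    if (!is.numeric(df[[col]])) {
      stop_invalid("track column is not numeric: ", col)
    }
  }
  df
}

#' @rdname table-io
#' @param nodes Node table from [classify_track()].
#' @export
write_nodes <- function(nodes, path) {
  cols <- c("cyprid_id", "source", "node_index", "x", "y",
            "first_frame", "last_frame", "mn", "w", "iw", "csw")
  write_csv_lf(nodes[, intersect(cols, names(nodes))], path)
}

#' @rdname table-io
#' @param events Ethogram event table from [classify_track()].
#' @export
write_ethogram <- function(events, path) {
  cols <- c("cyprid_id", "behaviour", "start_frame", "end_frame",
            "duration_s", "step_count")
  write_csv_lf(events[, intersect(cols, names(events))], path)
}

#' @rdname table-io
#' @param summary Summary table from [summarize_events()].
#' @export
write_summary <- function(summary, path) {
  write_csv_lf(summary, path)
}

#' Classify a track file into ethogram and summary tables
#'
#' CLI-oriented wrapper: reads a track CSV, classifies every animal, and
#' optionally writes the ethogram, node and summary tables.
#'
#' @param track_csv Input track table path (schema of [write_track()]).
#' @param config A [run_config()].
#' @param ethogram_csv,summary_csv,nodes_csv Optional output paths.
#' @return The [classify_track()] result, invisibly when outputs are
#'   written.
#' @export
classify_file <- function(track_csv, config = run_config(),
                          ethogram_csv = NULL, summary_csv = NULL,
                          nodes_csv = NULL) {
  track <- read_track(track_csv)
  res <- classify_track(track, config)
  wrote <- FALSE
  if (!is.null(ethogram_csv)) { write_ethogram(res$events, ethogram_csv); wrote <- TRUE }
  if (!is.null(summary_csv)) {
    write_summary(summarize_events(res$events), summary_csv); wrote <- TRUE
  }
  if (!is.null(nodes_csv)) { write_nodes(res$nodes, nodes_csv); wrote <- TRUE }
  if (wrote) invisible(res) else res
}

#' Simulate a labelled sequence to disk
#'
#' @param scripts,arena,seed As in [simulate_sequence()].
#' @param frames_dir Directory for the rendered PNG frames.
#' @param truth_csv Path for the ground-truth label table.
#' @return The [simulate_sequence()] result, invisibly.
#' @export
simulate_to_disk <- function(scripts, arena = arena_spec(), seed = 1L,
                             frames_dir, truth_csv = NULL) {
  sim <- simulate_sequence(scripts, arena, seed)
  write_frames(sim$frames, frames_dir)
  if (!is.null(truth_csv)) write_csv_lf(sim$truth, truth_csv)
  invisible(sim)
}
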