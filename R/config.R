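#' Pipeline configuration
#'
#' Collects every tunable constant of the tracking and classification
#' pipeline in one list, with the published operating values as defaults
#' where the method defines one (node radius 1.7 px, minimum node
#' membership 14 points, inspection angle threshold 30 degrees, step-length
#' ratio threshold 0.2, maximum-change threshold 0.3, step factor 0.85 of
#' the body length, close-search chain gate of 4 steps, 33 frames per
#' second). Image thresholds, cost-function weights and the miss patience
#' are not published; their defaults are documented package choices.
#'
#' @param diff_threshold Intensity difference (0-255 scale) above which a
#'   pixel is considered brighter than the current background during
#'   background modelling.
#' @param bin_threshold Intensity difference above which a pixel of
#'   `background - frame` is declared foreground during segmentation.
#'   Default is half the nominal blob/background contrast of the synthetic
#'   renderer (200 - 60 = 140, so 70).
#' @param min_area Minimum segment size in pixels; smaller components are
#'   discarded. The imaging requirement that each animal boundary span at
#'   least five pixels motivates the default of 5.
#' @param max_passes Upper bound on background-update passes before the
#'   model is returned unconverged.
#' @param invert Set `TRUE` for bright animals on a dark background; frames
#'   are inverted on ingestion rather than branching the algorithms.
#' @param merge_weights Numeric vector `c(a1, a2, a3)` weighting the merge
#'   cost `W = a1*N_black + a2*N_white - a3*N_cyprid`.
#' @param split_weights Numeric vector `c(w1, w2, w3)` weighting the split
#'   cost `Et = w1*Es + w2*Ed + w3*Ep`.
#' @param miss_patience Frames a vanished animal is retained (geometry
#'   frozen, provenance `"missed"`) before its track is retired.
#' @param dis_th Node radius in pixels.
#' @param mn_th Minimum number of node members.
#' @param strict_mn If `TRUE` (default) a node needs strictly more than
#'   `mn_th` members; if `FALSE`, at least `mn_th`.
#' @param angle_threshold_deg Minimum angular range swept about a terminal
#'   node for it to count as inspection.
#' @param ratio_threshold Upper bound on sd/mean of four consecutive step
#'   lengths in wide search.
#' @param mc_threshold Upper bound on the maximum relative deviation of step
#'   length from `step_factor * CL` in wide search.
#' @param step_factor Nominal step length as a fraction of the body length
#'   CL.
#' @param chain_steps Close-search chaining gate, expressed in steps: two
#'   inspection nodes chain when closer than `chain_steps * step_factor *
#'   CL`.
#' @param inspection_member_cap_s Inspection nodes whose dwell exceeds this
#'   many seconds are never absorbed into a close-search chain. Stored in
#'   seconds so it tracks the frame rate.
#' @param max_step_gap_s Maximum time gap between two consecutive nodes for
#'   them to count as a step (wide-search windows) or as chainable
#'   neighbours (close-search). Without this gate a swimming excursion that
#'   happens to return near its point of departure would be bridged into a
#'   walking or close-search event on spatial evidence alone.
#' @param frame_rate Frames per second of the sequence.
#' @param seed Integer seed recorded with the configuration.
#' @return A list of class `cypridtrack_config`.
#' @seealso [read_config()], [write_config()]
#' @export
run_config <- function(diff_threshold = 30,
                       bin_threshold = 70,
                       min_area = 5,
                       max_passes = 50,
                       invert = FALSE,
                       merge_weights = c(a1 = 1, a2 = 1, a3 = 1),
                       split_weights = c(w1 = 1, w2 = 1, w3 = 1),
                       miss_patience = 10,
                       dis_th = 1.7,
                       mn_th = 14,
                       strict_mn = TRUE,
                       angle_threshold_deg = 30,
                       ratio_threshold = 0.2,
                       mc_threshold = 0.3,
                       step_factor = 0.85,
                       chain_steps = 4,
                       inspection_member_cap_s = 20,
                       max_step_gap_s = 2,
                       frame_rate = 33,
                       seed = 1L) {
  cfg <- list(
    diff_threshold = diff_threshold,
    bin_threshold = bin_threshold,
    min_area = min_area,
    max_passes = max_passes,
    invert = invert,
    merge_weights = stats::setNames(as.numeric(merge_weights), c("a1", "a2", "a3")),
    split_weights = stats::setNames(as.numeric(split_weights), c("w1", "w2", "w3")),
    miss_patience = miss_patience,
    dis_th = dis_th,
    mn_th = mn_th,
    strict_mn = strict_mn,
    angle_threshold_deg = angle_threshold_deg,
    ratio_threshold = ratio_threshold,
    mc_threshold = mc_threshold,
    step_factor = step_factor,
    chain_steps = chain_steps,
    inspection_member_cap_s = inspection_member_cap_s,
    max_step_gap_s = max_step_gap_s,
    frame_rate = frame_rate,
    seed = as.integer(seed)
  )
  stopifnot(cfg$dis_th > 0, cfg$mn_th >= 1, cfg$frame_rate > 0,
            all(cfg$merge_weights > 0), all(cfg$split_weights > 0))
  class(cfg) <- "cypridtrack_config"
  cfg
}

#' Read a configuration from YAML or JSON
#'
#' Unknown keys raise an error; missing keys keep their defaults, so the
#' round trip `write_config(); read_config()` is lossless.
#'
#' @param path File with extension `.yaml`, `.yml` or `.json`.
#' @return A `cypridtrack_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_invalid("config file must be .yaml, .yml or .json: ", path)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_invalid("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Write a configuration to YAML or JSON
#'
#' @param config A `cypridtrack_config` list.
#' @param path Destination, extension selects the format.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cypridtrack_config"))
  x <- unclass(config)
  x$merge_weights <- as.list(x$merge_weights)
  x$split_weights <- as.list(x$split_weights)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop_invalid("config file must be .yaml, .yml or .json: ", path)
  }
  invisible(path)
}

#' @export
print.cypridtrack_config <- function(x, ...) {
  cat("cypridtrack configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# internal error helpers: classed conditions so callers can test precisely
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cypridtrack_invalid_input", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("cypridtrack_degenerate_geometry", "error")))
}
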