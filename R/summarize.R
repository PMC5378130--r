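#' Summarize behaviour events in the style of a results table
#'
#' For each behaviour (and optional experimental condition) reports the
#' event count, the total -- steps for wide search, seconds for the
#' other behaviours -- and the average per event. Averages are truncated
#' toward zero, matching the convention of reporting 1949 s over 11
#' events as an average of 177 s and 45 s over 2 events as 22 s.
#' Behaviours with no events keep `NA` totals and averages (printed as
#' an em-dash in the original layout).
#'
#' @param events Event `data.frame` (see [classify_track()]); an optional
#'   `condition` column splits the summary.
#' @param behaviours Behaviours to report, in row order.
#' @return `data.frame` with `condition` (if present), `behaviour`,
#'   `event_number`, `total`, `average`, `unit`.
#' @examples
#' ev <- data.frame(behaviour = "inspection",
#'                  duration_s = c(300, 200, 149), step_count = NA)
#' summarize_events(ev)
#' @export
summarize_events <- function(events,
                             behaviours = c("wide_search", "close_search",
                                            "inspection")) {
  conds <- if ("condition" %in% names(events)) unique(events$condition) else NA
  out <- list()
  for (cond in conds) {
    ev <- if (is.na(cond[1])) events else events[events$condition == cond, ]
    for (b in behaviours) {
      e <- ev[ev$behaviour == b, , drop = FALSE]
      n <- nrow(e)
      unit <- if (b == "wide_search") "step" else "s"
      total <- if (n == 0) NA_real_ else if (b == "wide_search") {
        sum(e$step_count)
      } else {
        sum(e$duration_s)
      }
      avg <- if (n == 0) NA_real_ else trunc(total / n)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, behaviour = b, event_number = n,
        total = total, average = avg, unit = unit
      )
    }
  }
  res <- do.call(rbind, out)
  if (all(is.na(res$condition))) res$condition <- NULL
  rownames(res) <- NULL
  res
}
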