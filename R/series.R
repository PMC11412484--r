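#' Construct a single event's annual-best series
#'
#' An `annual_best_series` holds the best mark achieved in one event in each
#' calendar year, together with its optimization direction (`minimize` for
#' timed events, `maximize` for jumps) and unit. This is the unit of
#' observation for everything downstream: record-evolution statistics,
#' extreme-value prediction, and the relative-fluctuation network.
#'
#' @param event_id Short string key (e.g. `"marathon"`).
#' @param marks Numeric vector of strictly positive annual best marks, named
#'   by year, or unnamed with `years` supplied.
#' @param direction `"minimize"` or `"maximize"`.
#' @param unit `"seconds"` or `"meters"`.
#' @param years Integer years, required when `marks` is unnamed.
#' @param year_range Declared admissible range of years (inclusive bounds).
#' @return An `annual_best_series` object.
#' @examples
#' annual_best_series("high_jump", c(`1992` = 2.34, `1993` = 2.45),
#'                    direction = "maximize", unit = "meters")
#' @export
annual_best_series <- function(event_id, marks,
                               direction = c("minimize", "maximize"),
                               unit = c("seconds", "meters"),
                               years = NULL,
                               year_range = c(1992L, 2018L)) {
  direction <- match.arg(direction)
  unit <- match.arg(unit)
  if (!is.null(years)) {
    names(marks) <- years
  }
  yrs <- suppressWarnings(as.integer(names(marks)))
  if (is.null(names(marks)) || anyNA(yrs)) {
    stop("marks must be named by (integer) year, or 'years' supplied",
         call. = FALSE)
  }
  marks <- as.numeric(marks)
  names(marks) <- yrs
  x <- structure(
    list(event_id = as.character(event_id), direction = direction,
         unit = unit, marks = marks[order(yrs)],
         year_range = as.integer(year_range)),
    class = "annual_best_series")
  validate_series(x)
}

validate_series <- function(x) {
  yrs <- series_years(x)
  if (anyNA(x$marks) || any(x$marks <= 0)) {
    stop(sprintf("event '%s': all marks must be strictly positive", x$event_id),
         call. = FALSE)
  }
  if (anyDuplicated(yrs)) {
    dup <- yrs[duplicated(yrs)][1]
    stop(sprintf("event '%s': duplicate year %d", x$event_id, dup), call. = FALSE)
  }
  out <- yrs < x$year_range[1] | yrs > x$year_range[2]
  if (any(out)) {
    stop(sprintf("event '%s': year %d outside declared range %d-%d",
                 x$event_id, yrs[out][1], x$year_range[1], x$year_range[2]),
         call. = FALSE)
  }
  invisible(x)
}

series_years <- function(x) as.integer(names(x$marks))

#' @export
print.annual_best_series <- function(x, ...) {
  yrs <- series_years(x)
  cat(sprintf("<annual_best_series> %s (%s, %s): %d years %d-%d\n",
              x$event_id, x$direction, x$unit, length(yrs),
              min(yrs), max(yrs)))
  invisible(x)
}

#' Extract a mark for a given year
#'
#' @param series An [annual_best_series()].
#' @param year Integer year.
#' @return The mark; errors (naming event and year) if absent.
#' @export
series_mark <- function(series, year) {
  m <- series$marks[as.character(year)]
  if (anyNA(m)) {
    stop(sprintf("event '%s': no mark for year %s", series$event_id,
                 paste(year[is.na(m)], collapse = ", ")), call. = FALSE)
  }
  unname(m)
}

# Marks on the internal maximize scale: times are negated so that "better"
# is always "larger" and one set of order-statistic formulas applies.
internal_marks <- function(series) {
  if (series$direction == "minimize") -series$marks else series$marks
}

#' Bundle series into a panel
#'
#' A `record_panel` is a named list of [annual_best_series()] objects, one
#' per event, optionally carrying the event catalog that fixes display order.
#'
#' @param series List of `annual_best_series`.
#' @param catalog Optional catalog tibble (see [event_catalog()]); when given,
#'   the panel is ordered by catalog index and every event must appear in it.
#' @return A `record_panel`.
#' @export
record_panel <- function(series, catalog = NULL) {
  ids <- vapply(series, function(s) s$event_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate event_id in panel: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(series) <- ids
  if (!is.null(catalog)) {
    validate_catalog(catalog)
    unknown <- setdiff(ids, catalog$event_id)
    if (length(unknown)) {
      stop("events not in catalog: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    keep <- catalog$event_id[catalog$event_id %in% ids]
    series <- series[order(match(ids, keep))]
  }
  structure(series, class = "record_panel", catalog = catalog)
}

#' @export
print.record_panel <- function(x, ...) {
  yrs <- range(unlist(lapply(x, series_years)))
  cat(sprintf("<record_panel> %d events, years %d-%d\n", length(x),
              yrs[1], yrs[2]))
  invisible(x)
}

#' @export
`[.record_panel` <- function(x, i) {
  record_panel(unclass(x)[i], catalog = attr(x, "catalog"))
}

panel_catalog <- function(panel) attr(panel, "catalog")

# catalog legend index per event (used for rank tie-breaks); events absent
# from the catalog fall back to panel position
panel_index <- function(panel) {
  ids <- names(panel)
  catalog <- panel_catalog(panel)
  if (is.null(catalog)) return(stats::setNames(seq_along(ids), ids))
  stats::setNames(catalog$index[match(ids, catalog$event_id)], ids)
}
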