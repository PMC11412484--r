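#' Read an annual-best panel from CSV
#'
#' The schema is long format with a mandatory header and columns
#' `event_id,year,mark` (plus an optional `unit` column, which must agree
#' with the catalog). Marks may be written in any dialect accepted by
#' [parse_mark()], so `"2:03:38"` and `"7418"` both work for a marathon.
#'
#' @param file Path or connection to a CSV file.
#' @param catalog Catalog tibble; every `event_id` in the file must appear in
#'   it, and direction/unit are taken from it.
#' @param year_range Admissible years (inclusive bounds).
#' @return A [record_panel()] with one series per event present in the file.
#' @export
read_annual_bests <- function(file, catalog = event_catalog(),
                              year_range = c(1992L, 2018L)) {
  validate_catalog(catalog)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("event_id", "year", "mark")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("panel CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  row_no <- seq_len(nrow(df)) + 1L  # header is line 1
  unknown <- !(df$event_id %in% catalog$event_id)
  if (any(unknown)) {
    stop(sprintf("row %d: unknown event_id '%s'", row_no[unknown][1],
                 df$event_id[unknown][1]), call. = FALSE)
  }
  dup <- duplicated(df[c("event_id", "year")])
  if (any(dup)) {
    stop(sprintf("row %d: duplicate (event, year) pair (%s, %s)",
                 row_no[dup][1], df$event_id[dup][1], df$year[dup][1]),
         call. = FALSE)
  }
  year <- suppressWarnings(as.integer(df$year))
  if (anyNA(year)) {
    stop(sprintf("row %d: malformed year '%s'", row_no[is.na(year)][1],
                 df$year[is.na(year)][1]), call. = FALSE)
  }
  series <- lapply(split(seq_len(nrow(df)), df$event_id), function(rows) {
    id <- df$event_id[rows[1]]
    meta <- catalog[catalog$event_id == id, ]
    marks <- vapply(rows, function(r) {
      tryCatch(parse_mark1(df$mark[r], meta$unit),
               error = function(e) stop(sprintf("row %d: %s", row_no[r],
                                                conditionMessage(e)),
                                        call. = FALSE))
    }, numeric(1))
    annual_best_series(id, marks, direction = meta$direction,
                       unit = meta$unit, years = year[rows],
                       year_range = year_range)
  })
  record_panel(series, catalog = catalog)
}

#' Write an annual-best panel to CSV
#'
#' Marks are written as plain decimals (full double precision), so a panel
#' round-trips through [read_annual_bests()] exactly.
#'
#' @param panel A [record_panel()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_annual_bests <- function(panel, file) {
  df <- panel_to_df(panel)
  df$mark <- format_mark_full(df$mark)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# long-format view of a panel
panel_to_df <- function(panel) {
  do.call(rbind, lapply(unname(unclass(panel)), function(s) {
    data.frame(event_id = s$event_id, year = series_years(s),
               mark = unname(s$marks), unit = s$unit,
               stringsAsFactors = FALSE)
  }))
}

# enough digits that as.numeric() recovers the exact double
format_mark_full <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE),
         character(1))
}
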