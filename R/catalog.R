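#' The 24-event catalog
#'
#' Returns the roster of men's track, field and swimming events analysed by
#' the package: eight track events (sprints, middle/long distance running,
#' marathon, hurdles), three jumps and thirteen swimming events. The index
#' column (1-24) is the conventional legend ordering used in correlation
#' figures; timed events are `minimize` (a smaller mark is better), jumps are
#' `maximize`.
#'
#' @param path Optional path to a catalog CSV with columns
#'   `index,event_id,name,category,direction,unit`. Defaults to the packaged
#'   24-event roster.
#' @return A tibble with one row per event, validated (unique ids, contiguous
#'   indices when the full roster is loaded, unit consistent with direction).
#' @examples
#' event_catalog()
#' @export
event_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "event_catalog.csv", package = "recordnet",
                        mustWork = TRUE)
  }
  cat_df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("index", "event_id", "name", "category", "direction", "unit")
  missing <- setdiff(required, names(cat_df))
  if (length(missing)) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cat_df <- tibble::as_tibble(cat_df[required])
  validate_catalog(cat_df)
  cat_df
}

validate_catalog <- function(catalog) {
  if (anyDuplicated(catalog$event_id)) {
    stop("catalog event_ids must be unique", call. = FALSE)
  }
  if (!all(catalog$direction %in% c("minimize", "maximize"))) {
    stop("catalog direction must be 'minimize' or 'maximize'", call. = FALSE)
  }
  if (!all(catalog$unit %in% c("seconds", "meters"))) {
    stop("catalog unit must be 'seconds' or 'meters'", call. = FALSE)
  }
  # full roster must carry the contiguous 1..24 legend indexing
  if (nrow(catalog) == 24 && !identical(sort(catalog$index), 1:24)) {
    stop("full 24-event catalog must have indices exactly 1..24", call. = FALSE)
  }
  bad <- catalog$direction == "minimize" & catalog$unit != "seconds"
  if (any(bad)) {
    stop("minimize (timed) events must be measured in seconds: ",
         paste(catalog$event_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(catalog)
}
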