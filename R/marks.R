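#' Parse a performance mark
#'
#' Converts a mark written in any of the common federation dialects into a
#' single positive number in SI units: seconds for timed events, meters for
#' jumps. Accepted dialects are a plain decimal (`"8.95"`, `"9.58"`), a
#' minutes string `"M:SS.ff"` (`"1:45.20"` is 105.20 s) and an hours string
#' `"H:MM:SS"` (`"2:03:38"` is 7418 s, the usual way marathon marks are
#' printed).
#'
#' @param text Character vector of mark strings.
#' @param unit `"seconds"` or `"meters"`. Sexagesimal dialects are only
#'   meaningful for `"seconds"`; a colon in a meters mark is an error.
#' @return Numeric vector of positive marks in SI units.
#' @examples
#' parse_mark("8.95", "meters")
#' parse_mark(c("9.58", "1:45.20", "2:03:38"), "seconds")
#' @export
parse_mark <- function(text, unit = c("seconds", "meters")) {
  unit <- match.arg(unit)
  vapply(as.character(text), parse_mark1, numeric(1), unit = unit,
         USE.NAMES = FALSE)
}

parse_mark1 <- function(text, unit) {
  raw <- trimws(text)
  if (is.na(raw) || !nzchar(raw)) {
    stop("empty or missing mark", call. = FALSE)
  }
  parts <- strsplit(raw, ":", fixed = TRUE)[[1]]
  if (length(parts) > 1 && unit == "meters") {
    stop(sprintf("mark '%s': sexagesimal notation is not valid for meters", raw),
         call. = FALSE)
  }
  if (length(parts) > 3) {
    stop(sprintf("mark '%s': too many ':' separated fields", raw), call. = FALSE)
  }
  num <- function(tok, integer_only = FALSE) {
    pat <- if (integer_only) "^[0-9]+$" else "^[0-9]+(\\.[0-9]+)?$"
    if (!grepl(pat, tok)) {
      stop(sprintf("mark '%s': malformed component '%s'", raw, tok), call. = FALSE)
    }
    as.numeric(tok)
  }
  value <- switch(as.character(length(parts)),
    "1" = num(parts[1]),
    # M:SS.ff — seconds field must stay below 60
    "2" = {
      m <- num(parts[1], integer_only = TRUE)
      s <- num(parts[2])
      if (s >= 60) stop(sprintf("mark '%s': seconds field %s >= 60", raw, parts[2]),
                        call. = FALSE)
      60 * m + s
    },
    # H:MM:SS(.ff)
    "3" = {
      h <- num(parts[1], integer_only = TRUE)
      m <- num(parts[2], integer_only = TRUE)
      s <- num(parts[3])
      if (m >= 60) stop(sprintf("mark '%s': minutes field %s >= 60", raw, parts[2]),
                        call. = FALSE)
      if (s >= 60) stop(sprintf("mark '%s': seconds field %s >= 60", raw, parts[3]),
                        call. = FALSE)
      3600 * h + 60 * m + s
    })
  if (!is.finite(value) || value <= 0) {
    stop(sprintf("mark '%s': marks must be strictly positive", raw), call. = FALSE)
  }
  value
}
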