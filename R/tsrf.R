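#' Time series of relative fluctuation (TSRF)
#'
#' Divides every year's mark by the baseline-year mark, turning each event
#' into a dimensionless series comparable across units and distances. For
#' timed (`minimize`) events the ratio is `x_j / x_i`; for jumps
#' (`maximize`) the reciprocal `x_i / x_j` is used, so that improvement
#' lowers the value for every event alike and the transform stays positive
#' and scale-free. The baseline year itself is excluded from the output
#' (its value would identically be 1).
#'
#' @param panel A [record_panel()]; every series must contain the baseline
#'   year and every year must be present in all series (no imputation).
#' @param baseline_year Baseline year `i` (default 1992).
#' @return A `tsrf_matrix`: numeric matrix, events in rows (panel order) and
#'   years in columns, with attribute `baseline_year`.
#' @export
compute_tsrf <- function(panel, baseline_year = 1992L) {
  baseline_year <- as.integer(baseline_year)
  year_sets <- lapply(panel, series_years)
  years <- sort(unique(unlist(year_sets)))
  for (id in names(panel)) {
    if (!(baseline_year %in% year_sets[[id]])) {
      stop(sprintf("event '%s': baseline year %d missing", id, baseline_year),
           call. = FALSE)
    }
    gap <- setdiff(years, year_sets[[id]])
    if (length(gap)) {
      stop(sprintf("event '%s': missing year %d (no imputation)", id, gap[1]),
           call. = FALSE)
    }
  }
  keep <- setdiff(years, baseline_year)
  values <- do.call(rbind, lapply(unname(unclass(panel)), function(s) {
    xi <- series_mark(s, baseline_year)
    xj <- series_mark(s, keep)
    if (s$direction == "minimize") xj / xi else xi / xj
  }))
  dimnames(values) <- list(names(panel), keep)
  structure(values, baseline_year = baseline_year, class = "tsrf_matrix")
}

#' @export
print.tsrf_matrix <- function(x, ...) {
  cat(sprintf("<tsrf_matrix> %d events x %d years (baseline %d)\n",
              nrow(x), ncol(x), attr(x, "baseline_year")))
  invisible(x)
}

#' Pairwise Pearson correlation of TSRF rows
#'
#' Pearson correlation between every pair of event fluctuation series over
#' the shared year axis, with two-sided p-values from the usual
#' t-transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param tsrf A `tsrf_matrix` (or any numeric matrix with events in rows);
#'   needs at least 3 years and no zero-variance row.
#' @return List with symmetric matrices `R` (unit diagonal) and `p` (zero
#'   diagonal), and `n_years`.
#' @export
correlation_matrix <- function(tsrf) {
  m <- unclass(tsrf)
  n <- ncol(m)
  if (n < 3) stop("need at least 3 shared years for correlation", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance TSRF (correlation undefined) for event: ",
         rownames(m)[v == 0][1], call. = FALSE)
  }
  R <- stats::cor(t(m))
  r_off <- pmin(pmax(R, -1), 1)
  tstat <- abs(r_off) * sqrt((n - 2) / pmax(1 - r_off^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  diag(R) <- 1
  diag(p) <- 0
  list(R = R, p = p, n_years = n)
}
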