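#' Percent change in a record between two years
#'
#' Signed percent change between a baseline and a target year, expressed on
#' the baseline mark's scale and oriented so that positive always means
#' improvement: for timed (`minimize`) events a drop from 100 to 90 is +10%,
#' for jumps (`maximize`) a rise from 8.00 to 8.40 is +5%. Negative values
#' are "negative growth" — the target-year record is worse than the baseline.
#'
#' @param series An [annual_best_series()].
#' @param baseline_year,target_year Years present in the series.
#' @return Signed percent (e.g. `10` for a 10% improvement).
#' @export
improvement_percent <- function(series, baseline_year, target_year) {
  base <- series_mark(series, baseline_year)
  target <- series_mark(series, target_year)
  if (series$direction == "minimize") {
    100 * (base - target) / base
  } else {
    100 * (target - base) / base
  }
}

#' Compare two equal-length year spans across a panel
#'
#' Pairs the k-th year of `span_a` with the k-th year of `span_b` and
#' computes [improvement_percent()] for every pair and event, plus the
#' per-event arithmetic mean. This is the span-wise "magnitude of change"
#' summary: with the default spans 1992-2005 vs 2005-2018, the pair
#' (1992, 2005) measures the first 13 years and (2005, 2018) the second.
#'
#' @param panel A [record_panel()].
#' @param span_a,span_b Integer year vectors of equal length (baseline span
#'   first; the denominator of every percent is the `span_a` mark).
#' @return A `span_comparison`: tibble with columns `event_id`, `n_pairs`,
#'   `mean_change`, carrying the full pair table in `attr(, "pairs")`.
#' @export
compare_spans <- function(panel, span_a = 1992:2005, span_b = 2005:2018) {
  span_a <- as.integer(span_a)
  span_b <- as.integer(span_b)
  if (length(span_a) != length(span_b)) {
    stop(sprintf("spans must have equal length (%d vs %d)",
                 length(span_a), length(span_b)), call. = FALSE)
  }
  if (length(span_a) == 0 || length(panel) == 0) {
    stop("empty span or empty panel", call. = FALSE)
  }
  pairs <- do.call(rbind, lapply(unname(unclass(panel)), function(s) {
    change <- vapply(seq_along(span_a), function(k) {
      improvement_percent(s, span_a[k], span_b[k])
    }, numeric(1))
    data.frame(event_id = s$event_id, year_a = span_a, year_b = span_b,
               change = change, stringsAsFactors = FALSE)
  }))
  summary <- tibble::tibble(
    event_id = names(panel),
    n_pairs = length(span_a),
    mean_change = unname(vapply(split(pairs$change, pairs$event_id)[names(panel)],
                                mean, numeric(1))))
  structure(summary, pairs = tibble::as_tibble(pairs),
            index = panel_index(panel),
            class = c("span_comparison", class(summary)))
}

#' Rank events by mean span-wise improvement
#'
#' Rank 1 is the event with the largest mean improvement. Ties are broken by
#' catalog legend index (or panel position when no catalog is attached), so
#' the ranking is always a full permutation.
#'
#' @param comparison A `span_comparison` from [compare_spans()].
#' @return Tibble `event_id`, `mean_change`, `rank`, sorted by rank.
#' @export
rank_events <- function(comparison) {
  if (!inherits(comparison, "span_comparison") || nrow(comparison) == 0) {
    stop("rank_events needs a non-empty span_comparison", call. = FALSE)
  }
  idx <- attr(comparison, "index")[comparison$event_id]
  ord <- order(-comparison$mean_change, idx)
  out <- tibble::tibble(event_id = comparison$event_id[ord],
                        mean_change = comparison$mean_change[ord],
                        rank = seq_along(ord))
  out
}

#' Headline record-evolution figures for a real panel
#'
#' Computes, from a user-supplied panel in the standard CSV schema, the
#' summary quantities usually quoted for the 1992-2018 period: the 2018 vs
#' 1992 improvement of the 200m backstroke and of the marathon, the ratio of
#' the 400m freestyle improvement to the 100m sprint improvement, and the
#' marathon's rank under the 1992-2002 vs 2018-2008 span pairing (second
#' span reversed, so 1992 pairs with 2018). These depend on externally
#' curated federation annual-best lists and are not computable from
#' synthetic panels.
#'
#' @param panel A [record_panel()] containing at least the events involved.
#' @return Tibble with columns `quantity` and `value`.
#' @export
evolution_headlines <- function(panel) {
  need <- c("back_200m", "marathon", "free_400m", "sprint_100m")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop("panel lacks required events: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  imp <- function(id) improvement_percent(panel[[id]], 1992, 2018)
  cmp <- compare_spans(panel, span_a = 1992:2002, span_b = 2018:2008)
  ranks <- rank_events(cmp)
  tibble::tibble(
    quantity = c("back_200m_improvement_pct", "marathon_improvement_pct",
                 "free400_over_sprint100_ratio", "marathon_rank"),
    value = c(imp("back_200m"), imp("marathon"),
              imp("free_400m") / imp("sprint_100m"),
              ranks$rank[ranks$event_id == "marathon"]))
}
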