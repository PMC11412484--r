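test_that("series construction enforces the panel invariants", {
  expect_error(toy_series(c(10, -1, 9)), "strictly positive")
  expect_error(toy_series(c(10, 9), years = c(1992, 1992)), "duplicate year")
  expect_error(toy_series(c(10, 9), years = c(1980, 1993)), "outside declared range")
  s <- toy_series(c(10, 9, 8))
  expect_s3_class(s, "annual_best_series")
  expect_error(series_mark(s, 2000), "no mark for year 2000")
})

test_that("the 24-event catalog loads with legend indices and typed events", {
  catalog <- event_catalog()
  expect_equal(nrow(catalog), 24)
  expect_equal(catalog$index, 1:24)
  expect_equal(sum(catalog$direction == "maximize"), 3)  # the three jumps
  expect_equal(sum(catalog$category == "swim"), 13)
  expect_true(all(catalog$unit[catalog$direction == "minimize"] == "seconds"))
})

test_that("reading a toy CSV maps rows to series and flags bad rows", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("event_id,year,mark",
               "marathon,1992,2:10:00",
               "marathon,1993,2:09:30",
               "marathon,1994,2:08:45"), csv)
  panel <- read_annual_bests(csv)
  expect_length(panel, 1)
  expect_equal(unname(panel$marathon$marks),
               c(2 * 3600 + 600, 2 * 3600 + 570, 2 * 3600 + 525))

  writeLines(c("event_id,year,mark", "marathon,1992,2:10:00",
               "marathon,1992,2:09:00"), csv)
  expect_error(read_annual_bests(csv), "row 3.*duplicate")
  writeLines(c("event_id,year,mark", "tiddlywinks,1992,10"), csv)
  expect_error(read_annual_bests(csv), "row 2.*unknown event_id")
  writeLines(c("event_id,year,mark", "marathon,1992,2:xx:00"), csv)
  expect_error(read_annual_bests(csv), "row 2.*malformed")
})

test_that("a full synthetic panel round-trips through write-then-read exactly", {
  panel <- simulate_panel(default_panel_spec(seed = 11),
                          catalog = event_catalog())
  csv <- tempfile(fileext = ".csv")
  write_annual_bests(panel, csv)
  back <- read_annual_bests(csv)
  expect_identical(names(back), names(panel))
  for (id in names(panel)) {
    expect_identical(back[[id]]$marks, panel[[id]]$marks)
    expect_identical(back[[id]]$direction, panel[[id]]$direction)
  }
})

test_that("improvement_percent is signed, direction-aware and baseline-scaled", {
  tmin <- toy_series(c(100, 90))
  tmax <- toy_series(c(8.00, 8.40), direction = "maximize")
  expect_equal(improvement_percent(tmin, 1992, 1993), 10)
  expect_equal(improvement_percent(tmax, 1992, 1993), 5)
  expect_equal(improvement_percent(toy_series(c(7, 7)), 1992, 1993), 0)
  # worse marks report negative growth
  expect_equal(improvement_percent(toy_series(c(100, 110)), 1992, 1993), -10)
  expect_error(improvement_percent(tmin, 1992, 2000), "no mark for year")
  # same relative move on their own scales is positive for both directions
  expect_gt(improvement_percent(toy_series(c(100, 90)), 1992, 1993), 0)
  expect_gt(improvement_percent(toy_series(c(90, 100), direction = "maximize"),
                                1992, 1993), 0)
})

test_that("compare_spans pairs years positionally and averages per event", {
  s <- toy_series(c(100, 100, 90, 80), years = 1992:1995)
  panel <- record_panel(list(s))
  cmp <- compare_spans(panel, span_a = 1992:1993, span_b = 1994:1995)
  pairs <- attr(cmp, "pairs")
  expect_equal(pairs$change, c(10, 20))
  expect_equal(cmp$mean_change, 15)

  const <- record_panel(list(toy_series(rep(5, 4), years = 1992:1995)))
  cmp0 <- compare_spans(const, 1992:1993, 1994:1995)
  expect_equal(attr(cmp0, "pairs")$change, c(0, 0))
  expect_equal(cmp0$mean_change, 0)
  expect_error(compare_spans(panel, 1992:1993, 1994:1996), "equal length")
})

test_that("rank_events is a dense catalog-tie-broken permutation", {
  mk <- function(id, m1, m2) toy_series(c(m1, m2), id = id, years = c(1992, 1993))
  panel <- record_panel(list(mk("a", 100, 95), mk("b", 100, 97), mk("c", 100, 93)))
  cmp <- compare_spans(panel, 1992, 1993)  # means: a 5, b 3, c 7
  r <- rank_events(cmp)
  expect_equal(r$event_id, c("c", "a", "b"))
  expect_equal(r$rank, 1:3)
  expect_setequal(r$event_id, names(panel))
  expect_equal(r$mean_change[1], max(cmp$mean_change))
  # tie-break by panel position when means are equal
  tied <- record_panel(list(mk("y", 100, 95), mk("x", 100, 95)))
  expect_equal(rank_events(compare_spans(tied, 1992, 1993))$event_id, c("y", "x"))
  single <- rank_events(compare_spans(record_panel(list(mk("only", 10, 9))),
                                      1992, 1993))
  expect_equal(single$rank, 1)
})

test_that("synthetic drifting panels rank by planted drift and scale with it", {
  mk_panel <- function(drifts, seed) {
    events <- tibble::tibble(event_id = paste0("ev", seq_along(drifts)),
                             direction = "minimize", unit = "seconds",
                             level = 100, sigma = 0.05, drift = drifts)
    simulate_panel(panel_spec(events, seed = seed))
  }
  # strictly ordered drifts -> ranking equals drift order (tiny noise)
  panel <- mk_panel(c(0.1, 0.4, 0.2, 0.3), seed = 5)
  r <- rank_events(compare_spans(panel))
  expect_equal(r$event_id, c("ev2", "ev4", "ev3", "ev1"))
  # mean change grows with drift magnitude
  lo <- compare_spans(mk_panel(rep(0.05, 3), seed = 9))
  hi <- compare_spans(mk_panel(rep(0.3, 3), seed = 9))
  expect_true(all(hi$mean_change > lo$mean_change))
})

test_that("evolution headline machinery computes the documented quantities", {
  catalog <- event_catalog()
  years <- 1992:2018
  mk <- function(id, start, annual_gain_pct) {
    meta <- catalog[catalog$event_id == id, ]
    sgn <- if (meta$direction == "minimize") -1 else 1
    marks <- start * (1 + sgn * annual_gain_pct / 100)^(years - 1992)
    annual_best_series(id, marks, direction = meta$direction,
                       unit = meta$unit, years = years)
  }
  panel <- record_panel(list(mk("back_200m", 120, 0.4), mk("marathon", 7800, 0.2),
                             mk("free_400m", 225, 0.3), mk("sprint_100m", 9.9, 0.1)),
                        catalog = catalog)
  h <- evolution_headlines(panel)
  expect_equal(h$value[h$quantity == "back_200m_improvement_pct"],
               100 * (1 - (1 - 0.004)^26))
  expect_equal(h$value[h$quantity == "marathon_improvement_pct"],
               100 * (1 - (1 - 0.002)^26))
  ratio <- (1 - (1 - 0.003)^26) / (1 - (1 - 0.001)^26)
  expect_equal(h$value[h$quantity == "free400_over_sprint100_ratio"], ratio)
  # marathon has the second-smallest improvement rate of the four
  expect_equal(h$value[h$quantity == "marathon_rank"], 3)
})
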