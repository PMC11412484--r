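#' Specify a synthetic annual-best panel
#'
#' A `panel_spec` describes the generative model the analysis assumes: each
#' event's annual best is a Gaussian fluctuation around a level that is
#' either stationary (the null regime, `drift = 0`) or improving linearly
#' (`drift` > 0, in the event's units per year, applied in the
#' direction-appropriate sign so positive drift always means improvement).
#' Fluctuations may be correlated across events through `correlation`, and
#' are independent across years.
#'
#' @param events Data frame / tibble with columns `event_id`, `direction`,
#'   `unit`, `level` (mean annual best, native scale), `sigma` (fluctuation
#'   sd, >= 0), `drift` (improvement per year, >= 0 improves).
#' @param correlation Cross-event correlation matrix for the fluctuation
#'   terms (symmetric PSD, unit diagonal). Default: identity.
#' @param years Year range (default 1992-2018).
#' @param seed Integer RNG seed; identical spec + seed reproduce the panel
#'   bit for bit.
#' @param drift_from First year at which drift applies (default: first panel
#'   year). Setting it past a fit window plants an improvement that begins
#'   only in the projection period.
#' @param ar1 Optional lag-1 autocorrelation of the fluctuations (default 0:
#'   independent years).
#' @return A `panel_spec`.
#' @export
panel_spec <- function(events, correlation = NULL, years = 1992:2018,
                       seed = 1L, drift_from = NULL, ar1 = 0) {
  events <- tibble::as_tibble(events)
  required <- c("event_id", "direction", "unit", "level", "sigma", "drift")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    stop("events table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (any(events$level <= 0)) stop("levels must be positive", call. = FALSE)
  n <- nrow(events)
  if (is.null(correlation)) correlation <- diag(n)
  correlation <- unname(as.matrix(correlation))
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      !isTRUE(all.equal(diag(correlation), rep(1, n)))) {
    stop("correlation must be symmetric with unit diagonal", call. = FALSE)
  }
  years <- as.integer(years)
  if (is.null(drift_from)) drift_from <- min(years)
  if (abs(ar1) >= 1) stop("ar1 must lie in (-1, 1)", call. = FALSE)
  structure(list(events = events, correlation = correlation, years = years,
                 seed = as.integer(seed), drift_from = as.integer(drift_from),
                 ar1 = ar1),
            class = "panel_spec")
}

#' Simulate an annual-best panel
#'
#' Draws, for event e and year t,
#' `level_e [+/-] drift_e * years_drifting + sigma_e * z_{e,t}` on the
#' event's native scale, where the `z` rows are standard Gaussians with the
#' spec's cross-event correlation (via the symmetric square root of the
#' correlation matrix). For `minimize` events drift is subtracted (marks get
#' faster), for `maximize` events added. Errors if any generated mark is
#' non-positive.
#'
#' @param spec A [panel_spec()].
#' @param catalog Optional catalog to attach to the resulting panel.
#' @return A [record_panel()].
#' @export
simulate_panel <- function(spec, catalog = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  ev <- spec$events
  n <- nrow(ev)
  t_len <- length(spec$years)
  root <- correlation_root(spec$correlation)
  set.seed(spec$seed)
  z <- root %*% matrix(stats::rnorm(n * t_len), n, t_len)
  if (spec$ar1 != 0) {
    for (j in 2:t_len) {
      z[, j] <- spec$ar1 * z[, j - 1] + sqrt(1 - spec$ar1^2) * z[, j]
    }
  }
  drift_years <- pmax(0, spec$years - spec$drift_from + 1L)
  series <- lapply(seq_len(n), function(e) {
    sgn <- if (ev$direction[e] == "minimize") -1 else 1
    marks <- ev$level[e] + sgn * ev$drift[e] * drift_years +
      ev$sigma[e] * sgn * z[e, ]
    if (any(marks <= 0)) {
      stop(sprintf("event '%s': generated a non-positive mark; raise the level or lower sigma/drift",
                   ev$event_id[e]), call. = FALSE)
    }
    annual_best_series(ev$event_id[e], marks, direction = ev$direction[e],
                       unit = ev$unit[e], years = spec$years,
                       year_range = range(spec$years))
  })
  record_panel(series, catalog = catalog)
}

# symmetric PSD square root; errors on a non-PSD matrix
correlation_root <- function(C) {
  eig <- eigen(C, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
}

#' Default 24-event synthetic panel specification
#'
#' Mimics the shape of the real 1992-2018 federation panel: the 24-event
#' roster at plausible levels and fluctuation scales, with a correlated
#' "co-evolving" block (both sprints, the marathon and all thirteen swimming
#' events, pairwise fluctuation correlation 0.8) that also improves
#' systematically (drift 1.5 fluctuation-sd per decade), and an uncorrelated
#' stationary block for the remaining track and field events. Running the
#' full pipeline on this spec reproduces the qualitative findings the
#' analysis is designed to surface: the drifting events escape the
#' prediction band and form one connected network component.
#'
#' @param seed Integer seed.
#' @param years Year range (default 1992-2018).
#' @return A [panel_spec()].
#' @export
default_panel_spec <- function(seed = 1L, years = 1992:2018) {
  catalog <- event_catalog()
  # plausible modern-era levels (seconds / meters) and annual-best sd
  level <- c(9.85, 19.6, 43.6, 102.0, 442.0, 1585.0, 7560.0,
             53.0, 115.5, 59.2, 128.5, 51.0, 113.5, 21.3, 47.5, 104.5,
             220.5, 465.0, 117.0, 248.0, 47.0, 8.65, 2.40, 17.85)
  sigma <- c(0.05, 0.12, 0.25, 0.55, 2.6, 9.0, 55.0,
             0.35, 0.75, 0.40, 0.85, 0.35, 0.75, 0.15, 0.30, 0.65,
             1.40, 3.00, 0.75, 1.60, 0.30, 0.10, 0.03, 0.15)
  block <- catalog$event_id %in% c(
    "sprint_100m", "sprint_200m", "marathon",
    catalog$event_id[catalog$category == "swim"])
  drift <- ifelse(block, 0.15 * sigma, 0)   # 1.5 sd per decade
  C <- diag(24)
  C[block, block] <- 0.8
  diag(C) <- 1
  events <- tibble::tibble(event_id = catalog$event_id,
                           direction = catalog$direction,
                           unit = catalog$unit,
                           level = level, sigma = sigma, drift = drift)
  panel_spec(events, correlation = C, years = years, seed = seed)
}

#' Read / write a panel spec as a YAML config file
#'
#' @param spec A [panel_spec()].
#' @param file Path to a YAML file.
#' @return `read_panel_spec` returns a [panel_spec()]; `write_panel_spec`
#'   returns `file` invisibly.
#' @export
write_panel_spec <- function(spec, file) {
  yaml::write_yaml(list(
    events = lapply(seq_len(nrow(spec$events)), function(i)
      as.list(spec$events[i, ])),
    correlation = lapply(seq_len(nrow(spec$correlation)), function(i)
      as.numeric(spec$correlation[i, ])),
    years = c(min(spec$years), max(spec$years)),
    seed = spec$seed, drift_from = spec$drift_from, ar1 = spec$ar1), file)
  invisible(file)
}

#' @rdname write_panel_spec
#' @export
read_panel_spec <- function(file) {
  raw <- yaml::read_yaml(file)
  events <- do.call(rbind, lapply(raw$events, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
  corr <- if (is.null(raw$correlation)) NULL else
    do.call(rbind, lapply(raw$correlation, as.numeric))
  panel_spec(events, correlation = corr,
             years = raw$years[1]:raw$years[2], seed = raw$seed,
             drift_from = raw$drift_from,
             ar1 = if (is.null(raw$ar1)) 0 else raw$ar1)
}

#' Empirical moments of the maximum of N iid standard Gaussians
#'
#' Monte-Carlo companion to [expected_max_exact()]: draws `reps` batches of
#' `N` standard normals and returns the mean and sd of the batch maxima.
#' Drawn in chunks, so large `reps` stay memory-friendly.
#'
#' @param N Batch size, `>= 1`.
#' @param reps Number of batches, `>= 1`.
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `se` (standard error of the mean), `reps`.
#' @export
simulate_iid_maxima <- function(N, reps, seed = 1L) {
  if (N < 1 || N != round(N)) stop("N must be a positive integer", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  set.seed(seed)
  chunk <- max(1, floor(2e6 / N))
  maxima <- numeric(reps)
  done <- 0
  while (done < reps) {
    k <- min(chunk, reps - done)
    m <- matrix(stats::rnorm(k * N), nrow = k)
    mx <- m[, 1]
    for (j in seq_len(N)[-1]) mx <- pmax(mx, m[, j])
    maxima[done + seq_len(k)] <- mx
    done <- done + k
  }
  s <- stats::sd(maxima)
  list(mean = mean(maxima), sd = s, se = s / sqrt(reps), reps = reps)
}
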