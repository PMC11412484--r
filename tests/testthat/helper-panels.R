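# Small construction helpers shared across the suite.

toy_series <- function(marks, direction = "minimize", id = "ev",
                       years = seq(1992, length.out = length(marks)),
                       unit = if (direction == "minimize") "seconds" else "meters") {
  annual_best_series(id, marks, direction = direction, unit = unit,
                     years = years)
}

# panel of uncorrelated synthetic events with shared settings
toy_spec <- function(n_events = 2, level = 100, sigma = 1, drift = 0,
                     years = 1992:2018, seed = 1, direction = "minimize",
                     correlation = NULL, drift_from = NULL) {
  unit <- if (direction == "minimize") "seconds" else "meters"
  events <- tibble::tibble(
    event_id = paste0("ev", seq_len(n_events)),
    direction = direction, unit = unit,
    level = level, sigma = sigma, drift = drift)
  panel_spec(events, correlation = correlation, years = years, seed = seed,
             drift_from = drift_from)
}

# quadratic approximation polynomials with the default coefficients,
# written out independently of the package internals
approx_mean_poly <- function(N) {
  L <- log(log(N))
  0.818 + 0.574 * L + 0.349 * L^2
}
approx_band_poly <- function(N) {
  L <- log(log(N))
  0.8023 - 0.2751 * L + 0.0020 * L^2
}
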