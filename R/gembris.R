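#' Fit the Gaussian record model on a baseline window
#'
#' The model treats annual bests as iid Gaussian fluctuations around a
#' stationary level. All model math runs on an internal "maximize" scale —
#' times are negated so that a better performance is always a larger value —
#' and predictions are mapped back to native units on output. `mu` and
#' `sigma` are the sample mean and sample standard deviation (n-1
#' denominator) of the annual bests in the window, on that internal scale.
#'
#' @param series An [annual_best_series()].
#' @param window Integer years of the baseline (fit) window; at least two of
#'   them must be present in the series. Defaults to 1992-2001.
#' @return A `gaussian_record_model` with fields `mu`, `sigma`, `fit_window`,
#'   `a_coeffs`, `b_coeffs`, `direction`, `event_id`.
#' @export
fit_gaussian_baseline <- function(series, window = 1992:2001) {
  window <- as.integer(window)
  yrs <- series_years(series)
  present <- window[window %in% yrs]
  if (length(present) < 2) {
    stop(sprintf("event '%s': fit window has %d observation(s), need >= 2",
                 series$event_id, length(present)), call. = FALSE)
  }
  x <- internal_marks(series)[as.character(present)]
  gaussian_record_model(mu = mean(x), sigma = stats::sd(x),
                        fit_window = present, direction = series$direction,
                        event_id = series$event_id)
}

#' Construct a Gaussian record model directly
#'
#' @param mu Mean annual best on the internal maximize scale.
#' @param sigma Standard deviation of annual bests (>= 0).
#' @param fit_window Years the model was fitted on (the prediction horizon N
#'   is counted from the first of these).
#' @param a_coeffs,b_coeffs Approximation coefficients of the expected-record
#'   polynomial and its uncertainty band; the defaults are the calibrated
#'   values `(0.818, 0.574, 0.349)` and `(0.8023, -0.2751, 0.0020)`.
#' @param direction Direction of the source event (to map predictions back
#'   to the native scale).
#' @param event_id Optional event key carried through to reports.
#' @export
gaussian_record_model <- function(mu, sigma, fit_window,
                                  a_coeffs = c(0.818, 0.574, 0.349),
                                  b_coeffs = c(0.8023, -0.2751, 0.0020),
                                  direction = c("maximize", "minimize"),
                                  event_id = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(length(a_coeffs) == 3, length(b_coeffs) == 3)
  if (!is.finite(sigma) || sigma < 0) {
    stop("sigma must be a nonnegative number", call. = FALSE)
  }
  if (length(fit_window) < 1) stop("fit_window must be nonempty", call. = FALSE)
  structure(list(mu = mu, sigma = sigma,
                 fit_window = as.integer(fit_window),
                 a_coeffs = as.numeric(a_coeffs),
                 b_coeffs = as.numeric(b_coeffs),
                 direction = direction, event_id = event_id),
            class = "gaussian_record_model")
}

#' @export
print.gaussian_record_model <- function(x, ...) {
  mu_native <- if (x$direction == "minimize") -x$mu else x$mu
  cat(sprintf(
    "<gaussian_record_model> %s: mu = %.4g (native), sigma = %.4g, fit %d-%d\n",
    x$event_id, mu_native, x$sigma, min(x$fit_window), max(x$fit_window)))
  invisible(x)
}

loglogN <- function(N) {
  if (any(N < 2)) stop("horizon N must be >= 2 (log log N undefined below)",
                       call. = FALSE)
  log(log(N))
}

#' Expected record over an N-year horizon
#'
#' The expected best-of-N annual performances under the fitted Gaussian
#' model, via the quadratic approximation in log log N:
#' `x_max = mu + sigma * (a0 + a1*loglogN + a2*loglogN^2)` on the internal
#' maximize scale, mapped back to native units (negated for timed events).
#' With the default coefficients and `sigma = 1` the approximation stays
#' within 0.06 of the exact expected maximum of N iid standard Gaussians
#' (see [expected_max_exact()]) for horizons N in 3-1000.
#'
#' @param model A `gaussian_record_model`.
#' @param N Integer horizon(s), `>= 2`.
#' @return Predicted record(s) on the event's native scale.
#' @export
expected_record <- function(model, N) {
  L <- loglogN(N)
  a <- model$a_coeffs
  pred <- model$mu + model$sigma * (a[1] + a[2] * L + a[3] * L^2)
  if (model$direction == "minimize") -pred else pred
}

#' Half-width of the record prediction band
#'
#' `sigma_E = sigma * (b0 + b1*loglogN + b2*loglogN^2)`, clamped at zero if
#' the polynomial goes negative. Scales linearly in `sigma`; with the default
#' coefficients it is positive and strictly decreasing over N in 2-1000.
#'
#' @inheritParams expected_record
#' @return Nonnegative band half-width(s), in the event's units.
#' @export
sigma_E <- function(model, N) {
  L <- loglogN(N)
  b <- model$b_coeffs
  pmax(0, model$sigma * (b[1] + b[2] * L + b[3] * L^2))
}

#' Classify observed records against the prediction band
#'
#' For each projection year the observed comparator is the running record —
#' the cumulative best-so-far mark from the start of the series — because
#' the model predicts the best of N years. The horizon is
#' `N = year - first fit-window year + 1`. A year is `inside` when
#' `|observed - predicted| <= sigma_E` on the internal scale, otherwise
#' `above` (observed better than predicted) or `below`. The event is flagged
#' `systematic_deviation` when the final `consecutive_k` years are all
#' outside the band on the same side — the signature of genuine systematic
#' improvement (side `"above"`) rather than random fluctuation.
#'
#' @param series An [annual_best_series()].
#' @param model The model from [fit_gaussian_baseline()].
#' @param projection Integer years to classify (must be present in the
#'   series). Defaults to 2002-2018.
#' @param consecutive_k Terminal run length required to flag systematic
#'   deviation (default 5).
#' @return A `deviation_report`: tibble with columns `year`, `N`, `observed`
#'   (running record, native scale), `predicted`, `sigma_E`, `status`, plus
#'   attributes `event_id`, `systematic_deviation`, `side`.
#' @export
classify_event_deviation <- function(series, model, projection = 2002:2018,
                                     consecutive_k = 5) {
  projection <- sort(as.integer(projection))
  if (length(projection) == 0) stop("empty projection window", call. = FALSE)
  yrs <- series_years(series)
  missing <- setdiff(projection, yrs)
  if (length(missing)) {
    stop(sprintf("event '%s': no mark for year %d", series$event_id,
                 missing[1]), call. = FALSE)
  }
  start <- min(model$fit_window)
  N <- projection - start + 1L
  if (any(N < 2)) {
    stop("projection must start at least one year after the fit-window start",
         call. = FALSE)
  }
  internal <- internal_marks(series)
  running <- cummax(internal)            # record process on the maximize scale
  obs_int <- running[match(projection, yrs)]
  a <- model$a_coeffs
  L <- loglogN(N)
  pred_int <- model$mu + model$sigma * (a[1] + a[2] * L + a[3] * L^2)
  band <- sigma_E(model, N)
  status <- unname(ifelse(abs(obs_int - pred_int) <= band, "inside",
                          ifelse(obs_int > pred_int, "above", "below")))
  k <- min(consecutive_k, length(status))
  tail_k <- status[(length(status) - k + 1):length(status)]
  systematic <- length(unique(tail_k)) == 1 && tail_k[1] != "inside"
  to_native <- if (series$direction == "minimize") function(v) -v else identity
  rep <- tibble::tibble(year = projection, N = N,
                        observed = unname(to_native(obs_int)),
                        predicted = to_native(pred_int),
                        sigma_E = band, status = status)
  structure(rep, event_id = series$event_id,
            systematic_deviation = systematic,
            side = if (systematic) tail_k[1] else NA_character_,
            consecutive_k = consecutive_k,
            class = c("deviation_report", class(rep)))
}

#' Summarize deviation reports across a panel
#'
#' @param reports List of `deviation_report` objects.
#' @return Tibble `event_id`, `systematic_deviation`, `side`,
#'   `n_years_outside`.
#' @export
deviation_summary <- function(reports) {
  tibble::tibble(
    event_id = vapply(reports, attr, character(1), which = "event_id"),
    systematic_deviation = vapply(reports, attr, logical(1),
                                  which = "systematic_deviation"),
    side = vapply(reports, attr, character(1), which = "side"),
    n_years_outside = vapply(reports, function(r) sum(r$status != "inside"),
                             integer(1)))
}
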