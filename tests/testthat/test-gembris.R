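test_that("baseline fit is the windowed mean/sd on the internal maximize scale", {
  s_const <- toy_series(c(10, 10, 10))
  m <- fit_gaussian_baseline(s_const, 1992:1994)
  expect_equal(m$mu, -10)      # timed event: internal scale is negated
  expect_equal(m$sigma, 0)
  s_max <- toy_series(1:3, direction = "maximize")
  m2 <- fit_gaussian_baseline(s_max, 1992:1994)
  expect_equal(m2$mu, 2)
  expect_equal(m2$sigma, 1)
  expect_error(fit_gaussian_baseline(s_const, 1992), ">= 2")
  # default coefficients are carried on every fitted model
  expect_equal(m$a_coeffs, c(0.818, 0.574, 0.349))
  expect_equal(m$b_coeffs, c(0.8023, -0.2751, 0.0020))
})

test_that("fit recovers generator truth within standard-error bounds", {
  n <- 10
  hits <- vapply(1:200, function(r) {
    spec <- toy_spec(n_events = 1, level = 50, sigma = 2, seed = 1000 + r,
                     years = seq(1992, length.out = n))
    m <- fit_gaussian_baseline(simulate_panel(spec)[[1]],
                               seq(1992, length.out = n))
    ok_mu <- abs(m$mu - (-50)) <= 3 * 2 / sqrt(n)
    ok_sd <- abs(m$sigma - 2) <= 3 * 2 / sqrt(2 * (n - 1))
    ok_mu && ok_sd
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("expected_record matches the printed-coefficient polynomial and the oracle", {
  m <- gaussian_record_model(mu = 0, sigma = 1, fit_window = 1992)
  expect_equal(expected_record(m, 10), approx_mean_poly(10), tolerance = 1e-12)
  expect_equal(expected_record(m, 10), 1.539503, tolerance = 1e-6)
  expect_equal(expected_record(m, 3), 0.875070, tolerance = 1e-6)
  expect_lt(abs(expected_record(m, 3) - expected_max_exact(3)), 0.06)
  expect_lt(abs(expected_record(m, 10) - expected_max_exact(10)), 0.06)
  expect_error(expected_record(m, 1), "N must be >= 2")
  # degenerate sigma: prediction collapses to the level for every horizon
  m0 <- gaussian_record_model(mu = 5, sigma = 0, fit_window = 1992)
  expect_equal(expected_record(m0, c(2, 10, 500)), rep(5, 3))
  # minimize events map back by negation
  mm <- gaussian_record_model(mu = -10, sigma = 1, fit_window = 1992,
                              direction = "minimize")
  expect_equal(expected_record(mm, 10), -(-10 + approx_mean_poly(10)))
})

test_that("expected_record grows with horizon and stays within 0.06 of exact", {
  m <- gaussian_record_model(mu = 0, sigma = 1, fit_window = 1992)
  Ns <- 3:200
  vals <- expected_record(m, Ns)
  expect_true(all(diff(vals) > 0))
  expect_true(all(diff(expected_max_exact(c(1:20, 50, 100))) > 0))
  dev <- abs(vals - expected_max_exact(Ns))
  expect_lt(max(dev), 0.06)
})

test_that("sigma_E evaluates the band polynomial, scales in sigma, clamps at zero", {
  m <- gaussian_record_model(mu = 0, sigma = 1, fit_window = 1992)
  expect_equal(sigma_E(m, 10), 0.574249, tolerance = 1e-6)
  expect_equal(sigma_E(m, 10), approx_band_poly(10), tolerance = 1e-12)
  m2 <- gaussian_record_model(mu = 0, sigma = 2, fit_window = 1992)
  expect_equal(sigma_E(m2, 10), 2 * sigma_E(m, 10))
  m0 <- gaussian_record_model(mu = 0, sigma = 0, fit_window = 1992)
  expect_equal(sigma_E(m0, c(2, 10, 100)), rep(0, 3))
  # a band polynomial that goes negative is clamped, not returned negative
  neg <- gaussian_record_model(mu = 0, sigma = 1, fit_window = 1992,
                               b_coeffs = c(0.1, -1, 0))
  expect_equal(sigma_E(neg, 100), 0)
  # default band is positive and strictly decreasing across the whole range
  band <- sigma_E(m, 2:1000)
  expect_true(all(band > 0))
  expect_true(all(diff(band) < 0))
})

test_that("deviation classification follows the band and the terminal-run rule", {
  # running record equal to the prediction every year -> all inside
  yrs <- 2002:2018
  N <- yrs - 1992 + 1
  s <- annual_best_series("ev", 10 + approx_mean_poly(N),
                          direction = "maximize", unit = "meters", years = yrs)
  m10 <- gaussian_record_model(mu = 10, sigma = 1, fit_window = 1992:2001,
                               direction = "maximize")
  rep <- classify_event_deviation(s, m10, yrs)
  expect_true(all(rep$status == "inside"))
  expect_false(attr(rep, "systematic_deviation"))
  expect_equal(rep$N, N)

  # zero-sigma model: any observed above mu sits above a zero-width band
  s2 <- toy_series(rep(c(10, 9), c(10, 7)), years = 1992:2008)
  m0 <- gaussian_record_model(mu = -10, sigma = 0, fit_window = 1992:2001,
                              direction = "minimize")
  rep2 <- classify_event_deviation(s2, m0, 2002:2008)
  expect_true(all(rep2$status == "above"))
  expect_true(attr(rep2, "systematic_deviation"))
  expect_equal(attr(rep2, "side"), "above")
})

test_that("strong post-window drift is flagged as systematic deviation above", {
  spec <- toy_spec(n_events = 1, level = 100, sigma = 0.5, drift = 0.25,
                   seed = 42, drift_from = 2002)
  s <- simulate_panel(spec)[[1]]
  m <- fit_gaussian_baseline(s, 1992:2001)
  rep <- classify_event_deviation(s, m, 2002:2018)
  expect_true(attr(rep, "systematic_deviation"))
  expect_equal(attr(rep, "side"), "above")
})

test_that("classification statuses are invariant under direction flip", {
  spec <- toy_spec(n_events = 1, level = 100, sigma = 1, drift = 0.1,
                   seed = 77, drift_from = 2002)
  s_min <- simulate_panel(spec)[[1]]
  # mirror event: same internal fluctuations presented as a maximize series
  s_max <- annual_best_series("mirror", 200 - s_min$marks,
                              direction = "maximize", unit = "meters",
                              years = series_years(s_min))
  r1 <- classify_event_deviation(s_min, fit_gaussian_baseline(s_min, 1992:2001))
  r2 <- classify_event_deviation(s_max, fit_gaussian_baseline(s_max, 1992:2001))
  expect_equal(r2$status, r1$status)
  expect_equal(attr(r2, "systematic_deviation"), attr(r1, "systematic_deviation"))
})

test_that("band coverage of the running record matches the closed-form rate", {
  # model given, series drawn from it: P(inside at horizon N) has the exact
  # closed form Phi(pred + sE)^N - Phi(pred - sE)^N for the running maximum
  m <- gaussian_record_model(mu = 0, sigma = 1, fit_window = 1992:2001,
                             direction = "maximize")
  N_final <- 27
  pred <- approx_mean_poly(N_final)
  sE <- approx_band_poly(N_final)
  expected_cov <- pnorm(pred + sE)^N_final - pnorm(pred - sE)^N_final
  reps <- 2000
  set.seed(314)
  inside <- vapply(seq_len(reps), function(i) {
    marks <- rnorm(27) + 100
    s <- annual_best_series("ev", marks, direction = "maximize",
                            unit = "meters", years = 1992:2018)
    m_i <- gaussian_record_model(mu = 100, sigma = 1, fit_window = 1992:2001,
                                 direction = "maximize")
    r <- classify_event_deviation(s, m_i, 2002:2018)
    r$status[r$year == 2018] == "inside"
  }, logical(1))
  tol <- 3 * sqrt(expected_cov * (1 - expected_cov) / reps)
  expect_lt(abs(mean(inside) - expected_cov), tol)
})
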