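#' Exact moments of the maximum of N iid standard Gaussians
#'
#' Numerical quadrature of the top-order-statistic density
#' `N * phi(x) * Phi(x)^(N-1)` gives the exact mean and standard deviation
#' of `max(Z_1, ..., Z_N)` for iid standard normal draws. This is the
#' independent oracle against which the quadratic log-log-N approximation in
#' [expected_record()] and [sigma_E()] is validated; closed forms exist at
#' `N = 1` (mean 0, sd 1) and `N = 2` (mean `1/sqrt(pi)`).
#'
#' @param N Integer vector, `>= 1`.
#' @return For `expected_max_exact`, the exact expectation(s); for
#'   `sd_max_exact`, the exact standard deviation(s). Absolute quadrature
#'   tolerance is at most 1e-6.
#' @examples
#' expected_max_exact(2) - 1 / sqrt(pi)   # ~ 0
#' expected_max_exact(10)                 # ~ 1.5388
#' @export
expected_max_exact <- function(N) {
  vapply(N, function(n) max_moment(n, 1), numeric(1))
}

#' @rdname expected_max_exact
#' @export
sd_max_exact <- function(N) {
  vapply(N, function(n) {
    m1 <- max_moment(n, 1)
    m2 <- max_moment(n, 2)
    sqrt(max(0, m2 - m1^2))
  }, numeric(1))
}

max_moment <- function(n, power) {
  if (is.na(n) || n < 1 || n != round(n)) {
    stop("N must be a positive integer", call. = FALSE)
  }
  stats::integrate(function(x) x^power * n * stats::dnorm(x) *
                     stats::pnorm(x)^(n - 1),
                   lower = -Inf, upper = Inf,
                   rel.tol = 1e-10, abs.tol = 1e-9)$value
}
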