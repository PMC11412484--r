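---
title: "Modelling the evolution of annual world records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of annual world records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recordnet)
```

## The problem

World records in track, field and swimming are the annual extremes of human
performance. Two questions recur when a panel of annual bests (here, 24
men's events over 1992--2018 in the default configuration) is analysed:

1. Are records improving *systematically*, or are new records just the
   occasional lucky draw from a stationary distribution of annual
   performances?
2. Do different events improve *together* — is there a common structure in
   how their records fluctuate from year to year?

`recordnet` answers the first with an extreme-value prediction model and
the second with a thresholded correlation network over direction-normalized
relative fluctuations, plus span-wise descriptive statistics of the
magnitude of change.

## The record prediction model

The null hypothesis treats an event's annual best $x_t$ as iid Gaussian,
$x_t \sim \mathcal{N}(\mu, \sigma^2)$, on an internal "maximize" scale
(times are negated so that better is always larger). Under that null, the
record after $N$ years is the maximum of $N$ iid Gaussians, whose
expectation has no closed form but is well approximated by a quadratic in
$\ln \ln N$:

$$x_\max(N) \approx \mu + \sigma\left(a_0 + a_1 \ln\ln N + a_2 (\ln\ln N)^2\right),$$

with calibrated coefficients $a_0 = 0.818$, $a_1 = 0.574$, $a_2 = 0.349$.
The package ships an exact oracle — numerical quadrature of the
top-order-statistic density $N\,\varphi(x)\,\Phi(x)^{N-1}$ — and the test
suite verifies that the approximation error stays below 0.06 standard
deviations over horizons $N \in [3, 1000]$ (the maximum, about 0.029,
occurs at $N = 3$; the bound fails below $N = 3$, which is why the
calibration interval starts there, and the package's own use never exceeds
$N = 27$):

```{r bound}
m <- gaussian_record_model(mu = 0, sigma = 1, fit_window = 1992)
N <- 3:1000
max(abs(expected_record(m, N) - expected_max_exact(N)))
```

The prediction is wrapped in a band of half-width

$$\sigma_E(N) = \sigma\left(b_0 + b_1 \ln\ln N + b_2 (\ln\ln N)^2\right),
\qquad b_0 = 0.8023,\; b_1 = -0.2751,\; b_2 = 0.0020,$$

clamped at zero if the polynomial ever goes negative. What population
quantity $\sigma_E$ estimates is deliberately left open here: it does not
numerically match the standard deviation of the $N$-Gaussian maximum (the
oracle `sd_max_exact()` shows multi-percent discrepancies), so the package
treats it as the band-half-width formula verbatim and asserts only the
qualitative property that it is positive and strictly decreasing in $N$,
which both it and `sd_max_exact()` are.

### Fitting, classification, and the deviation flag

`fit_gaussian_baseline()` estimates $(\mu, \sigma)$ as the sample mean and
sample standard deviation ($n-1$ denominator) over a baseline window,
1992--2001 by default. `classify_event_deviation()` then compares, for each
projection year, the *running record* (cumulative best-so-far, since the
model predicts the best of $N$ years) against the prediction at horizon
$N = \text{year} - \text{first fit year} + 1$, centred on the prediction
with a $\pm 1\,\sigma_E$ band. Each year is `inside`, `above` (better than
predicted) or `below`; an event is flagged `systematic_deviation` when its
final $K$ consecutive projection years (default $K = 5$) all fall outside
on the same side. The $K$-terminal-run rule is this package's
operationalization: the underlying method only inspects trajectories
visually, so some such rule is needed to make "deviates from the band" a
testable property.

### What the flag can and cannot detect

Two properties of this rule are worth stating plainly, because they were
measured by simulation rather than assumed:

* **Null behaviour.** Under the stationary null the per-year coverage of
  the $\pm\sigma_E$ band around the running record is only about 73% at
  long horizons (the exact coverage at horizon $N$ is
  $\Phi(p+\sigma_E)^N - \Phi(p-\sigma_E)^N$ for prediction $p$, which the
  suite checks by simulation), and outside-ness is strongly persistent
  because the running record is monotone. The flag's false-positive rate
  under the null is therefore substantial — about 0.32 in a 2000-replicate
  simulation. A flagged event is *evidence* of systematic improvement, not
  proof; conversely the stationary-null tests bound this rate, they do not
  make it small.
* **Power.** A linear drift injected after the fit window is detected with
  probability that rises steeply with the drift rate: roughly 55% at one
  fluctuation-sd per decade, ~75% at 1.5, and >90% only from about two
  fluctuation-sd per decade (estimated on 500+ replicates per point).
  Genuinely improving events in real panels move far faster than one sd
  per decade, so this is adequate in practice, but weak drifts near that
  boundary will often escape the flag.

## Record-evolution statistics

`improvement_percent()` is the signed percent change between two years on
the baseline year's scale, oriented so that positive always means
improvement regardless of direction. `compare_spans()` pairs two
equal-length year spans positionally (default 1992--2005 against
2005--2018, a fixed 13-year offset) and averages the paired changes per
event; `rank_events()` ranks events by that mean, ties broken by catalog
index so the ranking is a full permutation. Because the historically quoted
marathon ranking uses a differently oriented pairing (1992--2002 against
2018 down to 2008), spans are arbitrary vectors rather than ranges, and
`evolution_headlines()` encodes the four headline real-data quantities for
users who supply a curated federation panel; they are not computable from
synthetic data.

## The relevance network

Eq-style relative fluctuations make events dimensionless and comparable:
the TSRF of event $x$ with baseline year $i$ is $x_j / x_i$ for timed
events and $x_i / x_j$ for jumps (the reciprocal, chosen over negation
because it preserves positivity and scale-freeness), for
$j \ne i$. Improvement lowers the value for every event alike.
`correlation_matrix()` computes pairwise Pearson correlations across years
with two-sided p-values from the $t$-transform on $n-2$ degrees of
freedom, and `build_network()` draws an edge where $R > 0.7$ strictly and
(by default) $p < 0.05$ strictly, labels pair strength in signed bands
(high $|R| > 0.7$, moderate $0.4 \le |R| \le 0.7$, weak otherwise), and
reports connected components with singletons kept. No multiple-testing
correction is applied by default, mirroring the analysis convention of
reporting raw per-pair significance across all 276 pairs of a 24-event
panel; a Benjamini--Hochberg switch (`p_adjust = "BH"`) is available and
documented because the raw convention inflates family-wise error.

## The synthetic generator

`simulate_panel()` draws, for event $e$ in year $t$,
$\mathrm{level}_e \pm \left(\delta_e \cdot k_t + \sigma^*_e z_{e,t}\right)$
on the native scale, where $k_t$ counts years since drift onset, the sign
makes positive $\delta$ an improvement for both directions, and the
$z$ rows are standard Gaussians correlated across events through the
symmetric square root of the spec's correlation matrix (independent across
years; an AR(1) knob exists but defaults to off, since the stationary null
being emulated specifies no autocorrelation). The correlation is planted
between *performance* fluctuations, so a timed event and a jump with
planted correlation co-improve — which is what the TSRF is designed to
recover with positive sign. Marks must come out strictly positive;
the generator refuses specs that violate this.

`default_panel_spec()` fixes the study-shaped conditions used throughout
the tests: the 24-event roster over 1992--2018 at plausible modern levels
and annual-best fluctuation scales, a correlated co-evolving block (both
sprints, the marathon, all thirteen swimming events; pairwise fluctuation
correlation 0.8, drift 1.5 fluctuation-sd per decade — the order of
magnitude real improving events exhibit) and an uncorrelated stationary
block for the remaining track and field events. Drift enters linearly:
no functional form of "systematic improvement" is implied by the model,
and linear is the minimal choice that the band classifier can detect.

What the generator does *not* emulate: autocorrelated performance eras,
equipment or rule discontinuities (e.g. the polyurethane-swimsuit spike),
participation effects, measurement granularity (hand vs electronic
timing), or athlete-level structure. Passing tests on synthetic panels
therefore validate the statistical machinery, not the historical claims
about real federation data, which require externally curated inputs.

## Numerical and design choices

* Quadrature uses `stats::integrate` over the full real line at
  `rel.tol = 1e-10`, absolute tolerance well under $10^{-6}$; the suite
  cross-checks it against closed forms ($N = 1, 2$) and seeded Monte Carlo
  at $10^6$ replicates.
* All randomness is seeded; identical spec + seed reproduce panels bit for
  bit, and a pipeline rerun with the same config yields byte-identical CSV
  outputs.
* Zero fluctuation is allowed: a constant baseline gives $\sigma = 0$, a
  degenerate (zero-width) band, and classification relative to a point
  prediction. Zero-variance TSRF rows are an error in the correlation
  stage (the coefficient is undefined), deliberately not imputed.
* Ties in `rank_events()` break by catalog legend index; missing interior
  years are an error everywhere (no imputation); the baseline year is
  excluded from the TSRF per its definition.
* Problem sizes in the test suite (replicate counts of 100--2000,
  Monte-Carlo batches of $10^6$) were chosen to keep each statistical
  check's sampling error a factor of ~3 below the margin it asserts.

## Limitations

The model's null is iid Gaussian annual bests: heavy-tailed or trending
performance distributions violate it, and the deviation flag inherits the
high null false-positive rate and limited power against weak drift
discussed above. The network stage makes no causal or graph-theoretic
claims beyond connected components. Real-data headline figures depend
entirely on the curation of federation annual-best lists, which this
package does not scrape or ship.
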