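# mortseason

Seasonality of all-cause and cause-specific mortality time series.

Death rates in temperate climates are strongly seasonal — more deaths in
winter than in summer in older ages, and the reverse in young men, where
injury deaths peak in mid-summer. **mortseason** provides the complete
analysis chain for characterising that seasonality from stratified monthly
death counts (by age group, sex, cause of death and climate region), for
epidemiologists and biostatisticians working with vital-registration data:

1. **Monthly death rates** — counts aggregated per stratum, corrected to a
   common 31-day month (`count * 31 / days_in_month`), divided by monthly
   populations obtained by linear interpolation of yearly counts anchored
   at July.
2. **Wavelet detection of 12-month periodicity** — a Morlet continuous
   wavelet transform (central frequency ω₀ = 6) of the detrended series
   rescaled to [−1, 1], with a simulation p-value comparing the
   time-averaged power at the 12-month band (inside the cone of influence)
   against Gaussian white-noise series run through the identical pipeline:
   *p* = (1 + #{null ≥ observed}) / (1 + n_sims).
3. **Timing of maximum and minimum mortality** — circular statistics on the
   12 month-angles θ_m = 2π(m−1)/12: the *centre of gravity*
   θ̄ = arg Σ_j w_j e^{iθ_j} with months weighted by their death rates, and
   the *negative centre of gravity* with months weighted by their shortfall
   below the year's maximum rate; 95% CIs from a year-block bootstrap.
4. **Trends in seasonal amplitude** — per calendar year, the percent
   difference between the empirical maximum- and minimum-rate months,
   100·(r_max − r_min)/r_min, with a Poisson delta-method standard error
   100·(r_max/r_min)·√(1/d_max + 1/d_min); the yearly differences are
   regressed on year by inverse-variance-weighted least squares and the
   fitted line evaluated at the window endpoints.
5. **Temperature context** — population-weighted monthly regional
   aggregation of gridded sub-daily temperature fields and their
   climatologies.

Because individual-level mortality microdata are restricted, the package
ships a fully parameterised **synthetic generator** (Poisson monthly counts
with configurable baseline rate, secular trend, 12- and 6-month cosine
seasonal components with optional decaying amplitude, month-length effects
and exponential population growth, plus a sinusoidal gridded temperature
field), so every stage is testable end to end and the whole pipeline's
operating characteristics can be measured against planted truth.

## Worked example

Simulate a 37-year national stratum (~500 deaths/month, a 12-month seasonal
cycle of relative amplitude 0.2 peaking in January), build rates, and run
the three analyses:

```r
library(mortseason)

cfg <- simulation_config(
  years = 1980:2016,
  seasonal = tibble::tibble(period = 12, amplitude = 0.2, phase = 1,
                            halflife = NA_real_),
  baseline_rate = 5e-4, population_start = 1e6, population_growth = 0.01,
  seed = 7)
deaths <- simulate_deaths(cfg)
pop    <- simulate_population(cfg)

rates <- stratum_rates(deaths, pop, age_group = "65-74", sex = "male")

(cwt <- test_seasonality(rates, n_sims = 100, seed = 1))
#> Morlet wavelet power spectrum
#>   series length: 444 months; 63 periods in [ 2 , 71.84 ] months
#>   12-month seasonality p-value: 0.0099 ( 100 white-noise simulations )

seasonal_timing(rates, n_boot = 1000, seed = 2) |>
  dplyr::select(max_month, max_ci_lo, max_ci_hi,
                min_month, min_ci_lo, min_ci_hi)
#> # A tibble: 1 × 6
#>   max_month max_ci_lo max_ci_hi min_month min_ci_lo min_ci_hi
#>       <dbl>     <dbl>     <dbl>     <dbl>     <dbl>     <dbl>
#> 1      13.0      12.9      1.01      6.98      6.94      7.01

fit_weighted_trend(yearly_percent_difference(rates))
#> Weighted linear trend in seasonal percent difference
#>   slope: 0.055 pp/year (SE 0.143, p = 0.697)
#>   fitted 1980: 55.1%  ->  fitted 2016: 57.1%  (change +2.0 pp)
```

Reading the output: the wavelet p-value 0.0099 (= 1/101, the smallest value
attainable with 100 null simulations) flags clear 12-month periodicity; the
timing table recovers the planted January peak (13.0 ≡ month 1.0 across the
December–January wrap) and July minimum, each with a tight bootstrap CI;
and under a constant planted amplitude the trend in the peak-vs-trough
percent difference is flat (p = 0.70), as it should be. `autoplot()` works
on the wavelet and trend objects, and `tidy()`/`glance()` return their
tabular forms. `run_pipeline()` orchestrates all stages for many strata
from a single config (list or YAML), and `seasonality_profile()` gives
time-resolved p-values that show seasonality emerging or fading.

Real data enter through `load_deaths()` / `load_population()` (CSV), with
ICD-9/ICD-10 codes mapped to ten cause categories by a shipped,
overridable prefix-range table (`default_cause_map()`) and states mapped to
the nine NOAA climate regions (`climate_regions()`).

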