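# massincidence

Population-level analysis of U.S. mass-shooting incidence for
epidemiologists and quantitative social scientists. The package fits
three linked analyses to an incident series (events with ≥ 4 victim
fatalities, perpetrator excluded):

1. **Where.** A Bayesian zero-inflated Poisson (ZIP) regression of
   state-level counts with an intrinsic CAR (ICAR) structured effect, an
   exchangeable unstructured effect, and a log-population offset:

   log μᵢ = log Pᵢ + xᵢᵀβ + vᵢ + uᵢ,  logit πᵢ = xᵢᵀγ,
   yᵢ ~ πᵢ·δ₀ + (1 − πᵢ)·Poisson(μᵢ),

   with MCMC inference (adaptive Metropolis-within-Gibbs, Rcpp) and DIC
   comparison against the plain Poisson variant (π ≡ 0).
2. **When.** A non-homogeneous Poisson process view of the national
   series: binned counts fitted by log-linear Poisson regression,
   log λ(t) = β₁ + β₂·(years since 1982), plus the exponential
   inter-arrival MLE and forward risk probabilities
   P(event within t months) = 1 − e^(−λ̂ᴹ·t).
3. **How soon after coverage.** Rank correlations, ridge regression
   (GCV-selected penalty) and an adjusted Poisson interval model linking
   online media coverage density and search interest to the interval
   before the next incident, with outlier-removal sensitivity analysis.

A synthetic-data generator (`sim_truth()`, `simulate_study()`) emulates
all four inputs — incident series, state covariate panel, contiguous-US
adjacency graph, per-interval media table — with the statistical
structure the pipeline assumes, so every stage is testable without the
original compiled dataset. See the methods vignette
(`vignettes/incidence-modelling.Rmd`) for the models, priors, and design
decisions.

## Worked example

```r
library(massincidence)

st <- simulate_study(seed = 20180522)   # incidents + panel + media
nrow(st$incidents)
#> [1] 78

tf <- fit_trend(bin_counts(st$incidents, 2L,
                           end_date = as.Date("2018-05-31")))
tf
#> Poisson trend (degree 1, 2-year bins): log(lambda) = 0.16096 +0.06295 t
#>   AIC 77.4, Pearson dispersion 1.03, slope p = 2.2e-07
```

The slope is the estimated yearly change in the log incidence rate: here
the biannual expected count grows by about 6% per year, strongly
significant, with no evidence of overdispersion (Pearson statistic near
1). Converting the homogeneous-process MLE to a monthly rate and
tabulating forward risk:

```r
m <- interarrival_mle(st$incidents)
round(m$rate_monthly, 3)
#> [1] 0.186
risk_table(m$rate_monthly, c(1, 3, 6, 12))$probability_3dp
#> [1] 0.170 0.428 0.673 0.893
```

so under a constant continuation of this synthetic series there is a
17.0% chance of at least one incident within a month and 89.3% within a
year. The media analysis on the same run:

```r
media_analysis(st$intervals)
#> media-contagion analysis (n = 77 intervals)
#>   Spearman(density, interval) = -0.638 (p = 4.3e-10)
#>   ridge log-density coef = -0.683 (p = 1.3e-09, penalty 3.98)
#>   Poisson log-density coef = -0.917 (p = 0.58)
```

Higher coverage density after an incident goes with a shorter wait until
the next one (the generator couples them at Spearman −0.70; this run
realizes −0.64). The ridge coefficient is per SD of log density on the
log-interval scale; the Poisson model's dispersion-adjusted p-value is
deliberately conservative.

The spatial stage (slower; MCMC) and the full pipeline:

```r
fit <- fit_zip_car_mcmc(st$panel, n_chains = 2, n_iter = 12000, thin = 6,
                        seed = 1)
summarize_posterior(fit, "beta")     # Mean/SD/2.5%/Median/97.5% table
fit$dic$dic                          # marginal-focus DIC

run_pipeline(pipeline_config(outdir = "run1", seed = 1))
```

`run_pipeline()` writes every stage output (posterior summary CSV,
diagnostics, trend and forecast tables, the Spearman/ridge/Poisson media
reports, a sensitivity report) plus a hashed manifest under the output
directory. A thin CLI wrapper with `simulate`, `fit-spatial`,
`fit-trend`, `forecast`, `media` and `run-all` subcommands is installed
at `inst/scripts/massincidence-cli.R`.

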