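---
title: "Modelling mass-shooting incidence: spatial counts, national trend, and media contagion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mass-shooting incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massincidence)
```

## The three questions

`massincidence` implements a population-level analysis of U.S. mass
shootings (events with at least four victim fatalities, perpetrator
excluded) built around three questions:

1. **Do state-level factors predict where incidents occur?** State counts
   over the study period are modelled with a Bayesian zero-inflated
   Poisson (ZIP) regression with spatially structured and unstructured
   random effects and a log-population offset.
2. **Is the national rate increasing?** The national series is treated as
   a non-homogeneous Poisson process (NHPP); binned counts are fitted by a
   log-linear Poisson regression, and the fitted intensity converts into
   forward-looking risk probabilities.
3. **Does online media attention predict how soon the next incident
   occurs?** Each inter-incident interval is paired with the media
   coverage density (articles per day during the interval) and relative
   search interest, and their association is measured by rank correlation,
   ridge regression, and an adjusted Poisson interval model.

The original compiled incident/media dataset is not redistributable, so
the package ships a synthetic-data generator whose outputs have the
statistical structure every stage assumes. All parameter-recovery and
ordering claims in the test suite refer to that generator.

## The spatial count model

For state $i$ with population $P_i$, incident count $y_i$ and covariates
$x_i$ (FS/S firearm-suicide fraction as a gun-ownership proxy, serious
mental-illness rate, poverty rate, and a gun-law permissiveness
indicator),

$$\log \mu_i = \log P_i + x_i^\top\beta + v_i + u_i, \qquad
  \operatorname{logit} \pi_i = x_i^\top\gamma,$$

$$y_i \sim \pi_i\,\delta_0 + (1 - \pi_i)\,\mathrm{Poisson}(\mu_i).$$

$v$ carries an intrinsic conditional autoregressive (ICAR) prior on the
contiguous-border graph of the 50 states (Alaska and Hawaii are isolated
nodes, so their structured effect is pinned at zero by the per-component
sum-to-zero constraint), and $u$ is exchangeable normal. The excess-zero
model reuses the Poisson design matrix with its own coefficients
$\gamma$. Population enters as an offset, not a covariate.

The permissiveness indicator is 1 for the nine "may-issue" concealed-carry
states (CA, CT, DE, HI, MD, MA, NJ, NY, RI) and 0 otherwise; no published
coding exists for this covariate, so the minimal faithful choice is a
binary marker, overridable through the panel file.

### Priors

Coefficients get vague $\mathrm{N}(0, 10^2)$ priors. For the two effect
scales the default is a penalized-complexity prior,
$\sigma_v, \sigma_u \sim \mathrm{Exponential}(4.6)$ (so that
$P(\sigma > 1) = 0.01$), the modern disease-mapping default. The older
conjugate $\tau \sim \mathrm{Gamma}(0.5, 0.0005)$ prior is available via
`priors = list(family = "gamma")`, but it is not the default for a
structural reason: its density is unbounded at $\tau = 0$, which lets the
unstructured effect absorb structural zeros through arbitrarily large
negative values at negligible prior cost. The ZIP and plain Poisson
models then become practically indistinguishable, and the model
comparison the package exists to perform loses its meaning.

### Sampling

`fit_zip_car_mcmc()` runs an adaptive Metropolis-within-Gibbs sampler
(Rcpp). Design points that matter:

- The ZIP **mixture is used directly** in every update rather than
  augmenting with latent zero indicators. Augmentation removes
  structural-zero states from the Poisson likelihood, letting their
  random effects drift on the prior and destabilizing both the deviance
  summaries and the precision updates.
- Covariates are **centred internally** (draws are mapped back
  afterwards); percent-scale covariates otherwise make the intercept
  direction mix extremely slowly.
- Several **likelihood-invariant interweaving moves** handle the weakly
  identified directions of the hierarchy: a joint intercept/$u$ shift,
  per-state $v_i/u_i$ swaps (only $v_i + u_i$ is likelihood-identified),
  block rescalings of each effect vector, and joint
  $(c\,x, \tau/c^2)$ "funnel" moves that keep the Gaussian prior
  invariant and traverse the scale axis single-site Gibbs steps cannot.
- The precisions are **held at 1 for the first part of warm-up**. The
  first conjugate draw taken from a zero-initialized effect vector
  otherwise lands on an enormous precision and pins the effects at zero
  permanently.
- Proposal scales adapt by Robbins-Monro during warm-up (targets 0.44
  single-site, 0.23 for block moves) and are frozen afterwards.

Defaults are 4 chains of 20 000 iterations with the first half
discarded and thinning by 10. Convergence is summarized by split-$\hat R$
on every scalar draw; any value above 1.1 sets `converged = FALSE` with a
warning (and fails the pipeline stage).

### Model comparison by DIC

`compute_dic()` reports $\mathrm{DIC} = \bar D + p_D$ under two foci. The
default, **marginal**, integrates each state's combined random effect out
of the likelihood with 20-point Gauss-Hermite quadrature, using
$\mathrm{Var}(v_i) = [\text{L}^+]_{ii}/\tau_v$ from the graph-Laplacian
pseudo-inverse plus $1/\tau_u$; the plug-in point uses componentwise
posterior medians for coefficients and geometric means for the skewed
precisions. The **conditional** focus (random effects plugged in) is also
available. The marginal focus is the default because the comparison of a
ZIP against a plain Poisson model happens at the level of coefficients
and variance components: conditionally on 50 free state effects, a
Poisson model can imitate zero inflation almost perfectly, conditional
$p_D$ can even go negative (a known pathology of conditional DIC in
mixture models), and the criterion stops discriminating. Under the
marginal focus the imitation costs what it should, and on synthetic
panels with genuinely structural zeros the ZIP model is preferred
essentially always, which is the behaviour a practitioner comparing these
two models needs the criterion to have.

## The national trend and risk forecast

`bin_counts()` forms half-open calendar bins of one or two years from the
1982 origin; bin $k$ of width $w$ carries the year offset $kw$ (its start
year minus 1982), so the fitted line maps directly to per-bin expected
counts. A final bin only partially covered by the observation window
(January-May 2018 in the study layout) is flagged and its covered
fraction enters the fit as an exposure offset; `use_exposure = FALSE`
reproduces the naive fit.

`fit_trend()` is an ordinary Poisson GLM (IRLS via `stats::glm`) of
counts on the year offset, with Wald p-values, AIC, an optional quadratic
term, and the Pearson dispersion statistic. `compare_aic()` prefers the
lower AIC and resolves exact ties toward the biannual binning.

Two monthly rates summarize risk:

- `interarrival_mle()`: under a homogeneous process the inter-arrival
  times are exponential, with MLE $(n-1)/\text{span}$; months use
  $365.25/12$ days.
- `predict_monthly_rate()`: the fitted bin-level intensity
  $\exp(\beta_1 + \beta_2 t)$ divided by the months per bin (24 for
  biannual bins). The "most recent year" evaluation uses year offset 37:
  with the published coefficients this reproduces the published monthly
  rate 0.468 at three decimals, which is the only evidence available for
  the intended offset convention, and is recorded here as the package's
  choice.

`risk_table()` turns a monthly rate into
$P(\text{at least one event within } t\text{ months}) = 1 - e^{-\lambda t}$,
reported at full precision plus half-up rounding to 3 decimals (the
presentation convention of the published table; two of its printed cells
are consistent only with an unrounded rate, so exact agreement is
checked only on the self-consistent cells).

`smooth_interarrival()` presents the declining inter-arrival series with
a natural cubic smoothing spline whose smoother-matrix trace equals the
requested degrees of freedom (default 4), via `stats::smooth.spline`.

## The media-contagion analysis

`media_analysis()` combines three views of the same association between
an interval's media coverage density and its length:

- `spearman_matrix()` over interval length, coverage density, search
  interest and temporal order, with average ranks for ties and t-
  approximation p-values; constant columns yield flagged `NA` entries.
- `ridge_fit()` of the log interval on log density and temporal order:
  predictors standardized, intercept unpenalized, penalty by generalized
  cross-validation when not supplied, approximate p-values from the ridge
  effective covariance. The log-response is the package's reading of a
  skewed-duration regression (switchable); "temporal order" defaults to
  calendar days since the first incident rather than the ordinal index.
- `poisson_interval_fit()`: interval days regressed on log density,
  adjusting for the preceding event's fatalities and injuries, "time"
  entering as the offset $\log(1 + \text{days since the first
  incident})$ - the stated offset is ambiguous in the source, and this is
  the literal reading adopted. Standard errors are dispersion-adjusted
  (quasi-Poisson): durations treated as counts are far more variable than
  unit-dispersion Poisson, and unadjusted intervals would be badly
  anti-conservative (the null-calibration test verifies the adjusted
  intervals cover zero at their nominal rate).

Zero article counts are floored at half a count before the log (a
continuity correction, flagged in the output). Outlier sensitivity
(`sensitivity_remove()`) drops the intervals following named events and
re-runs all three views, reporting sign stability.
`interval_zscore()` standardizes a given interval within the
log-interval distribution; the sample-SD convention is the default, with
a population-SD switch.

## What the generator emulates - and what it does not

`sim_truth()` records every generating parameter next to each dataset.
The defaults emulate the study conditions, fixed once:

- **National series**: log-linear NHPP with the published coefficients
  (`a = 0.55683`, `b = 0.05033` on biannual bins), simulated by
  Lewis-Shedler thinning over January 1982 - May 2018. The intensity is
  calibrated so a bin starting at offset $t$ expects $e^{a+bt}$ events,
  matching the regression convention; integrated over the window this
  gives about 86 expected events. Same-day collisions are resolved by
  shifting the later event one day.
- **Casualties**: fatalities are 4 plus a negative-binomial excess with
  mean 4.33 (so the mean matches 833 fatalities per 100 events); injuries
  are negative-binomial with mean 12.92. No dispersion is published, so
  the sizes (0.9 and 0.45) were chosen once to give the heavy right tail
  such series show; only the means are calibrated.
- **State panel**: lognormal populations (median 4.3M, sdlog 0.95),
  covariates uniform over plausible ranges (FS/S 0.2-0.7, mental-illness
  13-25%, poverty 9-20%), ICAR + i.i.d. effects with scales 0.4 and 0.3,
  covariate effects zero (the published analysis found none), and
  intercepts set analytically so that about 19 of 50 states record zero
  incidents while the national total is about 100.
- **Media**: a Gaussian copula couples log density to the interval's
  normal scores at latent correlation $2\sin(\pi\rho_s/6)$, the value
  whose implied Spearman correlation equals the target (default
  $-0.70$); article counts are Poisson around density x days, and search
  interest is a noisy square-root transform of density rescaled to peak
  at exactly 100.

The generator does **not** emulate: real covariate geography (covariates
are spatially unstructured even though the adjacency is real), reporting
and deduplication artifacts in article counts, the 2004 change-point in
search data coverage, or any causal contagion mechanism - the media
coupling is a correlation by construction. Passing tests therefore show
that the pipeline recovers structure it is pointed at, not that the
published substantive findings are correct.

## Numerical choices and test scales

- Dates are day-resolved; intervals are exact day differences; same-day
  consecutive incidents are an error unless flooring is requested.
- ICAR simulation draws on the positive eigenspace of the component
  Laplacian (zero-sum enforced per component); isolated areas get 0.
- Thinning was chosen over time-rescaling for the NHPP simulator because
  the dominating-rate bound makes it easy to verify.
- The report tables round half-up to 3 decimals.
- Test and acceptance scales, chosen as the package's own working sizes:
  spatial fits in the automated suite use 2 chains x 12 000 iterations
  (half warm-up, thinning 6); recovery and ordering claims use 20 seeded
  panels; trend claims use 200 seeded replicates; media claims use 100
  seeded studies of roughly 80 intervals.

## Known limitations

- The FS/S proxy, illness and poverty covariates are cross-sectional
  averages applied to a 36-year incident window; the panel reader makes
  no attempt to time-align them.
- The ZIP likelihood treats events as independent given the state rates;
  the contagion analysis quantifies short-range dependence separately
  rather than feeding it back into the count model.
- With 50 areas and weak covariate effects the posterior for $\gamma$ is
  wide; the zero model is identified mainly through its intercept.
- Published magnitudes that depend on the original dataset (posterior
  tables, AIC values, the dispersion 1.53, the rates 0.227/0.468 as data
  estimates, the correlations and the ridge coefficient) are matched
  qualitatively on synthetic data, not numerically.
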