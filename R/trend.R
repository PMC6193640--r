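# National time-trend estimation on binned counts, inter-arrival analysis
# and analytic risk forecasting.

#' Bin incidents into calendar-year windows
#'
#' Half-open calendar bins `[origin + k*w, origin + (k+1)*w)` in years.
#' Bin `k` carries the year offset `k*w` (its start year minus the origin),
#' the convention under which the fitted log-linear trend maps directly to
#' per-bin expected counts. A final bin that the observation window only
#' partially covers is flagged and its covered fraction recorded, so the
#' trend fit can use it as an exposure offset.
#'
#' @param incidents an `incident_df` (or a `Date` vector).
#' @param width_years bin width, 1 or 2.
#' @param origin_year first bin's start year (default 1982).
#' @param end_date last date of the observation window (default: the last
#'   incident), used to measure coverage of the final bin.
#' @return object of class `binned_counts`: data.frame with `bin_start`,
#'   `year_offset`, `count`, `fraction` plus attributes.
#' @export
bin_counts <- function(incidents, width_years = 2L, origin_year = 1982L,
                       end_date = NULL) {
  stopifnot(width_years %in% c(1L, 2L))
  dates <- if (inherits(incidents, "incident_df")) incidents$date
           else as.Date(incidents)
  if (length(dates) == 0L) stop("no incidents to bin")
  yr <- as.integer(format(dates, "%Y"))
  if (any(yr < origin_year)) stop("incident before the origin year")
  k <- (yr - origin_year) %/% width_years
  if (is.null(end_date)) end_date <- max(dates)
  end_date <- as.Date(end_date)
  k_max <- (as.integer(format(end_date, "%Y")) - origin_year) %/% width_years
  counts <- tabulate(k + 1L, nbins = k_max + 1L)
  bin_start <- origin_year + (0:k_max) * width_years
  bin_start_date <- as.Date(paste0(bin_start, "-01-01"))
  bin_end_date <- as.Date(paste0(bin_start + width_years, "-01-01"))
  fraction <- rep(1, k_max + 1L)
  covered <- as.numeric(end_date + 1L - bin_start_date[k_max + 1L]) /
    as.numeric(bin_end_date[k_max + 1L] - bin_start_date[k_max + 1L])
  fraction[k_max + 1L] <- min(1, covered)
  out <- data.frame(bin_start = bin_start,
                    year_offset = (0:k_max) * width_years,
                    count = counts, fraction = fraction)
  structure(out, class = c("binned_counts", "data.frame"),
            width_years = width_years, origin_year = origin_year,
            partial_final = fraction[k_max + 1L] < 1)
}

#' Fit the log-linear (optionally quadratic) Poisson trend
#'
#' Poisson regression of bin counts on the year offset, fitted by
#' iteratively reweighted least squares ([stats::glm()]). Reports Wald
#' p-values, AIC, and the Pearson overdispersion statistic
#' `sum((y - mu)^2 / mu) / (n - k)`. When the final bin is partial its
#' covered fraction enters as an exposure offset (disable with
#' `use_exposure = FALSE` for the naive fit).
#'
#' @param binned a `binned_counts`.
#' @param degree 1 (linear) or 2 (adds a quadratic year term).
#' @param use_exposure include `log(fraction)` as an offset (default TRUE).
#' @return object of class `trend_fit`: coefficients, their covariance,
#'   `aic`, `pearson_dispersion`, `slope_p_value`, `quadratic_p_value`
#'   (degree 2 only), and the underlying `glm`.
#' @export
fit_trend <- function(binned, degree = 1L, use_exposure = TRUE) {
  stopifnot(degree %in% c(1L, 2L))
  if (nrow(binned) < degree + 2L) stop("too few bins for this degree")
  if (all(binned$count == 0L)) stop("all bin counts are zero")
  df <- data.frame(count = binned$count, t = binned$year_offset,
                   fraction = binned$fraction)
  off <- if (use_exposure) log(df$fraction) else rep(0, nrow(df))
  form <- if (degree == 1L) count ~ t else count ~ t + I(t^2)
  g <- glm(form, family = poisson(), data = df, offset = off)
  cf <- summary(g)$coefficients
  disp <- sum((df$count - g$fitted.values)^2 / g$fitted.values) /
    g$df.residual
  structure(list(
    coefficients = coef(g),
    vcov = vcov(g),
    aic = g$aic,
    pearson_dispersion = disp,
    slope_p_value = cf["t", "Pr(>|z|)"],
    quadratic_p_value = if (degree == 2L) cf["I(t^2)", "Pr(>|z|)"] else NA_real_,
    degree = degree,
    bin_width_years = attr(binned, "width_years"),
    origin_year = attr(binned, "origin_year"),
    glm = g),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson trend (degree %d, %d-year bins): log(lambda) = %.5f %+.5f t%s\n",
    x$degree, x$bin_width_years, x$coefficients[1], x$coefficients[2],
    if (x$degree == 2L) sprintf(" %+.5f t^2", x$coefficients[3]) else ""))
  cat(sprintf("  AIC %.1f, Pearson dispersion %.2f, slope p = %.2g\n",
              x$aic, x$pearson_dispersion, x$slope_p_value))
  invisible(x)
}

#' Compare two trend fits by AIC
#'
#' Lower AIC is preferred; on an exact tie the biannual binning is chosen
#' (with a note), as the coarser model of the pair.
#'
#' @param fit_annual,fit_biannual `trend_fit`s on 1- and 2-year bins.
#' @return list with `preferred` (`"annual"` or `"biannual"`),
#'   `delta_aic` (annual minus biannual) and the two AICs.
#' @export
compare_aic <- function(fit_annual, fit_biannual) {
  delta <- fit_annual$aic - fit_biannual$aic
  preferred <- if (delta > 0) "biannual" else if (delta < 0) "annual"
               else {
                 message("AIC tie; preferring the biannual binning")
                 "biannual"
               }
  list(preferred = preferred, delta_aic = delta,
       aic_annual = fit_annual$aic, aic_biannual = fit_biannual$aic)
}

#' Homogeneous-process inter-arrival MLE of the event rate
#'
#' Under a homogeneous Poisson process the inter-arrival times are
#' exponential with rate lambda; the MLE from an observed series is
#' `(n - 1) / span`, the number of gaps divided by the days between the
#' first and last events. The monthly rate uses an average month of
#' 365.25/12 days.
#'
#' @param dates incident dates (>= 2, first != last) or an `incident_df`.
#' @return list with `rate_daily`, `rate_monthly`, `n_events`, `span_days`.
#' @export
interarrival_mle <- function(dates) {
  if (inherits(dates, "incident_df")) dates <- dates$date
  dates <- sort(as.Date(dates))
  n <- length(dates)
  if (n < 2L) stop("need at least two incidents")
  span <- as.numeric(dates[n] - dates[1L])
  if (span == 0) stop("first and last incidents share a date")
  rate_daily <- (n - 1) / span
  list(rate_daily = rate_daily,
       rate_monthly = rate_daily * 365.25 / 12,
       n_events = n, span_days = span)
}

#' Forecast the probability of at least one event within t months
#'
#' For a constant monthly rate lambda the waiting time to the next event is
#' exponential, so `P(at least one event within t months) = 1 - exp(-lambda*t)`:
#' strictly increasing in both the rate and the horizon.
#'
#' @param monthly_rate events per month (> 0).
#' @param horizons months ahead (non-negative).
#' @return data.frame of class `risk_forecast` with `months`,
#'   `probability` (full precision) and `probability_3dp` (half-up
#'   rounding, the presentation convention).
#' @export
risk_table <- function(monthly_rate, horizons = c(1, 2, 3, 6, 9, 12)) {
  if (monthly_rate <= 0) stop("rate must be positive")
  if (any(horizons < 0)) stop("negative horizon")
  p <- 1 - exp(-monthly_rate * horizons)
  out <- data.frame(months = horizons, probability = p,
                    probability_3dp = round_half_up(p, 3L))
  structure(out, class = c("risk_forecast", "data.frame"),
            monthly_rate = monthly_rate)
}

round_half_up <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Monthly rate implied by a fitted trend at a year offset
#'
#' Converts the bin-level expected count `exp(b1 + b2*offset [+ b3*offset^2])`
#' to a monthly rate by dividing by the months per bin (24 for biannual, 12
#' for annual bins).
#'
#' @param fit a `trend_fit`, or a coefficient vector `(b1, b2[, b3])`.
#' @param year_offset years since the origin at which to evaluate.
#' @param bin_width_years needed when `fit` is a bare coefficient vector.
#' @return events per month.
#' @export
predict_monthly_rate <- function(fit, year_offset, bin_width_years = 2) {
  if (inherits(fit, "trend_fit")) {
    cf <- fit$coefficients
    bin_width_years <- fit$bin_width_years
  } else cf <- fit
  eta <- cf[1] + cf[2] * year_offset +
    if (length(cf) >= 3L) cf[3] * year_offset^2 else 0
  unname(exp(eta) / (12 * bin_width_years))
}

#' Smooth the inter-arrival series with a fixed-df smoothing spline
#'
#' Natural cubic smoothing spline with the penalty chosen so the trace of
#' the smoother matrix equals `df` (via [stats::smooth.spline()]), the
#' generalized-additive-model presentation of the declining inter-arrival
#' trend.
#'
#' @param x predictor (event index or date).
#' @param y inter-arrival values; if `x` is an `interval_df`, taken from it.
#' @param df effective degrees of freedom (default 4).
#' @return list with `x`, `fitted`, `df`, and the `smooth.spline` object.
#' @export
smooth_interarrival <- function(x, y = NULL, df = 4) {
  if (inherits(x, "interval_df")) {
    y <- x$interval_days
    x <- x$index
  }
  x <- as.numeric(x)
  if (length(unique(x)) < df + 1) stop("fewer distinct points than df + 1")
  fit <- smooth.spline(x, y, df = df, all.knots = TRUE)
  fv <- predict(fit, x)$y
  list(x = x, fitted = fv, df = fit$df, spline = fit)
}
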