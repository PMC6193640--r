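test_that("bin_counts uses half-open calendar bins with start offsets", {
  inc <- incident_table(as.Date(c("1982-06-01", "1983-12-31")),
                        c("TX", "CA"), c(4L, 5L), c(0L, 0L))
  b <- bin_counts(inc, 2L)
  expect_equal(b$count[1], 2L)       # 1982 and 1983 share bin 0
  expect_equal(b$year_offset[1], 0)

  dates <- simulate_nhpp_events(0.55683, 0.05033, seed = 12)
  b2 <- bin_counts(dates, 2L, end_date = as.Date("2018-05-31"))
  expect_equal(sum(b2$count), length(dates))   # conservation
  expect_true(attr(b2, "partial_final"))
  expect_lt(b2$fraction[nrow(b2)], 1)

  # biannual counts equal summed annual pairs
  b1y <- bin_counts(dates, 1L, end_date = as.Date("2018-05-31"))
  pair <- tapply(b1y$count, (seq_len(nrow(b1y)) - 1L) %/% 2L, sum)
  expect_equal(unname(b2$count), unname(as.integer(pair)))

  expect_error(bin_counts(as.Date("1980-01-01")), "origin")
})

test_that("fit_trend recovers coefficients and reports diagnostics", {
  # flat series: slope ~ 0, intercept ~ log(c)
  counts <- rep(7L, 15)
  bn <- structure(
    data.frame(bin_start = 1982 + seq(0, 28, 2), year_offset = seq(0, 28, 2),
               count = counts, fraction = 1),
    class = c("binned_counts", "data.frame"),
    width_years = 2L, origin_year = 1982L, partial_final = FALSE)
  f <- fit_trend(bn)
  expect_lt(abs(f$coefficients[2]), 1e-8)
  expect_equal(unname(f$coefficients[1]), log(7), tolerance = 1e-8)

  # noiseless exponential counts reproduce the generating coefficients
  t <- seq(0, 34, 2)
  bn2 <- structure(
    data.frame(bin_start = 1982 + t, year_offset = t,
               count = as.integer(round(exp(0.557 + 0.0503 * t))),
               fraction = 1),
    class = c("binned_counts", "data.frame"),
    width_years = 2L, origin_year = 1982L, partial_final = FALSE)
  f2 <- fit_trend(bn2)
  # independent oracle: Newton iteration on the Poisson log-likelihood
  bb <- c(0, 0)
  Xd <- cbind(1, t)
  for (k in 1:50) {
    mu <- exp(Xd %*% bb)
    bb <- bb + solve(crossprod(Xd, Xd * as.vector(mu)),
                     crossprod(Xd, bn2$count - mu))
  }
  expect_equal(unname(f2$coefficients), as.vector(bb), tolerance = 1e-8)
  expect_lt(abs(f2$coefficients[2] - 0.0503), 1e-2)
  # integer rounding of the small early-bin counts floors the achievable
  # intercept accuracy near 0.013
  expect_lt(abs(f2$coefficients[1] - 0.557), 2e-2)

  # quadratic term is available and carries a p-value
  f3 <- fit_trend(bn2, degree = 2L)
  expect_false(is.na(f3$quadratic_p_value))

  # equidispersed Poisson null: median Pearson dispersion near 1
  disp <- vapply(1:100, function(s) {
    set.seed(s)
    bd <- bn
    bd$count <- rpois(15, 7)
    if (all(bd$count == 0)) return(NA_real_)
    fit_trend(bd)$pearson_dispersion
  }, numeric(1))
  expect_gt(median(disp, na.rm = TRUE), 0.6)
  expect_lt(median(disp, na.rm = TRUE), 1.5)

  bad <- bn; bad$count <- rep(0L, 15)
  expect_error(fit_trend(bad), "zero")
})

test_that("AIC comparison prefers the lower value with a biannual tie rule", {
  dates <- simulate_nhpp_events(0.55683, 0.05033, seed = 44)
  fa <- fit_trend(bin_counts(dates, 1L, end_date = as.Date("2018-05-31")))
  fb <- fit_trend(bin_counts(dates, 2L, end_date = as.Date("2018-05-31")))
  cmp <- compare_aic(fa, fb)
  expect_equal(cmp$preferred,
               if (cmp$aic_biannual <= cmp$aic_annual) "biannual"
               else "annual")
  expect_equal(cmp$delta_aic, fa$aic - fb$aic)

  expect_message(tie <- compare_aic(fb, fb), "tie")
  expect_equal(tie$preferred, "biannual")

  # AIC definition: -2 loglik + 2k, checked against the glm by hand
  g <- fb$glm
  expect_equal(fb$aic, -2 * as.numeric(logLik(g)) + 2 * 2,
               tolerance = 1e-8)

  # biannual binning preferred in the majority of replicates
  pref <- vapply(1:40, function(i) {
    d <- simulate_nhpp_events(0.55683, 0.05033, seed = 8000 + i)
    compare_aic(
      fit_trend(bin_counts(d, 1L, end_date = as.Date("2018-05-31"))),
      fit_trend(bin_counts(d, 2L, end_date = as.Date("2018-05-31"))))$preferred
  }, character(1))
  expect_gt(mean(pref == "biannual"), 0.5)
})

test_that("inter-arrival MLE converts to a monthly rate", {
  # gaps of exactly one average month give rate 1/month
  d0 <- as.Date("2000-01-01")
  dates <- d0 + round((0:48) * 30.4375)
  expect_equal(interarrival_mle(dates)$rate_monthly, 1.0, tolerance = 1e-3)

  # 100 events spanning Feb 1982 to May 2018
  span_dates <- c(as.Date("1982-02-01"),
                  sort(sample(seq(as.Date("1982-02-02"),
                                  as.Date("2018-04-30"), by = 1), 98)),
                  as.Date("2018-05-01"))
  m <- interarrival_mle(span_dates)
  expect_equal(m$n_events, 100L)
  expect_equal(round(m$rate_monthly, 3), 0.228)

  expect_equal(interarrival_mle(d0 + c(0, 100))$rate_daily, 0.01)
  expect_error(interarrival_mle(d0), "two")
  expect_error(interarrival_mle(c(d0, d0)), "share a date")

  # scale equivariance: c times the spacing divides the rate by c
  base <- d0 + c(0, 13, 40, 95)
  wide <- d0 + c(0, 13, 40, 95) * 3
  expect_equal(interarrival_mle(base)$rate_daily,
               3 * interarrival_mle(wide)$rate_daily)
})

test_that("risk_table computes exponential-waiting-time probabilities", {
  rt <- risk_table(0.227, c(0, 1, 3))
  expect_equal(rt$probability[1], 0)
  expect_equal(rt$probability_3dp[2:3], c(0.203, 0.494))

  # strictly increasing in horizon and in rate; limit -> 1
  rt2 <- risk_table(0.468, c(1, 2, 6, 12, 600))
  expect_true(all(diff(rt2$probability) > 0))
  expect_true(all(risk_table(0.468, 1:6)$probability >
                    risk_table(0.227, 1:6)$probability))
  expect_equal(rt2$probability[5], 1, tolerance = 1e-12)

  expect_error(risk_table(0), "positive")
  expect_error(risk_table(0.2, -1), "horizon")
})

test_that("predict_monthly_rate converts bin-level intensity", {
  expect_equal(predict_monthly_rate(c(log(24), 0), 17), 1.0)
  expect_equal(predict_monthly_rate(c(0.55683, 0.05033), 0),
               exp(0.55683) / 24)
  # through a fitted object the bin width is taken from the fit
  t <- seq(0, 34, 2)
  bn <- structure(
    data.frame(bin_start = 1982 + t, year_offset = t,
               count = as.integer(round(exp(0.557 + 0.0503 * t))),
               fraction = 1),
    class = c("binned_counts", "data.frame"),
    width_years = 2L, origin_year = 1982L, partial_final = FALSE)
  f <- fit_trend(bn)
  expect_equal(predict_monthly_rate(f, 0),
               exp(f$coefficients[1]) / 24, ignore_attr = TRUE)
})

test_that("slope recovery holds under the fitted NHPP regime", {
  a <- 0.55683; b <- 0.05033
  hit <- vapply(1:60, function(i) {
    dates <- simulate_nhpp_events(a, b, seed = 2000 + i)
    f <- fit_trend(bin_counts(dates, 2L, end_date = as.Date("2018-05-31")))
    abs(f$coefficients[2] - b) <= 1.96 * sqrt(f$vcov[2, 2])
  }, logical(1))
  expect_gt(mean(hit), 0.85)
})

test_that("the fixed-df smoother reproduces lines and tracks decline", {
  x <- 1:30
  y <- 5 - 0.2 * x
  s <- smooth_interarrival(x, y, df = 4)
  expect_lt(max(abs(s$fitted - y)), 1e-6)
  expect_equal(s$df, 4, tolerance = 0.05)

  # df -> n approaches interpolation
  set.seed(2)
  yn <- y + rnorm(30, 0, 0.5)
  si <- smooth_interarrival(x, yn, df = 29)
  expect_lt(max(abs(si$fitted - yn)), 0.1)
  expect_error(smooth_interarrival(x, yn, df = 29.5), "df")

  # noisy declining inter-arrival series: fitted trend is decreasing
  set.seed(3)
  decl <- exp(5 - 0.05 * (1:80)) * exp(rnorm(80, 0, 0.6))
  sd4 <- smooth_interarrival(1:80, log(decl), df = 4)
  expect_lt(cor(sd4$fitted, 1:80, method = "spearman"), 0)

  expect_error(smooth_interarrival(1:4, 1:4, df = 4), "df")
})
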