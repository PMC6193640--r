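test_that("generators are pure functions of parameters and seed", {
  p1 <- simulate_state_panel(seed = 11)
  p2 <- simulate_state_panel(seed = 11)
  expect_identical(p1$states, p2$states)
  d1 <- simulate_nhpp_events(0.55683, 0.05033, seed = 3)
  d2 <- simulate_nhpp_events(0.55683, 0.05033, seed = 3)
  expect_identical(d1, d2)
  expect_false(identical(d1, simulate_nhpp_events(0.55683, 0.05033,
                                                  seed = 4)))
  s1 <- simulate_study(seed = 5)
  s2 <- simulate_study(seed = 5)
  expect_identical(s1$incidents, s2$incidents)
  expect_identical(s1$media, s2$media)
  # generators restore the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_study(seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("ICAR panel simulation honors its structural limits", {
  # structural-zero probability 1 forces all counts to zero
  tr <- sim_truth(zero_model = c(30, 0, 0, 0, 0))
  p <- simulate_state_panel(truth = tr, seed = 2)
  expect_true(all(p$states$incident_count == 0L))

  # sigma -> 0, beta = (log mu, 0...), population 1: i.i.d. Poisson(mu)
  mu <- 3
  tr2 <- sim_truth(beta = c(log(mu), 0, 0, 0, 0),
                   zero_model = c(-30, 0, 0, 0, 0),
                   sigma_v = 1e-8, sigma_u = 1e-8,
                   pop_meanlog = 0, pop_sdlog = 0)
  cnt <- simulate_state_panel(truth = tr2, seed = 3)$states$incident_count
  expect_lt(abs(mean(cnt) - mu), 3 * sqrt(mu / 50))

  # realized ICAR effect sums to zero within the connected component
  tr3 <- sim_truth()
  p3 <- simulate_state_panel(truth = tr3, seed = 4)
  v <- attr(p3, "truth")$v
  iso <- rowSums(p3$adjacency) == 0
  expect_lt(abs(sum(v[!iso])), 1e-8)
  expect_true(all(v[iso] == 0))

  expect_error(simulate_state_panel(adjacency = matrix(c(0, 1, 0, 0), 2),
                                    n_states = 2),
               "symmetric|n_states")
})

test_that("default panel preset matches the study conditions", {
  zeros <- totals <- numeric(30)
  for (i in seq_len(30)) {
    p <- simulate_state_panel(seed = 4000 + i)
    zeros[i] <- sum(p$states$incident_count == 0L)
    totals[i] <- sum(p$states$incident_count)
  }
  # ~19 of 50 states without incidents, ~100 incidents nationally
  expect_gt(mean(zeros), 15)
  expect_lt(mean(zeros), 23)
  expect_gt(mean(totals), 80)
  expect_lt(mean(totals), 120)
  # ZIP property: with positive structural-zero mass the empirical zero
  # count systematically exceeds what the Poisson component alone implies
  excess <- vapply(seq_len(30), function(i) {
    p <- simulate_state_panel(seed = 4000 + i)
    tr <- attr(p, "truth")
    s <- p$states
    X <- cbind(1, s$fss_ratio, s$mental_illness_rate, s$poverty_rate,
               s$permissiveness)
    mu <- s$population * exp(as.vector(X %*% tr$beta) + tr$v + tr$u)
    sum(s$incident_count == 0L) - sum(exp(-mu))
  }, numeric(1))
  expect_gt(mean(excess), 0)
})

test_that("NHPP thinning reproduces its intensity", {
  # homogeneous limit
  lamT <- exp(0.7) / 2 * 10
  n0 <- vapply(1:500, function(s)
    length(simulate_nhpp_events(0.7, 0, 0, 10, seed = s, as_date = FALSE)),
    numeric(1))
  expect_lt(abs(mean(n0) - lamT), 3 * sqrt(lamT / 500))

  # printed-coefficient regime: mean total matches the analytic integral
  a <- 0.55683; b <- 0.05033
  expected <- exp(a) * (exp(36.4 * b) - 1) / (exp(2 * b) - 1)
  n1 <- vapply(1:300, function(s)
    length(simulate_nhpp_events(a, b, seed = 9000 + s)), numeric(1))
  expect_lt(abs(mean(n1) - expected), 3 * sqrt(expected / 300))

  # per-bin chi-square goodness of fit over 500 replicates
  tot <- numeric(18)
  for (s in 1:500) {
    t <- simulate_nhpp_events(a, b, 0, 36, seed = 20000 + s,
                              as_date = FALSE)
    tot <- tot + tabulate(floor(t / 2) + 1L, nbins = 18L)
  }
  E <- 500 * exp(a + b * seq(0, 34, by = 2))
  chisq <- sum((tot - E)^2 / E)
  expect_gt(pchisq(chisq, df = 18, lower.tail = FALSE), 0.01)

  # degenerate window and overflow guard
  expect_length(simulate_nhpp_events(1, 0.1, 5, 5, seed = 1), 0L)
  expect_error(simulate_nhpp_events(0, 20, 0, 36), "overflow")
})

test_that("casualty attachment respects the case definition", {
  dates <- simulate_nhpp_events(0.55683, 0.05033, seed = 7)
  inc <- attach_casualties(dates, seed = 8)
  expect_true(all(inc$fatalities >= 4L))
  expect_true(all(inc$injuries >= 0L))

  # zero excess mass degenerates to exactly 4 fatalities
  tr0 <- sim_truth(fatality_excess_mean = 0, injury_mean = 0)
  inc0 <- attach_casualties(dates, truth = tr0, seed = 9)
  expect_true(all(inc0$fatalities == 4L))
  expect_true(all(inc0$injuries == 0L))

  # calibrated means: 833 deaths / 1292 injured per 100 events
  big <- attach_casualties(rep(as.Date("2000-01-01"), 4000) + seq_len(4000),
                           seed = 10)
  expect_lt(abs(mean(big$fatalities) - 8.33), 0.5)
  expect_lt(abs(mean(big$injuries) - 12.92), 1.2)
})

test_that("media generator hits its rank-correlation target", {
  set.seed(31)
  days <- rexp(80, 1 / 130) + 1

  # null coupling
  m0 <- simulate_media(days, rho_target = 0, seed = 1)
  expect_lt(abs(cor(m0$article_count / days, days, method = "spearman")),
            0.25)

  # copula Monte-Carlo oracle: mean sample Spearman near -0.70
  rhos <- vapply(1:200, function(s) {
    m <- simulate_media(days, rho_target = -0.70, seed = 100 + s)
    cor(m$article_count / days, days, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), -0.80)
  expect_lt(mean(rhos), -0.60)

  # search interest is rescaled so the peak is exactly 100
  m <- simulate_media(days, seed = 3)
  expect_equal(max(m$search_interest), 100)
  expect_true(all(m$search_interest >= 0 & m$search_interest <= 100))

  expect_error(simulate_media(days, rho_target = -1), "unattainable")
  expect_error(simulate_media(c(-1, 2)), "positive")
})

test_that("simulate_study produces a coherent linked bundle", {
  st <- simulate_study(seed = 77)
  expect_equal(sum(st$panel$states$incident_count), nrow(st$incidents))
  expect_equal(nrow(st$intervals), nrow(st$incidents) - 1L)
  expect_true(all(diff(st$incidents$date) > 0))
  expect_equal(st$intervals$media_density,
               st$intervals$media_article_count /
                 st$intervals$interval_days)
  # write + reread the full bundle
  d <- withr::local_tempdir()
  paths <- write_study(st, d)
  expect_true(all(file.exists(paths)))
  back <- read_incidents(paths["incidents"])
  expect_identical(back$date, st$incidents$date)
  panel <- read_state_panel(paths["states"], paths["adjacency"],
                            incidents = back)
  expect_equal(panel$states$incident_count,
               st$panel$states$incident_count)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$rho_target, st$truth$rho_target)
})
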