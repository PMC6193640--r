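test_that("zip_loglik matches closed forms and collapses to Poisson", {
  # single state, y = 0, mu = 1, pi = 0.5
  X <- matrix(1, 1, 1)
  expect_equal(zip_loglik(0L, X, 0, beta = 0, gamma = 0),
               log(0.5 + 0.5 * exp(-1)))
  # gamma -> -Inf (pi = 0): plain Poisson log-likelihood, computed
  # independently through dpois
  y <- c(0L, 2L, 5L)
  X3 <- cbind(1, c(0.2, 0.5, 0.9))
  off <- log(c(2, 3, 4))
  beta <- c(-0.3, 1.1)
  mu <- exp(off + as.vector(X3 %*% beta))
  expect_equal(zip_loglik(y, X3, off, beta, gamma = c(-500, 0)),
               sum(dpois(y, mu, log = TRUE)), tolerance = 1e-12)
  expect_equal(zip_loglik(y, X3, off, beta), sum(dpois(y, mu, log = TRUE)))
  expect_error(zip_loglik(c(-1L, 0L, 1L), X3, off, beta), "non-negative")
  expect_error(zip_loglik(c(0.5, 0, 1), X3, off, beta), "non-negative")
})

test_that("zip_loglik equals the brute-force mixture oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    X <- cbind(1, matrix(rnorm(3 * n), n, 3))
    off <- log(runif(n, 1, 10))
    beta <- rnorm(4, 0, 0.5)
    gamma <- rnorm(4, 0, 0.7)
    v <- rnorm(n, 0, 0.3); u <- rnorm(n, 0, 0.3)
    mu <- exp(off + as.vector(X %*% beta) + v + u)
    y <- ifelse(runif(n) < 0.4, 0L, rpois(n, mu))
    expect_equal(zip_loglik(y, X, off, beta, v, u, gamma),
                 zip_loglik_bruteforce(y, X, off, beta, v, u, gamma),
                 tolerance = 1e-10)
  }
})

test_that("the sampler is deterministic and structurally correct", {
  p <- simulate_state_panel(seed = 42)
  f1 <- suppressWarnings(fit_zip_car_mcmc(
    p, n_chains = 2, n_iter = 3000, thin = 3, seed = 7))
  f2 <- suppressWarnings(fit_zip_car_mcmc(
    p, n_chains = 2, n_iter = 3000, thin = 3, seed = 7))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$v, f2$v)

  # zero-sum constraint on the structured effect, per stored draw
  iso <- colnames(f1$v) %in% c("AK", "HI")
  expect_lt(max(abs(rowMeans(f1$v[, !iso]))), 1e-8)
  expect_true(all(f1$v[, iso] == 0))

  # Poisson variant omits the zero model
  fp <- suppressWarnings(fit_poisson_car_mcmc(
    p, n_chains = 2, n_iter = 3000, thin = 3, seed = 7))
  expect_null(fp$gamma)
  expect_false(is.null(f1$gamma))

  # Rhat reported for every scalar parameter (minus the pinned ones)
  expect_gte(length(f1$rhat), 5 + 5 + 48 + 50 + 2)
})

test_that("posterior summaries are ordered and degenerate draws collapse", {
  p <- simulate_state_panel(seed = 13)
  f <- suppressWarnings(fit_zip_car_mcmc(
    p, n_chains = 2, n_iter = 4000, thin = 4, seed = 2))
  s <- summarize_posterior(f)
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  expect_equal(nrow(summarize_posterior(f, "beta")), 5L)

  # constant draws: mean = median = both percentiles, pD = 0,
  # DIC = deviance at that point, under both foci
  fc <- f
  for (nm in c("beta", "gamma", "v", "u")) {
    fc[[nm]] <- matrix(colMeans(f[[nm]]), nrow(f[[nm]]), ncol(f[[nm]]),
                       byrow = TRUE, dimnames = dimnames(f[[nm]]))
  }
  fc$tau_v <- rep(exp(mean(log(f$tau_v))), length(f$tau_v))
  fc$tau_u <- rep(exp(mean(log(f$tau_u))), length(f$tau_u))
  d <- massincidence:::panel_design(p)
  fc$loglik <- rep(zip_loglik(d$y, d$X, d$offset, fc$beta[1, ],
                              fc$v[1, ], fc$u[1, ], fc$gamma[1, ]),
                   length(f$loglik))
  sc <- summarize_posterior(fc, "beta")
  expect_equal(sc$mean, sc$median)
  expect_equal(sc$q2.5, sc$q97.5)
  for (focus in c("conditional", "marginal")) {
    dic <- compute_dic(fc, p, focus = focus)
    expect_equal(dic$p_d, 0, tolerance = 1e-6)
    expect_equal(dic$dic, dic$d_hat, tolerance = 1e-6)
  }
})

test_that("ZIP and Poisson agree on data without excess zeros", {
  tr <- sim_truth(zero_model = c(-30, 0, 0, 0, 0))
  p <- simulate_state_panel(truth = tr, seed = 21)
  fz <- suppressWarnings(fit_zip_car_mcmc(
    p, n_chains = 2, n_iter = 8000, thin = 4, seed = 3))
  fp <- suppressWarnings(fit_poisson_car_mcmc(
    p, n_chains = 2, n_iter = 8000, thin = 4, seed = 3))
  for (j in 1:5) {
    mc <- sqrt(mcse_batch(fz$beta[, j])^2 + mcse_batch(fp$beta[, j])^2)
    expect_lt(abs(mean(fz$beta[, j]) - mean(fp$beta[, j])), 6 * mc)
  }
  # the extra zero-model block costs effective parameters
  expect_gt(fz$dic$p_d, fp$dic$p_d - 3)
})

test_that("a 50-state fit recovers known coefficients", {
  truth <- sim_truth()
  p <- simulate_state_panel(truth = truth, seed = 314)
  f <- suppressWarnings(fit_zip_car_mcmc(
    p, n_chains = 2, n_iter = 8000, thin = 4, seed = 1))
  s <- summarize_posterior(f, "beta")
  expect_true(all(abs(s$mean - truth$beta) <= 2.5 * s$sd))
  # paper-like regime (covariate effects ~ 0): FS/S interval brackets 0
  expect_lt(s$q2.5[2], 0)
  expect_gt(s$q97.5[2], 0)
})

test_that("a degenerate all-zero panel is handled without crashing", {
  tr <- sim_truth(zero_model = c(30, 0, 0, 0, 0))
  p <- simulate_state_panel(truth = tr, seed = 6)
  f <- suppressWarnings(fit_zip_car_mcmc(
    p, n_chains = 2, n_iter = 3000, thin = 3, seed = 1))
  s <- summarize_posterior(f, "beta")
  # beta is data-starved: intervals should be wide, not degenerate
  expect_gt(s$q97.5[1] - s$q2.5[1], 1)
  expect_true(is.finite(f$dic$dic))
})

test_that("kendall tau matches brute-force concordance counting", {
  p <- toy_panel(6L)
  k <- kendall_permissiveness(p)
  expect_equal(k$tau,
               kendall_bruteforce(p$states$fss_ratio,
                                  p$states$permissiveness),
               tolerance = 1e-12)
  expect_true(k$p_value > 0 && k$p_value <= 1)
  # perfectly concordant pair
  p2 <- toy_panel(6L)
  p2$states$permissiveness <- seq_len(6L)
  expect_equal(kendall_permissiveness(p2)$tau, 1.0)
})
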