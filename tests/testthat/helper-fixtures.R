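# Shared fixture builders: everything is generated in code at test time.

toy_incidents_csv <- function(path,
                              dates = c("2010-03-01", "2001-07-15",
                                        "2005-11-30"),
                              fatalities = c(5L, 4L, 7L),
                              injuries = c(2L, 0L, 11L),
                              states = c("TX", "CA", "OH")) {
  write.csv(data.frame(date = dates, state = states,
                       fatalities = fatalities, injuries = injuries),
            path, row.names = FALSE, quote = FALSE)
  path
}

# small ring-lattice panel with deterministic covariates
toy_panel <- function(n = 6L, counts = NULL) {
  codes <- sprintf("S%02d", seq_len(n))
  A <- matrix(0L, n, n, dimnames = list(codes, codes))
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    A[i, j] <- A[j, i] <- 1L
  }
  if (is.null(counts)) counts <- rep(1L, n)
  states <- data.frame(
    state = codes,
    population = seq(1e6, 2e6, length.out = n),
    fss_ratio = seq(0.3, 0.6, length.out = n),
    mental_illness_rate = seq(14, 20, length.out = n),
    poverty_rate = seq(10, 16, length.out = n),
    permissiveness = rep(c(0L, 1L), length.out = n),
    incident_count = counts)
  state_panel(states, A)
}

# independent brute-force ZIP mixture log-likelihood (direct density sums,
# no log-sum-exp), used as the oracle for zip_loglik
zip_loglik_bruteforce <- function(y, X, offset, beta, v, u, gamma) {
  mu <- exp(offset + as.vector(X %*% beta) + v + u)
  pi <- 1 / (1 + exp(-as.vector(X %*% gamma)))
  terms <- ifelse(y == 0,
                  pi + (1 - pi) * dpois(0L, mu),
                  (1 - pi) * dpois(y, mu))
  sum(log(terms))
}

# all-pairs Kendall tau-b with tie corrections (concordance counting)
kendall_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# batch-means Monte-Carlo standard error of a draw vector
mcse_batch <- function(x, n_batch = 20L) {
  b <- length(x) %/% n_batch
  means <- vapply(seq_len(n_batch),
                  function(k) mean(x[((k - 1L) * b + 1L):(k * b)]),
                  numeric(1))
  sd(means) / sqrt(n_batch)
}

quick_mcmc <- list(n_chains = 2L, n_iter = 6000L, thin = 3L)
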