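# Synthetic-data generators. Every generator is a pure function of
# (parameters, seed): the RNG state of the caller is saved and restored.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Ground-truth parameter set for the synthetic study
#'
#' Bundles every parameter the generators use, so that each simulated
#' dataset carries the truth it was drawn from (for parameter-recovery
#' tests). The defaults are the package's emulation of the study
#' conditions: ~100 incidents over 1982--2018 from a log-linear-intensity
#' non-homogeneous Poisson process, state counts that are zero in about 19
#' of 50 states, covariate effects at zero (no state-level predictor is
#' informative), mean casualties matching the national totals (8.33 killed,
#' 12.92 injured per event), and media densities whose rank correlation
#' with the following inter-incident interval is about -0.70.
#'
#' @param beta Poisson-part coefficients (intercept, FS/S, mental-illness
#'   rate, poverty rate, permissiveness) on the log scale over raw
#'   covariate units, with log population as an offset.
#' @param zero_model logit-scale coefficients of the excess-zero model
#'   (same design as `beta`).
#' @param sigma_v,sigma_u standard deviations of the structured (ICAR) and
#'   unstructured state effects.
#' @param intensity_a,intensity_b log-linear intensity of the national
#'   process: the expected count of a 2-year bin starting at year-offset t
#'   is `exp(intensity_a + intensity_b * t)`.
#' @param rho_target Spearman correlation coupling media density to the
#'   following interval.
#' @param fatality_excess_mean,fatality_dispersion negative-binomial mean
#'   and size of fatalities in excess of the 4-victim definition floor;
#'   excess mean 0 makes every event exactly 4 fatalities.
#' @param injury_mean,injury_dispersion negative-binomial mean/size for
#'   injuries.
#' @param pop_meanlog,pop_sdlog lognormal population distribution.
#' @param density_meanlog,density_sdlog lognormal marginal of media
#'   coverage density (articles/day).
#' @param seed default RNG seed recorded with generated data.
#' @return object of class `sim_truth` (a named list).
#' @export
sim_truth <- function(beta = c(-15.1, 0, 0, 0, 0),
                      zero_model = c(-2.77, 0, 0, 0, 0),
                      sigma_v = 0.4, sigma_u = 0.3,
                      intensity_a = 0.55683, intensity_b = 0.05033,
                      rho_target = -0.70,
                      fatality_excess_mean = 4.33,
                      fatality_dispersion = 0.9,
                      injury_mean = 12.92, injury_dispersion = 0.45,
                      pop_meanlog = log(4.3e6), pop_sdlog = 0.95,
                      density_meanlog = log(30), density_sdlog = 1.0,
                      seed = 20180522L) {
  stopifnot(sigma_v > 0, sigma_u > 0, rho_target >= -1, rho_target <= 1,
            length(beta) == 5L, length(zero_model) == 5L,
            fatality_excess_mean >= 0, injury_mean >= 0)
  structure(list(beta = beta, zero_model = zero_model,
                 sigma_v = sigma_v, sigma_u = sigma_u,
                 intensity_a = intensity_a, intensity_b = intensity_b,
                 rho_target = rho_target,
                 fatality_excess_mean = fatality_excess_mean,
                 fatality_dispersion = fatality_dispersion,
                 injury_mean = injury_mean,
                 injury_dispersion = injury_dispersion,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 density_meanlog = density_meanlog,
                 density_sdlog = density_sdlog,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

# Draw one intrinsic-CAR (ICAR) vector: zero-sum Gaussian per connected
# component with precision sigma^{-2} * graph Laplacian (sampled on the
# positive eigenspace of the Laplacian pseudo-inverse). Isolated nodes get 0.
ricar <- function(adjacency, sigma) {
  n <- nrow(adjacency)
  comp <- graph_components(adjacency)
  v <- numeric(n)
  for (ids in comp) {
    if (length(ids) < 2L) next
    L <- diag(rowSums(adjacency[ids, ids, drop = FALSE])) -
      adjacency[ids, ids, drop = FALSE]
    e <- eigen(L, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    z <- rnorm(sum(pos))
    v[ids] <- as.vector(e$vectors[, pos, drop = FALSE] %*%
                          (z * sigma / sqrt(e$values[pos])))
    v[ids] <- v[ids] - mean(v[ids])
  }
  v
}

graph_components <- function(adjacency) {
  n <- nrow(adjacency)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(adjacency[frontier, , drop = FALSE] == 1L,
                  arr.ind = TRUE)[, 2]
      nb <- unique(nb[comp[nb] == 0L])
      comp[nb] <- cur
      frontier <- nb
    }
  }
  split(seq_len(n), comp)
}

#' Simulate a state covariate panel with zero-inflated spatial counts
#'
#' Draws covariates from documented plausible ranges, structured effects
#' from an intrinsic CAR on the supplied neighborhood graph, unstructured
#' effects i.i.d. normal, and counts from a zero-inflated Poisson whose
#' mean is `population * exp(x'beta + v + u)` with structural-zero
#' probability `plogis(x'gamma)`.
#'
#' @param n_states number of areas (>= 3); defaults to the 50 U.S. states.
#' @param adjacency symmetric 0/1 neighbor matrix; defaults to
#'   [us_adjacency()] when `n_states` is 50, otherwise a ring lattice.
#' @param truth a [sim_truth()].
#' @param seed RNG seed (default `truth$seed`).
#' @return a `state_panel` with attribute `"truth"` holding `truth`
#'   augmented with the realized `v`, `u` and structural-zero indicators.
#' @export
simulate_state_panel <- function(n_states = 50L, adjacency = NULL,
                                 truth = sim_truth(), seed = truth$seed) {
  stopifnot(n_states >= 3L)
  if (is.null(adjacency)) {
    if (n_states == 50L) {
      adjacency <- us_adjacency()
    } else {  # ring lattice fallback for generic sizes
      codes <- sprintf("S%02d", seq_len(n_states))
      adjacency <- matrix(0L, n_states, n_states,
                          dimnames = list(codes, codes))
      for (i in seq_len(n_states)) {
        j <- i %% n_states + 1L
        adjacency[i, j] <- adjacency[j, i] <- 1L
      }
    }
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency matrix is not symmetric")
  }
  if (nrow(adjacency) != n_states) stop("adjacency size != n_states")
  codes <- rownames(adjacency)
  with_seed(seed, {
    population <- rlnorm(n_states, truth$pop_meanlog, truth$pop_sdlog)
    fss <- runif(n_states, 0.2, 0.7)
    mental <- runif(n_states, 13, 25)
    poverty <- runif(n_states, 9, 20)
    perm <- if (all(MAY_ISSUE_STATES %in% codes)) {
      as.integer(codes %in% MAY_ISSUE_STATES)
    } else {
      rbinom(n_states, 1L, 9 / 50)
    }
    X <- cbind(1, fss, mental, poverty, perm)
    v <- ricar(adjacency, truth$sigma_v)
    u <- rnorm(n_states, 0, truth$sigma_u)
    mu <- population * exp(as.vector(X %*% truth$beta) + v + u)
    pi0 <- plogis(as.vector(X %*% truth$zero_model))
    z <- rbinom(n_states, 1L, pi0)
    counts <- ifelse(z == 1L, 0L, rpois(n_states, mu))
    states <- data.frame(state = codes, population = round(population),
                         fss_ratio = fss, mental_illness_rate = mental,
                         poverty_rate = poverty, permissiveness = perm,
                         incident_count = as.integer(counts),
                         stringsAsFactors = FALSE)
    panel <- state_panel(states, adjacency)
    tr <- truth
    tr$v <- v[match(panel$states$state, codes)]
    tr$u <- u[match(panel$states$state, codes)]
    tr$structural_zero <- z[match(panel$states$state, codes)]
    attr(panel, "truth") <- tr
    panel
  })
}

# Continuous intensity (events/year) matched to the binned trend model:
# the expected count of a bin of `bin_width` years starting at offset t0
# equals exp(a + b * t0).
nhpp_intensity <- function(t, a, b, bin_width = 2) {
  if (b == 0) return(rep(exp(a) / bin_width, length(t)))
  exp(a) * b / (exp(bin_width * b) - 1) * exp(b * t)
}

#' Simulate event times from a log-linear-intensity Poisson process
#'
#' Lewis--Shedler thinning against the dominating constant rate: candidate
#' points are drawn homogeneously at the maximum intensity over the window
#' and kept with probability `lambda(t) / lambda_max`. The intensity is
#' parameterized so that the expected count of a `bin_width`-year bin
#' starting at year-offset `t` is `exp(a + b * t)`, matching the binned
#' trend regression.
#'
#' @param a,b log-linear intensity intercept and slope (per year-offset).
#' @param t_start,t_end window in years since `origin_year` (default the
#'   Jan 1982 -- May 2018 study span).
#' @param seed RNG seed.
#' @param origin_year calendar year at offset 0.
#' @param bin_width_years bin width the intensity is calibrated to.
#' @param as_date return calendar `Date`s (default) or numeric year offsets.
#' @return sorted event times.
#' @export
simulate_nhpp_events <- function(a, b, t_start = 0, t_end = 36.4,
                                 seed = NULL, origin_year = 1982L,
                                 bin_width_years = 2,
                                 as_date = TRUE) {
  if (t_end < t_start) stop("t_end must be >= t_start")
  if (max(abs(c(a + b * t_start, a + b * t_end))) > 500) {
    stop("intensity overflow: |a + b*t| too large over the window")
  }
  with_seed(seed, {
    if (t_end == t_start) {
      t <- numeric(0)
    } else {
      lam <- function(t) nhpp_intensity(t, a, b, bin_width_years)
      lam_max <- max(lam(t_start), lam(t_end))
      n_cand <- rpois(1L, lam_max * (t_end - t_start))
      cand <- sort(runif(n_cand, t_start, t_end))
      t <- cand[runif(n_cand) < lam(cand) / lam_max]
    }
    if (!as_date) return(t)
    as.Date(paste0(origin_year, "-01-01")) + floor(t * 365.25)
  })
}

#' Attach simulated casualty counts to event dates
#'
#' Fatalities are 4 (the definition floor) plus a negative-binomial excess;
#' injuries are negative-binomial. Defaults are calibrated to the national
#' totals of 8.33 fatalities and 12.92 injuries per event.
#'
#' @param dates event dates (sorted `Date` vector).
#' @param truth a [sim_truth()] supplying the casualty parameters.
#' @param seed RNG seed.
#' @param states optional state codes to record per event.
#' @return an `incident_df`.
#' @export
attach_casualties <- function(dates, truth = sim_truth(),
                              seed = truth$seed, states = NULL) {
  n <- length(dates)
  with_seed(seed, {
    fat <- 4L + rnb(n, truth$fatality_excess_mean,
                    truth$fatality_dispersion)
    inj <- rnb(n, truth$injury_mean, truth$injury_dispersion)
    if (is.null(states)) states <- rep("XX", n)
    incident_table(dates, states, fat, inj)
  })
}

rnb <- function(n, mu, size) {
  if (mu == 0) return(integer(n))
  rnbinom(n, size = size, mu = mu)
}

#' Simulate per-interval media coverage coupled to interval length
#'
#' A Gaussian copula couples log media density to the interval length: the
#' intervals' normal scores are mixed with independent noise at the latent
#' correlation `2*sin(pi*rho_target/6)`, the value for which the implied
#' Spearman correlation of the bivariate normal equals `rho_target`.
#' Article counts are Poisson around density x days, and search interest is
#' a noisy monotone (power) transform of density rescaled so its maximum is
#' exactly 100, mirroring relative search-volume indices.
#'
#' @param interval_days positive interval lengths (days).
#' @param rho_target Spearman correlation between density and interval, in
#'   (-1, 1) (the degenerate endpoints are rejected because noise from the
#'   count and rescaling steps is always present).
#' @param truth a [sim_truth()] for the density marginal.
#' @param seed RNG seed.
#' @param search_power,search_noise monotone-transform exponent and
#'   lognormal noise SD for search interest.
#' @return data.frame with `interval_index`, `article_count`,
#'   `search_interest`.
#' @export
simulate_media <- function(interval_days, rho_target = -0.70,
                           truth = sim_truth(), seed = truth$seed,
                           search_power = 0.5, search_noise = 0.3) {
  n <- length(interval_days)
  if (n < 1L) stop("no intervals supplied")
  if (any(interval_days <= 0)) stop("interval_days must be positive")
  if (abs(rho_target) >= 1) {
    stop("|rho_target| = 1 is unattainable with noisy counts")
  }
  r <- 2 * sin(pi * rho_target / 6)  # latent normal corr for this Spearman
  with_seed(seed, {
    z1 <- qnorm((rank(interval_days, ties.method = "average") - 0.5) / n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    density <- exp(truth$density_meanlog + truth$density_sdlog * z2)
    counts <- rpois(n, density * interval_days)
    s_raw <- density^search_power * exp(rnorm(n, 0, search_noise))
    data.frame(interval_index = seq_len(n),
               article_count = counts,
               search_interest = 100 * s_raw / max(s_raw))
  })
}

#' Simulate the complete study input bundle
#'
#' Generates, under one truth and seed: the national event series (NHPP
#' with casualties, events assigned to states with probability proportional
#' to each state's modeled rate), the state covariate panel with counts
#' tallied from the incident table, and the per-interval media table
#' coupled to interval lengths. Same-date event collisions are resolved by
#' shifting the later event forward one day, keeping dates distinct.
#'
#' @param truth a [sim_truth()].
#' @param seed RNG seed (default `truth$seed`).
#' @param t_start,t_end study window in years since 1982.
#' @return list with elements `incidents` (`incident_df`), `panel`
#'   (`state_panel`), `intervals` (`interval_df` with media columns),
#'   `media` (raw media table), and `truth`.
#' @export
simulate_study <- function(truth = sim_truth(), seed = truth$seed,
                           t_start = 0, t_end = 36.4) {
  with_seed(seed, {
    dates <- simulate_nhpp_events(truth$intensity_a, truth$intensity_b,
                                  t_start, t_end, seed = NULL)
    dates <- make_dates_distinct(dates)
    panel0 <- simulate_state_panel(truth = truth, seed = NULL)
    tr <- attr(panel0, "truth")
    X <- cbind(1, panel0$states$fss_ratio,
               panel0$states$mental_illness_rate,
               panel0$states$poverty_rate, panel0$states$permissiveness)
    w <- panel0$states$population *
      exp(as.vector(X %*% truth$beta) + tr$v + tr$u) *
      (1 - tr$structural_zero)
    if (sum(w) <= 0) stop("all states structurally zero; cannot place events")
    st <- sample(panel0$states$state, length(dates), replace = TRUE,
                 prob = w)
    incidents <- attach_casualties(dates, truth, seed = NULL, states = st)
    panel <- state_panel(panel0$states, panel0$adjacency,
                         incidents = incidents)
    attr(panel, "truth") <- tr
    gaps <- as.numeric(diff(incidents$date))
    media <- simulate_media(gaps, truth$rho_target, truth, seed = NULL)
    intervals <- build_intervals(incidents, media$article_count,
                                 media$search_interest)
    list(incidents = incidents, panel = panel, intervals = intervals,
         media = media, truth = truth)
  })
}

make_dates_distinct <- function(dates) {
  if (length(dates) < 2L) return(dates)
  for (i in 2:length(dates)) {
    if (dates[i] <= dates[i - 1L]) dates[i] <- dates[i - 1L] + 1L
  }
  dates
}

#' Write a simulated study bundle to the pipeline's input files
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(incidents = file.path(dir, "incidents.csv"),
             states = file.path(dir, "states.csv"),
             adjacency = file.path(dir, "adjacency.txt"),
             media = file.path(dir, "media.csv"),
             truth = file.path(dir, "truth.json"))
  write_incidents(study$incidents, paths["incidents"])
  write_state_panel(study$panel, paths["states"], paths["adjacency"])
  write.csv(study$media, paths["media"], row.names = FALSE, quote = FALSE)
  tr <- unclass(study$truth)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
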