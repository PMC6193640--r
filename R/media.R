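# Media-contagion analysis: rank correlations, ridge regression and a
# Poisson interval model linking online coverage of one incident to the
# time until the next.

#' Spearman rank-correlation matrix with p-values
#'
#' Average ranks for ties; p-values from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom. A
#' constant column yields an undefined (NA) entry, flagged via the
#' `"undefined"` attribute and a warning rather than silently.
#'
#' @param columns data.frame or matrix of numeric columns (>= 4 rows).
#' @return list with `rho` (matrix, unit diagonal), `p_value` (matrix) and
#'   `n`.
#' @export
spearman_matrix <- function(columns) {
  X <- as.matrix(columns)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 rows")
  const <- apply(X, 2L, function(c) length(unique(c)) == 1L)
  R <- apply(X, 2L, rank)  # average ranks for ties
  rho <- suppressWarnings(cor(R))
  diag(rho) <- 1
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho)[!const] <- 1
  if (any(const)) {
    warning("constant column(s), correlation undefined: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  out <- list(rho = rho, p_value = p, n = n)
  attr(out, "undefined") <- colnames(X)[const]
  out
}

#' Ridge regression with GCV penalty selection and approximate p-values
#'
#' Predictors are standardized internally (mean 0, SD 1) and the response
#' centered; the intercept is unpenalized. The solution is
#' `(X'X + penalty*I)^{-1} X'y` on the standardized scale, reported both
#' there and back-transformed. When no penalty is supplied it is chosen by
#' generalized cross-validation. Approximate p-values come from the ridge
#' effective covariance `sigma^2 W X'X W`, `W = (X'X + penalty*I)^{-1}`,
#' with `sigma^2` estimated from the residuals on the effective residual
#' degrees of freedom.
#'
#' @param y numeric response.
#' @param X numeric matrix (or data.frame) of predictors.
#' @param penalty non-negative ridge penalty; `NULL` (default) selects it
#'   by GCV over a log-spaced grid.
#' @return list of class `ridge_fit`: standardized and original-scale
#'   coefficients, `intercept`, `penalty`, `gcv`, `edf`, `se`, `p_value`.
#' @export
ridge_fit <- function(y, X, penalty = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > p + 1L)
  if (!is.null(penalty) && penalty < 0) stop("penalty must be >= 0")
  mx <- colMeans(X); sx <- apply(X, 2L, sd)
  if (any(sx == 0)) stop("constant predictor column")
  Xs <- scale(X, center = mx, scale = sx)
  my <- mean(y); yc <- y - my

  sv <- svd(Xs)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  fit_at <- function(lam) {
    shrink <- sv$d / (d2 + lam)
    b <- sv$v %*% (shrink * uty)
    fitted <- Xs %*% b
    edf <- sum(d2 / (d2 + lam))
    rss <- sum((yc - fitted)^2)
    list(b = as.vector(b), edf = edf, rss = rss,
         gcv = n * rss / (n - edf)^2)
  }
  if (is.null(penalty)) {
    grid <- 10^seq(-4, 5, length.out = 181)
    gcvs <- vapply(grid, function(l) fit_at(l)$gcv, numeric(1))
    penalty <- grid[which.min(gcvs)]
  }
  f <- fit_at(penalty)
  sigma2 <- f$rss / max(n - f$edf - 1, 1)  # -1 for the fitted intercept
  W <- sv$v %*% (t(sv$v) / (d2 + penalty))
  V <- sigma2 * W %*% (crossprod(Xs)) %*% W
  se <- sqrt(diag(V))
  z <- f$b / se
  coef_orig <- f$b / sx
  structure(list(
    coefficients_std = setNames(f$b, colnames(X)),
    coefficients = setNames(coef_orig, colnames(X)),
    intercept = my - sum(coef_orig * mx),
    penalty = penalty, edf = f$edf, gcv = f$gcv, sigma2 = sigma2,
    se = setNames(se, colnames(X)),
    p_value = setNames(2 * pnorm(-abs(z)), colnames(X))),
    class = "ridge_fit")
}

# floor zero article counts at half a count before taking logs
# (continuity correction); returns the adjusted density and a flag
adjust_density <- function(intervals, floor_count = 0.5) {
  dens <- intervals$media_density
  floored <- !is.na(dens) & dens * intervals$interval_days < floor_count
  dens[floored] <- floor_count / intervals$interval_days[floored]
  list(density = dens, floored = floored)
}

#' Poisson regression of the interval on log media density
#'
#' Models the number of days to the next incident as a Poisson response on
#' the log-transformed media coverage density, adjusting for the preceding
#' event's fatalities and injuries, with calendar time entering as an
#' offset (`log(1 + days since the first incident)`). Standard errors are
#' dispersion-adjusted (quasi-Poisson), since day counts are far more
#' variable than a unit-dispersion Poisson. Zero article counts are floored
#' at half a count before the log; zero-length intervals are an error.
#'
#' @param intervals an `interval_df` with media columns and the preceding
#'   event's `fatalities`/`injuries` (as built by [build_intervals()]).
#' @param use_offset include the calendar-time offset (default TRUE).
#' @return list of class `interval_poisson_fit`: `coefficients`, `se`,
#'   `p_value`, `dispersion`, `n`, `floored` count, and the `glm`.
#' @export
poisson_interval_fit <- function(intervals, use_offset = TRUE) {
  if (any(intervals$interval_days <= 0)) stop("zero-length interval")
  adj <- adjust_density(intervals)
  d <- data.frame(
    days = round(intervals$interval_days),
    log_density = log(adj$density),
    fatalities = intervals$fatalities,
    injuries = intervals$injuries,
    t_cal = as.numeric(intervals$start_date - min(intervals$start_date)))
  off <- if (use_offset) log(1 + d$t_cal) else rep(0, nrow(d))
  g <- glm(days ~ log_density + fatalities + injuries,
           family = quasipoisson(), data = d, offset = off)
  cf <- summary(g)$coefficients
  # constant (aliased) predictors have no estimable effect: report 0
  full <- c("(Intercept)", "log_density", "fatalities", "injuries")
  est <- setNames(rep(0, 4L), full)
  se <- p <- setNames(rep(NA_real_, 4L), full)
  est[rownames(cf)] <- cf[, "Estimate"]
  se[rownames(cf)] <- cf[, "Std. Error"]
  p[rownames(cf)] <- cf[, 4L]
  structure(list(coefficients = est,
                 se = se,
                 p_value = p,
                 dispersion = summary(g)$dispersion,
                 n = nrow(d), floored = sum(adj$floored), glm = g),
            class = "interval_poisson_fit")
}

#' Standardized position of an interval among log-transformed intervals
#'
#' `(log(x) - mean(log(all))) / SD(log(all))`: how unusual an interval is
#' within the log-scale distribution of all intervals (negative = shorter
#' than typical).
#'
#' @param interval_days the interval to standardize.
#' @param all_intervals the reference set of intervals (days).
#' @param sd_type `"sample"` (default) or `"population"` SD.
#' @return z-score(s).
#' @export
interval_zscore <- function(interval_days, all_intervals,
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  lg <- log(all_intervals)
  s <- if (sd_type == "sample") sd(lg)
       else sqrt(mean((lg - mean(lg))^2))
  (log(interval_days) - mean(lg)) / s
}

#' Full media-contagion analysis of an interval table
#'
#' Computes (1) the Spearman matrix over the interval length, media
#' coverage density, search interest and temporal order; (2) a ridge
#' regression of the log interval on log density and temporal order
#' (standardized, GCV penalty unless supplied); and (3) the adjusted
#' Poisson interval model. Temporal order is calendar days since the first
#' incident.
#'
#' @param intervals an `interval_df` with media columns.
#' @param penalty optional fixed ridge penalty.
#' @param ridge_log_response model `log(interval)` in the ridge (default
#'   TRUE; FALSE uses the raw interval).
#' @return object of class `media_fit` with elements `spearman`, `ridge`,
#'   `poisson`, `n`.
#' @export
media_analysis <- function(intervals, penalty = NULL,
                           ridge_log_response = TRUE) {
  if (nrow(intervals) < 4L) stop("need at least 4 intervals")
  adj <- adjust_density(intervals)
  t_cal <- as.numeric(intervals$start_date - min(intervals$start_date))
  cols <- data.frame(interval_days = intervals$interval_days,
                     media_density = adj$density,
                     search_interest = intervals$search_interest,
                     temporal_order = t_cal)
  sp <- spearman_matrix(cols)
  y <- if (ridge_log_response) log(intervals$interval_days)
       else intervals$interval_days
  rg <- ridge_fit(y, cbind(log_density = log(adj$density),
                           temporal_order = t_cal), penalty = penalty)
  pf <- poisson_interval_fit(intervals)
  structure(list(spearman = sp, ridge = rg, poisson = pf,
                 n = nrow(intervals)),
            class = "media_fit")
}

#' @export
print.media_fit <- function(x, ...) {
  cat(sprintf(
    "media-contagion analysis (n = %d intervals)\n", x$n))
  cat(sprintf("  Spearman(density, interval) = %.3f (p = %.2g)\n",
              x$spearman$rho["media_density", "interval_days"],
              x$spearman$p_value["media_density", "interval_days"]))
  cat(sprintf("  ridge log-density coef = %.3f (p = %.2g, penalty %.3g)\n",
              x$ridge$coefficients_std["log_density"],
              x$ridge$p_value["log_density"], x$ridge$penalty))
  cat(sprintf("  Poisson log-density coef = %.3f (p = %.2g)\n",
              x$poisson$coefficients["log_density"],
              x$poisson$p_value["log_density"]))
  invisible(x)
}

#' Sensitivity re-analysis after removing outlier events
#'
#' Drops every interval that follows one of the excluded events and re-runs
#' the full media analysis, reporting whether the sign and nominal
#' significance of the density-interval association are stable.
#'
#' @param intervals an `interval_df` with media columns.
#' @param exclude_events `event_id`s whose following interval is removed.
#' @param ... passed to [media_analysis()].
#' @return list with `full`, `reduced` (both `media_fit`) and `comparison`
#'   (data.frame of the density-interval association under each method).
#' @export
sensitivity_remove <- function(intervals, exclude_events = character(), ...) {
  keep <- !(intervals$start_event %in% exclude_events)
  if (sum(keep) < 4L) {
    stop("fewer than 4 intervals left after exclusion")
  }
  full <- media_analysis(intervals, ...)
  reduced <- media_analysis(intervals[keep, , drop = FALSE], ...)
  pull <- function(fit) c(
    spearman = unname(fit$spearman$rho["media_density", "interval_days"]),
    ridge = unname(fit$ridge$coefficients_std["log_density"]),
    poisson = unname(fit$poisson$coefficients["log_density"]))
  comparison <- data.frame(full = pull(full), reduced = pull(reduced))
  comparison$sign_stable <- sign(comparison$full) == sign(comparison$reduced)
  list(full = full, reduced = reduced, comparison = comparison,
       n_removed = sum(!keep))
}
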