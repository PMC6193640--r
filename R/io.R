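#' @useDynLib massincidence, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate coef cor dpois glm median plogis pnorm
#'   poisson pt qnorm quantile rbinom rgamma rlnorm rnbinom rnorm rpois
#'   runif sd setNames smooth.spline var vcov predict qgamma rbeta
#'   cor.test quasipoisson confint.default
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Domain containers
# ---------------------------------------------------------------------------

#' Construct an incident table
#'
#' An incident table records one mass-shooting event per row: an opaque
#' identifier, a calendar date, a two-letter state code, the number of
#' victims killed and the number injured. The study definition requires at
#' least four victim fatalities (perpetrator excluded), so rows below that
#' threshold are rejected unless `min_fatalities` is lowered.
#'
#' @param date `Date` vector (or ISO-8601 strings) of event dates.
#' @param state character vector of two-letter state codes.
#' @param fatalities integer vector of victims killed (>= `min_fatalities`).
#' @param injuries integer vector of victims injured (>= 0).
#' @param event_id optional identifiers; generated as `ev0001`... if absent.
#' @param min_fatalities inclusion threshold, default 4.
#' @return a `data.frame` of class `incident_df`, sorted ascending by date
#'   (ties keep input order).
#' @export
incident_table <- function(date, state, fatalities, injuries,
                           event_id = NULL, min_fatalities = 4L) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable date in incident table")
  n <- length(date)
  stopifnot(length(state) == n, length(fatalities) == n,
            length(injuries) == n)
  fatalities <- as.integer(fatalities)
  injuries <- as.integer(injuries)
  bad <- which(fatalities < min_fatalities)
  if (length(bad)) {
    stop(sprintf(
      "row %s: fatalities below the inclusion threshold of %d",
      paste(bad, collapse = ", "), min_fatalities))
  }
  if (any(injuries < 0)) stop("negative injury count")
  if (is.null(event_id)) event_id <- sprintf("ev%04d", seq_len(n))
  out <- data.frame(event_id = as.character(event_id), date = date,
                    state = as.character(state),
                    fatalities = fatalities, injuries = injuries,
                    stringsAsFactors = FALSE)
  out <- out[order(out$date), , drop = FALSE]  # stable: ties keep file order
  rownames(out) <- NULL
  class(out) <- c("incident_df", "data.frame")
  out
}

#' Read an incident series from CSV
#'
#' Expects columns `date` (ISO-8601), `state`, `fatalities`, `injuries` and
#' an optional `event_id`. Rows are returned sorted ascending by date.
#' Rows with fewer than `min_fatalities` victim deaths are an error under
#' `on_violation = "error"` (the default, per the case definition), dropped
#' with a warning under `"drop"`, or kept under `"keep"`.
#'
#' @param path CSV file path.
#' @param min_fatalities inclusion threshold, default 4.
#' @param on_violation one of `"error"`, `"drop"`, `"keep"`.
#' @param study_window optional length-2 `Date` vector; events outside it
#'   are an error.
#' @return an `incident_df` (possibly zero rows, with a warning).
#' @export
read_incidents <- function(path, min_fatalities = 4L,
                           on_violation = c("error", "drop", "keep"),
                           study_window = NULL) {
  on_violation <- match.arg(on_violation)
  d <- read_table_checked(path, c("date", "state", "fatalities", "injuries"))
  if (nrow(d) == 0L) {
    warning("incident file ", path, " contains no rows")
    return(incident_table(as.Date(character()), character(),
                          integer(), integer()))
  }
  dates <- as.Date(as.character(d$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("row ", paste(which(is.na(dates)), collapse = ", "),
         ": unparseable date in ", path)
  }
  fat <- suppressWarnings(as.integer(d$fatalities))
  if (anyNA(fat)) stop("non-integer fatalities in ", path)
  low <- which(fat < min_fatalities)
  if (length(low) && on_violation == "error") {
    stop(sprintf("row %s: fatalities below the inclusion threshold of %d",
                 paste(low, collapse = ", "), min_fatalities))
  }
  keep <- rep(TRUE, nrow(d))
  if (length(low) && on_violation == "drop") {
    warning(length(low), " row(s) below the fatality threshold dropped")
    keep[low] <- FALSE
  }
  thr <- if (on_violation == "keep") 0L else min_fatalities
  out <- incident_table(dates[keep], d$state[keep], fat[keep],
                        d$injuries[keep],
                        event_id = if ("event_id" %in% names(d))
                          d$event_id[keep] else NULL,
                        min_fatalities = thr)
  if (!is.null(study_window)) {
    study_window <- as.Date(study_window)
    if (any(out$date < study_window[1] | out$date > study_window[2])) {
      stop("incident date outside the configured study window")
    }
  }
  out
}

#' Write an incident series to CSV
#' @param incidents an `incident_df`.
#' @param path output path.
#' @export
write_incidents <- function(incidents, path) {
  write.csv(as.data.frame(incidents), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  d
}

# ---------------------------------------------------------------------------
# Derived covariates
# ---------------------------------------------------------------------------

#' Firearm-suicide share of all suicides (FS/S gun-ownership proxy)
#'
#' The standard area-level proxy for household gun ownership: the average
#' yearly number of firearm suicides divided by the average yearly number of
#' all suicides.
#'
#' @param firearm_suicides yearly firearm-suicide counts.
#' @param all_suicides yearly all-suicide counts (same length, all > 0).
#' @return a proportion in \[0, 1\].
#' @examples
#' compute_fss_ratio(c(10, 20), c(40, 40))  # 0.375
#' @export
compute_fss_ratio <- function(firearm_suicides, all_suicides) {
  if (length(firearm_suicides) != length(all_suicides)) {
    stop("series lengths differ")
  }
  if (any(all_suicides <= 0)) stop("all-suicide counts must be positive")
  if (any(firearm_suicides < 0)) stop("negative firearm-suicide count")
  if (any(firearm_suicides > all_suicides)) {
    stop("firearm suicides exceed all suicides in at least one year")
  }
  mean(firearm_suicides) / mean(all_suicides)
}

#' Inter-incident intervals with media covariates
#'
#' Builds the renewal-style interval table: interval `i` spans incident `i`
#' to incident `i + 1`, measured in exact days. Media coverage density is
#' the number of online articles published during the interval divided by
#' its length in days; search interest is the Google-Trends-style relative
#' volume (peak = 100).
#'
#' @param incidents an `incident_df` with at least two rows.
#' @param media_counts optional per-interval article counts
#'   (length `nrow(incidents) - 1`).
#' @param search_interest optional per-interval search-interest values.
#' @param same_day `"error"` (default) to reject consecutive incidents on
#'   the same date, `"floor"` to floor such intervals at 1 day.
#' @return a `data.frame` of class `interval_df` with columns `index`,
#'   `start_event`, `end_event`, `start_date`, `interval_days`,
#'   `media_article_count`, `media_density`, `search_interest`, plus the
#'   preceding event's `fatalities` and `injuries`.
#' @export
build_intervals <- function(incidents, media_counts = NULL,
                            search_interest = NULL,
                            same_day = c("error", "floor")) {
  same_day <- match.arg(same_day)
  n <- nrow(incidents)
  if (n < 2L) stop("need at least two incidents to form intervals")
  gaps <- as.numeric(diff(incidents$date))
  if (any(gaps == 0)) {
    if (same_day == "error") {
      stop("consecutive incidents share a date (zero-length interval); ",
           "use same_day = \"floor\" to floor at one day")
    }
    gaps[gaps == 0] <- 1
  }
  m <- n - 1L
  check_aux <- function(x, label) {
    if (!is.null(x) && length(x) != m) {
      stop(label, " must have length n_incidents - 1 = ", m)
    }
    x
  }
  media_counts <- check_aux(media_counts, "media_counts")
  search_interest <- check_aux(search_interest, "search_interest")
  out <- data.frame(
    index = seq_len(m),
    start_event = incidents$event_id[-n],
    end_event = incidents$event_id[-1L],
    start_date = incidents$date[-n],
    interval_days = gaps,
    media_article_count = if (is.null(media_counts)) NA_real_
      else as.numeric(media_counts),
    media_density = if (is.null(media_counts)) NA_real_
      else as.numeric(media_counts) / gaps,
    search_interest = if (is.null(search_interest)) NA_real_
      else as.numeric(search_interest),
    fatalities = incidents$fatalities[-n],
    injuries = incidents$injuries[-n],
    stringsAsFactors = FALSE)
  class(out) <- c("interval_df", "data.frame")
  out
}

#' Read a per-interval media table
#'
#' Columns: `interval_index`, `article_count`, `search_interest`.
#' @param path CSV file path.
#' @return data.frame ordered by `interval_index`.
#' @export
read_media <- function(path) {
  d <- read_table_checked(path,
                          c("interval_index", "article_count",
                            "search_interest"))
  d <- d[order(d$interval_index), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# ---------------------------------------------------------------------------
# State panel + adjacency
# ---------------------------------------------------------------------------

#' Read a state adjacency edge list
#'
#' One undirected edge (`"ST1 ST2"`) per line; a line holding a single code
#' declares an isolated state (no land neighbors). Lines starting with `#`
#' are comments. The graph is symmetrized and deduplicated on read.
#'
#' @param path edge-list file.
#' @param states optional character vector of allowed codes; edges naming a
#'   code outside it are an error.
#' @return symmetric 0/1 adjacency matrix with state codes as dimnames.
#' @export
read_adjacency <- function(path, states = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  lens <- lengths(toks)
  if (any(lens > 2L)) stop("malformed adjacency line: ", lines[lens > 2L][1])
  singletons <- unlist(toks[lens == 1L])
  pairs <- do.call(rbind, toks[lens == 2L])
  codes <- sort(unique(c(singletons, as.vector(pairs))))
  if (!is.null(states)) {
    unknown <- setdiff(codes, states)
    if (length(unknown)) {
      stop("adjacency names unknown state(s): ",
           paste(unknown, collapse = ", "))
    }
    codes <- states
  }
  A <- matrix(0L, length(codes), length(codes),
              dimnames = list(codes, codes))
  if (!is.null(pairs)) {
    if (any(pairs[, 1] == pairs[, 2])) stop("self-loop in adjacency")
    dup <- duplicated(t(apply(pairs, 1L, sort)))
    if (any(dup)) warning(sum(dup), " duplicate edge(s) deduplicated")
    pairs <- pairs[!dup, , drop = FALSE]
    A[pairs] <- 1L
    A[pairs[, 2:1, drop = FALSE]] <- 1L
  }
  iso <- rownames(A)[rowSums(A) == 0L]
  if (length(iso)) {
    message("isolated state(s) in adjacency (own ICAR component): ",
            paste(iso, collapse = ", "))
  }
  A
}

#' The shipped 50-state contiguous-border adjacency
#' @return symmetric 0/1 matrix over the 50 two-letter state codes
#'   (Alaska and Hawaii are isolated nodes).
#' @export
us_adjacency <- function() {
  path <- system.file("extdata", "us_state_adjacency.txt",
                      package = "massincidence")
  suppressMessages(read_adjacency(path))
}

#' Construct a state covariate panel
#'
#' Bundles the 50-state (or generic areal) covariate table with its
#' neighborhood graph. Covariates follow the incidence model: population
#' (used as an offset on the log scale), the FS/S gun-ownership proxy, the
#' serious-mental-illness rate (percent of adults), the poverty rate
#' (percent), and a gun-law permissiveness indicator (1 for "may-issue"
#' permit regimes).
#'
#' @param states data.frame with columns `state`, `population`,
#'   `fss_ratio`, `mental_illness_rate`, `poverty_rate`, `permissiveness`,
#'   and optionally `incident_count`.
#' @param adjacency symmetric 0/1 matrix over the same state codes.
#' @param incidents optional `incident_df` used to (re)derive
#'   `incident_count`; its per-state tally must total its row count.
#' @return object of class `state_panel`: list with elements `states`
#'   (data.frame) and `adjacency` (matrix).
#' @export
state_panel <- function(states, adjacency, incidents = NULL) {
  req <- c("state", "population", "fss_ratio", "mental_illness_rate",
           "poverty_rate", "permissiveness")
  missing <- setdiff(req, names(states))
  if (length(missing)) {
    stop("state table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(states$population <= 0)) stop("population must be positive")
  if (any(states$fss_ratio < 0 | states$fss_ratio > 1)) {
    stop("fss_ratio outside [0, 1]")
  }
  if (any(states$mental_illness_rate < 0 |
          states$mental_illness_rate > 100) ||
      any(states$poverty_rate < 0 | states$poverty_rate > 100)) {
    stop("percent rate outside [0, 100]")
  }
  if (anyDuplicated(states$state)) stop("duplicate state code")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency matrix is not symmetric")
  }
  if (any(diag(adjacency) != 0)) stop("adjacency has self-loops")
  if (!setequal(rownames(adjacency), states$state)) {
    stop("adjacency codes do not match the state table")
  }
  states <- states[order(states$state), , drop = FALSE]
  rownames(states) <- NULL
  adjacency <- adjacency[states$state, states$state]
  if (!is.null(incidents)) {
    unknown <- setdiff(unique(incidents$state), states$state)
    if (length(unknown)) {
      stop("incident in state absent from panel: ",
           paste(unknown, collapse = ", "))
    }
    tab <- table(factor(incidents$state, levels = states$state))
    states$incident_count <- as.integer(tab)
    stopifnot(sum(states$incident_count) == nrow(incidents))
  } else if (is.null(states$incident_count)) {
    stop("provide incident_count or an incident table")
  }
  if (any(states$incident_count < 0)) stop("negative incident count")
  structure(list(states = states, adjacency = adjacency),
            class = "state_panel")
}

#' Read a state panel from CSV plus an adjacency file
#' @param states_path CSV with the columns of [state_panel()].
#' @param adjacency_path edge-list file (see [read_adjacency()]).
#' @param incidents optional `incident_df` to derive per-state counts.
#' @return a `state_panel`.
#' @export
read_state_panel <- function(states_path, adjacency_path, incidents = NULL) {
  st <- read_table_checked(states_path,
                           c("state", "population", "fss_ratio",
                             "mental_illness_rate", "poverty_rate",
                             "permissiveness"))
  A <- read_adjacency(adjacency_path, states = sort(st$state))
  state_panel(st, A, incidents = incidents)
}

#' @export
print.state_panel <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf(
    "state_panel: %d states, %d edges, %d incident(s), %d zero-count state(s)\n",
    n, sum(x$adjacency) / 2L, sum(x$states$incident_count),
    sum(x$states$incident_count == 0L)))
  invisible(x)
}

#' Write a state panel's table and adjacency to disk
#' @param panel a `state_panel`.
#' @param states_path,adjacency_path output paths.
#' @export
write_state_panel <- function(panel, states_path, adjacency_path) {
  write.csv(panel$states, states_path, row.names = FALSE, quote = FALSE)
  A <- panel$adjacency
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  edges <- paste(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]])
  iso <- rownames(A)[rowSums(A) == 0L]
  writeLines(c(iso, sort(edges)), adjacency_path)
  invisible(panel)
}

# The nine "may-issue" concealed-carry states used as the default
# permissiveness indicator.
MAY_ISSUE_STATES <- c("CA", "CT", "DE", "HI", "MD", "MA", "NJ", "NY", "RI")
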