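## Readouts of one completed run, derived entirely from the event log, and
## the two wet-lab-style estimators (half-life from shut-off, RNAPII speed
## from ChIP run-off) for arbitrary time-course tables.

# per-tick state-count series reconstructed by cumulative summation of
# event deltas; the event log fully determines every state trajectory
.series_from_events <- function(ev, n_ticks, model) {
  delta <- function(plus, minus) {
    d <- numeric(n_ticks)
    for (e in plus) {
      tt <- ev$tick[ev$event == e]
      if (length(tt)) d <- d + tabulate(tt, n_ticks)
    }
    for (e in minus) {
      tt <- ev$tick[ev$event == e]
      if (length(tt)) d <- d - tabulate(tt, n_ticks)
    }
    cumsum(d)
  }
  on_gene <- delta("initiation", c("termination", "dropoff"))
  inactive <- if (model == "model1") {
    delta("backtrack", c("tfiis_rescue", "ccr4_reactivate", "spont_reactivate"))
  } else {
    delta("inactivate", c("tfiis_rescue", "tfiis_rescue_i", "ccr4_rescue",
                          "spont_reactivate", "dropoff"))
  }
  backtracked <- delta("backtrack", c("tfiis_rescue", "ccr4_reactivate",
                                      "spont_reactivate", "dropoff"))
  pool <- delta("mrna_birth", "mrna_death")
  list(on_gene = on_gene, inactive = inactive, backtracked = backtracked,
       pool = pool)
}

#' Compute the readouts of one completed run
#'
#' Derives the five characteristic steady-state parameters (plus two
#' auxiliary ones) from an event log, restricted to the recording window:
#' time-averaged mRNA pool size; mRNA half-life (exponential half-life
#' matching the mean observed lifetime); fraction of recorded ticks with at
#' least one polymerase on the gene (total occupancy) and with at least one
#' actively elongating polymerase (active occupancy); RNAPII speed
#' (`gene_length` / mean ticks per completed transcription cycle); mean
#' cycle time; and the fraction of on-gene polymerase-ticks spent
#' backtracked.  Metrics that cannot be computed (no completed cycle, no
#' completed mRNA lifetime) are reported as `NA`, not zero.
#'
#' @param event_log event-log data frame from [run_sim()] (columns `tick`,
#'   `event`, `a1`, `a2`).
#' @param recording_window integer length-2, first and last recorded tick.
#' @param config the run's `sim_config`.
#' @return A `metric_set` list.
#' @export
compute_metrics <- function(event_log, recording_window, config) {
  w1 <- as.integer(recording_window[1]); w2 <- as.integer(recording_window[2])
  if (w2 < w1) stop("empty observation window")
  ser <- .series_from_events(event_log, w2, config$model)
  w <- w1:w2
  active <- ser$on_gene - ser$inactive
  pol_ticks <- sum(ser$on_gene[w])
  # completed transcription cycles: pair each termination with that
  # polymerase's most recent initiation
  term <- event_log[event_log$event == "termination" &
                      event_log$tick >= w1 & event_log$tick <= w2, ]
  init <- event_log[event_log$event == "initiation", ]
  cycles <- numeric(0)
  if (nrow(term)) {
    for (k in seq_len(nrow(term))) {
      st <- init$tick[init$a1 == term$a1[k] & init$tick <= term$tick[k]]
      if (length(st)) cycles <- c(cycles, term$tick[k] - max(st) + 1L)
    }
  }
  # completed mRNA lifetimes (deaths within the window)
  births <- event_log[event_log$event == "mrna_birth", ]
  deaths <- event_log[event_log$event == "mrna_death" &
                        event_log$tick >= w1 & event_log$tick <= w2, ]
  lifetimes <- deaths$tick - births$tick[match(deaths$a1, births$a1)]
  lifetimes <- lifetimes[!is.na(lifetimes)]
  structure(list(
    mrna_mean = mean(ser$pool[w]),
    half_life = if (length(lifetimes)) half_life_from_lifetimes(lifetimes) else NA_real_,
    total_occupancy = mean(ser$on_gene[w] >= 1),
    active_occupancy = mean(active[w] >= 1),
    speed = if (length(cycles)) config$gene_length / mean(cycles) else NA_real_,
    cycle_ticks = if (length(cycles)) mean(cycles) else NA_real_,
    backtracked_fraction = if (pol_ticks > 0) sum(ser$backtracked[w]) / pol_ticks else NA_real_,
    n_cycles = length(cycles),
    n_lifetimes = length(lifetimes)
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0(
    "  mRNA mean %.2f | half-life %.1f ticks | occupancy total %.3f / ",
    "active %.3f\n  speed %.3f pos/tick (cycle %.1f ticks, n=%d) | ",
    "backtracked fraction %.3f\n"),
    x$mrna_mean, x$half_life, x$total_occupancy, x$active_occupancy,
    x$speed, x$cycle_ticks, x$n_cycles, x$backtracked_fraction))
  invisible(x)
}

#' mRNA half-life from completed lifetimes
#'
#' Returns `ln(2) * mean(lifetimes)`: the half-life of the exponential
#' decay law whose mean lifetime matches the observed mean.
#'
#' @param lifetimes numeric vector of completed mRNA lifetimes (ticks).
#' @return Half-life in ticks, or `NA` for an empty input.
#' @export
half_life_from_lifetimes <- function(lifetimes) {
  if (!length(lifetimes)) return(NA_real_)
  log(2) * mean(lifetimes)
}

#' mRNA half-life from a transcription shut-off time course
#'
#' Implements the threshold-crossing estimator used for shut-off assays:
#' the initial value is the (linearly interpolated) signal at `start_from`
#' minutes, and the half-life is the first time, linearly interpolated
#' between samples, at which the signal falls to half that value, minus
#' `start_from`.  Re-basing to minute 5 (`start_from = 5`) handles mutants
#' whose signal does not drop immediately.
#'
#' @param tc data frame with ascending `time` (minutes) and `value` columns
#'   (at least two points).
#' @param start_from time origin in minutes (default 0).
#' @return Half-life in minutes.
#' @export
half_life_from_shutoff <- function(tc, start_from = 0) {
  stopifnot(is.data.frame(tc), all(c("time", "value") %in% names(tc)))
  if (nrow(tc) < 2L) stop("time course needs at least 2 points")
  if (any(diff(tc$time) <= 0)) stop("times must be strictly increasing")
  if (start_from < min(tc$time) || start_from > max(tc$time))
    stop("start_from outside the observation window")
  v0 <- stats::approx(tc$time, tc$value, xout = start_from)$y
  half <- v0 / 2
  sel <- tc$time >= start_from
  tt <- c(start_from, tc$time[sel & tc$time > start_from])
  vv <- c(v0, tc$value[sel & tc$time > start_from])
  below <- which(vv <= half)
  if (!length(below)) stop("half-life exceeds observation window")
  i <- below[1]
  if (i == 1L) return(0)
  t_cross <- tt[i - 1] + (vv[i - 1] - half) / (vv[i - 1] - vv[i]) *
    (tt[i] - tt[i - 1])
  t_cross - start_from
}

#' RNAPII speed from a run-off occupancy series
#'
#' Implements the run-off estimator: each spatial occupancy profile is
#' divided point-wise by the previous time point (so only polymerases that
#' remain transcribing are counted), the area of RNAPII lost over the
#' interval is computed by trapezoidal integration of the lost fraction
#' over the amplicon positions where polymerases were still present
#' (scaled to `gene_length`), each interval speed is that cleared distance
#' over the elapsed time, and the overall speed is the average of interval
#' speeds weighted by the RNAPII amount remaining at the start of each
#' interval.  Intervals whose signal increases beyond
#' `tolerance` after shut-off are excluded with a warning.
#'
#' @param profiles data frame with columns `time` (minutes), `position`
#'   (coordinate along the gene) and `value` (percent IP), with the same
#'   position grid at every time.
#' @param gene_length gene length in the same units as `position`.
#' @param tolerance allowed fractional signal increase before an interval
#'   is excluded (default 0.05).
#' @return Speed in positions per minute.
#' @export
speed_from_runoff <- function(profiles, gene_length, tolerance = 0.05) {
  stopifnot(is.data.frame(profiles),
            all(c("time", "position", "value") %in% names(profiles)))
  times <- sort(unique(profiles$time))
  if (length(times) < 2L) stop("need at least 2 time points after shut-off")
  pos <- sort(unique(profiles$position))
  prof <- sapply(times, function(t) {
    p <- profiles[profiles$time == t, ]
    p$value[match(pos, p$position)]
  })
  if (anyNA(prof)) stop("every time point needs the same position grid")
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  span <- max(pos) - min(pos)
  if (span <= 0) stop("need at least 2 amplicon positions")
  speeds <- weights <- numeric(0)
  for (k in 2:length(times)) {
    v0 <- prof[, k - 1]; v1 <- prof[, k]
    q <- ifelse(v0 > 0, v1 / v0, 0)
    present <- trapz(pos, as.numeric(v0 > 0))
    if (present > 0 && trapz(pos, q) / present > 1 + tolerance) {
      warning("signal increases after shut-off at t = ", times[k],
              "; interval excluded")
      next
    }
    # cleared distance = area of the lost fraction over the positions where
    # polymerases were still present at the previous time point
    loss <- ifelse(v0 > 0, 1 - pmin(v1 / v0, 1), 0)
    cleared <- trapz(pos, loss) * gene_length / span
    speeds <- c(speeds, cleared / (times[k] - times[k - 1]))
    weights <- c(weights, trapz(pos, v0))
  }
  if (!length(speeds)) stop("no usable interval after exclusions")
  if (sum(weights) <= 0) return(0)
  sum(speeds * weights) / sum(weights)
}

#' Read a shut-off time-course CSV
#'
#' Expects columns `time`, `value` and optionally `amplicon` (1-based
#' positions along the gene).  Times must be strictly increasing within
#' each amplicon.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_timecourse <- function(path) {
  tc <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "value") %in% names(tc)))
    stop("time course needs 'time' and 'value' columns")
  grp <- if ("amplicon" %in% names(tc)) tc$amplicon else rep(1, nrow(tc))
  for (g in unique(grp)) {
    if (any(diff(tc$time[grp == g]) <= 0))
      stop("times must be strictly increasing")
  }
  tc
}
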