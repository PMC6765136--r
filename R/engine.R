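#' Advance the world by one tick
#'
#' Applies the fixed phase order: movement, initiation, elongation updates,
#' factor actions (Ccr4-Not before TFIIS), termination, mRNA lifecycle,
#' bookkeeping.  The phase order inside a tick is part of the model
#' definition and is identical between the R and C++ engines.
#'
#' The phase functions `attempt_initiation()`, `elongation_update()`,
#' `ccr4_action()`, `tfiis_action()`, `terminate_pols()` and
#' `mrna_lifecycle()` implement the biological rule set; each takes the
#' world and configuration and returns the updated world.
#'
#' @param world a `sim_world` from [init_world()].
#' @param config the `sim_config` used to build the world.
#' @return The world after one tick.
#' @export
step_world <- function(world, config) {
  world$tick <- world$tick + 1L
  world <- .movement_phase(world, config)
  world <- attempt_initiation(world, config)
  world <- elongation_update(world, config)
  world <- ccr4_action(world, config)
  world <- tfiis_action(world, config)
  world <- terminate_pols(world, config)
  world <- mrna_lifecycle(world, config)
  world
}

.events_to_df <- function(mat) {
  if (is.list(mat)) {
    mat <- if (length(mat)) do.call(rbind, mat) else matrix(integer(0), 0, 4)
  }
  codes <- event_codes()
  data.frame(
    tick = as.integer(mat[, 1]),
    event = names(codes)[match(mat[, 2], codes)],
    code = as.integer(mat[, 2]),
    a1 = as.integer(mat[, 3]),
    a2 = ifelse(mat[, 4] == 0L, NA_integer_, as.integer(mat[, 4])),
    stringsAsFactors = FALSE
  )
}

#' Run one complete simulation
#'
#' Steps the world for `burn_in_ticks + record_ticks` ticks and returns the
#' full append-only event log plus the computed readouts
#' ([compute_metrics()] applied to the recording window).  Two runs with the
#' same configuration (including seed) produce identical event logs.
#'
#' @param config a validated [sim_config()].
#' @param engine `"cpp"` (production path) or `"r"` (reference engine;
#'   identical rules, much slower, different RNG stream).
#' @param metrics if `FALSE`, skip metric computation and return the log only.
#' @return A `sim_run` list: `config`, `events` (data frame with columns
#'   `tick`, `event`, `code`, `a1`, `a2`), `n_ticks`, and `metrics`
#'   (a `metric_set`, unless `metrics = FALSE`).
#' @examples
#' cfg <- sim_config(burn_in_ticks = 100L, record_ticks = 200L)
#' run <- run_sim(cfg)
#' run$metrics
#' @export
run_sim <- function(config, engine = c("cpp", "r"), metrics = TRUE) {
  engine <- match.arg(engine)
  validate_config(config)
  if (engine == "cpp") {
    out <- engine_run_cpp(unclass(config))
    ev <- .events_to_df(out$events)
    n_ticks <- out$n_ticks
  } else {
    world <- init_world(config)
    n_ticks <- config$burn_in_ticks + config$record_ticks
    for (i in seq_len(n_ticks)) world <- step_world(world, config)
    ev <- .events_to_df(world$events)
  }
  res <- structure(list(config = config, events = ev, n_ticks = n_ticks),
                   class = "sim_run")
  if (metrics) res$metrics <- compute_metrics(ev, recording_window =
      c(config$burn_in_ticks + 1L, n_ticks), config = config)
  res
}

#' @export
print.sim_run <- function(x, ...) {
  cat("<sim_run> ", x$config$model, "/", x$config$ccr4_mode, ", ",
      x$n_ticks, " ticks, ", nrow(x$events), " events\n", sep = "")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Export an event log as TSV
#'
#' Writes columns `tick`, `event`, `agent_ids` (comma-joined), the on-demand
#' event-log export format.
#'
#' @param run a `sim_run` (or an event-log data frame).
#' @param path output path.
#' @export
write_event_log <- function(run, path) {
  ev <- if (inherits(run, "sim_run")) run$events else run
  out <- data.frame(
    tick = ev$tick, event = ev$event,
    agent_ids = ifelse(is.na(ev$a2), as.character(ev$a1),
                       paste(ev$a1, ev$a2, sep = ",")),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
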