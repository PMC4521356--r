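# Monitors: periodic recording of neural and synaptic variables, and spike
# event recording.

#' Record variables during simulation
#'
#' Attaches a monitor to a population, view or projection.  At every
#' `period` ms of recording (default: every step) the current value of each
#' variable is appended to an internal buffer; [monitor_get()] returns the
#' buffers as matrices and empties them.  The special variable name
#' `"spike"` records spike events as (time, rank) pairs at every step.
#'
#' @param net The network.
#' @param target Population, view or projection.
#' @param variables Character vector of variable names (and/or `"spike"`).
#' @param period Recording period in ms; default one step.
#' @return An `rs_monitor`.
#' @export
monitor <- function(net, target, variables, period = NULL) {
  mon <- new.env(parent = emptyenv())
  class(mon) <- "rs_monitor"
  mon[["net"]] <- net
  mon[["target"]] <- target
  mon[["variables"]] <- variables
  mon[["period"]] <- period
  mon[["state"]] <- "recording"
  mon[["counter"]] <- 0L
  mon[["times"]] <- numeric(0)
  mon[["buffers"]] <- stats::setNames(
    rep(list(list()), length(setdiff(variables, "spike"))),
    setdiff(variables, "spike"))
  mon[["spike_times"]] <- numeric(0)
  mon[["spike_ranks"]] <- integer(0)
  net[["monitors"]][[length(net[["monitors"]]) + 1L]] <- mon
  mon
}

#' Pause, resume or stop a monitor
#'
#' Paused monitors keep their buffers; stopped monitors no longer record at
#' all.
#'
#' @param mon An `rs_monitor`.
#' @name monitor-state
NULL

#' @rdname monitor-state
#' @export
monitor_pause <- function(mon) {
  mon[["state"]] <- "paused"
  invisible(mon)
}

#' @rdname monitor-state
#' @export
monitor_resume <- function(mon) {
  mon[["state"]] <- "recording"
  invisible(mon)
}

#' @rdname monitor-state
#' @export
monitor_stop <- function(mon) {
  mon[["state"]] <- "stopped"
  invisible(mon)
}

monitor_value <- function(target, name) {
  get_attribute(target, name)
}

# Called by the engine in stage 7.
monitor_record <- function(mon) {
  if (mon[["state"]] != "recording") return(invisible(mon))
  net <- mon[["net"]]
  t_now <- net[["t"]] + net[["dt"]]   # time at the end of this step
  target <- mon[["target"]]
  if ("spike" %in% mon[["variables"]]) {
    # spikes are stamped with the start-of-step time, so that recorded times
    # fed back into a spike_source_array() reproduce the same raster
    pr <- pop_ranks(target)
    spk <- pr$pop[["last_spiked"]][pr$ranks + 1L]
    if (any(spk)) {
      ranks <- pr$ranks[spk]
      mon[["spike_times"]] <- c(mon[["spike_times"]],
                                rep(net[["t"]], length(ranks)))
      mon[["spike_ranks"]] <- c(mon[["spike_ranks"]], ranks)
    }
  }
  vars <- setdiff(mon[["variables"]], "spike")
  if (length(vars) == 0L) return(invisible(mon))
  period_steps <- max(1L, as.integer(round(
    (mon[["period"]] %||% net[["dt"]]) / net[["dt"]])))
  mon[["counter"]] <- mon[["counter"]] + 1L
  if (mon[["counter"]] %% period_steps != 0L) return(invisible(mon))
  buffers <- mon[["buffers"]]
  for (v in vars) {
    buffers[[v]][[length(buffers[[v]]) + 1L]] <- monitor_value(target, v)
  }
  mon[["buffers"]] <- buffers
  mon[["times"]] <- c(mon[["times"]], t_now)
  invisible(mon)
}

#' Retrieve and drain recorded values
#'
#' @param mon An `rs_monitor`.
#' @param variable Optional single variable name; default: all.
#' @return For a regular variable, a matrix with one row per recorded time
#'   point (row names are times in ms) and one column per unit/synapse; for
#'   `"spike"`, a data frame with columns `time_ms` and `rank`.  Without
#'   `variable`, a named list.  Buffers are emptied.
#' @export
monitor_get <- function(mon, variable = NULL) {
  out <- list()
  for (v in setdiff(mon[["variables"]], "spike")) {
    rows <- mon[["buffers"]][[v]]
    m <- if (length(rows) == 0L) {
      matrix(numeric(0), nrow = 0, ncol = 0)
    } else {
      mm <- do.call(rbind, rows)
      rownames(mm) <- format(mon[["times"]])
      mm
    }
    out[[v]] <- m
  }
  if ("spike" %in% mon[["variables"]]) {
    out[["spike"]] <- data.frame(time_ms = mon[["spike_times"]],
                                 rank = mon[["spike_ranks"]])
  }
  # drain
  mon[["buffers"]] <- stats::setNames(
    rep(list(list()), length(setdiff(mon[["variables"]], "spike"))),
    setdiff(mon[["variables"]], "spike"))
  mon[["times"]] <- numeric(0)
  mon[["spike_times"]] <- numeric(0)
  mon[["spike_ranks"]] <- integer(0)
  if (!is.null(variable)) return(out[[variable]])
  out
}

#' Export recordings as delimited text
#'
#' Writes one file per variable (`<prefix><var>.txt`): a header row of unit
#' ranks followed by one row per time point (first column: time in ms).
#' Spike recordings are written as a two-column `(time_ms, rank)` event list.
#'
#' @param recordings A list as returned by [monitor_get()].
#' @param prefix Path prefix for the output files.
#' @return The written file paths, invisibly.
#' @export
export_recordings <- function(recordings, prefix) {
  files <- character(0)
  for (v in names(recordings)) {
    f <- paste0(prefix, v, ".txt")
    rec <- recordings[[v]]
    if (is.data.frame(rec)) {
      utils::write.table(rec, f, row.names = FALSE, quote = FALSE, sep = " ")
    } else {
      df <- data.frame(time_ms = as.numeric(rownames(rec)), rec)
      names(df) <- c("time_ms", paste0("unit_", seq_len(ncol(rec)) - 1L))
      utils::write.table(df, f, row.names = FALSE, quote = FALSE, sep = " ")
    }
    files <- c(files, f)
  }
  invisible(files)
}
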