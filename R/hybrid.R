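# Hybrid rate <-> spike conversion.
#
# Rate-to-spike: Poisson populations draw, for each unit and step, a spike
# with probability rate * dt / 1000 (rate in Hz, dt in ms) — a per-step
# Bernoulli approximation of a Poisson process, accurate while p << 1.  The
# rate can be fixed, a time expression, or driven by the weighted sum of a
# rate-coded input projection (a pre-synaptic rate of 1.0 through weight 1.0
# yields 1 Hz trains; weight 100.0 yields 100 Hz).
#
# Spike-to-rate: a decoding projection accumulates the weighted spikes
# received in a sliding window of T ms and reports
#   sum(target) = count / (T[s] * number of incoming synapses)
# so that unit-weight 1 Hz inputs decode to 1.0.

make_special_population <- function(net, size, name, special, storage) {
  geometry <- as.integer(size)
  if (any(geometry <= 0L)) stop("geometry must be positive", call. = FALSE)
  pop <- new.env(parent = emptyenv())
  class(pop) <- "rs_population"
  pop[["net"]] <- net
  pop[["geometry"]] <- geometry
  pop[["size"]] <- prod(geometry)
  pop[["model"]] <- NULL
  pop[["spiking"]] <- TRUE
  pop[["special"]] <- special
  pop[["name"]] <- name
  pop[["id"]] <- length(net[["populations"]]) + 1L
  pop[["storage"]] <- storage
  pop[["shared"]] <- character(0)
  pop[["last_spiked"]] <- rep(FALSE, prod(geometry))
  pop[["refrac_remaining"]] <- integer(prod(geometry))
  register_population(net, pop, name)
  pop
}

#' Poisson spiking population
#'
#' @param net The network.
#' @param geometry Size or shape.
#' @param rates Firing rate in Hz: a scalar, a per-unit vector, or a string
#'   expression of time `t` (ms), e.g. `"50 + 50 * sin(2*pi*t/1000)"`.
#'   Ignored when `target` is given.
#' @param target When set, the rate of each unit is its weighted sum of
#'   inputs over the projections with this target (input-driven encoder);
#'   negative input sums are treated as silence.
#' @param name Optional name.
#' @return An `rs_population` whose units fire as independent Poisson
#'   processes.  The attribute `rates` exposes the instantaneous rate.
#' @export
poisson_population <- function(net, geometry, rates = NULL, target = NULL,
                               name = NULL) {
  if (is.null(rates) && is.null(target)) {
    stop("either rates or target must be given", call. = FALSE)
  }
  size <- prod(as.integer(geometry))
  special <- list(kind = "poisson", target = target, rate_expr = NULL)
  storage <- list(rates = numeric(size))
  if (is.null(target)) {
    if (is.character(rates)) {
      special$rate_expr <- resolve_generic(dsl_str2lang(rates))$expr
    } else {
      if (any(rates < 0)) stop("negative rate", call. = FALSE)
      storage$rates <- rep_len(rates, size)
    }
  }
  pop <- make_special_population(net, geometry, name, special, storage)
  pop
}

#' Spike-source population with scheduled spike times
#'
#' @param net The network.
#' @param spike_times List with one sorted numeric vector of spike times (ms)
#'   per unit; times are rounded to the simulation grid and duplicates within
#'   one step collapse to a single spike.  Schedules can be replaced between
#'   [simulate()] calls with [set_spike_times()].
#' @param name Optional name.
#' @return An `rs_population` emitting exactly the scheduled spikes.
#' @export
spike_source_array <- function(net, spike_times, name = NULL) {
  stopifnot(is.list(spike_times))
  special <- list(kind = "spike_array")
  storage <- list()
  pop <- make_special_population(net, length(spike_times), name, special,
                                 storage)
  pop[["spike_times"]] <- lapply(spike_times, sort)
  pop
}

#' Replace the schedule of a spike-source population
#' @param pop A [spike_source_array()] population.
#' @param spike_times As in [spike_source_array()]; times earlier than the
#'   current simulation time are ignored.
#' @export
set_spike_times <- function(pop, spike_times) {
  if (is.null(pop[["special"]]) || pop[["special"]]$kind != "spike_array") {
    stop("not a spike-source population", call. = FALSE)
  }
  stopifnot(length(spike_times) == pop[["size"]])
  pop[["spike_times"]] <- lapply(spike_times, sort)
  if (!is.null(pop[["comp"]])) {
    pop[["comp"]] <- compile_special(pop[["net"]], pop)
  }
  invisible(pop)
}

compile_special <- function(net, pop) {
  sp <- pop[["special"]]
  comp <- list(special = sp$kind)
  if (sp$kind == "poisson") {
    comp$sum_targets <- if (!is.null(sp$target)) sp$target else character(0)
    comp$rate_expr <- sp$rate_expr
    comp$target <- sp$target
    comp$warned_p <- FALSE
  } else if (sp$kind == "spike_array") {
    # per-unit sorted step indices (grid-rounded, de-duplicated)
    comp$steps <- lapply(pop[["spike_times"]], function(ts)
      unique(as.integer(round(ts / net[["dt"]]))))
    comp$ptr <- rep(1L, pop[["size"]])
  }
  comp
}

update_special <- function(net, pop) {
  comp <- pop[["comp"]]
  size <- pop[["size"]]
  if (comp$special == "poisson") {
    st <- pop[["storage"]]
    rates <- if (!is.null(comp$target)) {
      pmax(pop[["inputs"]]$sums[[comp$target]] %||% 0, 0)
    } else if (!is.null(comp$rate_expr)) {
      vals <- rs_eval(comp$rate_expr, list(t = net[["t"]], dt = net[["dt"]]))
      if (any(vals < 0)) stop("negative rate", call. = FALSE)
      vals
    } else {
      st$rates
    }
    rates <- rep_len(rates, size)
    p <- rates * net[["dt"]] / 1000
    if (!comp$warned_p && any(p > 0.1)) {
      warning("Poisson spike probability per step exceeds 0.1; the per-step ",
              "Bernoulli approximation degrades (reduce dt or the rate)",
              call. = FALSE)
      comp$warned_p <- TRUE
      pop[["comp"]] <- comp
    }
    p <- pmin(p, 1)
    pop[["last_spiked"]] <- stats::runif(size) < p
    st$rates <- rates
    pop[["storage"]] <- st
  } else if (comp$special == "spike_array") {
    cur <- net[["step"]]
    spk <- logical(size)
    ptr <- comp$ptr
    steps <- comp$steps
    for (i in seq_len(size)) {
      si <- steps[[i]]
      # skip any missed/past entries
      while (ptr[i] <= length(si) && si[ptr[i]] < cur) ptr[i] <- ptr[i] + 1L
      if (ptr[i] <= length(si) && si[ptr[i]] == cur) {
        spk[i] <- TRUE
        ptr[i] <- ptr[i] + 1L
      }
    }
    comp$ptr <- ptr
    pop[["comp"]] <- comp
    pop[["last_spiked"]] <- spk
  }
  pop[["inputs"]] <- list(sums = list(), g = list())
  invisible(pop)
}

# ---- decoding projection ----------------------------------------------------

#' Sliding-window decoding projection
#'
#' Connects a spiking population to a rate-coded one.  The post-synaptic
#' input `sum(target)` at time `t` is the weighted count of spikes that
#' arrived in the window `(t - T, t]`, normalized by the window length in
#' seconds and the number of incoming synapses, so unit-weight 1 Hz inputs
#' decode to 1.0.
#'
#' @param net The network.
#' @param pre Spiking population (or view).
#' @param post Rate-coded population (or view).
#' @param target Target name read as `sum(target)` by the post population.
#' @param window Window length T in ms; must be a multiple of dt.  Default:
#'   one simulation step.
#' @return An `rs_projection`; connect it with the usual `connect_*` methods.
#' @export
decoding_projection <- function(net, pre, post, target, window = NULL) {
  prr <- pop_ranks(pre)
  if (!prr$pop[["spiking"]]) {
    stop("decoding requires a spiking pre-synaptic population", call. = FALSE)
  }
  proj <- projection(net, pre, post, target)
  proj[["kind_hint"]] <- "decoding"
  proj[["window"]] <- window
  proj
}

compile_decoding <- function(net, proj) {
  comp <- proj[["comp"]]
  win <- proj[["window"]] %||% net[["dt"]]
  wn <- as.integer(round(win / net[["dt"]]))
  if (wn < 1L || abs(wn * net[["dt"]] - win) > 1e-9) {
    stop("decoding window must be a positive multiple of dt", call. = FALSE)
  }
  npost <- comp$post_pop[["size"]]
  comp$win_steps <- wn
  comp$win_sec <- wn * net[["dt"]] / 1000
  comp$ring <- matrix(0, wn, npost)
  comp$ring_ptr <- 1L
  comp$total <- numeric(npost)
  nsyn <- tabulate(proj[["syn"]]$post + 1L, nbins = npost)
  comp$norm <- ifelse(nsyn > 0L, comp$win_sec * nsyn, Inf)
  proj[["comp"]] <- comp
  invisible(proj)
}

propagate_decoding <- function(net, proj) {
  comp <- proj[["comp"]]
  syn <- proj[["syn"]]
  npost <- comp$post_pop[["size"]]
  cnt <- numeric(npost)
  for (g in comp$delay_groups) {
    flags <- pop_delayed_output(comp$pre_pop, g$d)
    idx <- g$idx[flags[syn$pre[g$idx] + 1L]]
    if (length(idx) > 0L) {
      cnt <- cnt + aggregate_post(syn$w[idx], syn$post[idx], npost, "sum")
    }
  }
  ptr <- comp$ring_ptr
  comp$total <- comp$total - comp$ring[ptr, ] + cnt
  comp$ring[ptr, ] <- cnt
  comp$ring_ptr <- if (ptr == comp$win_steps) 1L else ptr + 1L
  proj[["comp"]] <- comp
  add_input_sum(comp$post_pop, comp$target, comp$total / comp$norm)
}

decoding_value <- function(proj) {
  comp <- proj[["comp"]]
  comp$total / comp$norm
}

#' Relative decoding error
#'
#' Mean normalized deviation of a decoded rate trace from its target rate
#' over a horizon: `(1/H) * sum(|r(t) - F| / F) * dt` for `t` in the first
#' `H` ms of the trace.
#'
#' @param trace Decoded rate trace, one value per step.
#' @param target Target rate F (> 0).
#' @param dt Step of the trace in ms.
#' @param horizon_ms Averaging horizon in ms (default 250).
#' @return The error (0 for a perfect trace, 1 for constant silence).
#' @export
decoding_error <- function(trace, target, dt = 1, horizon_ms = 250) {
  if (target <= 0) stop("target rate must be > 0", call. = FALSE)
  n <- min(length(trace), as.integer(round(horizon_ms / dt)))
  sum(abs(trace[seq_len(n)] - target) / target) * dt / horizon_ms
}
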