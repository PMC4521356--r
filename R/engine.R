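# The simulation engine: network container, compilation, and the fixed
# seven-stage step.
#
# Every step executes, strictly in order: (1) propagation of previous-step
# outputs (weighted sums for rate-coded projections, conductance increments
# and pre_spike statements for delayed spikes), (2) neural updates with spike
# emission/reset/refractoriness, (3) push of new outputs into the delay
# buffers, (4) continuous synaptic updates, (5) post-synaptic event
# statements, (6) structural plasticity, (7) recording.  Cross-population
# reads therefore always observe previous-step outputs; the minimal synaptic
# latency is one step.

#' Create a network
#'
#' @param dt Integration step in ms (default 1.0).
#' @param seed Seed for the network's private random stream, which governs
#'   connectivity, initial values and all simulation noise.  Unset: drawn
#'   from R's global RNG.
#' @param method Default numerical method for ODEs without a per-variable
#'   method flag: `"explicit"` (default), `"implicit"`, `"exponential"` or
#'   `"midpoint"`.
#' @param debug Check for NaN/overflow every step instead of every 100 steps.
#' @return An object of class `rs_network`.
#' @export
network <- function(dt = 1.0, seed = NULL, method = "explicit",
                    debug = FALSE) {
  stopifnot(dt > 0)
  net <- new.env(parent = emptyenv())
  class(net) <- "rs_network"
  net[["dt"]] <- dt
  net[["seed"]] <- seed %||% sample.int(.Machine$integer.max, 1L)
  net[["method"]] <- match.arg(method,
                               c("explicit", "implicit", "exponential",
                                 "midpoint"))
  net[["debug"]] <- debug
  net[["populations"]] <- list()
  net[["projections"]] <- list()
  net[["monitors"]] <- list()
  net[["step"]] <- 0L
  net[["t"]] <- 0
  net[["compiled"]] <- FALSE
  net[["rng_state"]] <- NULL
  net[["rng_active"]] <- FALSE
  net
}

#' Current simulation time
#' @param net A network.
#' @return Time in ms (`step * dt`).
#' @export
net_time <- function(net) net[["t"]]

# Run code under the network's private RNG stream (reentrant).
with_net_rng <- function(net, code) {
  if (isTRUE(net[["rng_active"]])) return(code)
  glob <- globalenv()
  had_old <- exists(".Random.seed", envir = glob, inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = glob)
  if (is.null(net[["rng_state"]])) {
    set.seed(net[["seed"]])
  } else {
    assign(".Random.seed", net[["rng_state"]], envir = glob)
  }
  net[["rng_active"]] <- TRUE
  on.exit({
    net[["rng_state"]] <- get(".Random.seed", envir = glob)
    net[["rng_active"]] <- FALSE
    if (had_old) assign(".Random.seed", old, envir = glob)
    else rm(".Random.seed", envir = glob)
  })
  code
}

#' @export
print.rs_network <- function(x, ...) {
  cat("Network: ", length(x[["populations"]]), " population(s), ",
      length(x[["projections"]]), " projection(s), dt = ", x[["dt"]],
      " ms, t = ", x[["t"]], " ms\n", sep = "")
  invisible(x)
}

# ---- compilation ------------------------------------------------------------

# Rename per-expression temporaries (.rand_k, .gop_k) to names unique within
# the enclosing compiled object, collecting their specifications.
rename_specials <- function(res, uid, rand_out, gop_out, n_hint) {
  map <- list()
  for (k in seq_along(res$randoms)) {
    nm <- paste0(".rand_", uid, "_", k)
    map[[paste0(".rand_", k)]] <- as.name(nm)
    rand_out[[nm]] <- list(spec = res$randoms[[k]], n = n_hint)
  }
  for (k in seq_along(res$gops)) {
    nm <- paste0(".gop_", uid, "_", k)
    map[[paste0(".gop_", k)]] <- as.name(nm)
    gop_out[[nm]] <- res$gops[[k]]
  }
  expr <- if (length(map)) dsl_substitute(res$expr, map) else res$expr
  list(expr = expr, randoms = rand_out, gops = gop_out)
}

# Group a model's variables (in declaration order) into update items:
# individual assignments and blocks of consecutive ODEs sharing a method.
# `locality_of(v)` must return "local"/"shared"; event-driven ODEs are
# excluded (returned separately).
compile_items <- function(variables, default_method, uid_prefix) {
  rand_specs <- list(); gop_specs <- list()
  items <- list()
  event_vars <- list()
  pending <- list()   # consecutive ODE specs with same (method, locality)
  flush <- function() {
    if (length(pending) == 0L) return()
    method <- pending[[1L]]$method2
    plan <- plan_builder(method)(pending)
    items[[length(items) + 1L]] <<- list(
      type = "block", plan = plan,
      names = vapply(pending, `[[`, character(1), "name"),
      mins = lapply(pending, `[[`, "min"),
      maxs = lapply(pending, `[[`, "max"),
      locality = pending[[1L]]$locality)
    pending <<- list()
  }
  uid <- 0L
  for (v in variables) {
    uid <- uid + 1L
    n_hint <- if (v$locality == "shared") "shared" else "local"
    rn <- rename_specials(v$res, paste0(uid_prefix, uid), rand_specs,
                          gop_specs, n_hint)
    rand_specs <- rn$randoms; gop_specs <- rn$gops
    v$res$expr <- rn$expr
    v$rhs <- rn$expr
    method <- if (v$method == "inherit") default_method else v$method
    v$method2 <- method
    if (v$kind == "ode" && method == "event-driven") {
      event_vars[[length(event_vars) + 1L]] <- v
      next
    }
    if (v$kind == "ode") {
      if (length(pending) > 0L &&
          (pending[[1L]]$method2 != method ||
           pending[[1L]]$locality != v$locality)) flush()
      pending[[length(pending) + 1L]] <- v
    } else {
      flush()
      items[[length(items) + 1L]] <- list(
        type = "assign", name = v$name, op = v$op, expr = rn$expr,
        min = v$min, max = v$max, locality = v$locality)
    }
  }
  flush()
  list(items = items, randoms = rand_specs, gops = gop_specs,
       event_vars = event_vars)
}

clamp_value <- function(x, lo, hi) {
  if (!is.null(lo)) x <- pmax(x, lo)
  if (!is.null(hi)) x <- pmin(x, hi)
  x
}

apply_op <- function(old, op, val) {
  switch(op,
         "=" = val,
         "+=" = old + val,
         "-=" = old - val,
         "*=" = old * val,
         "/=" = old / val,
         stop("unknown operator: ", op, call. = FALSE))
}

compile_population <- function(net, pop) {
  model <- pop[["model"]]
  comp <- list()
  if (!is.null(pop[["special"]])) {
    pop[["comp"]] <- compile_special(net, pop)
    return(invisible(pop))
  }
  default <- net[["method"]]
  ci <- compile_items(model$variables, default, paste0("p", pop[["id"]], "_"))
  comp$items <- ci$items
  comp$randoms <- ci$randoms
  comp$gops <- ci$gops
  # referenced input sums and conductances (from all expressions)
  sums <- character(0); gts <- character(0)
  col <- function(res) {
    sums <<- union(sums, res$sums); gts <<- union(gts, res$g_refs)
  }
  for (v in model$variables) col(v$res)
  if (model$spiking) {
    col(model$spike$res)
    for (st in model$reset) col(st$res)
  }
  comp$sum_targets <- sums
  comp$g_targets <- gts
  # conductance storage for every referenced target; targets that only gain
  # increments through projections are added by compile_projection later
  comp$auto_g <- character(0)
  st <- pop[["storage"]]
  for (tg in gts) {
    gn <- paste0("g_", tg)
    if (!(gn %in% names(st))) {
      st[[gn]] <- numeric(pop[["size"]])
      comp$auto_g <- union(comp$auto_g, tg)
    }
  }
  pop[["storage"]] <- st
  comp$var_names <- vapply(model$variables, `[[`, character(1), "name")
  comp$cond_vars <- grep("^g_", comp$var_names, value = TRUE)
  if (model$spiking) {
    uid <- 0L
    comp$spike_expr <- model$spike$res$expr
    reset_items <- list()
    for (st in model$reset) {
      uid <- uid + 1L
      rn <- rename_specials(st$res, paste0("r", uid), comp$randoms,
                            comp$gops, "local")
      comp$randoms <- rn$randoms; comp$gops <- rn$gops
      spec <- Find(function(v) v$name == st$name, model$variables)
      reset_items[[length(reset_items) + 1L]] <- list(
        name = st$name, op = st$op, expr = rn$expr,
        min = spec$min, max = spec$max)
    }
    comp$reset <- reset_items
    refr <- model$refractory
    if (is.null(refr)) {
      comp$refr_steps <- 0L
    } else if (is.numeric(refr)) {
      comp$refr_steps <- as.integer(round(refr / net[["dt"]]))
    } else {
      comp$refr_attr <- refr  # name; variable takes precedence (same storage)
    }
  }
  pop[["comp"]] <- comp
  invisible(pop)
}

compile_network_population_g <- function(pop, target) {
  # ensure g_<target> storage exists; auto (instantaneous) if not declared
  gn <- paste0("g_", target)
  comp <- pop[["comp"]]
  if (!(gn %in% names(pop[["storage"]]))) {
    st <- pop[["storage"]]
    st[[gn]] <- numeric(pop[["size"]])
    pop[["storage"]] <- st
    comp$auto_g <- union(comp$auto_g, target)
  }
  comp$g_targets <- union(comp$g_targets, target)
  pop[["comp"]] <- comp
  invisible(pop)
}

#' Compile a network
#'
#' Builds the per-step update plans, converts delays to steps, sizes the
#' delay buffers and freezes the structure.  Called automatically by
#' [simulate()] when needed.
#'
#' @param net A network.
#' @export
compile_network <- function(net) {
  dt <- net[["dt"]]
  for (pop in net[["populations"]]) {
    pop[["inputs"]] <- list(sums = list(), g = list())
    compile_population(net, pop)
  }
  max_delay <- integer(length(net[["populations"]]))
  for (proj in net[["projections"]]) {
    compile_projection(net, proj)
    pre_pop <- pop_ranks(proj[["pre"]])$pop
    id <- pre_pop[["id"]]
    md <- if (synapse_count(proj) > 0L) max(proj[["comp"]]$delay_steps) else 1L
    max_delay[id] <- max(max_delay[id], md)
  }
  for (pop in net[["populations"]]) {
    cap <- max(1L, max_delay[pop[["id"]]])
    init <- if (pop[["spiking"]]) rep(FALSE, pop[["size"]])
            else rep_len(pop[["storage"]]$r, pop[["size"]])
    pop[["out_buffer"]] <- rep(list(init), cap)
  }
  net[["compiled"]] <- TRUE
  invisible(net)
}

compile_projection <- function(net, proj) {
  if (identical(proj[["kind_hint"]], "shared")) {
    return(compile_shared(net, proj))
  }
  if (!proj[["connected"]]) {
    stop("projection ", proj[["id"]], " has no synapses; call a connect_* ",
         "method before simulating", call. = FALSE)
  }
  dt <- net[["dt"]]
  model <- proj[["model"]]
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  comp <- list(pre_pop = prr$pop, post_pop = por$pop,
               pre_ranks = prr$ranks, post_ranks = por$ranks)
  kind <- proj[["kind_hint"]] %||%
    (if (prr$pop[["spiking"]]) "spike" else "rate")
  comp$kind <- kind
  # pre./post. attribute references used anywhere in the synapse model
  refs <- list(pre = character(0), post = character(0))
  collect_refs <- function(res) {
    refs$pre <<- union(refs$pre, res$pre_refs)
    refs$post <<- union(refs$post, res$post_refs)
  }
  for (v in model$variables) collect_refs(v$res)
  collect_refs(model$psp_res)
  for (st in model$pre_spike) collect_refs(st$res)
  for (st in model$post_spike) collect_refs(st$res)
  if (!is.null(model$creating)) collect_refs(model$creating$res)
  if (!is.null(model$pruning)) collect_refs(model$pruning$res)
  comp$refs <- refs
  syn <- proj[["syn"]]
  # delays -> steps (>= 1, rounded to the grid with a warning)
  d_ms <- syn$delay_ms
  d_ms[is.na(d_ms)] <- dt
  steps <- pmax(1L, as.integer(round(d_ms / dt)))
  if (any(abs(steps * dt - d_ms) > 1e-9)) {
    warning("synaptic delays rounded to a multiple of dt (", dt, " ms) in ",
            "projection ", proj[["id"]], call. = FALSE)
  }
  comp$delay_steps <- steps
  groups <- split(seq_along(steps), steps)
  comp$delay_groups <- lapply(names(groups), function(d)
    list(d = as.integer(d), idx = groups[[d]]))
  comp$post_index <- split(seq_along(syn$post),
                           factor(syn$post, levels = seq_len(por$pop[["size"]]) - 1L))
  comp$operator <- model$operator
  comp$psp_expr <- model$psp_res$expr
  comp$psp_simple <- identical(comp$psp_expr, quote(w * pre.r))
  comp$continuous <- kind == "spike" && model$psp_given
  comp$target <- proj[["target"]]

  # continuous variable plans (stage 4) and event-driven solutions
  if (length(model$variables) > 0L || kind == "spike") {
    ci <- compile_items(model$variables, net[["method"]],
                        paste0("j", proj[["id"]], "_"))
    comp$items <- ci$items
    comp$randoms <- ci$randoms
    comp$gops <- ci$gops
    if (length(ci$event_vars) > 0L) {
      state_names <- c(vapply(model$variables, `[[`, character(1), "name"), "w")
      comp$event_solution <- build_event_solution(ci$event_vars,
                                                  state_names = state_names)
      comp$event_names <- vapply(ci$event_vars, `[[`, character(1), "name")
      comp$event_bounds <- lapply(ci$event_vars, function(v)
        list(min = v$min, max = v$max))
      names(comp$event_bounds) <- comp$event_names
    } else {
      comp$event_names <- character(0)
    }
  } else {
    comp$items <- list(); comp$randoms <- list(); comp$gops <- list()
    comp$event_names <- character(0)
  }
  # w bounds if declared
  wspec <- Find(function(v) v$name == "w", model$variables)
  comp$w_min <- wspec$min; comp$w_max <- wspec$max
  # event statements
  compile_stmts <- function(stmts, label) {
    out <- list()
    uid <- 0L
    for (st in stmts) {
      uid <- uid + 1L
      rn <- rename_specials(st$res, paste0("s", label, uid), comp$randoms,
                            comp$gops, "event")
      comp$randoms <<- rn$randoms; comp$gops <<- rn$gops
      if (st$name == "g_target" && st$op != "+=") {
        stop("g_target only supports '+=' in event statements", call. = FALSE)
      }
      spec <- Find(function(v) v$name == st$name, model$variables)
      out[[length(out) + 1L]] <- list(
        name = st$name, op = st$op, expr = rn$expr,
        min = if (st$name == "w") comp$w_min else spec$min,
        max = if (st$name == "w") comp$w_max else spec$max)
    }
    out
  }
  if (kind == "spike") {
    comp$pre_spike <- compile_stmts(model$pre_spike, "a")
    comp$post_spike <- compile_stmts(model$post_spike, "b")
    if (any(vapply(comp$post_spike, function(s) s$name == "g_target",
                   logical(1)))) {
      stop("g_target can only be modified in pre_spike", call. = FALSE)
    }
    compile_network_population_g(por$pop, proj[["target"]])
  }
  # shared (postsynaptic) variable names
  comp$shared_vars <- names(proj[["post_shared"]])[
    vapply(proj[["post_shared"]], function(v)
      length(v) > 1L, logical(1))]
  comp$shared_params <- setdiff(names(proj[["post_shared"]]),
                                comp$shared_vars)
  comp$local_vars <- names(syn$vars)
  proj[["comp"]] <- comp
  if (kind == "decoding") compile_decoding(net, proj)
  invisible(proj)
}

# ---- bindings ---------------------------------------------------------------

# Global-operation value: op applied over a population attribute (own scope)
# or a pre./post. attribute (synapse scope).
gop_value <- function(gop, own_storage = NULL, proj = NULL) {
  ref <- gop$ref
  vals <- if (!is.null(proj) && startsWith(ref, "pre.")) {
    at <- sub("^pre\\.", "", ref)
    get_attribute(proj[["pre"]], at)
  } else if (!is.null(proj) && startsWith(ref, "post.")) {
    at <- sub("^post\\.", "", ref)
    get_attribute(proj[["post"]], at)
  } else {
    own_storage[[ref]]
  }
  switch(gop$op, mean = mean(vals), min = min(vals), max = max(vals))
}

# Bindings for per-synapse expressions over synapse subset `idx`.
# `pre_r` optionally supplies the delayed pre-synaptic rate per synapse (full
# length, indexed by idx).
syn_bindings <- function(net, proj, idx, pre_r = NULL) {
  syn <- proj[["syn"]]; comp <- proj[["comp"]]
  pre_pop <- comp$pre_pop; post_pop <- comp$post_pop
  b <- list(t = net[["t"]], dt = net[["dt"]])
  b$w <- syn$w[idx]
  for (nm in names(syn$vars)) b[[nm]] <- syn$vars[[nm]][idx]
  ps <- proj[["post_shared"]]
  for (nm in comp$shared_params) b[[nm]] <- ps[[nm]]
  for (nm in comp$shared_vars) b[[nm]] <- ps[[nm]][syn$post[idx] + 1L]
  pre_idx <- syn$pre[idx] + 1L
  post_idx <- syn$post[idx] + 1L
  prs <- pre_pop[["storage"]]; pos <- post_pop[["storage"]]
  # pre./post. references resolved lazily: only those the model uses
  refs <- proj[["comp"]]$refs
  for (at in refs$pre) {
    b[[paste0("pre.", at)]] <- if (at == "r" && !is.null(pre_r)) {
      pre_r[idx]
    } else {
      v <- prs[[at]]
      if (length(v) == 1L) v else v[pre_idx]
    }
  }
  for (at in refs$post) {
    v <- pos[[at]]
    b[[paste0("post.", at)]] <- if (length(v) == 1L) v else v[post_idx]
  }
  for (gn in names(comp$gops)) {
    b[[gn]] <- gop_value(comp$gops[[gn]], proj = proj)
  }
  b
}

# Aggregate per-synapse values into a per-post vector under the operator.
aggregate_post <- function(vals, post, npost, operator, post_index = NULL) {
  out <- numeric(npost)
  if (length(vals) == 0L) return(out)
  if (operator %in% c("sum", "mean")) {
    rs <- rowsum(vals, post)
    ranks <- as.integer(rownames(rs)) + 1L
    out[ranks] <- rs[, 1L]
    if (operator == "mean") {
      cnt <- rowsum(rep(1, length(vals)), post)
      out[ranks] <- out[ranks] / cnt[, 1L]
    }
  } else {
    f <- if (operator == "max") max else min
    spl <- split(vals, post)
    ranks <- as.integer(names(spl)) + 1L
    out[ranks] <- vapply(spl, f, numeric(1))
  }
  out
}

add_input_sum <- function(pop, target, vec) {
  inputs <- pop[["inputs"]]
  cur <- inputs$sums[[target]]
  inputs$sums[[target]] <- if (is.null(cur)) vec else cur + vec
  pop[["inputs"]] <- inputs
}

add_input_g <- function(pop, target, vec) {
  inputs <- pop[["inputs"]]
  cur <- inputs$g[[target]]
  inputs$g[[target]] <- if (is.null(cur)) vec else cur + vec
  pop[["inputs"]] <- inputs
}

# ---- stage 1: propagation ---------------------------------------------------

# Delayed pre-synaptic output per synapse (rate r or spike flags).
delayed_pre_output <- function(proj) {
  syn <- proj[["syn"]]; comp <- proj[["comp"]]
  n <- length(syn$pre)
  out <- if (comp$pre_pop[["spiking"]]) logical(n) else numeric(n)
  for (g in comp$delay_groups) {
    buf <- pop_delayed_output(comp$pre_pop, g$d)
    out[g$idx] <- buf[syn$pre[g$idx] + 1L]
  }
  out
}

#' Current input of a projection
#'
#' Evaluates, without advancing the simulation, what the projection
#' contributes to its post-synaptic population this step: the aggregated
#' `psp` over delayed pre-synaptic rates for rate-coded projections, or the
#' decoded rate for decoding projections.
#'
#' @param proj A projection (network must be compiled).
#' @return Per-post-neuron vector (parent-population size).
#' @export
compute_input_sums <- function(proj) {
  net <- proj[["net"]]
  if (!net[["compiled"]]) compile_network(net)
  comp <- proj[["comp"]]
  if (comp$kind == "decoding") return(decoding_value(proj))
  syn <- proj[["syn"]]
  pre_r <- delayed_pre_output(proj)
  vals <- if (comp$psp_simple) syn$w * pre_r
          else rs_eval(comp$psp_expr,
                       syn_bindings(net, proj, seq_along(syn$pre),
                                    pre_r = pre_r))
  aggregate_post(vals, syn$post, comp$post_pop[["size"]], comp$operator)
}

propagate_rate <- function(net, proj) {
  comp <- proj[["comp"]]
  add_input_sum(comp$post_pop, comp$target, compute_input_sums(proj))
}

propagate_spike <- function(net, proj) {
  comp <- proj[["comp"]]; syn <- proj[["syn"]]
  if (comp$continuous) {
    # non-linear synapses: psp summed into g_target every step
    vals <- rs_eval(comp$psp_expr,
                    syn_bindings(net, proj, seq_along(syn$pre)))
    agg <- aggregate_post(rep_len(vals, length(syn$pre)), syn$post,
                          comp$post_pop[["size"]], "sum")
    add_input_g(comp$post_pop, comp$target, agg)
  }
  for (g in comp$delay_groups) {
    flags <- pop_delayed_output(comp$pre_pop, g$d)
    idx <- g$idx[flags[syn$pre[g$idx] + 1L]]
    if (length(idx) > 0L) handle_spike_event(net, proj, idx, comp$pre_spike)
  }
}

# Execute event statements (pre_spike or post_spike) for synapse subset idx,
# advancing event-driven variables first.
handle_spike_event <- function(net, proj, idx, stmts, now = NULL) {
  comp <- proj[["comp"]]; syn <- proj[["syn"]]
  # pre-synaptic events run at spike arrival (stage 1, start of step);
  # post-synaptic events at the end of the emitting step (stage 5, t + dt),
  # so an isolated pre/post pair at nominal separation dt_spike with the
  # minimal delay sees exactly dt_spike of trace decay in either direction.
  now <- now %||% net[["t"]]
  if (length(comp$event_names) > 0L) {
    b <- syn_bindings(net, proj, idx)
    elapsed <- now - syn$last_event[idx]
    new <- comp$event_solution$advance(b, elapsed)
    for (nm in names(new)) {
      bd <- comp$event_bounds[[nm]]
      val <- clamp_value(new[[nm]], bd$min, bd$max)
      syn$vars[[nm]][idx] <- val
      b[[nm]] <- val
    }
    syn$last_event[idx] <- now
  } else {
    b <- NULL
  }
  if (length(stmts) > 0L) {
    if (is.null(b)) b <- syn_bindings(net, proj, idx)
    for (rn in names(comp$randoms)) {
      if (!identical(comp$randoms[[rn]]$n, "event")) next
      b[[rn]] <- draw_random_node(comp$randoms[[rn]]$spec, length(idx), b)
    }
    for (st in stmts) {
      val <- rs_eval(st$expr, b)
      if (st$name == "g_target") {
        inc <- rep_len(val, length(idx))
        agg <- aggregate_post(inc, syn$post[idx], comp$post_pop[["size"]],
                              "sum")
        add_input_g(comp$post_pop, comp$target, agg)
      } else if (st$name == "w") {
        nv <- clamp_value(apply_op(syn$w[idx], st$op, val),
                          comp$w_min, comp$w_max)
        syn$w[idx] <- nv
        b$w <- nv
      } else {
        nv <- clamp_value(apply_op(syn$vars[[st$name]][idx], st$op, val),
                          st$min, st$max)
        syn$vars[[st$name]][idx] <- nv
        b[[st$name]] <- nv
      }
    }
  }
  proj[["syn"]] <- syn
  invisible(proj)
}

# ---- stage 2: neural update -------------------------------------------------

update_population <- function(net, pop) {
  if (!is.null(pop[["special"]])) return(update_special(net, pop))
  comp <- pop[["comp"]]
  st <- pop[["storage"]]
  size <- pop[["size"]]
  dt <- net[["dt"]]
  inputs <- pop[["inputs"]]
  shared <- pop[["shared"]]

  b <- st
  b$t <- net[["t"]]; b$dt <- dt
  for (tg in comp$sum_targets) {
    b[[paste0(".sum_", tg)]] <- inputs$sums[[tg]] %||% 0
  }
  for (tg in comp$g_targets) {
    gn <- paste0("g_", tg)
    inc <- inputs$g[[tg]]
    if (tg %in% comp$auto_g) {
      val <- if (is.null(inc)) numeric(size) else inc
      st[[gn]] <- val
    } else if (!is.null(inc)) {
      st[[gn]] <- st[[gn]] + inc
    }
    b[[gn]] <- st[[gn]]
  }
  for (gn in names(comp$gops)) {
    b[[gn]] <- gop_value(comp$gops[[gn]], own_storage = st)
  }
  for (rn in names(comp$randoms)) {
    spec <- comp$randoms[[rn]]
    n <- if (identical(spec$n, "shared")) 1L else size
    b[[rn]] <- draw_random_node(spec$spec, n, b)
  }

  refrac <- pop[["refrac_remaining"]]
  frozen <- refrac > 0L
  any_frozen <- any(frozen)
  old <- if (any_frozen) st

  for (item in comp$items) {
    if (item$type == "assign") {
      val <- rs_eval(item$expr, b)
      nv <- apply_op(if (item$locality == "shared") st[[item$name]]
                     else rep_len(st[[item$name]], size), item$op, val)
      if (item$locality == "shared") nv <- nv[1L]
      nv <- clamp_value(nv, item$min, item$max)
      st[[item$name]] <- nv
      b[[item$name]] <- nv
    } else {
      new <- item$plan$step(b, dt)
      for (i in seq_along(item$names)) {
        nm <- item$names[i]
        nv <- clamp_value(new[[nm]], item$mins[[i]], item$maxs[[i]])
        if (nm %in% shared) nv <- nv[1L]
        else nv <- rep_len(nv, size)
        st[[nm]] <- nv
        b[[nm]] <- nv
      }
    }
  }

  # refractory neurons: only conductance variables advance
  if (any_frozen) {
    for (nm in setdiff(comp$var_names, comp$cond_vars)) {
      if (nm %in% shared) next
      v <- st[[nm]]
      v[frozen] <- rep_len(old[[nm]], size)[frozen]
      st[[nm]] <- v
      b[[nm]] <- v
    }
  }

  spiked <- integer(0)
  if (pop[["spiking"]]) {
    cond <- rep_len(rs_eval(comp$spike_expr, b), size)
    cond[is.na(cond)] <- FALSE
    spiked <- which(cond & !frozen)
    if (length(spiked) > 0L) {
      bs <- b
      for (nm in names(st)) {
        if (!(nm %in% shared) && length(st[[nm]]) == size) {
          bs[[nm]] <- st[[nm]][spiked]
        }
      }
      for (item in comp$reset) {
        val <- rs_eval(item$expr, bs)
        nv <- clamp_value(apply_op(bs[[item$name]], item$op, val),
                          item$min, item$max)
        v <- st[[item$name]]
        v[spiked] <- rep_len(nv, length(spiked))
        st[[item$name]] <- v
        bs[[item$name]] <- nv
      }
      # enter refractory state
      steps <- if (!is.null(comp$refr_attr)) {
        vals <- st[[comp$refr_attr]]
        if (any(vals < 0)) stop("negative refractory duration", call. = FALSE)
        as.integer(round(rep_len(vals, size)[spiked] / dt))
      } else {
        comp$refr_steps
      }
      refrac[frozen] <- refrac[frozen] - 1L
      refrac[spiked] <- steps
    } else {
      refrac[frozen] <- refrac[frozen] - 1L
    }
  }
  # instantaneous conductances: the summed increments were visible to this
  # update only; reset to 0 for the next step
  for (tg in comp$auto_g) {
    st[[paste0("g_", tg)]] <- numeric(size)
  }
  spk <- logical(size)
  spk[spiked] <- TRUE
  pop[["last_spiked"]] <- spk
  pop[["refrac_remaining"]] <- refrac
  pop[["storage"]] <- st
  pop[["inputs"]] <- list(sums = inputs$sums, g = list())
  invisible(pop)
}

# ---- stage 3: delayed outputs -----------------------------------------------

push_outputs <- function(pop) {
  buf <- pop[["out_buffer"]]
  out <- if (pop[["spiking"]]) pop[["last_spiked"]] else pop[["storage"]]$r
  cap <- length(buf)
  pop[["out_buffer"]] <- if (cap == 1L) list(out) else c(list(out), buf[-cap])
  invisible(pop)
}

# ---- stage 4: synaptic updates ----------------------------------------------

update_projection <- function(net, proj) {
  comp <- proj[["comp"]]
  if (length(comp$items) == 0L) return(invisible(proj))
  syn <- proj[["syn"]]
  n <- length(syn$pre)
  if (n == 0L) return(invisible(proj))
  pre_r <- if (!comp$pre_pop[["spiking"]]) delayed_pre_output(proj)
  b <- syn_bindings(net, proj, seq_len(n), pre_r = pre_r)
  # shared (postsynaptic) bindings, over the full post population
  ps <- proj[["post_shared"]]
  post_st <- comp$post_pop[["storage"]]
  bs <- list(t = net[["t"]], dt = net[["dt"]])
  for (nm in names(ps)) bs[[nm]] <- ps[[nm]]
  for (at in comp$refs$post) {
    v <- post_st[[at]]
    bs[[paste0("post.", at)]] <- v
  }
  for (gn in names(comp$gops)) {
    bs[[gn]] <- gop_value(comp$gops[[gn]], proj = proj)
    b[[gn]] <- bs[[gn]]
  }
  npost <- comp$post_pop[["size"]]
  for (rn in names(comp$randoms)) {
    spec <- comp$randoms[[rn]]
    if (identical(spec$n, "event")) next
    nn <- if (identical(spec$n, "shared")) npost else n
    val <- draw_random_node(spec$spec, nn, if (nn == n) b else bs)
    if (nn == n) b[[rn]] <- val else bs[[rn]] <- val
  }
  post_map <- syn$post + 1L

  for (item in comp$items) {
    if (item$locality == "shared") {
      if (item$type == "assign") {
        val <- rs_eval(item$expr, bs)
        nv <- clamp_value(apply_op(ps[[item$name]], item$op,
                                   rep_len(val, npost)), item$min, item$max)
        ps[[item$name]] <- nv
        bs[[item$name]] <- nv
        b[[item$name]] <- nv[post_map]
      } else {
        new <- item$plan$step(bs, net[["dt"]])
        for (i in seq_along(item$names)) {
          nm <- item$names[i]
          nv <- clamp_value(rep_len(new[[nm]], npost),
                            item$mins[[i]], item$maxs[[i]])
          ps[[nm]] <- nv
          bs[[nm]] <- nv
          b[[nm]] <- nv[post_map]
        }
      }
    } else {
      if (item$type == "assign") {
        val <- rs_eval(item$expr, b)
        cur <- if (item$name == "w") syn$w else syn$vars[[item$name]]
        nv <- clamp_value(apply_op(cur, item$op, rep_len(val, n)),
                          item$min, item$max)
        if (item$name == "w") syn$w <- nv else syn$vars[[item$name]] <- nv
        b[[item$name]] <- nv
      } else {
        new <- item$plan$step(b, net[["dt"]])
        for (i in seq_along(item$names)) {
          nm <- item$names[i]
          nv <- clamp_value(rep_len(new[[nm]], n),
                            item$mins[[i]], item$maxs[[i]])
          if (nm == "w") syn$w <- nv else syn$vars[[nm]] <- nv
          b[[nm]] <- nv
        }
      }
    }
  }
  proj[["post_shared"]] <- ps
  proj[["syn"]] <- syn
  invisible(proj)
}

# ---- stage 5: post-synaptic events ------------------------------------------

post_events <- function(net, proj) {
  comp <- proj[["comp"]]
  if (comp$kind != "spike") return(invisible(proj))
  if (length(comp$post_spike) == 0L && length(comp$event_names) == 0L) {
    return(invisible(proj))
  }
  spk <- comp$post_pop[["last_spiked"]]
  ranks <- which(spk) - 1L
  if (length(ranks) == 0L) return(invisible(proj))
  idx <- unlist(comp$post_index[as.character(ranks)], use.names = FALSE)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(invisible(proj))
  handle_spike_event(net, proj, idx, comp$post_spike,
                     now = net[["t"]] + net[["dt"]])
}

# ---- stage 7: NaN guard -----------------------------------------------------

check_network_state <- function(net) {
  for (pop in net[["populations"]]) {
    st <- pop[["storage"]]
    for (nm in names(st)) {
      if (is.numeric(st[[nm]]) && any(!is.finite(st[[nm]]))) {
        stop("non-finite value in population ",
             pop[["name"]] %||% pop[["id"]], ", variable '", nm,
             "' at t = ", net[["t"]], " ms", call. = FALSE)
      }
    }
  }
  for (proj in net[["projections"]]) {
    syn <- proj[["syn"]]
    if (any(!is.finite(syn$w))) {
      stop("non-finite weight in projection ", proj[["id"]], " at t = ",
           net[["t"]], " ms", call. = FALSE)
    }
  }
  invisible(net)
}

# ---- the step ---------------------------------------------------------------

#' Advance a network by one step
#'
#' Executes the seven simulation stages and increments the clock by `dt`.
#' Usually called through [simulate()].
#'
#' @param net A compiled network.
#' @export
step_network <- function(net) {
  if (!net[["compiled"]]) compile_network(net)
  with_net_rng(net, {
    # stage 1: propagation of previous-step outputs
    for (pop in net[["populations"]]) {
      pop[["inputs"]] <- list(sums = list(), g = list())
    }
    for (proj in net[["projections"]]) {
      switch(proj[["comp"]]$kind,
             rate = propagate_rate(net, proj),
             spike = propagate_spike(net, proj),
             decoding = propagate_decoding(net, proj),
             shared = propagate_shared(net, proj))
    }
    # stage 2: neural updates, spike emission
    for (pop in net[["populations"]]) update_population(net, pop)
    # stage 3: delayed outputs
    for (pop in net[["populations"]]) push_outputs(pop)
    # stage 4: continuous synaptic updates
    for (proj in net[["projections"]]) {
      if (proj[["comp"]]$kind %in% c("rate", "spike")) {
        update_projection(net, proj)
      }
    }
    # stage 5: post-synaptic events
    for (proj in net[["projections"]]) post_events(net, proj)
    # stage 6: structural plasticity
    for (proj in net[["projections"]]) apply_structural_rules(proj)
    # stage 7: recording
    for (mon in net[["monitors"]]) monitor_record(mon)
    net[["step"]] <- net[["step"]] + 1L
    net[["t"]] <- net[["step"]] * net[["dt"]]
    if (net[["debug"]] || net[["step"]] %% 100L == 0L) {
      check_network_state(net)
    }
  })
  invisible(net)
}

#' Simulate for a duration
#'
#' Runs `round(duration / dt)` steps.  Attributes can be read and modified
#' freely between calls; successive calls continue the same random stream, so
#' two 500 ms runs reproduce one 1000 ms run exactly.
#'
#' @param net A network.
#' @param duration Duration in ms (>= 0).
#' @export
simulate <- function(net, duration) {
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  nsteps <- as.integer(round(duration / net[["dt"]]))
  for (i in seq_len(nsteps)) step_network(net)
  invisible(net)
}

#' Simulate until a stop condition holds
#'
#' Steps the network until any of the listed populations' stop conditions is
#' satisfied (`any` quantifier: some neuron; `all`: every neuron), or until
#' `max_duration` elapses.
#'
#' @param net A network.
#' @param max_duration Maximal duration in ms.
#' @param populations A population or list of populations with
#'   `stop_condition`s.
#' @return Elapsed simulated time in ms.
#' @export
simulate_until <- function(net, max_duration, populations) {
  if (inherits(populations, "rs_population")) populations <- list(populations)
  for (pop in populations) {
    if (is.null(pop[["stop_condition"]])) {
      stop("population has no stop_condition", call. = FALSE)
    }
  }
  nsteps <- as.integer(round(max_duration / net[["dt"]]))
  for (i in seq_len(nsteps)) {
    step_network(net)
    for (pop in populations) {
      sc <- pop[["stop_condition"]]
      b <- pop[["storage"]]
      b$t <- net[["t"]]; b$dt <- net[["dt"]]
      vals <- rep_len(rs_eval(sc$res$expr, b), pop[["size"]])
      hit <- if (sc$quantifier == "all") all(vals) else any(vals)
      if (isTRUE(hit)) return(i * net[["dt"]])
    }
  }
  nsteps * net[["dt"]]
}
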