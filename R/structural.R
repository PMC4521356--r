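# Structural plasticity: runtime creation and pruning of synapses, either
# explicitly or through condition rules declared on the synapse model.

# Recompute the projection's compiled indexes after a connectivity change.
refresh_projection_indexes <- function(proj) {
  net <- proj[["net"]]
  if (!net[["compiled"]] || is.null(proj[["comp"]])) return(invisible(proj))
  comp <- proj[["comp"]]
  syn <- proj[["syn"]]
  dt <- net[["dt"]]
  d_ms <- syn$delay_ms
  d_ms[is.na(d_ms)] <- dt
  steps <- pmax(1L, as.integer(round(d_ms / dt)))
  comp$delay_steps <- steps
  groups <- split(seq_along(steps), steps)
  comp$delay_groups <- lapply(names(groups), function(d)
    list(d = as.integer(d), idx = groups[[d]]))
  npost <- comp$post_pop[["size"]]
  comp$post_index <- split(seq_along(syn$post),
                           factor(syn$post, levels = seq_len(npost) - 1L))
  proj[["comp"]] <- comp
  # grow the pre-population delay buffer if a new delay exceeds its capacity
  pre_pop <- comp$pre_pop
  buf <- pre_pop[["out_buffer"]]
  need <- max(1L, steps)
  if (!is.null(buf) && need > length(buf)) {
    filler <- if (pre_pop[["spiking"]]) rep(FALSE, pre_pop[["size"]])
              else rep(0, pre_pop[["size"]])
    pre_pop[["out_buffer"]] <- c(buf, rep(list(filler), need - length(buf)))
  }
  invisible(proj)
}

#' Create a synapse at runtime
#'
#' The synapse is inserted in rank order, its per-synapse variables start at
#' their declared initial values, and it participates in the next
#' propagation stage.
#'
#' @param proj A projection.
#' @param pre_rank,post_rank 0-based ranks in the parent populations.
#' @param w Weight (default 0).
#' @param d Delay in ms (default: one step).
#' @export
create_synapse <- function(proj, pre_rank, post_rank, w = 0, d = NULL) {
  syn <- proj[["syn"]]
  if (any(syn$pre == pre_rank & syn$post == post_rank)) {
    stop("synapse (", pre_rank, " -> ", post_rank, ") already exists",
         call. = FALSE)
  }
  pos <- findInterval(post_rank * 2^26 + pre_rank,
                      syn$post * 2^26 + syn$pre) + 1L
  ins <- function(vec, val) append(vec, val, after = pos - 1L)
  syn$pre <- ins(syn$pre, as.integer(pre_rank))
  syn$post <- ins(syn$post, as.integer(post_rank))
  syn$w <- ins(syn$w, w)
  syn$delay_ms <- ins(syn$delay_ms, d %||% NA_real_)
  syn$last_event <- ins(syn$last_event, proj[["net"]][["t"]])
  model <- proj[["model"]]
  for (nm in names(syn$vars)) {
    vspec <- Find(function(v) v$name == nm, model$variables)
    pspec <- Find(function(p) p$name == nm, model$parameters)
    init <- if (!is.null(vspec)) vspec$init else pspec$default
    syn$vars[[nm]] <- ins(syn$vars[[nm]], init)
  }
  proj[["syn"]] <- syn
  refresh_projection_indexes(proj)
  invisible(proj)
}

#' Remove a synapse at runtime
#'
#' @inheritParams create_synapse
#' @export
prune_synapse <- function(proj, pre_rank, post_rank) {
  syn <- proj[["syn"]]
  pos <- which(syn$pre == pre_rank & syn$post == post_rank)
  if (length(pos) == 0L) {
    stop("no synapse (", pre_rank, " -> ", post_rank, ") to prune",
         call. = FALSE)
  }
  prune_at <- function(idx) {
    syn$pre <<- syn$pre[-idx]; syn$post <<- syn$post[-idx]
    syn$w <<- syn$w[-idx]; syn$delay_ms <<- syn$delay_ms[-idx]
    syn$last_event <<- syn$last_event[-idx]
    for (nm in names(syn$vars)) syn$vars[[nm]] <<- syn$vars[[nm]][-idx]
  }
  prune_at(pos)
  proj[["syn"]] <- syn
  refresh_projection_indexes(proj)
  invisible(proj)
}

#' Start and stop structural-plasticity rules
#'
#' The synapse model's `creating` / `pruning` rules only run once explicitly
#' started.  `period` sets how often (in ms) the conditions are checked; the
#' default is every step, which is expensive — prefer a coarser period.
#'
#' @param proj A projection whose model declares the rule.
#' @param period Check period in ms (default: every step).
#' @name structural-rules
NULL

#' @rdname structural-rules
#' @export
start_creating <- function(proj, period = NULL) {
  if (is.null(proj[["model"]]$creating)) {
    stop("synapse model declares no creating rule", call. = FALSE)
  }
  proj[["creating_active"]] <- TRUE
  proj[["creating_period"]] <- period
  proj[["creating_last"]] <- proj[["net"]][["step"]]
  invisible(proj)
}

#' @rdname structural-rules
#' @export
stop_creating <- function(proj) {
  proj[["creating_active"]] <- FALSE
  invisible(proj)
}

#' @rdname structural-rules
#' @export
start_pruning <- function(proj, period = NULL) {
  if (is.null(proj[["model"]]$pruning)) {
    stop("synapse model declares no pruning rule", call. = FALSE)
  }
  proj[["pruning_active"]] <- TRUE
  proj[["pruning_period"]] <- period
  proj[["pruning_last"]] <- proj[["net"]][["step"]]
  invisible(proj)
}

#' @rdname structural-rules
#' @export
stop_pruning <- function(proj) {
  proj[["pruning_active"]] <- FALSE
  invisible(proj)
}

rule_due <- function(proj, which) {
  if (!isTRUE(proj[[paste0(which, "_active")]])) return(FALSE)
  net <- proj[["net"]]
  period <- proj[[paste0(which, "_period")]]
  steps <- if (is.null(period)) 1L
           else max(1L, as.integer(round(period / net[["dt"]])))
  (net[["step"]] - proj[[paste0(which, "_last")]] + 1L) %% steps == 0L
}

# Stage 6 of the step: evaluate active creating/pruning rules.
apply_structural_rules <- function(proj) {
  model <- proj[["model"]]
  if (is.null(model) ||
      (is.null(model$creating) && is.null(model$pruning))) {
    return(invisible(proj))
  }
  net <- proj[["net"]]
  created <- pruned <- 0L
  if (!is.null(model$pruning) && rule_due(proj, "pruning")) {
    rule <- model$pruning
    syn <- proj[["syn"]]
    n <- length(syn$pre)
    if (n > 0L) {
      b <- syn_bindings(net, proj, seq_len(n))
      hold <- rep_len(as.logical(rs_eval(rule$res$expr, b)), n)
      hold[is.na(hold)] <- FALSE
      if (rule$proba < 1) hold <- hold & stats::runif(n) < rule$proba
      if (any(hold)) {
        doomed <- which(hold)
        pruned <- length(doomed)
        syn$pre <- syn$pre[-doomed]; syn$post <- syn$post[-doomed]
        syn$w <- syn$w[-doomed]; syn$delay_ms <- syn$delay_ms[-doomed]
        syn$last_event <- syn$last_event[-doomed]
        for (nm in names(syn$vars)) syn$vars[[nm]] <- syn$vars[[nm]][-doomed]
        proj[["syn"]] <- syn
        refresh_projection_indexes(proj)
      }
    }
  }
  if (!is.null(model$creating) && rule_due(proj, "creating")) {
    rule <- model$creating
    comp <- proj[["comp"]]
    prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
    # enumerate absent (pre, post) pairs
    pre_all <- rep(prr$ranks, times = length(por$ranks))
    post_all <- rep(por$ranks, each = length(prr$ranks))
    syn <- proj[["syn"]]
    npre_tot <- prr$pop[["size"]]
    existing <- as.numeric(syn$post) * npre_tot + syn$pre
    keys <- as.numeric(post_all) * npre_tot + pre_all
    absent <- !(keys %in% existing)
    if (identical(prr$pop, por$pop)) absent <- absent & pre_all != post_all
    if (any(absent)) {
      pre_c <- pre_all[absent]; post_c <- post_all[absent]
      prs <- prr$pop[["storage"]]; pos <- por$pop[["storage"]]
      b <- list(t = net[["t"]], dt = net[["dt"]])
      for (at in rule$res$pre_refs) {
        v <- prs[[at]]
        b[[paste0("pre.", at)]] <- if (length(v) == 1L) v else v[pre_c + 1L]
      }
      for (at in rule$res$post_refs) {
        v <- pos[[at]]
        b[[paste0("post.", at)]] <- if (length(v) == 1L) v else v[post_c + 1L]
      }
      ps <- proj[["post_shared"]]
      for (nm in names(ps)) {
        b[[nm]] <- if (length(ps[[nm]]) == 1L) ps[[nm]] else ps[[nm]][post_c + 1L]
      }
      hold <- rep_len(as.logical(rs_eval(rule$res$expr, b)), length(pre_c))
      hold[is.na(hold)] <- FALSE
      if (rule$proba < 1) {
        hold <- hold & stats::runif(length(pre_c)) < rule$proba
      }
      if (any(hold)) {
        for (i in which(hold)) {
          create_synapse(proj, pre_c[i], post_c[i],
                         w = rule$w %||% 0, d = rule$d)
        }
        created <- sum(hold)
      }
    }
  }
  if (created > 0L || pruned > 0L) {
    log <- proj[["structural_log"]] %||% list()
    log[[length(log) + 1L]] <- list(t = net[["t"]], created = created,
                                    pruned = pruned)
    proj[["structural_log"]] <- log
  }
  invisible(proj)
}
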