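# Neuron and synapse model constructors.
#
# A model is the parsed, validated form of the plain-text parameter/equation
# blocks.  Populations and projections instantiate storage from it; the
# numerical layer (numerics.R) turns its ODEs into per-step update plans.

# Parse a statement list such as `reset`, `pre_spike` or `post_spike`:
# plain assignments (augmented operators allowed), no flags.
parse_statements <- function(text, scope) {
  stmts <- dsl_split_statements(text)
  lapply(stmts, function(stmt) {
    asg <- dsl_split_assign(stmt)
    if (is.null(asg)) {
      stop("statement must be an assignment: ", stmt, call. = FALSE)
    }
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", asg$lhs)) {
      stop("invalid assignment target: ", asg$lhs, call. = FALSE)
    }
    list(name = asg$lhs, op = asg$op,
         res = resolve_generic(dsl_str2lang(asg$rhs)))
  })
}

#' Define a neuron model
#'
#' Parses the textual description of a neuron into a validated model.  A model
#' with a `spike` condition is a spiking neuron (with optional `reset`
#' statements and a `refractory` period); a model without one is rate-coded
#' and must declare a variable named `r`, the instantaneous firing rate read
#' by outgoing projections.
#'
#' @param parameters Parameter block (see [parse_parameters()]).
#' @param equations Equation block (see [parse_variables()]).
#' @param spike Optional boolean spike condition, e.g. `"v > v_thresh"`.
#' @param reset Optional statements applied after a spike, e.g.
#'   `"v = c \n u += d"`.
#' @param refractory Optional refractory period: a duration in ms, or the name
#'   of a parameter/variable holding one (a variable takes precedence over a
#'   parameter of the same name).
#' @param name Optional model name (used in printing).
#' @return An object of class `rs_neuron_model`.
#' @examples
#' lif <- neuron_model(
#'   parameters = "tau = 10.0 : population\nB = 0.0",
#'   equations = "tau * dr/dt + r = sum(exc) + B : min = 0.0")
#' @export
neuron_model <- function(parameters = "", equations = "", spike = NULL,
                         reset = NULL, refractory = NULL, name = NULL) {
  params <- parse_parameters(parameters)
  vars <- parse_variables(equations, scope = "neuron")
  pnames <- vapply(params, `[[`, character(1), "name")
  vnames <- vapply(vars, `[[`, character(1), "name")
  dup <- intersect(pnames, vnames)
  if (length(dup) > 0L) {
    stop("name(s) declared both as parameter and variable: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  spiking <- !is.null(spike)
  if (!spiking && !("r" %in% vnames)) {
    stop("a rate-coded neuron model must declare a variable named 'r'",
         call. = FALSE)
  }
  scope <- list(kind = "neuron", spiking = spiking,
                names = c(pnames, vnames), extra = character(0))
  for (i in seq_along(vars)) {
    vars[[i]]$res <- validate_resolved(vars[[i]]$res, scope)
  }
  spike_cond <- NULL
  reset_stmts <- list()
  refr <- NULL
  if (spiking) {
    spike_cond <- parse_condition(spike)
    spike_cond$res <- validate_resolved(resolve_generic(spike_cond$expr), scope)
    spike_cond$expr <- spike_cond$res$expr
    if (!is.null(reset)) {
      reset_stmts <- parse_statements(reset, scope)
      for (i in seq_along(reset_stmts)) {
        st <- reset_stmts[[i]]
        if (!(st$name %in% vnames)) {
          stop("reset statement assigns to undeclared variable: ", st$name,
               call. = FALSE)
        }
        reset_stmts[[i]]$res <- validate_resolved(st$res, scope)
      }
    }
    if (!is.null(refractory)) {
      if (is.numeric(refractory)) {
        if (refractory < 0) stop("refractory period must be >= 0", call. = FALSE)
        refr <- refractory
      } else if (is.character(refractory)) {
        if (!(refractory %in% c(pnames, vnames))) {
          stop("refractory refers to undeclared name: ", refractory,
               call. = FALSE)
        }
        refr <- refractory
      } else {
        stop("refractory must be a number (ms) or an attribute name",
             call. = FALSE)
      }
    }
  } else if (!is.null(reset) || !is.null(refractory)) {
    stop("reset/refractory require a spike condition", call. = FALSE)
  }
  structure(list(
    parameters = params, variables = vars, spiking = spiking,
    spike = spike_cond, reset = reset_stmts, refractory = refr,
    name = name %||% if (spiking) "custom spiking neuron" else
      "custom rate-coded neuron"
  ), class = "rs_neuron_model")
}

#' Define a synapse model
#'
#' For rate-coded pre-synaptic populations the synapse contributes
#' `psp` (default `w * pre.r`) to the post-synaptic input `sum(target)`,
#' aggregated with `operator` (`sum`, `max`, `min` or `mean`).  For spiking
#' pre-synaptic populations transmission is event-driven: `pre_spike`
#' statements (default `g_target += w`) run when a pre-synaptic spike arrives,
#' `post_spike` statements when the post-synaptic neuron fires.  Declaring
#' `psp` on a spiking projection switches to continuous transmission: `psp` is
#' summed into `g_target` at every step (non-linear synapses such as NMDA).
#'
#' Variables flagged `event-driven` are advanced exactly (closed-form solution
#' of their linear ODE) whenever a pre- or post-synaptic spike reaches the
#' synapse, immediately before the event statements execute.
#'
#' `creating` / `pruning` are optional structural-plasticity rules: boolean
#' conditions with optional `proba`, `w` and `d` flags (see
#' [start_creating()]).
#'
#' @param parameters,equations Textual blocks, as for [neuron_model()].
#'   The flag `postsynaptic` marks a parameter/variable as shared per
#'   post-synaptic neuron.
#' @param psp Optional per-synapse output expression.
#' @param operator Aggregation across incoming synapses (rate-coded /
#'   continuous transmission only).
#' @param pre_spike,post_spike Statement blocks run at spike events; they may
#'   assign only to synaptic variables, `w` and `g_target`.
#' @param creating,pruning Optional structural-plasticity rules.
#' @param name Optional model name.
#' @return An object of class `rs_synapse_model`.
#' @export
synapse_model <- function(parameters = "", equations = "", psp = NULL,
                          operator = c("sum", "max", "min", "mean"),
                          pre_spike = NULL, post_spike = NULL,
                          creating = NULL, pruning = NULL, name = NULL) {
  operator <- match.arg(operator)
  params <- parse_parameters(parameters)
  vars <- parse_variables(equations, scope = "synapse")
  pnames <- vapply(params, `[[`, character(1), "name")
  vnames <- vapply(vars, `[[`, character(1), "name")
  dup <- intersect(pnames, vnames)
  if (length(dup) > 0L) {
    stop("name(s) declared both as parameter and variable: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  # `w` is implicitly a per-synapse variable (the connection weight); a model
  # may give it dynamics by declaring an equation for it, but not shadow it
  # with a parameter.
  if ("w" %in% pnames) {
    stop("'w' is the implicit connection weight and cannot be a parameter",
         call. = FALSE)
  }
  for (v in vars) {
    if (v$name == "w" && v$locality == "shared") {
      stop("'w' is a per-synapse variable and cannot be postsynaptic",
           call. = FALSE)
    }
  }
  scope <- list(kind = "synapse", spiking = FALSE,
                names = c(pnames, vnames), extra = c("w", "g_target"))
  for (i in seq_along(vars)) {
    vars[[i]]$res <- validate_resolved(vars[[i]]$res, scope)
  }
  psp_given <- !is.null(psp)
  psp_expr <- dsl_str2lang(psp %||% "w * pre.r")
  psp_res <- validate_resolved(resolve_generic(psp_expr), scope)
  psp_expr <- psp_res$expr

  compile_event <- function(text, label) {
    stmts <- parse_statements(text, scope)
    for (i in seq_along(stmts)) {
      st <- stmts[[i]]
      if (!(st$name %in% c(vnames, "w", "g_target"))) {
        stop(label, " may modify only synaptic variables, 'w' and 'g_target'; ",
             "got: ", st$name, call. = FALSE)
      }
      stmts[[i]]$res <- validate_resolved(st$res, scope)
    }
    stmts
  }
  pre_stmts <- if (!is.null(pre_spike)) compile_event(pre_spike, "pre_spike")
               else list(list(name = "g_target", op = "+=",
                              res = validate_resolved(resolve_generic(quote(w)),
                                                      scope)))
  post_stmts <- if (!is.null(post_spike)) compile_event(post_spike, "post_spike")
                else list()

  parse_rule <- function(text, kind) {
    if (is.null(text)) return(NULL)
    cond <- parse_condition(text)
    cond$res <- validate_resolved(resolve_generic(cond$expr), scope)
    shared <- vnames[vapply(vars, function(v) v$locality == "shared", logical(1))]
    shared_p <- pnames[vapply(params, function(p) p$locality == "shared", logical(1))]
    if (kind == "creating") {
      used <- all.vars(cond$res$expr)
      bad <- intersect(used, c(setdiff(vnames, shared), "w",
                               setdiff(pnames, shared_p)))
      if (length(bad) > 0L) {
        stop("a creating rule cannot reference per-synapse attributes: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
    cond$proba <- dsl_flag_number(cond$flags, "proba", 1)
    cond$w <- dsl_flag_number(cond$flags, "w", NULL)
    cond$d <- dsl_flag_number(cond$flags, "d", NULL)
    cond
  }

  structure(list(
    parameters = params, variables = vars,
    psp = psp_expr, psp_res = psp_res, psp_given = psp_given,
    operator = operator,
    pre_spike = pre_stmts, post_spike = post_stmts,
    creating = parse_rule(creating, "creating"),
    pruning = parse_rule(pruning, "pruning"),
    name = name %||% "custom synapse"
  ), class = "rs_synapse_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rs_neuron_model <- function(x, ...) {
  cat(if (x$spiking) "Spiking" else "Rate-coded", "neuron model:", x$name, "\n")
  cat("  parameters:", paste(vapply(x$parameters, `[[`, character(1), "name"),
                             collapse = ", "), "\n")
  cat("  variables: ", paste(vapply(x$variables, `[[`, character(1), "name"),
                             collapse = ", "), "\n")
  if (x$spiking) cat("  spike:", dsl_deparse(x$spike$expr), "\n")
  invisible(x)
}

#' @export
print.rs_synapse_model <- function(x, ...) {
  cat("Synapse model:", x$name, "\n")
  cat("  parameters:", paste(vapply(x$parameters, `[[`, character(1), "name"),
                             collapse = ", "), "\n")
  cat("  variables: ", paste(vapply(x$variables, `[[`, character(1), "name"),
                             collapse = ", "), "\n")
  cat("  psp:", dsl_deparse(x$psp), "(", x$operator, ")\n")
  invisible(x)
}

#' Serialize a model back to its textual blocks
#'
#' Produces a list of text blocks which, fed back to [neuron_model()] /
#' [synapse_model()], parse to a structurally identical model.
#'
#' @param model An `rs_neuron_model` or `rs_synapse_model`.
#' @return Named list of character blocks.
#' @export
model_to_text <- function(model) {
  if (inherits(model, "rs_neuron_model")) {
    out <- list(parameters = serialize_parameters(model$parameters),
                equations = serialize_variables(model$variables, "population"))
    if (model$spiking) {
      out$spike <- dsl_deparse(model$spike$expr)
      if (length(model$reset) > 0L) {
        out$reset <- paste(vapply(model$reset, function(st)
          paste0(st$name, " ", st$op, " ", dsl_deparse(dsl_unresolve(st$res$expr, st$res))), character(1)),
          collapse = "\n")
      }
      out$refractory <- model$refractory
    }
    return(out)
  }
  if (inherits(model, "rs_synapse_model")) {
    out <- list(parameters = serialize_parameters(model$parameters),
                equations = serialize_variables(model$variables, "postsynaptic"))
    if (model$psp_given) out$psp <- dsl_deparse(model$psp)
    out$operator <- model$operator
    out$pre_spike <- paste(vapply(model$pre_spike, function(st)
      paste0(st$name, " ", st$op, " ", dsl_deparse(dsl_unresolve(st$res$expr, st$res))), character(1)),
      collapse = "\n")
    if (length(model$post_spike) > 0L) {
      out$post_spike <- paste(vapply(model$post_spike, function(st)
        paste0(st$name, " ", st$op, " ", dsl_deparse(dsl_unresolve(st$res$expr, st$res))), character(1)),
        collapse = "\n")
    }
    return(out)
  }
  stop("not a model object", call. = FALSE)
}
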