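# Numerical methods: transform a block of first-order ODEs (already in
# canonical gradient form dX/dt = f(...)) into a per-step update plan, or into
# an exact event-driven closed form for linear ODEs with constant
# coefficients.
#
# An update plan advances all variables of its block *simultaneously*: every
# gradient is evaluated on the pre-update values before any variable is
# written.  Plans are evaluated against a bindings list (variable values,
# parameters, inputs, pre-drawn random values) layered over the shared DSL
# base environment.

rs_the <- new.env(parent = emptyenv())

rs_eval_base <- function() {
  if (is.null(rs_the$base_env)) rs_the$base_env <- dsl_base_env()
  rs_the$base_env
}

rs_eval <- function(expr, bindings) {
  eval(expr, bindings, rs_eval_base())
}

# Accept variable specs from parse_variables() (resolved or not).  For
# unresolved specs, resolve in a permissive generic scope so the stand-alone
# interface works on bare parsed ODEs.
ode_exprs <- function(odes) {
  stopifnot(length(odes) > 0L)
  lapply(odes, function(v) {
    if (is.null(v$kind) || v$kind != "ode") {
      stop("update-plan builders take ODE variable specs; '", v$name,
           "' is not an ODE", call. = FALSE)
    }
    if (!is.null(v$res)) return(v$res$expr)
    resolve_vocabulary(v$rhs, list(kind = "generic", strict = FALSE,
                                   names = character(0),
                                   extra = character(0)))$expr
  })
}

ode_names <- function(odes) vapply(odes, `[[`, character(1), "name")

new_update_plan <- function(method, names, step, describe) {
  structure(list(method = method, names = names, step = step,
                 describe = describe),
            class = "rs_update_plan")
}

#' @export
print.rs_update_plan <- function(x, ...) {
  cat("Update plan (", x$method, " method)\n", sep = "")
  for (line in x$describe) cat("  ", line, "\n", sep = "")
  invisible(x)
}

# Symbolic derivative wrapper: returns NULL when the expression contains
# constructs stats::D cannot differentiate (conditionals, clip, ...).
rs_deriv <- function(expr, name) {
  tryCatch(stats::D(expr, name), error = function(e) NULL)
}

expr_contains <- function(expr, names) {
  length(intersect(all.vars(expr), names)) > 0L
}

#' Build an explicit (forward) Euler update plan
#'
#' Gradients are evaluated at the current time; each variable is advanced by
#' `dt * f(current state)`, all variables simultaneously.
#'
#' @param odes A list of ODE variable specs as returned by
#'   [parse_variables()] (the `rhs` of each is the canonical gradient).
#' @return An `rs_update_plan`; its `step(bindings, dt)` function returns the
#'   named list of next values.
#' @examples
#' odes <- parse_variables("tau * dr/dt + r = .sum_exc")
#' plan <- build_explicit_euler(odes)
#' plan$step(list(r = 0, tau = 10, .sum_exc = 1), dt = 1)
#' @export
build_explicit_euler <- function(odes) {
  nms <- ode_names(odes)
  exprs <- ode_exprs(odes)
  step <- function(bindings, dt) {
    grads <- lapply(exprs, rs_eval, bindings = bindings)
    out <- vector("list", length(nms))
    names(out) <- nms
    for (i in seq_along(nms)) {
      out[[i]] <- bindings[[nms[i]]] + dt * grads[[i]]
    }
    out
  }
  new_update_plan("explicit", nms, step, vapply(seq_along(nms), function(i)
    paste0(nms[i], " += dt * (", dsl_deparse(exprs[[i]]), ")"), character(1)))
}

#' Build a midpoint (second-order Runge-Kutta) update plan
#'
#' Evaluates the gradient at the current time, estimates the state at
#' `t + dt/2` for all variables jointly, and advances each variable by
#' `dt * f(midpoint state)`.
#'
#' @inheritParams build_explicit_euler
#' @return An `rs_update_plan`.
#' @export
build_midpoint <- function(odes) {
  nms <- ode_names(odes)
  exprs <- ode_exprs(odes)
  step <- function(bindings, dt) {
    k <- lapply(exprs, rs_eval, bindings = bindings)
    mid <- bindings
    for (i in seq_along(nms)) {
      mid[[nms[i]]] <- bindings[[nms[i]]] + dt / 2 * k[[i]]
    }
    out <- vector("list", length(nms))
    names(out) <- nms
    for (i in seq_along(nms)) {
      out[[i]] <- bindings[[nms[i]]] + dt * rs_eval(exprs[[i]], mid)
    }
    out
  }
  new_update_plan("midpoint", nms, step, vapply(seq_along(nms), function(i)
    paste0(nms[i], " += dt * f_", nms[i], "(state + dt/2 * k)"), character(1)))
}

#' Build an implicit (backward) Euler update plan
#'
#' Gradients are evaluated at the next time step, which requires the system to
#' be linear in its ODE variables: `x' = x + dt * (A x' + c)` is solved as
#' `(I - dt A) x' = x + dt c`.  The (possibly state-dependent) coefficients
#' `A` and `c` are extracted at each step by evaluating the gradients at basis
#' points, so non-ODE quantities (conductances, inputs) enter at their current
#' values.
#'
#' @inheritParams build_explicit_euler
#' @return An `rs_update_plan`.
#' @export
build_implicit_euler <- function(odes) {
  nms <- ode_names(odes)
  exprs <- ode_exprs(odes)
  n <- length(nms)
  # build-time linearity check: d f_i / d x_j must not depend on any ODE var
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!expr_contains(exprs[[i]], nms[j])) next
      d <- rs_deriv(exprs[[i]], nms[j])
      if (is.null(d) || expr_contains(d, nms)) {
        stop("implicit Euler requires a system linear in its variables; '",
             nms[i], "' is non-linear in '", nms[j], "'", call. = FALSE)
      }
    }
  }
  step <- function(bindings, dt) {
    zero <- bindings
    for (nm in nms) zero[[nm]] <- 0
    cvec <- lapply(exprs, rs_eval, bindings = zero)
    acols <- vector("list", n)   # acols[[j]][[i]] = d f_i / d x_j (vectors)
    for (j in seq_len(n)) {
      bj <- zero
      bj[[nms[j]]] <- 1
      fj <- lapply(exprs, rs_eval, bindings = bj)
      acols[[j]] <- lapply(seq_len(n), function(i) fj[[i]] - cvec[[i]])
    }
    x <- lapply(nms, function(nm) bindings[[nm]])
    out <- vector("list", n)
    names(out) <- nms
    if (n == 1L) {
      out[[1]] <- (x[[1]] + dt * cvec[[1]]) / (1 - dt * acols[[1]][[1]])
    } else if (n == 2L) {
      m11 <- 1 - dt * acols[[1]][[1]]; m12 <- -dt * acols[[2]][[1]]
      m21 <- -dt * acols[[1]][[2]];    m22 <- 1 - dt * acols[[2]][[2]]
      r1 <- x[[1]] + dt * cvec[[1]]
      r2 <- x[[2]] + dt * cvec[[2]]
      det <- m11 * m22 - m12 * m21
      out[[1]] <- (r1 * m22 - m12 * r2) / det
      out[[2]] <- (m11 * r2 - r1 * m21) / det
    } else {
      len <- max(vapply(x, length, integer(1)))
      sol <- matrix(0, len, n)
      xs <- lapply(x, rep_len, length.out = len)
      cs <- lapply(cvec, rep_len, length.out = len)
      am <- lapply(seq_len(n), function(i)
        lapply(seq_len(n), function(j) rep_len(acols[[j]][[i]], len)))
      for (u in seq_len(len)) {
        M <- diag(n) - dt * vapply(seq_len(n), function(j)
          vapply(seq_len(n), function(i) am[[i]][[j]][u], numeric(1)),
          numeric(n))
        rhs <- vapply(seq_len(n), function(i) xs[[i]][u] + dt * cs[[i]][u],
                      numeric(1))
        sol[u, ] <- solve(M, rhs)
      }
      for (i in seq_len(n)) out[[i]] <- sol[, i]
    }
    out
  }
  new_update_plan("implicit", nms, step, vapply(seq_along(nms), function(i)
    paste0(nms[i], "' solves (I - dt A) x' = x + dt c, f_", nms[i], " = ",
           dsl_deparse(exprs[[i]])), character(1)))
}

#' Build an exponential Euler update plan
#'
#' Each equation is canonized to `tau_eq * dx/dt + x = A_eq` with `tau_eq` and
#' `A_eq` free of `x` (they may depend on other quantities, evaluated at their
#' pre-update values).  The update is then
#' `x(t+dt) = x + (1 - exp(-dt/tau_eq)) * (A_eq - x)`, which is exact for
#' uncoupled linear equations with coefficients held constant over the step.
#'
#' @inheritParams build_explicit_euler
#' @return An `rs_update_plan`.  The canonical forms are exposed in
#'   `$forms` as per-variable `tau_eq` / `A_eq` expressions.
#' @export
build_exponential_euler <- function(odes) {
  nms <- ode_names(odes)
  exprs <- ode_exprs(odes)
  forms <- vector("list", length(nms))
  names(forms) <- nms
  for (i in seq_along(nms)) {
    f <- exprs[[i]]
    if (expr_contains(f, nms[i])) {
      a <- rs_deriv(f, nms[i])
      if (is.null(a) || expr_contains(a, nms[i])) {
        stop("cannot canonize equation for '", nms[i],
             "' to tau_eq * dx/dt + x = A_eq (non-linear in ", nms[i], ")",
             call. = FALSE)
      }
    } else {
      a <- 0
    }
    b <- dsl_substitute(f, stats::setNames(list(0), nms[i]))
    forms[[i]] <- list(a = a, b = b,
                       tau_eq = bquote(-1 / (.(a))),
                       A_eq = bquote(-(.(b)) / (.(a))))
  }
  step <- function(bindings, dt) {
    avals <- lapply(forms, function(fo) rs_eval(fo$a, bindings))
    bvals <- lapply(forms, function(fo) rs_eval(fo$b, bindings))
    out <- vector("list", length(nms))
    names(out) <- nms
    for (i in seq_along(nms)) {
      x <- bindings[[nms[i]]]
      a <- avals[[i]]; b <- bvals[[i]]
      n <- max(length(x), length(a), length(b))
      x <- rep_len(x, n); a <- rep_len(a, n); b <- rep_len(b, n)
      new <- x + dt * b                      # a == 0: pure drift limit
      nz <- a != 0
      if (any(nz)) {
        A <- -b[nz] / a[nz]
        new[nz] <- x[nz] + (1 - exp(a[nz] * dt)) * (A - x[nz])
      }
      out[[i]] <- new
    }
    out
  }
  plan <- new_update_plan("exponential", nms, step,
    vapply(seq_along(nms), function(i)
      paste0(nms[i], " += (1 - exp(-dt/tau_eq)) * (A_eq - ", nms[i],
             "), tau_eq = ", dsl_deparse(forms[[i]]$tau_eq)), character(1)))
  plan$forms <- forms
  plan
}

#' Build an exact event-driven solution for linear synaptic ODEs
#'
#' Only legal for ODEs of the form `dx/dt = a x + b` where `a` and `b` are
#' constants over time (they may reference parameters but no state variable,
#' no input and no random term).  The closed-form map over an elapsed interval
#' `e` is `x -> (x + b/a) exp(a e) - b/a` (or `x + b e` when `a = 0`), applied
#' only when a pre- or post-synaptic spike reaches the synapse.
#'
#' @inheritParams build_explicit_euler
#' @param state_names Names that count as state (variables of the enclosing
#'   model); defaults to the names of `odes`.
#' @return An `rs_event_solution` with an `advance(bindings, elapsed)`
#'   function.
#' @export
build_event_solution <- function(odes, state_names = NULL) {
  nms <- ode_names(odes)
  exprs <- ode_exprs(odes)
  state_names <- state_names %||% nms
  forms <- vector("list", length(nms))
  names(forms) <- nms
  for (i in seq_along(nms)) {
    f <- exprs[[i]]
    a <- if (expr_contains(f, nms[i])) rs_deriv(f, nms[i]) else 0
    b <- dsl_substitute(f, stats::setNames(list(0), nms[i]))
    bad_syms <- c(setdiff(state_names, character(0)), "t")
    bad <- is.null(a) ||
      expr_contains(a, c(bad_syms, nms[i])) ||
      expr_contains(b, bad_syms) ||
      any(startsWith(all.vars(f), ".rand_")) ||
      any(startsWith(all.vars(f), ".sum_"))
    if (bad) {
      stop("event-driven integration requires '", nms[i],
           "' to follow a linear ODE with constant coefficients",
           call. = FALSE)
    }
    forms[[i]] <- list(a = a, b = b)
  }
  advance <- function(bindings, elapsed) {
    if (any(elapsed < 0)) stop("negative elapsed time", call. = FALSE)
    out <- vector("list", length(nms))
    names(out) <- nms
    for (i in seq_along(nms)) {
      x <- bindings[[nms[i]]]
      a <- rs_eval(forms[[i]]$a, bindings)
      b <- rs_eval(forms[[i]]$b, bindings)
      n <- max(length(x), length(a), length(b), length(elapsed))
      x <- rep_len(x, n); a <- rep_len(a, n); b <- rep_len(b, n)
      e <- rep_len(elapsed, n)
      new <- x + b * e
      nz <- a != 0
      if (any(nz)) {
        xs <- -b[nz] / a[nz]   # steady state
        new[nz] <- xs + (x[nz] - xs) * exp(a[nz] * e[nz])
      }
      out[[i]] <- new
    }
    out
  }
  structure(list(names = nms, forms = forms, advance = advance),
            class = "rs_event_solution")
}

#' Advance event-driven state by elapsed time
#'
#' Applies the closed-form solution for the interval `now - last_event_time`
#' and reports the new state together with the updated event time.
#'
#' @param state Named list of current values (vectors allowed; parameters
#'   referenced by the closed form must be included).
#' @param last_event_time Time (ms) of the previous event.
#' @param now Current time (ms); must be `>= last_event_time`.
#' @param solution An `rs_event_solution` from [build_event_solution()].
#' @return List with `state` (updated values) and `last_event_time = now`.
#' @export
advance_event <- function(state, last_event_time, now, solution) {
  elapsed <- now - last_event_time
  if (any(elapsed < 0)) stop("negative elapsed time", call. = FALSE)
  new <- solution$advance(state, elapsed)
  state[names(new)] <- new
  list(state = state, last_event_time = now)
}

# Dispatch a method name to its plan builder.
plan_builder <- function(method) {
  switch(method,
         explicit = build_explicit_euler,
         implicit = build_implicit_euler,
         exponential = build_exponential_euler,
         midpoint = build_midpoint,
         stop("unknown numerical method: ", method, call. = FALSE))
}
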