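# Parsing of parameter and equation blocks into validated specifications.

#' Parse a parameter block
#'
#' A parameter block is a (multi-line) string where each statement has the
#' form `name = value [: flags]`.  Statements are separated by newlines or
#' semicolons and `#` starts a comment.  Recognized flags are `population`
#' and `postsynaptic` (the parameter is shared: one value per population or
#' per post-synaptic neuron instead of one per unit/synapse), and `int` /
#' `bool` (storage type; the default is a double).
#'
#' @param text Parameter block as a character string (or vector of lines).
#' @return A list of parameter specifications, each a list with fields
#'   `name`, `locality` (`"per-unit"` or `"shared"`), `dtype` (`"real"`,
#'   `"integer"` or `"boolean"`) and `default`.
#' @examples
#' parse_parameters("tau = 10.0 : population\nB = 0.0")
#' @export
parse_parameters <- function(text) {
  stmts <- dsl_split_statements(text)
  out <- list()
  for (stmt in stmts) {
    parts <- dsl_strip_flags_strict(stmt)
    asg <- dsl_split_assign(parts$body)
    if (is.null(asg) || asg$op != "=") {
      stop("parameter statement must be 'name = value': ", stmt, call. = FALSE)
    }
    name <- asg$lhs
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
      stop("invalid parameter name: ", name, call. = FALSE)
    }
    if (name %in% c("t", "dt")) {
      stop("'", name, "' is a reserved name", call. = FALSE)
    }
    if (name %in% vapply(out, `[[`, character(1), "name")) {
      stop("duplicate parameter name: ", name, call. = FALSE)
    }
    flags <- parts$flags
    unknown <- setdiff(names(flags), c("population", "postsynaptic", "int", "bool"))
    if (length(unknown) > 0L) {
      stop("unknown parameter flag(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    dtype <- if (isTRUE(flags$int)) "integer" else if (isTRUE(flags$bool)) "boolean" else "real"
    locality <- if (isTRUE(flags$population) || isTRUE(flags$postsynaptic)) "shared" else "per-unit"
    value <- tryCatch(
      eval(dsl_str2lang(asg$rhs), list(pi = pi), baseenv()),
      error = function(e) NULL)
    if (dtype == "boolean") {
      if (!is.logical(value) && !(is.numeric(value) && value %in% c(0, 1))) {
        stop("unparseable boolean value for parameter ", name, ": ", asg$rhs,
             call. = FALSE)
      }
      value <- as.logical(value)
    } else {
      if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
        stop("unparseable value for parameter ", name, ": ", asg$rhs,
             call. = FALSE)
      }
      if (dtype == "integer") value <- as.integer(round(value))
    }
    out[[length(out) + 1L]] <- structure(
      list(name = name, locality = locality, dtype = dtype, default = value),
      class = "rs_parameter_spec")
  }
  out
}

#' Normalize a first-order ODE to gradient form
#'
#' Takes an equation containing exactly one derivative token `dX/dt` — the
#' left-hand side may be an affine combination such as
#' `tau*dv/dt + v = E` — and solves it algebraically for the derivative,
#' returning the right-hand side of the canonical form `dX/dt = f(...)`.
#' The equation must be linear in the derivative.
#'
#' @param text The equation as a string.
#' @return A list with `name` (the differentiated variable) and `gradient`
#'   (an R language object for `f`).
#' @examples
#' normalize_ode("tau*dv/dt + v = E")
#' @export
normalize_ode <- function(text) {
  s <- dsl_replace_derivs(text)
  grads <- unique(unlist(regmatches(
    s, gregexpr("\\.grad_[A-Za-z_][A-Za-z0-9_]*", s))))
  if (length(grads) == 0L) stop("no derivative term in: ", text, call. = FALSE)
  if (length(grads) > 1L) {
    stop("multiple distinct derivatives in one equation: ", text, call. = FALSE)
  }
  var <- sub("^\\.grad_", "", grads)
  asg <- dsl_split_assign(s)
  if (is.null(asg)) stop("ODE must contain '=': ", text, call. = FALSE)
  if (asg$op != "=") {
    stop("ODE cannot use the augmented operator '", asg$op, "': ", text,
         call. = FALSE)
  }
  rhs <- dsl_str2lang(asg$rhs)
  if (trimws(asg$lhs) == grads) {
    # already canonical: dX/dt = f(...)
    return(list(name = var, gradient = rhs))
  }
  lhs <- dsl_str2lang(asg$lhs)
  # Special vocabulary (random draws, input sums, global ops) is extracted to
  # shared temporary symbols first, so that algebraic manipulation never
  # duplicates a random draw into independent ones.
  res <- resolve_generic(call("-", lhs, call("(", rhs)))
  list(name = var, gradient = normalize_gradient(res$expr, grads, text))
}

# Solve F(grad) = 0, F linear in `gradsym`, for grad: F = a*grad + b.
normalize_gradient <- function(fexpr, gradsym, label) {
  var <- sub("^\\.grad_", "", gradsym)
  if (!dsl_linear_in(fexpr, gradsym)) {
    stop("equation is not solvable for ", var, "'s derivative (appears ",
         "non-linearly): ", label, call. = FALSE)
  }
  b <- dsl_substitute(fexpr, stats::setNames(list(0), gradsym))
  a <- rs_deriv(fexpr, gradsym)
  if (is.null(a)) {
    # non-differentiable constructs around the derivative's coefficient:
    # fall back to the finite difference F(1) - F(0), exact under linearity
    f1 <- dsl_substitute(fexpr, stats::setNames(list(1), gradsym))
    a <- call("-", call("(", f1), call("(", b))
  }
  a_val <- tryCatch(eval(a, list(pi = pi), baseenv()), error = function(e) NULL)
  b_val <- tryCatch(eval(b, list(pi = pi), baseenv()), error = function(e) NULL)
  if (!is.null(a_val) && is.numeric(a_val)) a <- a_val
  if (!is.null(b_val) && is.numeric(b_val)) b <- b_val
  if (identical(a, 0)) {
    stop("equation does not contain ", var, "'s derivative: ", label,
         call. = FALSE)
  }
  if (identical(b, 0)) return(0)
  if (identical(a, 1)) return(call("-", call("(", b)))
  bquote(-(.(b)) / (.(a)))
}

# TRUE if `expr` is linear in the symbol `sym` (appears through +,-,*,/,()
# chains only, never in a denominator, never inside another function, and
# never multiplied by itself).
dsl_linear_in <- function(expr, sym) {
  contains <- function(e) {
    if (is.symbol(e)) return(identical(as.character(e), sym))
    if (is.call(e)) return(any(vapply(as.list(e)[-1L], contains, logical(1))))
    FALSE
  }
  linear <- function(e) {
    if (is.symbol(e)) return(TRUE)
    if (is.atomic(e)) return(TRUE)
    if (!is.call(e)) return(FALSE)
    op <- as.character(e[[1]])
    args <- as.list(e)[-1L]
    if (op == "(") return(linear(args[[1]]))
    if (op %in% c("+", "-")) return(all(vapply(args, linear, logical(1))))
    if (op == "*" && length(args) == 2L) {
      inl <- contains(args[[1]]); inr <- contains(args[[2]])
      if (inl && inr) return(FALSE)
      if (inl) return(linear(args[[1]]))
      if (inr) return(linear(args[[2]]))
      return(TRUE)
    }
    if (op == "/" && length(args) == 2L) {
      if (contains(args[[2]])) return(FALSE)
      return(linear(args[[1]]))
    }
    # any other call (function, power, comparison) must not contain sym
    return(!contains(e))
  }
  linear(expr)
}

#' Parse an equation block into variable specifications
#'
#' Each statement either is a regular assignment `lhs = rhs` (augmented
#' operators `+=`, `-=`, `*=`, `/=` allowed) or contains a derivative token
#' `dX/dt`, making it a first-order ODE (plain `=` only).  Declaration order
#' is preserved.  Recognized flags: `init = v` (initial value, default 0),
#' `min = v` / `max = v` (clamping bounds), `population` / `postsynaptic`
#' (shared locality), a numerical method (`explicit`, `implicit`,
#' `exponential`, `midpoint`, `event-driven`), and `int` / `bool`.
#'
#' @param text Equation block (string or vector of lines).
#' @param scope `"neuron"` or `"synapse"`; controls which vocabulary is legal
#'   when the enclosing model is built.
#' @return A list of variable specifications with fields `name`, `kind`
#'   (`"assignment"` or `"ode"`), `op` (assignment operator), `rhs` (language
#'   object; for ODEs, the normalized gradient), `init`, `min`, `max`,
#'   `locality`, `method` and `dtype`.
#' @export
parse_variables <- function(text, scope = c("neuron", "synapse")) {
  scope <- match.arg(scope)
  stmts <- dsl_split_statements(text)
  out <- list()
  for (stmt in stmts) {
    parts <- dsl_strip_flags(stmt)
    flags <- parts$flags
    body <- dsl_replace_derivs(parts$body)
    is_ode <- grepl(".grad_", body, fixed = TRUE)
    if (is_ode) {
      grads <- unique(unlist(regmatches(
        body, gregexpr("\\.grad_[A-Za-z_][A-Za-z0-9_]*", body))))
      if (length(grads) > 1L) {
        stop("multiple distinct derivatives in one equation: ", stmt,
             call. = FALSE)
      }
      name <- sub("^\\.grad_", "", grads)
      asg <- dsl_split_assign(body)
      if (is.null(asg)) stop("ODE must contain '=': ", stmt, call. = FALSE)
      if (asg$op != "=") {
        stop("ODE cannot use augmented operator: ", stmt, call. = FALSE)
      }
      rhs_lang <- dsl_str2lang(asg$rhs)
      if (trimws(asg$lhs) == grads) {
        res <- resolve_generic(rhs_lang)
      } else {
        lhs_lang <- dsl_str2lang(asg$lhs)
        res <- resolve_generic(call("-", lhs_lang, call("(", rhs_lang)))
        res$expr <- normalize_gradient(res$expr, grads, stmt)
      }
      op <- "="
      rhs <- res$expr
      kind <- "ode"
    } else {
      asg <- dsl_split_assign(parts$body)
      if (is.null(asg)) {
        stop("variable statement must be an assignment: ", stmt, call. = FALSE)
      }
      name <- asg$lhs
      if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
        stop("invalid variable name: ", name, call. = FALSE)
      }
      op <- asg$op
      res <- resolve_generic(dsl_str2lang(asg$rhs))
      rhs <- res$expr
      kind <- "assignment"
    }
    if (name %in% c("t", "dt")) {
      stop("'", name, "' is a reserved name", call. = FALSE)
    }
    if (name %in% vapply(out, `[[`, character(1), "name")) {
      stop("duplicate variable name: ", name, call. = FALSE)
    }
    methods <- intersect(names(flags), dsl_method_flags)
    if (length(methods) > 1L) {
      stop("conflicting method flags for ", name, call. = FALSE)
    }
    method <- if (length(methods) == 1L) methods else "inherit"
    if (method == "event-driven" && (scope != "synapse" || kind != "ode")) {
      stop("event-driven integration is only available for synaptic ODEs: ",
           name, call. = FALSE)
    }
    vmin <- dsl_flag_number(flags, "min")
    vmax <- dsl_flag_number(flags, "max")
    if (!is.null(vmin) && !is.null(vmax) && vmin > vmax) {
      stop("min bound exceeds max bound for ", name, call. = FALSE)
    }
    known <- c("init", "min", "max", "population", "postsynaptic",
               "int", "bool", dsl_method_flags)
    unknown <- setdiff(names(flags), known)
    if (length(unknown) > 0L) {
      stop("unknown variable flag(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[[length(out) + 1L]] <- structure(list(
      name = name, kind = kind, op = op, rhs = rhs, res = res,
      init = dsl_flag_number(flags, "init", 0),
      min = vmin, max = vmax,
      locality = if (isTRUE(flags$population) || isTRUE(flags$postsynaptic))
        "shared" else "per-unit",
      method = method,
      dtype = if (isTRUE(flags$int)) "integer" else if (isTRUE(flags$bool))
        "boolean" else "real"
    ), class = "rs_variable_spec")
  }
  out
}

#' Parse a boolean condition
#'
#' Used for spike conditions, stop conditions and structural-plasticity rules.
#' Relational operators (`<`, `>`, `<=`, `>=`, `==`, `!=`) and the logical
#' connectives `and`, `or`, `not` are available.  A trailing `: all` flag (for
#' stop conditions) is returned as the quantifier; extra flags such as
#' `proba = p`, `w = v`, `d = v` (structural rules) are returned verbatim.
#'
#' @param text The condition as a string.
#' @return List with `expr` (language object), `quantifier` (`"any"` or
#'   `"all"`) and `flags` (remaining flags).
#' @export
parse_condition <- function(text) {
  parts <- dsl_strip_flags(text)
  flags <- parts$flags
  quantifier <- if (isTRUE(flags$all)) "all" else "any"
  flags$all <- NULL
  expr <- dsl_str2lang(parts$body)
  if (!dsl_is_boolean(expr)) {
    stop("condition is not a boolean expression: ", text, call. = FALSE)
  }
  list(expr = expr, quantifier = quantifier, flags = flags)
}

# Shallow type check: the top node must yield a boolean.
dsl_is_boolean <- function(e) {
  if (is.logical(e)) return(TRUE)
  if (is.call(e)) {
    op <- if (is.symbol(e[[1]])) as.character(e[[1]]) else ""
    if (op %in% c("<", ">", "<=", ">=", "==", "!=", "&", "|", "!")) return(TRUE)
    if (op == "(") return(dsl_is_boolean(e[[2]]))
    if (op == ".ite") return(dsl_is_boolean(e[[3]]) && dsl_is_boolean(e[[4]]))
  }
  FALSE
}

# ---- serialization (round-trip support) -------------------------------------

serialize_parameters <- function(params) {
  lines <- vapply(params, function(p) {
    flags <- character(0)
    if (p$locality == "shared") flags <- c(flags, "population")
    if (p$dtype == "integer") flags <- c(flags, "int")
    if (p$dtype == "boolean") flags <- c(flags, "bool")
    val <- if (p$dtype == "boolean") tolower(as.character(p$default))
           else format(p$default)
    paste0(p$name, " = ", val,
           if (length(flags)) paste0(" : ", paste(flags, collapse = ", ")) else "")
  }, character(1))
  paste(lines, collapse = "\n")
}

serialize_variables <- function(vars, shared_flag = "population") {
  lines <- vapply(vars, function(v) {
    rhs_text <- dsl_deparse(dsl_unresolve(v$rhs, v$res))
    body <- if (v$kind == "ode") {
      paste0("d", v$name, "/dt = ", rhs_text)
    } else {
      paste0(v$name, " ", v$op, " ", rhs_text)
    }
    flags <- character(0)
    if (!identical(v$init, 0)) flags <- c(flags, paste0("init = ", format(v$init)))
    if (!is.null(v$min)) flags <- c(flags, paste0("min = ", format(v$min)))
    if (!is.null(v$max)) flags <- c(flags, paste0("max = ", format(v$max)))
    if (v$locality == "shared") flags <- c(flags, shared_flag)
    if (v$method != "inherit") flags <- c(flags, v$method)
    if (v$dtype == "integer") flags <- c(flags, "int")
    if (v$dtype == "boolean") flags <- c(flags, "bool")
    paste0(body,
           if (length(flags)) paste0(" : ", paste(flags, collapse = ", ")) else "")
  }, character(1))
  paste(lines, collapse = "\n")
}
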