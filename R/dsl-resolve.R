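# Vocabulary resolution: bind the special DSL vocabulary (input sums,
# conductances, random draws, global operations, pre./post. references) to
# typed reference nodes, and reject unknown identifiers and functions.

dsl_math_functions <- c(
  "cos", "sin", "tan", "acos", "asin", "atan", "atan2",
  "cosh", "sinh", "tanh", "exp", "log", "log2", "log10", "sqrt",
  "abs", "fabs", "floor", "ceil", "ceiling", "pow", "clip",
  "min", "max", "mean", ".ite"
)

dsl_random_dists <- c("Uniform", "Normal", "LogNormal", "Exponential", "Gamma")

# Base evaluation environment shared by all compiled expressions.  Vectorized
# semantics: min/max with several arguments are element-wise.
dsl_base_env <- function() {
  env <- new.env(parent = baseenv())
  env$.ite <- function(cond, yes, no) {
    n <- max(length(cond), length(yes), length(no))
    cond <- rep_len(as.logical(cond), n)
    out <- rep_len(no, n)
    if (any(cond)) out[cond] <- rep_len(yes, n)[cond]
    out
  }
  env$pow <- function(x, y) x^y
  env$clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  env$ceil <- ceiling
  env$fabs <- abs
  env$min <- function(...) if (...length() == 1L) base::min(...) else Reduce(pmin, list(...))
  env$max <- function(...) if (...length() == 1L) base::max(...) else Reduce(pmax, list(...))
  env$pi <- pi
  env
}

# Resolve the vocabulary of one expression tree.
#
# scope: list with
#   kind       "neuron" | "synapse" | "generic"
#   spiking    TRUE/FALSE (neuron scope: is the model a spiking one)
#   names      declared parameter/variable names visible as plain symbols
#   extra      additional legal plain symbols (e.g. "w", "g_target")
#   strict     reject unknown plain identifiers (default TRUE; the generic
#              scope used by the stand-alone numerics interface sets FALSE
#              and treats unknown symbols as externally bound parameters)
#
# Returns list(expr, randoms, sums, gops, pre_refs, post_refs, g_refs) where
# `expr` has random draws replaced by `.rand_<k>` symbols, input sums by
# `.sum_<target>` and global operations by `.gop_<k>`.
resolve_vocabulary <- function(expr, scope) {
  if (is.null(scope$strict)) scope$strict <- TRUE
  randoms <- list()
  gops <- list()
  sums <- character(0)
  pre_refs <- character(0)
  post_refs <- character(0)
  g_refs <- character(0)

  reserved <- c("t", "dt", "pi", "TRUE", "FALSE")

  walk <- function(e) {
    if (is.atomic(e)) return(e)
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (nm %in% c(scope$names, scope$extra, reserved)) return(e)
      if (startsWith(nm, ".rand_") || startsWith(nm, ".sum_") ||
          startsWith(nm, ".gop_") || startsWith(nm, ".grad_")) return(e)
      if (startsWith(nm, "pre.")) {
        if (scope$kind == "neuron") {
          stop("pre./post. references are only valid in synapse models: ", nm,
               call. = FALSE)
        }
        pre_refs <<- union(pre_refs, sub("^pre\\.", "", nm))
        return(e)
      }
      if (startsWith(nm, "post.")) {
        if (scope$kind == "neuron") {
          stop("pre./post. references are only valid in synapse models: ", nm,
               call. = FALSE)
        }
        post_refs <<- union(post_refs, sub("^post\\.", "", nm))
        return(e)
      }
      if (grepl("^g_[A-Za-z0-9_]+$", nm)) {
        if (scope$kind == "neuron" && !isTRUE(scope$spiking)) {
          stop("conductances (", nm, ") are only available in spiking neurons; ",
               "rate-coded neurons use sum(target)", call. = FALSE)
        }
        g_refs <<- union(g_refs, sub("^g_", "", nm))
        return(e)
      }
      if (!scope$strict) return(e)
      stop("unknown identifier '", nm, "' in model equations", call. = FALSE)
    }
    if (is.call(e)) {
      head <- e[[1]]
      op <- if (is.symbol(head)) as.character(head) else ""
      args <- as.list(e)[-1L]
      # input sum: sum(target)
      if (op == "sum" && length(args) == 1L && is.symbol(args[[1]])) {
        if (scope$kind == "neuron" && isTRUE(scope$spiking)) {
          stop("sum(target) is only available in rate-coded neurons; ",
               "spiking neurons use g_target", call. = FALSE)
        }
        target <- as.character(args[[1]])
        sums <<- union(sums, target)
        return(as.name(paste0(".sum_", target)))
      }
      # random draws
      if (op %in% dsl_random_dists) {
        k <- length(randoms) + 1L
        randoms[[k]] <<- list(dist = op, args = args)
        return(as.name(paste0(".rand_", k)))
      }
      # global operations: mean/min/max over a single attribute reference
      if (op %in% c("mean", "min", "max") && length(args) == 1L &&
          is.symbol(args[[1]])) {
        ref <- as.character(args[[1]])
        k <- length(gops) + 1L
        if (startsWith(ref, "pre.") || startsWith(ref, "post.")) {
          if (scope$kind == "neuron") {
            stop("global operations over pre./post. attributes are only valid ",
                 "in synapse models: ", op, "(", ref, ")", call. = FALSE)
          }
        } else if (!(ref %in% c(scope$names, scope$extra))) {
          stop("global operation over unknown attribute: ", op, "(", ref, ")",
               call. = FALSE)
        }
        gops[[k]] <<- list(op = op, ref = ref)
        return(as.name(paste0(".gop_", k)))
      }
      if (op %in% c("+", "-", "*", "/", "^", "<", ">", "<=", ">=", "==", "!=",
                    "&", "|", "!", "(")) {
        # arithmetic / relational / logical operators
      } else if (!(op %in% dsl_math_functions)) {
        stop("unknown function '", op, "' in model equations", call. = FALSE)
      }
      e <- as.call(c(list(head), lapply(args, walk)))
      return(e)
    }
    e
  }

  out <- walk(expr)
  list(expr = out, randoms = randoms, sums = sums, gops = gops,
       pre_refs = pre_refs, post_refs = post_refs, g_refs = g_refs)
}

# Permissive first-pass resolution used at parse time: extracts the special
# vocabulary into temporary symbols without knowing the enclosing model.
resolve_generic <- function(expr) {
  resolve_vocabulary(expr, list(kind = "generic", strict = FALSE,
                                names = character(0), extra = character(0)))
}

# Second pass at model-build time: validate a parse-time resolution record
# against the actual model scope.  Checks every plain identifier, applies the
# scope rules for input sums / conductances / pre./post. references, and
# fills in the reference records.
validate_resolved <- function(res, scope) {
  reserved <- c("t", "dt", "pi")
  sums <- character(0); g_refs <- character(0)
  pre_refs <- character(0); post_refs <- character(0)

  check_sym <- function(nm) {
    if (nm %in% c(scope$names, scope$extra, reserved)) return(invisible())
    if (startsWith(nm, ".rand_") || startsWith(nm, ".gop_") ||
        startsWith(nm, ".grad_")) return(invisible())
    if (startsWith(nm, ".sum_")) {
      if (scope$kind == "neuron" && isTRUE(scope$spiking)) {
        stop("sum(target) is only available in rate-coded neurons; ",
             "spiking neurons use g_target", call. = FALSE)
      }
      sums <<- union(sums, sub("^\\.sum_", "", nm))
      return(invisible())
    }
    if (startsWith(nm, "pre.") || startsWith(nm, "post.")) {
      if (scope$kind != "synapse") {
        stop("pre./post. references are only valid in synapse models: ", nm,
             call. = FALSE)
      }
      if (startsWith(nm, "pre.")) pre_refs <<- union(pre_refs, sub("^pre\\.", "", nm))
      else post_refs <<- union(post_refs, sub("^post\\.", "", nm))
      return(invisible())
    }
    if (grepl("^g_[A-Za-z0-9_]+$", nm)) {
      if (scope$kind == "neuron" && !isTRUE(scope$spiking)) {
        stop("conductances (", nm, ") are only available in spiking neurons; ",
             "rate-coded neurons use sum(target)", call. = FALSE)
      }
      g_refs <<- union(g_refs, sub("^g_", "", nm))
      return(invisible())
    }
    stop("unknown identifier '", nm, "' in model equations", call. = FALSE)
  }

  for (nm in all.vars(res$expr)) check_sym(nm)
  for (rnd in res$randoms) {
    for (arg in rnd$args) for (nm in all.vars(arg)) check_sym(nm)
  }
  for (gop in res$gops) {
    ref <- gop$ref
    if (startsWith(ref, "pre.") || startsWith(ref, "post.")) {
      if (scope$kind != "synapse") {
        stop("global operations over pre./post. attributes are only valid in ",
             "synapse models: ", gop$op, "(", ref, ")", call. = FALSE)
      }
      if (startsWith(ref, "pre.")) pre_refs <- union(pre_refs, sub("^pre\\.", "", ref))
      else post_refs <- union(post_refs, sub("^post\\.", "", ref))
    } else if (!(ref %in% c(scope$names, scope$extra))) {
      stop("global operation over unknown attribute: ", gop$op, "(", ref, ")",
           call. = FALSE)
    }
  }
  res$sums <- sums; res$g_refs <- g_refs
  res$pre_refs <- pre_refs; res$post_refs <- post_refs
  res
}

# Inverse of resolve_generic for serialization: put the original vocabulary
# calls back in place of the temporary symbols.
dsl_unresolve <- function(expr, res) {
  walk <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (startsWith(nm, ".sum_")) {
        return(call("sum", as.name(sub("^\\.sum_", "", nm))))
      }
      if (startsWith(nm, ".rand_")) {
        k <- as.integer(sub("^\\.rand_", "", nm))
        rnd <- res$randoms[[k]]
        return(as.call(c(list(as.name(rnd$dist)), lapply(rnd$args, walk))))
      }
      if (startsWith(nm, ".gop_")) {
        k <- as.integer(sub("^\\.gop_", "", nm))
        gop <- res$gops[[k]]
        return(call(gop$op, as.name(gop$ref)))
      }
      return(e)
    }
    if (is.call(e)) {
      return(as.call(c(list(e[[1]]), lapply(as.list(e)[-1L], walk))))
    }
    e
  }
  walk(expr)
}
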