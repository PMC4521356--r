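# Projections: the set of synapses between two populations for one target.
#
# Connectivity is stored per post-synaptic neuron (list-of-lists semantics) in
# flattened parallel vectors sorted by (post, pre): `syn$pre` / `syn$post`
# hold 0-based parent-population ranks, `syn$w` the weights, `syn$delay_ms`
# the transmission delays, and `syn$vars` the per-synapse model variables.
# Postsynaptic (shared) variables hold one value per post-synaptic neuron.

#' Create a projection
#'
#' The projection is empty until one of the `connect_*` methods builds its
#' synapses.
#'
#' @param net The network.
#' @param pre,post Pre-/post-synaptic population or view.
#' @param target Target name (e.g. `"exc"`, `"inh"`): post-synaptic neurons
#'   read this projection's input as `sum(target)` (rate-coded) or `g_target`
#'   (spiking).
#' @param model Optional [synapse_model()]; the default synapse is a plain
#'   weight (`psp = w * pre.r` for rate-coded, `g_target += w` for spiking).
#' @return An object of class `rs_projection`.
#' @export
projection <- function(net, pre, post, target, model = NULL) {
  stopifnot(inherits(net, "rs_network"))
  if (!is.null(model) && !inherits(model, "rs_synapse_model")) {
    stop("model must be an rs_synapse_model", call. = FALSE)
  }
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", target)) {
    stop("invalid target name: ", target, call. = FALSE)
  }
  proj <- new.env(parent = emptyenv())
  class(proj) <- "rs_projection"
  proj[["net"]] <- net
  proj[["pre"]] <- pre
  proj[["post"]] <- post
  proj[["target"]] <- target
  proj[["model"]] <- model %||% default_synapse()
  proj[["kind"]] <- NA_character_   # decided at network compile
  proj[["connected"]] <- FALSE
  proj[["syn"]] <- list(pre = integer(0), post = integer(0),
                        w = numeric(0), delay_ms = numeric(0),
                        vars = list(), last_event = numeric(0))
  proj[["post_shared"]] <- list()
  proj[["id"]] <- length(net[["projections"]]) + 1L
  net[["projections"]][[length(net[["projections"]]) + 1L]] <- proj
  net[["compiled"]] <- FALSE
  proj
}

default_synapse <- function() {
  if (is.null(rs_the$default_synapse)) {
    rs_the$default_synapse <- synapse_model(name = "default synapse")
  }
  rs_the$default_synapse
}

#' Number of synapses in a projection
#' @param proj A projection.
#' @return Integer count.
#' @export
synapse_count <- function(proj) length(proj[["syn"]]$pre)

# Install enumerated synapses (parent ranks, 0-based), sorting by (post, pre)
# and initializing per-synapse variables.
install_synapses <- function(proj, pre, post, w, delay_ms, sorted = FALSE) {
  n <- length(pre)
  stopifnot(length(post) == n)
  w <- rep_len(w, n)
  delay_ms <- rep_len(delay_ms, n)
  if (!sorted && n > 0L) {
    o <- order(post, pre)
    pre <- pre[o]; post <- post[o]; w <- w[o]; delay_ms <- delay_ms[o]
  }
  if (n > 1L) {
    npre_tot <- pop_ranks(proj[["pre"]])$pop[["size"]]
    if (anyDuplicated(as.numeric(post) * npre_tot + pre)) {
      stop("duplicate (pre, post) pair in projection", call. = FALSE)
    }
  }
  model <- proj[["model"]]
  vars <- list()
  for (v in model$variables) {
    if (v$name == "w" || v$locality == "shared") next
    vars[[v$name]] <- rep(v$init, n)
  }
  for (p in model$parameters) {
    if (p$locality == "shared") next
    vars[[p$name]] <- rep(p$default, n)
  }
  post_shared <- list()
  npost <- pop_ranks(proj[["post"]])$pop[["size"]]
  for (v in model$variables) {
    if (v$name != "w" && v$locality == "shared") {
      post_shared[[v$name]] <- rep(v$init, npost)
    }
  }
  for (p in model$parameters) {
    if (p$locality == "shared") post_shared[[p$name]] <- p$default
  }
  proj[["syn"]] <- list(pre = as.integer(pre), post = as.integer(post),
                        w = as.numeric(w), delay_ms = as.numeric(delay_ms),
                        vars = vars, last_event = numeric(n))
  proj[["post_shared"]] <- post_shared
  proj[["connected"]] <- TRUE
  proj[["net"]][["compiled"]] <- FALSE
  invisible(proj)
}

resolve_delay_default <- function(proj, delays) {
  # NA means "minimal delay" (one step); resolved against dt at compile time
  if (is.null(delays)) NA_real_ else delays
}

#' Fully connect two populations
#'
#' Every (pre, post) pair receives one synapse.  When pre and post are the
#' same population, self-connections are excluded unless
#' `allow_self_connections = TRUE`.
#'
#' @param proj A projection.
#' @param weights Scalar, vector or [Uniform()] style specification.
#' @param delays Transmission delay(s) in ms (default: one simulation step).
#' @param allow_self_connections Keep synapses with `pre == post` when both
#'   sides are the same population.
#' @return The projection, invisibly.
#' @export
connect_all_to_all <- function(proj, weights, delays = NULL,
                               allow_self_connections = FALSE) {
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  same_pop <- identical(prr$pop, por$pop)
  npre <- length(prr$ranks); npost <- length(por$ranks)
  pre <- rep(prr$ranks, times = npost)
  post <- rep(por$ranks, each = npre)
  if (same_pop && !allow_self_connections) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  n <- length(pre)
  with_net_rng(proj[["net"]], {
    w <- draw_value(weights, n)
    d <- draw_value(resolve_delay_default(proj, delays), n)
  })
  install_synapses(proj, pre, post, w, d, sorted = TRUE)
}

#' Connect with fixed probability
#'
#' Each ordered (pre, post) pair is included independently with probability
#' `p`; self-connections within one population are excluded unless requested.
#'
#' @inheritParams connect_all_to_all
#' @param p Connection probability in `[0, 1]`.
#' @return The projection, invisibly.
#' @export
connect_fixed_probability <- function(proj, p, weights, delays = NULL,
                                      allow_self_connections = FALSE) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  same_pop <- identical(prr$pop, por$pop)
  pre_list <- vector("list", length(por$ranks))
  with_net_rng(proj[["net"]], {
    for (i in seq_along(por$ranks)) {
      keep <- stats::runif(length(prr$ranks)) < p
      cand <- prr$ranks[keep]
      if (same_pop && !allow_self_connections) {
        cand <- cand[cand != por$ranks[i]]
      }
      pre_list[[i]] <- cand
    }
    counts <- lengths(pre_list)
    pre <- unlist(pre_list, use.names = FALSE) %||% integer(0)
    post <- rep(por$ranks, counts)
    n <- length(pre)
    w <- draw_value(weights, n)
    d <- draw_value(resolve_delay_default(proj, delays), n)
  })
  install_synapses(proj, pre, post, w, d, sorted = TRUE)
}

#' Connect matching ranks one-to-one
#'
#' @inheritParams connect_all_to_all
#' @return The projection, invisibly.
#' @export
connect_one_to_one <- function(proj, weights, delays = NULL) {
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  if (length(prr$ranks) != length(por$ranks)) {
    stop("one-to-one requires equal sizes", call. = FALSE)
  }
  n <- length(prr$ranks)
  with_net_rng(proj[["net"]], {
    w <- draw_value(weights, n)
    d <- draw_value(resolve_delay_default(proj, delays), n)
  })
  install_synapses(proj, prr$ranks, por$ranks, w, d)
}

#' Connect from a user pattern function
#'
#' @inheritParams connect_all_to_all
#' @param fun Function called as `fun(pre_ranks, post_ranks)` (0-based ranks
#'   of the available units) returning a data frame with columns `pre`,
#'   `post`, `w` and optionally `d` (delay in ms).
#' @return The projection, invisibly.
#' @export
connect_from_function <- function(proj, fun) {
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  df <- with_net_rng(proj[["net"]], fun(prr$ranks, por$ranks))
  if (nrow(df) == 0L) {
    return(install_synapses(proj, integer(0), integer(0), numeric(0),
                            numeric(0)))
  }
  if (!all(df$pre %in% prr$ranks) || !all(df$post %in% por$ranks)) {
    stop("rank out of range in pattern function output", call. = FALSE)
  }
  d <- if ("d" %in% names(df)) df$d else NA_real_
  install_synapses(proj, df$pre, df$post, df$w, d)
}

#' Connect from a dense weight matrix
#'
#' @inheritParams connect_all_to_all
#' @param w Matrix of weights with one row per post-synaptic neuron and one
#'   column per pre-synaptic neuron; `NA` entries create no synapse.
#' @return The projection, invisibly.
#' @export
connect_from_matrix <- function(proj, w, delays = NULL) {
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  stopifnot(nrow(w) == length(por$ranks), ncol(w) == length(prr$ranks))
  idx <- which(!is.na(w), arr.ind = TRUE)
  pre <- prr$ranks[idx[, 2L]]
  post <- por$ranks[idx[, 1L]]
  d <- with_net_rng(proj[["net"]],
                    draw_value(resolve_delay_default(proj, delays),
                               length(pre)))
  install_synapses(proj, pre, post, w[idx], d)
}

#' Distance-dependent connectivity
#'
#' Distances are Euclidean over the 0-based geometry coordinates of the two
#' populations (which must have the same number of dimensions).  The weight
#' and optional probability kernels receive the distance; normalization is
#' left to the kernels.
#'
#' @inheritParams connect_all_to_all
#' @param weight_fun Function distance -> weight.
#' @param prob_fun Optional function distance -> inclusion probability.
#' @return The projection, invisibly.
#' @export
connect_distance_dependent <- function(proj, weight_fun, prob_fun = NULL,
                                       delays = NULL,
                                       allow_self_connections = FALSE) {
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  gpre <- prr$pop[["geometry"]]; gpost <- por$pop[["geometry"]]
  if (length(gpre) != length(gpost)) {
    stop("distance-dependent connector requires equal dimensionality",
         call. = FALSE)
  }
  same_pop <- identical(prr$pop, por$pop)
  cpre <- t(vapply(prr$ranks, rank_to_coord, integer(length(gpre)),
                   geometry = gpre))
  cpost <- t(vapply(por$ranks, rank_to_coord, integer(length(gpost)),
                    geometry = gpost))
  pre_list <- vector("list", length(por$ranks))
  w_list <- vector("list", length(por$ranks))
  with_net_rng(proj[["net"]], {
    for (i in seq_along(por$ranks)) {
      dist <- sqrt(colSums((t(cpre) - cpost[i, ])^2))
      keep <- rep(TRUE, length(dist))
      if (!is.null(prob_fun)) keep <- stats::runif(length(dist)) < prob_fun(dist)
      if (same_pop && !allow_self_connections) {
        keep <- keep & prr$ranks != por$ranks[i]
      }
      pre_list[[i]] <- prr$ranks[keep]
      w_list[[i]] <- weight_fun(dist[keep])
    }
    counts <- lengths(pre_list)
    pre <- unlist(pre_list, use.names = FALSE) %||% integer(0)
    post <- rep(por$ranks, counts)
    w <- unlist(w_list, use.names = FALSE) %||% numeric(0)
    d <- draw_value(resolve_delay_default(proj, delays), length(pre))
  })
  install_synapses(proj, pre, post, w, d, sorted = TRUE)
}

# ---- connectivity files -----------------------------------------------------

#' Save projection connectivity to a file
#'
#' Delimited text with header `pre_rank post_rank weight delay_ms` (0-based
#' ranks); files ending in `.rds` use R's binary serialization instead.  Both
#' formats round-trip exactly through [connect_from_file()].
#'
#' @param proj A connected projection.
#' @param file Path.
#' @export
save_connectivity <- function(proj, file) {
  syn <- proj[["syn"]]
  df <- data.frame(pre_rank = syn$pre, post_rank = syn$post,
                   weight = syn$w, delay_ms = syn$delay_ms)
  if (grepl("\\.rds$", file)) {
    saveRDS(df, file)
  } else {
    # %.17g keeps doubles exact across the round trip
    txt <- data.frame(pre_rank = df$pre_rank, post_rank = df$post_rank,
                      weight = sprintf("%.17g", df$weight),
                      delay_ms = sprintf("%.17g", df$delay_ms))
    utils::write.table(txt, file, row.names = FALSE, quote = FALSE, sep = " ")
  }
  invisible(file)
}

#' Connect from a connectivity file
#'
#' @inheritParams save_connectivity
#' @return The projection, invisibly.
#' @export
connect_from_file <- function(proj, file) {
  df <- if (grepl("\\.rds$", file)) readRDS(file)
        else utils::read.table(file, header = TRUE)
  need <- c("pre_rank", "post_rank", "weight", "delay_ms")
  if (!all(need %in% names(df))) {
    stop("connectivity file must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  }
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  if (!all(df$pre_rank %in% prr$ranks) || !all(df$post_rank %in% por$ranks)) {
    stop("rank out of range in connectivity file", call. = FALSE)
  }
  install_synapses(proj, df$pre_rank, df$post_rank, df$weight, df$delay_ms)
}

#' Dense weight matrix of a projection
#'
#' @param proj A projection.
#' @return Matrix (post x pre, parent-population sizes) with `NA` where no
#'   synapse exists.
#' @export
connectivity_matrix <- function(proj) {
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  syn <- proj[["syn"]]
  m <- matrix(NA_real_, por$pop[["size"]], prr$pop[["size"]])
  m[cbind(syn$post + 1L, syn$pre + 1L)] <- syn$w
  m
}

# ---- attribute access -------------------------------------------------------

#' @export
get_attribute.rs_projection <- function(obj, name) {
  syn <- obj[["syn"]]
  if (name == "w") return(syn$w)
  if (name %in% c("d", "delay")) return(syn$delay_ms)
  if (name %in% names(syn$vars)) return(syn$vars[[name]])
  if (name %in% names(obj[["post_shared"]])) return(obj[["post_shared"]][[name]])
  stop("undeclared projection attribute: ", name, call. = FALSE)
}

#' @export
set_attribute.rs_projection <- function(obj, name, value) {
  syn <- obj[["syn"]]
  n <- length(syn$pre)
  if (name == "w") {
    syn$w <- with_net_rng(obj[["net"]], draw_value(value, n))
  } else if (name %in% c("d", "delay")) {
    syn$delay_ms <- with_net_rng(obj[["net"]], draw_value(value, n))
    obj[["net"]][["compiled"]] <- FALSE
  } else if (name %in% names(syn$vars)) {
    syn$vars[[name]] <- with_net_rng(obj[["net"]], draw_value(value, n))
  } else if (name %in% names(obj[["post_shared"]])) {
    ps <- obj[["post_shared"]]
    ps[[name]] <- if (length(ps[[name]]) == 1L) {
      if (length(value) != 1L) {
        stop("shared parameter '", name, "' accepts a single value",
             call. = FALSE)
      }
      as.numeric(value)
    } else {
      with_net_rng(obj[["net"]], draw_value(value, length(ps[[name]])))
    }
    obj[["post_shared"]] <- ps
    obj[["syn"]] <- syn
    return(invisible(obj))
  } else {
    stop("undeclared projection attribute: ", name, call. = FALSE)
  }
  obj[["syn"]] <- syn
  invisible(obj)
}

#' @export
`$.rs_projection` <- function(x, name) {
  syn_names <- c("w", "d", "delay", names(x[["syn"]]$vars),
                 names(x[["post_shared"]]))
  if (name %in% syn_names) return(get_attribute(x, name))
  x[[name]]
}

#' @export
`$<-.rs_projection` <- function(x, name, value) {
  syn_names <- c("w", "d", "delay", names(x[["syn"]]$vars),
                 names(x[["post_shared"]]))
  if (name %in% syn_names) {
    set_attribute(x, name, value)
  } else {
    assign(name, value, envir = x)
  }
  x
}

#' @export
print.rs_projection <- function(x, ...) {
  cat("Projection (target '", x[["target"]], "'): ", synapse_count(x),
      " synapses\n", sep = "")
  invisible(x)
}
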