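# Populations: homogeneous groups of neurons with per-attribute storage.
#
# A population is an environment (reference semantics: simulation steps mutate
# it in place).  Per-unit attributes are flat 1-D vectors regardless of the
# declared geometry; shared (population-flagged) attributes hold one scalar.
# Ranks are 0-based and map to multi-dimensional coordinates in row-major
# order.

#' Create a population
#'
#' @param net The network (see [network()]) the population belongs to.
#' @param geometry Number of neurons, or an integer vector describing a
#'   multi-dimensional shape (row-major rank order).
#' @param model A [neuron_model()].
#' @param name Optional unique name.
#' @param stop_condition Optional boolean condition (e.g. `"r > 1.0"`, with an
#'   optional `: all` quantifier) used by [simulate_until()].
#' @return An object of class `rs_population`.  Model attributes can be read
#'   and written with `$` (e.g. `pop$v`, `pop$noise <- 5`); scalars broadcast
#'   to all units, vectors must match the population size, and [Uniform()]
#'   style specifications draw one value per unit.
#' @export
population <- function(net, geometry, model, name = NULL,
                       stop_condition = NULL) {
  stopifnot(inherits(net, "rs_network"))
  if (!inherits(model, "rs_neuron_model")) {
    stop("model must be an rs_neuron_model", call. = FALSE)
  }
  geometry <- as.integer(geometry)
  if (length(geometry) < 1L || any(geometry <= 0L)) {
    stop("geometry must be positive", call. = FALSE)
  }
  size <- prod(geometry)
  pop <- new.env(parent = emptyenv())
  class(pop) <- "rs_population"
  pop[["net"]] <- net
  pop[["geometry"]] <- geometry
  pop[["size"]] <- size
  pop[["model"]] <- model
  pop[["spiking"]] <- model$spiking
  pop[["special"]] <- NULL
  pop[["name"]] <- name
  pop[["id"]] <- length(net[["populations"]]) + 1L

  storage <- list()
  shared <- character(0)
  for (p in model$parameters) {
    if (p$locality == "shared") {
      storage[[p$name]] <- p$default
      shared <- c(shared, p$name)
    } else {
      storage[[p$name]] <- rep(p$default, size)
    }
  }
  for (v in model$variables) {
    if (v$locality == "shared") {
      storage[[v$name]] <- v$init
      shared <- c(shared, v$name)
    } else {
      storage[[v$name]] <- rep(v$init, size)
    }
  }
  pop[["storage"]] <- storage
  pop[["shared"]] <- shared
  pop[["last_spiked"]] <- rep(FALSE, size)
  pop[["refrac_remaining"]] <- integer(size)

  if (!is.null(stop_condition)) {
    sc <- parse_condition(stop_condition)
    scope <- list(kind = "neuron", spiking = model$spiking,
                  names = names(storage), extra = character(0))
    sc$res <- validate_resolved(resolve_generic(sc$expr), scope)
    pop[["stop_condition"]] <- sc
  }

  register_population(net, pop, name)
  pop
}

register_population <- function(net, pop, name) {
  if (!is.null(name)) {
    existing <- vapply(net[["populations"]], function(p)
      p[["name"]] %||% "", character(1))
    if (name %in% existing) {
      stop("duplicate population name: ", name, call. = FALSE)
    }
  }
  net[["populations"]][[length(net[["populations"]]) + 1L]] <- pop
  net[["compiled"]] <- FALSE
  invisible(pop)
}

#' Convert coordinates to a rank
#'
#' Ranks are 0-based; coordinates are 0-based and mapped in row-major order
#' (the last dimension varies fastest).
#'
#' @param coord 0-based integer coordinate vector.
#' @param geometry Population geometry.
#' @return 0-based rank.
#' @export
coord_to_rank <- function(coord, geometry) {
  stopifnot(length(coord) == length(geometry))
  if (any(coord < 0) || any(coord >= geometry)) {
    stop("coordinate out of range", call. = FALSE)
  }
  rank <- 0
  for (d in seq_along(geometry)) {
    rank <- rank * geometry[d] + coord[d]
  }
  as.integer(rank)
}

#' Convert a rank to coordinates
#'
#' @param rank 0-based rank.
#' @param geometry Population geometry.
#' @return 0-based integer coordinate vector (row-major).
#' @export
rank_to_coord <- function(rank, geometry) {
  if (rank < 0 || rank >= prod(geometry)) stop("rank out of range", call. = FALSE)
  nd <- length(geometry)
  coord <- integer(nd)
  for (d in rev(seq_len(nd))) {
    coord[d] <- rank %% geometry[d]
    rank <- rank %/% geometry[d]
  }
  coord
}

# ---- views ------------------------------------------------------------------

#' Subset of a population
#'
#' Attribute reads and writes through a view affect exactly the selected
#' units; projections accept views on either side.
#'
#' @param pop Population (or view).
#' @param ranks 0-based ranks of the selected units.
#' @return An `rs_population_view`.
#' @export
population_view <- function(pop, ranks) {
  if (inherits(pop, "rs_population_view")) {
    ranks <- pop$ranks[ranks + 1L]
    pop <- pop$pop
  }
  ranks <- as.integer(ranks)
  if (any(ranks < 0L) || any(ranks >= pop[["size"]])) {
    stop("view rank out of range", call. = FALSE)
  }
  structure(list(pop = pop, ranks = ranks), class = "rs_population_view")
}

#' @export
`[.rs_population` <- function(x, i) {
  population_view(x, as.integer(i) - 1L)  # R-style 1-based indexing
}

#' @export
`[.rs_population_view` <- function(x, i) {
  structure(list(pop = x$pop, ranks = x$ranks[as.integer(i)]),
            class = "rs_population_view")
}

# Underlying population and 0-based ranks of any population-like object.
pop_ranks <- function(obj) {
  if (inherits(obj, "rs_population_view")) {
    list(pop = obj$pop, ranks = obj$ranks)
  } else {
    list(pop = obj, ranks = seq_len(obj[["size"]]) - 1L)
  }
}

pop_size <- function(obj) {
  if (inherits(obj, "rs_population_view")) length(obj$ranks)
  else obj[["size"]]
}

# ---- attribute access -------------------------------------------------------

#' Read an attribute
#'
#' @param obj Population, view or projection.
#' @param name Declared parameter or variable name.
#' @return Per-unit vector (or scalar for shared attributes).
#' @export
get_attribute <- function(obj, name) {
  UseMethod("get_attribute")
}

#' Write an attribute
#'
#' Scalars broadcast; vectors must match the target size; [Uniform()] style
#' specifications draw one value per unit.  Shared attributes accept scalars
#' only.
#'
#' @param obj Population, view or projection.
#' @param name Declared parameter or variable name.
#' @param value New value.
#' @export
set_attribute <- function(obj, name, value) {
  UseMethod("set_attribute")
}

#' @export
get_attribute.rs_population <- function(obj, name) {
  storage <- obj[["storage"]]
  if (!(name %in% names(storage))) {
    stop("undeclared attribute: ", name, call. = FALSE)
  }
  storage[[name]]
}

#' @export
set_attribute.rs_population <- function(obj, name, value) {
  storage <- obj[["storage"]]
  if (!(name %in% names(storage))) {
    stop("undeclared attribute: ", name, call. = FALSE)
  }
  if (name %in% obj[["shared"]]) {
    if (inherits(value, "rs_random")) value <- value$draw(1L)
    if (length(value) != 1L) {
      stop("shared attribute '", name, "' accepts a single value",
           call. = FALSE)
    }
    storage[[name]] <- as.numeric(value)
  } else {
    storage[[name]] <- with_net_rng(obj[["net"]],
                                    draw_value(value, obj[["size"]]))
  }
  obj[["storage"]] <- storage
  invisible(obj)
}

#' @export
get_attribute.rs_population_view <- function(obj, name) {
  vals <- get_attribute(obj$pop, name)
  if (name %in% obj$pop[["shared"]]) return(vals)
  vals[obj$ranks + 1L]
}

#' @export
set_attribute.rs_population_view <- function(obj, name, value) {
  pop <- obj$pop
  if (name %in% pop[["shared"]]) {
    stop("cannot set shared attribute '", name, "' through a view",
         call. = FALSE)
  }
  storage <- pop[["storage"]]
  if (!(name %in% names(storage))) {
    stop("undeclared attribute: ", name, call. = FALSE)
  }
  vals <- with_net_rng(pop[["net"]], draw_value(value, length(obj$ranks)))
  storage[[name]][obj$ranks + 1L] <- vals
  pop[["storage"]] <- storage
  invisible(obj)
}

#' @export
`$.rs_population` <- function(x, name) {
  if (name %in% names(x[["storage"]])) return(get_attribute(x, name))
  x[[name]]
}

#' @export
`$<-.rs_population` <- function(x, name, value) {
  if (name %in% names(x[["storage"]])) {
    set_attribute(x, name, value)
  } else {
    assign(name, value, envir = x)
  }
  x
}

#' @export
print.rs_population <- function(x, ...) {
  cat("Population", if (!is.null(x[["name"]])) paste0("'", x[["name"]], "'"),
      "of", x[["size"]], "neurons (geometry",
      paste(x[["geometry"]], collapse = "x"), "),",
      if (x[["spiking"]]) "spiking" else "rate-coded", "\n")
  invisible(x)
}

#' @export
print.rs_population_view <- function(x, ...) {
  cat("View of", length(x$ranks), "neurons\n")
  invisible(x)
}

# Output value of a population-like at a given delay in steps (>= 1): rate r
# for rate-coded populations, logical spike flags for spiking ones.  Index 1
# of the buffer is the previous step's output.
pop_delayed_output <- function(pop, d) {
  buf <- pop[["out_buffer"]]
  if (d > length(buf)) {
    stop("delay ", d, " exceeds buffer capacity for population ",
         pop[["id"]], call. = FALSE)
  }
  buf[[d]]
}
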