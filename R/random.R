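# Random distribution specifications.
#
# The same distribution vocabulary serves two purposes: inside model equations
# (where calls like Uniform(-1, 1) are extracted into per-step, per-unit
# draws) and as initializers for attributes, weights and delays.  The exported
# constructors return a specification object with a `draw(n)` function; all
# draws go through the owning network's RNG stream so that a network seed
# fully determines connectivity, initial values and simulation noise.

rs_random_spec <- function(dist, args, draw) {
  structure(list(dist = dist, args = args, draw = draw), class = "rs_random")
}

#' Random distribution specifications
#'
#' Used to initialize attributes, weights or delays, mirroring the
#' distributions available inside model equations.  `Uniform(min, max)`,
#' `Normal(mu, sigma)`, `LogNormal(mu, sigma)` (log-scale parameters),
#' `Exponential(rate)` and `Gamma(shape, scale)`.
#'
#' @param min,max,mu,sigma,rate,shape,scale Distribution parameters.
#' @return An `rs_random` specification with a `draw(n)` function.
#' @name distributions
NULL

#' @rdname distributions
#' @export
Uniform <- function(min, max) {
  rs_random_spec("Uniform", list(min, max),
                 function(n) stats::runif(n, min, max))
}

#' @rdname distributions
#' @export
Normal <- function(mu, sigma) {
  rs_random_spec("Normal", list(mu, sigma),
                 function(n) stats::rnorm(n, mu, sigma))
}

#' @rdname distributions
#' @export
LogNormal <- function(mu, sigma) {
  rs_random_spec("LogNormal", list(mu, sigma),
                 function(n) stats::rlnorm(n, mu, sigma))
}

#' @rdname distributions
#' @export
Exponential <- function(rate) {
  rs_random_spec("Exponential", list(rate),
                 function(n) stats::rexp(n, rate))
}

#' @rdname distributions
#' @export
Gamma <- function(shape, scale = 1) {
  rs_random_spec("Gamma", list(shape, scale),
                 function(n) stats::rgamma(n, shape = shape, scale = scale))
}

# Draw for an in-equation random node (spec from resolve_vocabulary): the
# arguments are expressions evaluated against the current bindings.
draw_random_node <- function(spec, n, bindings) {
  vals <- lapply(spec$args, rs_eval, bindings = bindings)
  switch(spec$dist,
         Uniform = stats::runif(n, vals[[1]], vals[[2]]),
         Normal = stats::rnorm(n, vals[[1]], vals[[2]]),
         LogNormal = stats::rlnorm(n, vals[[1]], vals[[2]]),
         Exponential = stats::rexp(n, vals[[1]]),
         Gamma = stats::rgamma(n, shape = vals[[1]],
                               scale = if (length(vals) > 1L) vals[[2]] else 1),
         stop("unknown distribution: ", spec$dist, call. = FALSE))
}

# Resolve a value specification (scalar, vector, or rs_random) to a vector.
draw_value <- function(value, n) {
  if (inherits(value, "rs_random")) return(value$draw(n))
  if (is.numeric(value) || is.logical(value)) {
    if (length(value) == 1L) return(rep(value, n))
    if (length(value) == n) return(value)
    stop("value length ", length(value), " does not match size ", n,
         call. = FALSE)
  }
  stop("value must be numeric or an rs_random specification", call. = FALSE)
}
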