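# Weight-sharing projections: convolution, filter banks and pooling.
#
# One kernel (or none, for pooling) is shared by all post-synaptic neurons;
# the mapping from post coordinates to the center of the corresponding
# pre-synaptic region is derived automatically from the shape ratio and can
# be overridden.  Shared projections are rate-coded only and non-plastic.

#' Derive the post-to-pre sampling map
#'
#' For each dimension the ratio `r_d = pre_d / post_d` maps post coordinate
#' `c` to the pre center `floor(c * r_d + r_d / 2)`; the pooling extent is
#' `ceiling(r_d)` and the region assigned to `c` starts at `floor(c * r_d)`.
#' Ratios below 1 are allowed for convolution (upsampling).
#'
#' @param pre_shape,post_shape Positive integer vectors of equal length.
#' @return List with `ratio`, `extent` (per-dimension region size),
#'   `center(coords)` and `start(coords)` functions mapping 0-based post
#'   coordinate matrices (one row per unit) to pre coordinates.
#' @export
derive_sampling_map <- function(pre_shape, post_shape) {
  stopifnot(length(pre_shape) == length(post_shape),
            all(pre_shape > 0), all(post_shape > 0))
  ratio <- pre_shape / post_shape
  list(
    ratio = ratio,
    extent = as.integer(ceiling(ratio)),
    center = function(coords) {
      coords <- rbind(coords)
      floor(sweep(coords, 2L, ratio, `*`) + rep(ratio / 2, each = nrow(coords)))
    },
    start = function(coords) {
      coords <- rbind(coords)
      floor(sweep(coords, 2L, ratio, `*`))
    }
  )
}

#' Weight-sharing projection
#'
#' @param net The network.
#' @param pre,post Rate-coded populations.
#' @param target Target name (read as `sum(target)` by the post population).
#' @param operation `"convolution"` (requires [connect_convolve()]) or a
#'   pooling operation `"max"` / `"min"` / `"mean"` (requires
#'   [connect_pooling()]).
#' @return An `rs_projection` of kind `shared`.
#' @export
shared_projection <- function(net, pre, post, target,
                              operation = c("convolution", "max", "min",
                                            "mean")) {
  operation <- match.arg(operation)
  prr <- pop_ranks(pre); por <- pop_ranks(post)
  if (prr$pop[["spiking"]] || por$pop[["spiking"]]) {
    stop("weight sharing is only available for rate-coded populations",
         call. = FALSE)
  }
  if (inherits(pre, "rs_population_view") ||
      inherits(post, "rs_population_view")) {
    stop("shared projections connect whole populations", call. = FALSE)
  }
  proj <- projection(net, pre, post, target)
  proj[["kind_hint"]] <- "shared"
  proj[["operation"]] <- operation
  proj[["connected"]] <- TRUE   # no explicit synapses
  proj
}

#' Define a convolution over a shared projection
#'
#' The post-synaptic input is
#' `sum(target)(x) = sum_i W(i) * pre.r(center(x) - i)` with the kernel `W`
#' indexed by offsets `-d .. d` per dimension (odd kernel sizes).  When pre
#' and post shapes differ, the sampling map of [derive_sampling_map()]
#' relocates each post neuron's center.  A kernel with fewer dimensions than
#' the pre-synaptic geometry is applied along the leading dimensions
#' separately for each trailing coordinate (e.g. per color channel).  A list
#' of kernels defines a filter bank: the post population carries one extra
#' trailing dimension indexing the filter.
#'
#' @param proj A [shared_projection()] created with
#'   `operation = "convolution"`.
#' @param weights Numeric array (odd extents) or list of arrays (filter
#'   bank).
#' @param padding Value of `pre.r` outside the population: `"zero"` or
#'   `"edge"` (clamp to border).
#' @return The projection, invisibly.
#' @export
connect_convolve <- function(proj, weights, padding = c("zero", "edge")) {
  if (!identical(proj[["kind_hint"]], "shared") ||
      proj[["operation"]] != "convolution") {
    stop("connect_convolve requires a shared projection with ",
         "operation = 'convolution'", call. = FALSE)
  }
  proj[["kernel"]] <- weights
  proj[["padding"]] <- match.arg(padding)
  proj[["net"]][["compiled"]] <- FALSE
  invisible(proj)
}

#' Define a pooling operation over a shared projection
#'
#' Each post-synaptic neuron takes the maximal (minimal, mean) firing rate
#' over its pre-synaptic region, without any weights.  The per-dimension
#' region extent is derived from the shape ratio (see
#' [derive_sampling_map()]) unless overridden; edge regions truncate to
#' valid coordinates and mean-pooling divides by the actual region size.
#'
#' @param proj A [shared_projection()] with a pooling operation.
#' @param extent Optional per-dimension region size override.
#' @return The projection, invisibly.
#' @export
connect_pooling <- function(proj, extent = NULL) {
  if (!identical(proj[["kind_hint"]], "shared") ||
      proj[["operation"]] == "convolution") {
    stop("connect_pooling requires a shared projection with a pooling ",
         "operation", call. = FALSE)
  }
  proj[["extent_override"]] <- extent
  proj[["net"]][["compiled"]] <- FALSE
  invisible(proj)
}

#' Region extent of a pooling projection
#'
#' @param proj A compiled pooling projection.
#' @return Integer vector: pre-synaptic region size per dimension.
#' @export
pooling_extent <- function(proj) {
  net <- proj[["net"]]
  if (!net[["compiled"]]) compile_network(net)
  proj[["comp"]]$extent
}

# Row-major strides of a geometry.
geometry_strides <- function(g) {
  nd <- length(g)
  s <- integer(nd)
  s[nd] <- 1L
  if (nd > 1L) for (d in (nd - 1L):1L) s[d] <- s[d + 1L] * g[d + 1L]
  s
}

# 0-based coordinates of all ranks of a geometry (row-major), as a matrix.
geometry_coords <- function(g) {
  n <- prod(g)
  m <- matrix(0L, n, length(g))
  r <- 0:(n - 1)
  for (d in rev(seq_along(g))) {
    m[, d] <- r %% g[d]
    r <- r %/% g[d]
  }
  m
}

compile_shared <- function(net, proj) {
  prr <- pop_ranks(proj[["pre"]]); por <- pop_ranks(proj[["post"]])
  comp <- list(kind = "shared", pre_pop = prr$pop, post_pop = por$pop,
               target = proj[["target"]], delay_steps = 1L,
               operation = proj[["operation"]])
  gpre <- prr$pop[["geometry"]]; gpost <- por$pop[["geometry"]]
  if (proj[["operation"]] == "convolution") {
    weights <- proj[["kernel"]]
    if (is.null(weights)) {
      stop("convolution projection has no kernel; call connect_convolve()",
           call. = FALSE)
    }
    bank <- is.list(weights)
    kernels <- if (bank) weights else list(weights)
    kdims <- lapply(kernels, function(w) if (is.null(dim(w))) length(w)
                                         else dim(w))
    if (length(unique(kdims)) != 1L) {
      stop("all kernels of a bank must share one shape", call. = FALSE)
    }
    kd <- kdims[[1L]]
    k <- length(kd)
    if (any(kd %% 2L == 0L)) {
      stop("kernel extents must be odd (offsets -d..d)", call. = FALSE)
    }
    if (k > length(gpre)) {
      stop("kernel has more dimensions than the pre-synaptic population",
           call. = FALSE)
    }
    if (any(kd > gpre[seq_len(k)])) {
      stop("kernel extent exceeds the pre-synaptic shape", call. = FALSE)
    }
    # post shape: [map dims][pre extra dims][bank dim]
    n_extra <- length(gpre) - k
    expected_nd <- k + n_extra + (if (bank) 1L else 0L)
    if (length(gpost) != expected_nd) {
      stop("post geometry must have ", expected_nd, " dimension(s) for this ",
           "kernel", call. = FALSE)
    }
    if (n_extra > 0L &&
        !all(gpost[k + seq_len(n_extra)] == gpre[k + seq_len(n_extra)])) {
      stop("trailing (channel) dimensions of pre and post must match",
           call. = FALSE)
    }
    if (bank && gpost[length(gpost)] != length(kernels)) {
      stop("last post dimension must index the ", length(kernels),
           " filters of the bank", call. = FALSE)
    }
    map <- derive_sampling_map(gpre[seq_len(k)], gpost[seq_len(k)])
    coords <- geometry_coords(gpost)
    centers <- map$center(coords[, seq_len(k), drop = FALSE])
    half <- (kd - 1L) %/% 2L
    offs <- geometry_coords(kd)   # 0-based kernel indices
    comp$conv <- list(
      k = k, n_extra = n_extra, bank = bank, kernels = kernels,
      centers = centers,
      extra = if (n_extra > 0L) coords[, k + seq_len(n_extra), drop = FALSE],
      filter = if (bank) coords[, ncol(coords)],
      offsets = sweep(offs, 2L, half, `-`),   # -d..d per dim
      kidx = offs + 1L,
      strides = geometry_strides(gpre),
      gpre = gpre,
      padding = proj[["padding"]] %||% "zero")
    comp$extent <- map$extent
  } else {
    if (length(gpre) != length(gpost)) {
      stop("pooling requires equal dimensionality", call. = FALSE)
    }
    if (any(gpost > gpre)) {
      stop("post population larger than pre in a pooled dimension",
           call. = FALSE)
    }
    map <- derive_sampling_map(gpre, gpost)
    extent <- proj[["extent_override"]] %||% map$extent
    extent <- as.integer(rep_len(extent, length(gpre)))
    coords <- geometry_coords(gpost)
    comp$pool <- list(
      starts = map$start(coords),
      offsets = geometry_coords(extent),
      strides = geometry_strides(gpre),
      gpre = gpre)
    comp$extent <- extent
  }
  proj[["comp"]] <- comp
  invisible(proj)
}

# Per-post output of a shared projection given the delayed pre rates.
shared_output <- function(proj, pre_r) {
  comp <- proj[["comp"]]
  npost <- comp$post_pop[["size"]]
  if (comp$operation == "convolution") {
    cv <- comp$conv
    out <- numeric(npost)
    sel_all <- seq_len(npost)
    groups <- if (cv$bank) split(sel_all, cv$filter) else list(sel_all)
    for (f in seq_along(groups)) {
      sel <- groups[[f]]
      W <- cv$kernels[[f]]
      centers <- cv$centers[sel, , drop = FALSE]
      extra <- if (cv$n_extra > 0L) cv$extra[sel, , drop = FALSE]
      for (oi in seq_len(nrow(cv$offsets))) {
        wv <- W[rbind(cv$kidx[oi, ])]
        if (wv == 0) next
        pc <- sweep(centers, 2L, cv$offsets[oi, ], `-`)
        if (cv$padding == "edge") {
          for (d in seq_len(cv$k)) {
            pc[, d] <- pmin(pmax(pc[, d], 0L), cv$gpre[d] - 1L)
          }
          valid <- rep(TRUE, nrow(pc))
        } else {
          valid <- rep(TRUE, nrow(pc))
          for (d in seq_len(cv$k)) {
            valid <- valid & pc[, d] >= 0L & pc[, d] < cv$gpre[d]
          }
        }
        full <- if (cv$n_extra > 0L) cbind(pc, extra) else pc
        ranks <- as.vector(full %*% cv$strides)
        if (any(valid)) {
          out[sel[valid]] <- out[sel[valid]] + wv * pre_r[ranks[valid] + 1L]
        }
      }
    }
    return(out)
  }
  # pooling
  pl <- comp$pool
  op <- comp$operation
  acc <- rep(if (op == "max") -Inf else if (op == "min") Inf else 0, npost)
  cnt <- numeric(npost)
  for (oi in seq_len(nrow(pl$offsets))) {
    pc <- sweep(pl$starts, 2L, pl$offsets[oi, ], `+`)
    valid <- rep(TRUE, npost)
    for (d in seq_len(ncol(pc))) {
      valid <- valid & pc[, d] < pl$gpre[d]
    }
    if (!any(valid)) next
    ranks <- as.vector(pc %*% pl$strides)
    vals <- pre_r[ranks[valid] + 1L]
    if (op == "max") {
      acc[valid] <- pmax(acc[valid], vals)
    } else if (op == "min") {
      acc[valid] <- pmin(acc[valid], vals)
    } else {
      acc[valid] <- acc[valid] + vals
      cnt[valid] <- cnt[valid] + 1
    }
  }
  if (op == "mean") acc <- acc / pmax(cnt, 1)
  acc
}

propagate_shared <- function(net, proj) {
  comp <- proj[["comp"]]
  pre_r <- pop_delayed_output(comp$pre_pop, 1L)
  add_input_sum(comp$post_pop, comp$target, shared_output(proj, pre_r))
}

# ---- kernel files -----------------------------------------------------------

#' Write a kernel to a delimited text file
#'
#' Format: a header line `# dims: d1 d2 ...` followed by the values in
#' row-major order, one per line.  Round-trips exactly through
#' [read_kernel()].
#'
#' @param kernel Numeric array.
#' @param file Path.
#' @export
write_kernel <- function(kernel, file) {
  dims <- if (is.null(dim(kernel))) length(kernel) else dim(kernel)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# dims:", paste(dims, collapse = " ")), con)
  # row-major order: first dimension slowest
  vals <- as.vector(aperm(array(kernel, dims), rev(seq_along(dims))))
  writeLines(format(vals, digits = 17), con)
  invisible(file)
}

#' Read a kernel written by [write_kernel()]
#'
#' @param file Path.
#' @return Numeric array.
#' @export
read_kernel <- function(file) {
  lines <- readLines(file)
  dims <- as.integer(strsplit(sub("^# dims:\\s*", "", lines[1L]), "\\s+")[[1L]])
  vals <- as.numeric(lines[-1L])
  aperm(array(vals, rev(dims)), rev(seq_along(dims)))
}
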