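# Populations, geometry, attribute access, connectors, delays and
# reproducibility.

test_that("populations initialize storage from defaults and map coordinates", {
  net <- network(seed = 1)
  pop <- population(net, 1000L, standard_neuron("Izhikevich"))
  expect_equal(pop[["size"]], 1000L)
  expect_equal(pop$v, rep(-65, 1000))
  expect_equal(pop$u, rep(-13, 1000))
  expect_equal(pop$a, rep(0.02, 1000))
  expect_equal(pop$v_thresh, 30)   # shared scalar

  net2 <- network(seed = 1)
  p2 <- population(net2, c(2, 3), hold_neuron())
  expect_equal(p2[["size"]], 6L)
  expect_equal(coord_to_rank(c(1, 2), c(2, 3)), 5L)
  expect_equal(rank_to_coord(5, c(2, 3)), c(1L, 2L))
  # bijection
  for (r in 0:5) expect_equal(coord_to_rank(rank_to_coord(r, c(2, 3)),
                                            c(2, 3)), r)

  expect_error(population(net2, 0, hold_neuron()), "positive")
  expect_error(population(net2, 3, hold_neuron(), name = "a") &
               population(net2, 3, hold_neuron(), name = "a"))
})

test_that("attribute writes broadcast, views write element-wise, shared reject arrays", {
  net <- network(seed = 1)
  pop <- population(net, 1000L, standard_neuron("Izhikevich"))
  exc <- pop[1:800]
  set_attribute(exc, "noise", 5.0)
  expect_equal(pop$noise[1:800], rep(5, 800))
  expect_equal(pop$noise[801:1000], rep(0, 200))
  vals <- seq_len(800) / 800
  set_attribute(exc, "a", vals)
  expect_equal(get_attribute(exc, "a"), vals)   # write-then-read round trip
  expect_equal(pop$a[801:1000], rep(0.02, 200))
  # $ assignment goes through set_attribute
  pop$d <- 2.0
  expect_equal(pop$d, rep(2, 1000))
  expect_error(set_attribute(pop, "v_thresh", c(1, 2)), "single value")
  expect_error(set_attribute(pop, "a", c(1, 2, 3)), "does not match")
  expect_error(set_attribute(pop, "zz", 1), "undeclared")
  # random initializer draws per unit
  set_attribute(pop, "v", Uniform(-70, -60))
  expect_true(all(pop$v >= -70 & pop$v <= -60))
  expect_gt(stats::sd(pop$v), 0)
})

test_that("all-to-all connector counts pairs and excludes self-connections", {
  net <- network(seed = 1)
  a <- population(net, 40L, hold_neuron())
  b <- population(net, 25L, rate_neuron())
  pj <- projection(net, a, b, "exc")
  connect_all_to_all(pj, 1.0)
  expect_equal(synapse_count(pj), 1000L)

  # same population: self-connections excluded by default, opt-in flag
  pj2 <- projection(net, b, b, "exc")
  connect_all_to_all(pj2, 1.0)
  expect_equal(synapse_count(pj2), 25L * 24L)
  pj3 <- projection(net, b, b, "inh")
  connect_all_to_all(pj3, 1.0, allow_self_connections = TRUE)
  expect_equal(synapse_count(pj3), 625L)

  # single pair
  net4 <- network(seed = 1)
  x <- population(net4, 1L, hold_neuron())
  y <- population(net4, 1L, rate_neuron())
  p4 <- projection(net4, x, y, "exc")
  connect_all_to_all(p4, 0.25)
  expect_equal(synapse_count(p4), 1L)
  expect_equal(p4$w, 0.25)

  # random weights: empirical mean by the law of large numbers
  net5 <- network(seed = 7)
  u <- population(net5, 300L, hold_neuron())
  v <- population(net5, 300L, rate_neuron())
  p5 <- projection(net5, u, v, "exc")
  connect_all_to_all(p5, Uniform(0, 1))
  expect_equal(mean(p5$w), 0.5, tolerance = 0.005)
})

test_that("fixed-probability connector matches binomial statistics", {
  net <- network(seed = 3)
  a <- population(net, 200L, hold_neuron())
  b <- population(net, 200L, rate_neuron())
  p0 <- projection(net, a, b, "exc")
  connect_fixed_probability(p0, 0, 1.0)
  expect_equal(synapse_count(p0), 0L)

  p1 <- projection(net, a, b, "inh")
  connect_fixed_probability(p1, 1, 1.0)
  expect_equal(synapse_count(p1), 200L * 200L)

  p2 <- projection(net, a, b, "mod")
  connect_fixed_probability(p2, 0.02, 1.0)
  n <- 200 * 200
  expect_lt(abs(synapse_count(p2) - 0.02 * n), 4 * sqrt(n * 0.02 * 0.98))

  expect_error(connect_fixed_probability(projection(net, a, b, "x"), 1.5, 1),
               "0, 1")
})

test_that("one-to-one, pattern-function and matrix connectors enumerate exactly", {
  net <- network(seed = 1)
  a <- population(net, 10L, hold_neuron())
  b <- population(net, 10L, rate_neuron())
  p1 <- projection(net, a, b, "exc")
  connect_one_to_one(p1, 2.0)
  expect_equal(synapse_count(p1), 10L)
  expect_equal(p1[["syn"]]$pre, p1[["syn"]]$post)

  p2 <- projection(net, a, b, "inh")
  connect_from_function(p2, function(pre, post) {
    data.frame(pre = c(0, 1, 2), post = c(5, 5, 6), w = c(1, 2, 3))
  })
  expect_equal(synapse_count(p2), 3L)
  m <- connectivity_matrix(p2)
  expect_equal(m[6, 1], 1)
  expect_equal(m[6, 2], 2)
  expect_equal(m[7, 3], 3)

  # empty generator
  p3 <- projection(net, a, b, "m2")
  connect_from_function(p3, function(pre, post)
    data.frame(pre = integer(0), post = integer(0), w = numeric(0)))
  expect_equal(synapse_count(p3), 0L)

  # duplicates and out-of-range ranks are rejected
  expect_error(connect_from_function(projection(net, a, b, "m3"),
    function(pre, post) data.frame(pre = c(0, 0), post = c(1, 1),
                                   w = c(1, 1))), "duplicate")
  expect_error(connect_from_function(projection(net, a, b, "m4"),
    function(pre, post) data.frame(pre = 99, post = 0, w = 1)),
    "out of range")

  # dense matrix with NA holes
  W <- matrix(NA_real_, 10, 10)
  W[3, 4] <- 0.5; W[7, 1] <- -1
  p5 <- projection(net, a, b, "m5")
  connect_from_matrix(p5, W)
  expect_equal(synapse_count(p5), 2L)
  expect_equal(connectivity_matrix(p5)[3, 4], 0.5)
})

test_that("connectivity files round-trip exactly", {
  net <- network(seed = 9)
  a <- population(net, 30L, hold_neuron())
  b <- population(net, 30L, rate_neuron())
  p1 <- projection(net, a, b, "exc")
  connect_fixed_probability(p1, 0.3, Uniform(0, 1), delays = 2)
  f <- tempfile(fileext = ".txt")
  save_connectivity(p1, f)
  p2 <- projection(net, a, b, "inh")
  connect_from_file(p2, f)
  expect_identical(p1[["syn"]]$pre, p2[["syn"]]$pre)
  expect_identical(p1[["syn"]]$post, p2[["syn"]]$post)
  expect_identical(p1[["syn"]]$w, p2[["syn"]]$w)
  expect_identical(p1[["syn"]]$delay_ms, p2[["syn"]]$delay_ms)
  unlink(f)
})

test_that("distance-dependent connector uses Euclidean geometry distances", {
  net <- network(seed = 2)
  a <- population(net, c(5, 5), hold_neuron())
  b <- population(net, c(5, 5), rate_neuron())
  pj <- projection(net, a, b, "exc")
  connect_distance_dependent(pj, weight_fun = function(d) exp(-d^2))
  # weight between (0,0) and (1,1) is exp(-2)
  syn <- pj[["syn"]]
  i <- which(syn$pre == 0 & syn$post == coord_to_rank(c(1, 1), c(5, 5)))
  expect_equal(syn$w[i], exp(-2))
})

test_that("step changes propagate after exactly the synaptic delay", {
  for (d in c(1, 2, 5)) {
    net <- network(dt = 1, seed = 1)
    src <- population(net, 1L, hold_neuron())
    tgt <- population(net, 1L, rate_neuron())
    pj <- projection(net, src, tgt, "exc")
    connect_all_to_all(pj, 1.0, delays = d)
    compile_network(net)
    set_attribute(src, "r", 5.0)
    seen <- integer(0)
    for (k in 1:8) {
      simulate(net, 1)
      if (compute_input_sums(pj)[1] > 0) { seen <- k; break }
    }
    expect_equal(seen, d)
  }
})

test_that("sub-step delays are rounded up to dt with a warning", {
  net <- network(dt = 1, seed = 1)
  src <- population(net, 1L, hold_neuron())
  tgt <- population(net, 1L, rate_neuron())
  pj <- projection(net, src, tgt, "exc")
  connect_all_to_all(pj, 1.0, delays = 0.25)
  expect_warning(compile_network(net), "rounded")
  expect_equal(pj[["comp"]]$delay_steps, 1L)
})

test_that("identical seeds give bit-identical connectivity and initial values", {
  make <- function(seed) {
    net <- network(dt = 0.1, seed = seed)
    pop <- population(net, 100L, standard_neuron("Izhikevich"))
    set_attribute(pop, "v", Uniform(-70, -60))
    pj <- projection(net, pop, pop, "exc")
    connect_fixed_probability(pj, 0.1, Uniform(0, 0.5))
    list(v = pop$v, pre = pj[["syn"]]$pre, post = pj[["syn"]]$post,
         w = pj[["syn"]]$w)
  }
  expect_identical(make(123), make(123))
  expect_false(identical(make(123)$w, make(124)$w))
})

test_that("synapse counts are conserved through pruning and re-creation", {
  net <- network(seed = 5)
  a <- population(net, 10L, hold_neuron())
  b <- population(net, 10L, rate_neuron())
  pj <- projection(net, a, b, "exc")
  connect_all_to_all(pj, 1.0)
  n0 <- synapse_count(pj)
  per_post <- lengths(split(pj[["syn"]]$pre, pj[["syn"]]$post))
  expect_equal(sum(per_post), n0)
  prune_synapse(pj, 3, 4)
  expect_equal(synapse_count(pj), n0 - 1L)
  expect_error(prune_synapse(pj, 3, 4), "no synapse")
  create_synapse(pj, 3, 4, w = 1.0)
  expect_equal(synapse_count(pj), n0)
  expect_error(create_synapse(pj, 3, 4), "already exists")
  # ordering by (post, pre) is preserved
  syn <- pj[["syn"]]
  o <- order(syn$post, syn$pre)
  expect_identical(o, seq_along(o))
})
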