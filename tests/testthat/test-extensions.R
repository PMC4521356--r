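# Weight-sharing projections (convolution, filter banks, pooling) and
# structural plasticity.

conv_net <- function(pre_shape, post_shape, operation = "convolution",
                     seed = 3) {
  net <- network(dt = 1, seed = seed)
  p1 <- population(net, pre_shape, hold_neuron())
  p2 <- population(net, post_shape, neuron_model(equations = "r = sum(exc)"))
  pj <- shared_projection(net, p1, p2, "exc", operation = operation)
  list(net = net, pre = p1, post = p2, proj = pj)
}

test_that("a delta kernel reproduces the input and averaging preserves constants", {
  fx <- conv_net(c(8, 8), c(8, 8))
  K <- matrix(0, 3, 3); K[2, 2] <- 1
  connect_convolve(fx$proj, K)
  img <- matrix(runif(64), 8, 8)
  set_image(fx$pre, img)
  simulate(fx$net, 2)
  expect_equal(get_image(fx$post), img, tolerance = 1e-12)

  fx2 <- conv_net(c(8, 8), c(8, 8))
  connect_convolve(fx2$proj, matrix(1 / 9, 3, 3))
  set_image(fx2$pre, matrix(3.5, 8, 8))
  simulate(fx2$net, 2)
  out <- get_image(fx2$post)
  expect_equal(out[2:7, 2:7], matrix(3.5, 6, 6), tolerance = 1e-12)
  # zero padding shrinks the borders
  expect_equal(out[1, 1], 3.5 * 4 / 9, tolerance = 1e-12)
  # edge padding keeps them
  fx3 <- conv_net(c(8, 8), c(8, 8))
  connect_convolve(fx3$proj, matrix(1 / 9, 3, 3), padding = "edge")
  set_image(fx3$pre, matrix(3.5, 8, 8))
  simulate(fx3$net, 2)
  expect_equal(get_image(fx3$post), matrix(3.5, 8, 8), tolerance = 1e-12)
})

test_that("convolution matches the brute-force double-loop oracle", {
  set.seed(14)
  fx <- conv_net(c(16, 16), c(16, 16))
  K <- matrix(rnorm(9), 3, 3)
  connect_convolve(fx$proj, K)
  img <- matrix(runif(256), 16, 16)
  set_image(fx$pre, img)
  simulate(fx$net, 2)
  expect_equal(get_image(fx$post), brute_conv2(img, K), tolerance = 1e-12)
})

test_that("convolution is linear in its input", {
  set.seed(15)
  K <- matrix(rnorm(9), 3, 3)
  run <- function(img) {
    fx <- conv_net(c(10, 10), c(10, 10))
    connect_convolve(fx$proj, K)
    set_image(fx$pre, img)
    simulate(fx$net, 2)
    get_image(fx$post)
  }
  X <- matrix(runif(100), 10, 10)
  Y <- matrix(runif(100), 10, 10)
  a <- 1.7; b <- -0.4
  expect_equal(run(a * X + b * Y), a * run(X) + b * run(Y), tolerance = 1e-10)
})

test_that("sub-sampled and per-channel convolutions map coordinates correctly", {
  # 8x8 -> 4x4: ratio 2, centers at 1, 3, 5, 7
  fx <- conv_net(c(8, 8), c(4, 4))
  K <- matrix(0, 3, 3); K[2, 2] <- 1
  connect_convolve(fx$proj, K)
  img <- matrix(seq_len(64), 8, 8)
  set_image(fx$pre, img)
  simulate(fx$net, 2)
  out <- matrix(get_attribute(fx$post, "r"), 4, 4, byrow = TRUE)
  expect_equal(out, img[c(2, 4, 6, 8), c(2, 4, 6, 8)])

  # per-channel: 2-D kernel over a (6, 6, 2) population
  net <- network(dt = 1, seed = 1)
  p1 <- population(net, c(6, 6, 2), hold_neuron())
  p2 <- population(net, c(6, 6, 2), neuron_model(equations = "r = sum(exc)"))
  pj <- shared_projection(net, p1, p2, "exc")
  connect_convolve(pj, K)
  vals <- runif(72)
  set_attribute(p1, "r", vals)
  simulate(net, 2)
  expect_equal(get_attribute(p2, "r"), vals, tolerance = 1e-12)

  # filter bank: two kernels add a trailing dimension
  netb <- network(dt = 1, seed = 1)
  b1 <- population(netb, c(6, 6), hold_neuron())
  b2 <- population(netb, c(6, 6, 2), neuron_model(equations = "r = sum(exc)"))
  pb <- shared_projection(netb, b1, b2, "exc")
  connect_convolve(pb, list(K, 2 * K))
  imgb <- matrix(runif(36), 6, 6)
  set_image(b1, imgb)
  simulate(netb, 2)
  out_b <- array(get_attribute(b2, "r"), c(2, 6, 6))  # reversed dims
  expect_equal(t(out_b[1, , ]), imgb, tolerance = 1e-12)
  expect_equal(t(out_b[2, , ]), 2 * imgb, tolerance = 1e-12)

  # kernel larger than the population is rejected
  fx_err <- conv_net(c(3, 3), c(3, 3))
  connect_convolve(fx_err$proj, matrix(1, 5, 5))
  expect_error(compile_network(fx_err$net), "exceeds")
})

test_that("sampling maps derive ratios, centers and extents", {
  m <- derive_sampling_map(200, 100)
  expect_equal(m$ratio, 2)
  expect_equal(m$extent, 2L)
  expect_equal(as.vector(m$center(matrix(0:4))), c(1, 3, 5, 7, 9))

  m2 <- derive_sampling_map(c(7, 7), c(7, 7))
  expect_equal(m2$extent, c(1L, 1L))
  expect_equal(m2$center(matrix(c(3, 4), 1)), matrix(c(3, 4), 1))

  m3 <- derive_sampling_map(9, 3)
  expect_equal(as.vector(m3$center(matrix(0:2))), c(1, 4, 7))
  expect_equal(m3$extent, 3L)
  # full-cover partition: the regions tile the pre axis exactly
  starts <- as.vector(m3$start(matrix(0:2)))
  covered <- unlist(lapply(starts, function(s) s + 0:2))
  expect_equal(sort(covered), 0:8)
})

test_that("pooling extracts regional statistics with truncated edge regions", {
  # auto extent 2x2 for 200x200 -> 100x100
  fx <- conv_net(c(200, 200), c(100, 100), operation = "max")
  connect_pooling(fx$proj)
  expect_equal(pooling_extent(fx$proj), c(2L, 2L))

  # constant field: max pool returns the constant
  fx2 <- conv_net(c(6, 6), c(3, 3), operation = "max")
  connect_pooling(fx2$proj)
  set_image(fx2$pre, matrix(0.42, 6, 6))
  simulate(fx2$net, 2)
  expect_equal(get_attribute(fx2$post, "r"), rep(0.42, 9))

  # 4x4 with a single maximal element vs exhaustive enumeration
  img <- matrix(runif(16), 4, 4)
  img[3, 2] <- 10
  for (op in c("max", "min", "mean")) {
    fx3 <- conv_net(c(4, 4), c(2, 2), operation = op)
    connect_pooling(fx3$proj)
    set_image(fx3$pre, img)
    simulate(fx3$net, 2)
    out <- matrix(get_attribute(fx3$post, "r"), 2, 2, byrow = TRUE)
    f <- switch(op, max = max, min = min, mean = mean)
    oracle <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      oracle[i, j] <- f(img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    }
    expect_equal(out, oracle, info = op)
  }

  # min <= mean <= max element-wise
  set.seed(8)
  img2 <- matrix(runif(81), 9, 9)
  vals <- lapply(c("min", "mean", "max"), function(op) {
    fx4 <- conv_net(c(9, 9), c(3, 3), operation = op)
    connect_pooling(fx4$proj)
    set_image(fx4$pre, img2)
    simulate(fx4$net, 2)
    get_attribute(fx4$post, "r")
  })
  expect_true(all(vals[[1]] <= vals[[2]] & vals[[2]] <= vals[[3]]))

  # post larger than pre is rejected
  fx5 <- conv_net(c(4, 4), c(8, 8), operation = "max")
  connect_pooling(fx5$proj)
  expect_error(compile_network(fx5$net), "larger")
})

test_that("shared projections refuse spiking populations", {
  net <- network(dt = 1, seed = 1)
  s <- population(net, c(4, 4), standard_neuron("Izhikevich"))
  r <- population(net, c(4, 4), neuron_model(equations = "r = sum(exc)"))
  expect_error(shared_projection(net, s, r, "exc"), "rate-coded")
})

test_that("kernel files round-trip through the offsets header format", {
  K <- array(rnorm(24), c(2, 3, 4))
  f <- tempfile(fileext = ".txt")
  write_kernel(K, f)
  K2 <- read_kernel(f)
  expect_equal(K2, K, tolerance = 1e-15)
  unlink(f)
})

test_that("explicit synapse creation and pruning keep state consistent", {
  net <- network(dt = 1, seed = 2)
  a <- population(net, 5L, hold_neuron())
  b <- population(net, 5L, rate_neuron())
  pj <- projection(net, a, b, "exc",
                   model = synapse_model(equations = "age = age + dt"))
  connect_one_to_one(pj, 1.0)
  compile_network(net)
  simulate(net, 3)
  # created synapses start at their declared inits and act immediately
  create_synapse(pj, 0, 3, w = 2.0)
  syn <- pj[["syn"]]
  i <- which(syn$pre == 0 & syn$post == 3)
  expect_equal(syn$vars$age[i], 0)
  set_attribute(a, "r", 1.0)
  simulate(net, 2)
  # participates in propagation (2.0 plus the existing one-to-one synapse)
  expect_equal(compute_input_sums(pj)[4], 3.0)
  prune_synapse(pj, 0, 3)
  expect_equal(synapse_count(pj), 5L)
})

test_that("condition rules create and prune synapses with stated probability", {
  # creating: predicate over pre/post rates, proba = 1, matches enumeration
  net <- network(dt = 1, seed = 4)
  a <- population(net, 10L, hold_neuron())
  b <- population(net, 10L, hold_neuron())
  syn <- synapse_model(creating = "pre.r * post.r > 0.9 : w = 0.5")
  pj <- projection(net, a, b, "exc", model = syn)
  connect_from_function(pj, function(pre, post)
    data.frame(pre = 0, post = 0, w = 1))
  ra <- runif(10); rb <- runif(10)
  set_attribute(a, "r", ra)
  compile_network(net)
  set_attribute(b, "r", rb)
  start_creating(pj)
  simulate(net, 1)
  expected <- outer(rb, ra) > 0.9   # post x pre predicate
  expected[1, 1] <- TRUE            # pre-existing synapse
  got <- !is.na(connectivity_matrix(pj))
  expect_equal(got, expected)
  new_syn <- pj[["syn"]]
  expect_true(all(new_syn$w[-which(new_syn$pre == 0 & new_syn$post == 0)] == 0.5))

  # pruning with probability 0.5: binomial statistics over many synapses
  net2 <- network(dt = 1, seed = 9)
  a2 <- population(net2, 100L, hold_neuron())
  b2 <- population(net2, 100L, rate_neuron())
  syn2 <- synapse_model(parameters = "max_age = 1.0 : postsynaptic",
                        equations = "age = age + dt",
                        pruning = "age > max_age : proba = 0.5")
  pj2 <- projection(net2, a2, b2, "exc", model = syn2)
  connect_all_to_all(pj2, 1.0)
  n0 <- synapse_count(pj2)
  compile_network(net2)
  simulate(net2, 2)          # ages exceed max_age
  start_pruning(pj2)
  simulate(net2, 1)
  pruned <- n0 - synapse_count(pj2)
  # z-test against Binomial(n0, 0.5), alpha = 0.01
  z <- (pruned - 0.5 * n0) / sqrt(n0 * 0.25)
  expect_lt(abs(z), qnorm(0.995))

  # probability 0 changes nothing
  net3 <- network(dt = 1, seed = 5)
  a3 <- population(net3, 10L, hold_neuron())
  b3 <- population(net3, 10L, rate_neuron())
  syn3 <- synapse_model(equations = "age = age + dt",
                        pruning = "age > 0.0 : proba = 0.0")
  pj3 <- projection(net3, a3, b3, "exc", model = syn3)
  connect_all_to_all(pj3, 1.0)
  compile_network(net3)
  start_pruning(pj3)
  simulate(net3, 5)
  expect_equal(synapse_count(pj3), 100L)
})

test_that("creating rules cannot reference per-synapse state", {
  expect_error(
    synapse_model(equations = "age = age + dt",
                  creating = "age > 10.0"),
    "per-synapse")
})
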