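# The seven-stage step: propagation, neural update, spike emission, reset,
# refractoriness, monitors, stop conditions and determinism.

test_that("a leaky rate neuron decays geometrically under explicit Euler", {
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 1L, neuron_model(
    parameters = "tau = 10.0 : population",
    equations = "tau * dr/dt + r = sum(exc) : init = 1.0"))
  for (k in 1:5) {
    simulate(net, 1)
    expect_equal(pop$r, (1 - 0.1)^k, tolerance = 1e-12)
  }
})

test_that("pre-spike increments arrive exactly one step after emission", {
  net <- network(dt = 1, seed = 1)
  A <- spike_source_array(net, list(c(5)))
  B <- population(net, 1L, receiver_neuron(tau = 5))
  pj <- projection(net, A, B, "exc")
  connect_all_to_all(pj, 2.0)
  g_trace <- numeric(0)
  spk_trace <- logical(0)
  for (k in 1:8) {
    simulate(net, 1)
    g_trace <- c(g_trace, B$g_exc)
    spk_trace <- c(spk_trace, A[["last_spiked"]])
  }
  # A fires during the step labelled t = 5 (6th step)
  expect_equal(which(spk_trace), 6L)
  # g_exc must be zero through that step and jump at the next one, never
  # the same step
  expect_equal(g_trace[1:6], rep(0, 6))
  expect_equal(g_trace[7], 2 * exp(-1 / 5), tolerance = 1e-12)
})

test_that("an empty network still advances its clock", {
  net <- network(dt = 0.5, seed = 1)
  simulate(net, 5)
  expect_equal(net_time(net), 5)
  expect_equal(net[["step"]], 10L)
})

test_that("input sums aggregate psp under the declared operator", {
  make <- function(operator) {
    net <- network(dt = 1, seed = 1)
    src <- population(net, 2L, hold_neuron())
    tgt <- population(net, 2L, rate_neuron())
    model <- if (operator == "sum") NULL else
      synapse_model(operator = operator)
    pj <- projection(net, src, tgt, "exc", model = model)
    # both sources onto post 0 only; post 1 has no synapses
    connect_from_function(pj, function(pre, post)
      data.frame(pre = c(0, 1), post = c(0, 0),
                 w = if (operator == "sum") c(0.5, 0.5) else c(1, 1)))
    compile_network(net)
    set_attribute(src, "r", c(1, 3))
    simulate(net, 2)   # let the rates propagate
    compute_input_sums(pj)
  }
  expect_equal(make("sum"), c(2, 0))
  expect_equal(make("max"), c(3, 0))
  expect_equal(make("min"), c(1, 0))
  expect_equal(make("mean"), c(2, 0))
})

test_that("spike emission applies reset statements and refractoriness", {
  # Izhikevich-style reset
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 2L, standard_neuron("Izhikevich"))
  set_attribute(pop, "i_offset", c(10, 0))
  simulate(net, 200)
  mon <- monitor(net, pop, "spike")
  simulate(net, 200)
  sp <- monitor_get(mon, "spike")
  expect_gt(sum(sp$rank == 0), 3)     # driven unit fires tonically
  expect_equal(sum(sp$rank == 1), 0)  # undriven unit stays silent
  # after each spike v was reset to c and u incremented by d
  expect_lt(max(pop$v), 30 + 1e-9)

  # refractory period: 2 ms at dt = 0.1 -> 20 frozen steps, conductances
  # keep decaying
  net2 <- network(dt = 0.1, seed = 1)
  m <- neuron_model(
    parameters = "tau = 5.0 : population",
    equations = "tau * dg_exc/dt = -g_exc : exponential
                 dv/dt = 10.0 : init = 0.0",
    spike = "v > 1.0", reset = "v = 0.0", refractory = 2.0)
  pop2 <- population(net2, 1L, m)
  set_attribute(pop2, "g_exc", 1.0)
  compile_network(net2)
  v_trace <- g_trace <- numeric(0)
  for (k in 1:40) {
    simulate(net2, 0.1)
    v_trace <- c(v_trace, pop2$v)
    g_trace <- c(g_trace, pop2$g_exc)
  }
  # v ramps 1 unit/ms, crosses 1.0 at step 2 (v would be 1.1), resets
  first_spike <- which(diff(v_trace) < 0)[1] + 1
  expect_equal(v_trace[first_spike], 0)
  # the following 20 steps are frozen at the reset value
  expect_equal(v_trace[first_spike + 1:20], rep(0, 20))
  expect_gt(v_trace[first_spike + 21], 0)
  # conductance decays throughout, including the refractory span
  expect_equal(g_trace, exp(-(1:40) * 0.1 / 5), tolerance = 1e-9)
})

test_that("simulate counts steps and splitting a run preserves the state bit-for-bit", {
  run <- function(chunks) {
    net <- network(dt = 1, seed = 77)
    pop <- population(net, 50L, standard_neuron("Izhikevich"))
    set_attribute(pop, "noise", 5.0)
    set_attribute(pop, "i_offset", 4.0)
    for (d in chunks) simulate(net, d)
    pop_state(pop)
  }
  expect_identical(run(1000), run(c(500, 500)))
  expect_identical(run(1000), run(rep(100, 10)))

  net <- network(dt = 1, seed = 1)
  population(net, 1L, hold_neuron())
  simulate(net, 0)
  expect_equal(net[["step"]], 0L)
  simulate(net, 1000)
  expect_equal(net[["step"]], 1000L)
  expect_error(simulate(net, -1), ">= 0")
})

test_that("simulate_until stops on any/all quantified conditions", {
  ramp <- neuron_model(equations = "r += 0.1")
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 1L, ramp, stop_condition = "r > 1.0")
  expect_equal(simulate_until(net, 100, pop), 11)
  expect_equal(pop$r, 1.1, tolerance = 1e-12)

  # never met: runs to the maximal duration
  net2 <- network(dt = 1, seed = 1)
  pop2 <- population(net2, 1L, hold_neuron(), stop_condition = "r > 1.0")
  expect_equal(simulate_until(net2, 50, pop2), 50)

  # ": all" waits for the slowest unit
  net3 <- network(dt = 1, seed = 1)
  m3 <- neuron_model(parameters = "slope = 0.1", equations = "r += slope")
  pop3 <- population(net3, 2L, m3, stop_condition = "r > 1.0 : all")
  set_attribute(pop3, "slope", c(0.2, 0.07))
  expect_equal(simulate_until(net3, 100, pop3), 15)
})

test_that("monitors record at the requested period and drain on get", {
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 3L, neuron_model(
    parameters = "tau = 10.0 : population",
    equations = "tau * dr/dt + r = sum(exc) : init = 1.0"))
  mon <- monitor(net, pop, "r", period = 10)
  simulate(net, 100)
  rec <- monitor_get(mon, "r")
  expect_equal(nrow(rec), 10L)
  expect_equal(ncol(rec), 3L)
  expect_equal(as.numeric(rownames(rec)), seq(10, 100, by = 10))
  expect_equal(unname(rec[1, 1]), 0.9^10, tolerance = 1e-12)
  # drained
  expect_equal(nrow(monitor_get(mon, "r")), 0L)
  # pause/resume
  monitor_pause(mon)
  simulate(net, 50)
  expect_equal(nrow(monitor_get(mon, "r")), 0L)
  monitor_resume(mon)
  simulate(net, 50)
  expect_equal(nrow(monitor_get(mon, "r")), 5L)
})

test_that("a recorded membrane trace matches a stand-alone scalar oracle", {
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 1L, standard_neuron("Izhikevich"))
  set_attribute(pop, "i_offset", 10)
  mon <- monitor(net, pop, c("v", "u"))
  simulate(net, 300)
  rec <- monitor_get(mon)
  # scalar reimplementation of the same update (explicit Euler, same stage
  # order: I first, then simultaneous v/u increments, then spike/reset)
  v <- -65; u <- -13; vs <- us <- numeric(300)
  for (k in 1:300) {
    I <- 10
    dv <- 0.04 * v^2 + 5 * v + 140 - u + I
    du <- 0.02 * (0.2 * v - u)
    v <- v + dv; u <- u + du
    if (v > 30) { v <- -65; u <- u + 8 }
    vs[k] <- v; us[k] <- u
  }
  expect_equal(as.numeric(rec$v), vs, tolerance = 1e-9)
  expect_equal(as.numeric(rec$u), us, tolerance = 1e-9)
})

test_that("undeclared conductances reset each step, declared ones decay", {
  # instantaneous (undeclared) conductance: zero after every update
  net <- network(dt = 1, seed = 1)
  A <- spike_source_array(net, list(c(2, 3)))
  B <- population(net, 1L, neuron_model(
    equations = "dv/dt = g_exc", spike = "v > 1e9"))
  pj <- projection(net, A, B, "exc")
  connect_all_to_all(pj, 1.5)
  v_prev <- 0
  for (k in 1:6) {
    simulate(net, 1)
    expect_equal(B$g_exc, 0)   # reset for the next step
    v_prev <- c(v_prev, B$v)
  }
  # but each arriving spike contributed one step of integration
  expect_equal(B$v, 3.0)

  # declared conductance follows its exponential between spikes
  net2 <- network(dt = 1, seed = 1)
  A2 <- spike_source_array(net2, list(c(2)))
  B2 <- population(net2, 1L, receiver_neuron(tau = 7))
  pj2 <- projection(net2, A2, B2, "exc")
  connect_all_to_all(pj2, 1.0)
  g <- numeric(0)
  for (k in 1:8) { simulate(net2, 1); g <- c(g, B2$g_exc) }
  arrival <- which(g > 0)[1]
  decay <- g[arrival:8]
  expect_equal(decay, decay[1] * exp(-(seq_along(decay) - 1) / 7),
               tolerance = 1e-9)
})

test_that("min/max bounds clamp variables at every observable point", {
  net <- network(dt = 1, seed = 6)
  pop <- population(net, 100L, neuron_model(
    equations = "r = r + Normal(0.0, 2.0) : min = 0.0, max = 1.0"))
  mon <- monitor(net, pop, "r")
  simulate(net, 50)
  rec <- monitor_get(mon, "r")
  expect_true(all(rec >= 0 & rec <= 1))
})

test_that("referencing a target with no incoming projection contributes zero", {
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 1L, neuron_model(
    equations = "r = sum(exc) + sum(ghost) + 1.0"))
  simulate(net, 2)
  expect_equal(pop$r, 1.0)
})

test_that("the NaN guard aborts and names the offending variable", {
  net <- network(dt = 1, seed = 1, debug = TRUE)
  pop <- population(net, 1L, neuron_model(
    equations = "r = r + 1.0\nq = log(-1.0) * 0.0 + sqrt(0.0 - r)"),
    name = "bad")
  expect_error(suppressWarnings(simulate(net, 5)), "bad.*q|q.*bad")
})

test_that("deleting and re-running with one seed reproduces recordings", {
  run <- function() {
    net <- network(dt = 1, seed = 31)
    pop <- population(net, 20L, standard_neuron("Izhikevich"))
    set_attribute(pop, "noise", 3.0)
    set_attribute(pop, "i_offset", 5.0)
    mon <- monitor(net, pop, "spike")
    simulate(net, 300)
    monitor_get(mon, "spike")
  }
  expect_identical(run(), run())
})
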