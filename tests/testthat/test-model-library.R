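# Library of standard neuron and synapse models: every entry must parse and
# simulate; the plasticity rules must match their analytic event semantics.

test_that("every registered model parses cleanly and simulates 100 steps", {
  reg <- standard_models()
  for (nm in reg$neurons) {
    model <- standard_neuron(nm)
    dt <- if (nm == "HH_cond_exp") 0.01 else 0.1
    net <- network(dt = dt, seed = 1)
    pop <- population(net, 5L, model)
    expect_no_error(simulate(net, 100 * dt))
    expect_true(all(vapply(pop[["storage"]], function(v)
      all(is.finite(v)), logical(1))), info = nm)
  }
  for (nm in reg$synapses) {
    model <- standard_synapse(nm)
    net <- network(dt = 0.1, seed = 1)
    spiking <- nm %in% c("STP", "STDP", "NMDA")
    pre <- if (spiking) poisson_population(net, 5L, rates = 20)
           else population(net, 5L, hold_neuron())
    post <- if (spiking) population(net, 5L, receiver_neuron())
            else population(net, 5L, rate_neuron())
    pj <- projection(net, pre, post, "exc", model = model)
    connect_all_to_all(pj, 0.5)
    expect_no_error(simulate(net, 10))
  }
})

test_that("Izhikevich with excitatory defaults fires regularly under constant current", {
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 1L, standard_neuron("Izhikevich"))
  set_attribute(pop, "i_offset", 10)
  mon <- monitor(net, pop, "spike")
  simulate(net, 500)
  sp <- monitor_get(mon, "spike")
  isi <- diff(sp$time_ms)
  expect_gt(nrow(sp), 5)
  # tonic firing: inter-spike intervals settle to a constant
  expect_lt(stats::sd(tail(isi, 5)), 1e-9)
})

test_that("the leaky integrator decays to zero without input", {
  net <- network(dt = 1, seed = 1)
  pop <- population(net, 3L, standard_neuron("LeakyIntegrator"))
  set_attribute(pop, "r", 1.0)
  simulate(net, 200)
  expect_equal(pop$r, rep(0, 3), tolerance = 1e-8)
})

test_that("IF_cond_exp responds to one spike with the analytic double exponential", {
  dt <- 0.01
  net <- network(dt = dt, seed = 1)
  src <- spike_source_array(net, list(c(5)))
  pop <- population(net, 1L, standard_neuron("IF_cond_exp"))
  w <- 0.001   # small conductance: linear regime
  pj <- projection(net, src, pop, "exc")
  connect_all_to_all(pj, w)
  mon <- monitor(net, pop, "v")
  simulate(net, 40)
  v <- as.numeric(monitor_get(mon, "v"))
  dv <- v + 65
  arrival <- which(dv > 1e-12)[1]
  tau_m <- 20; tau_s <- 5; e_rev <- 0; v_rest <- -65; cm <- 1
  tt <- (seq_along(v) - arrival) * dt
  oracle <- ifelse(tt < 0, 0,
                   (e_rev - v_rest) * w / cm * (exp(-tt / tau_m) - exp(-tt / tau_s)) /
                     (1 / tau_s - 1 / tau_m))
  peak <- max(oracle)
  expect_lt(max(abs(dv - oracle)) / peak, 0.01)
})

test_that("STP event updates follow the literal increment sequencing", {
  # first spike with u = x = init: conductance increment uses pre-update
  # values, then x is depleted with the pre-update u and u facilitates
  net <- network(dt = 1, seed = 1)
  pre <- spike_source_array(net, list(c(5, 10)))
  post <- population(net, 1L, receiver_neuron(tau = 1e6))
  stp <- standard_synapse("STP")
  pj <- projection(net, pre, post, "exc", model = stp)
  connect_all_to_all(pj, 1.0)
  set_attribute(pj, "tau_facil", 1e9)  # freeze facilitation between spikes
  set_attribute(pj, "tau_rec", 1e9)    # freeze recovery between spikes
  simulate(net, 8)
  # after the first spike: increment w*0.5*1; x <- 1*(1-0.5); u <- 0.75
  # (tolerances reflect the large-but-finite freezing time constants)
  expect_equal(pj$x, 0.5, tolerance = 1e-6)
  expect_equal(pj$u, 0.75, tolerance = 1e-6)
  g1 <- post$g_exc
  expect_equal(g1, 0.5, tolerance = 1e-4)
  simulate(net, 5)
  # second spike: increment w*0.75*0.5; x <- 0.5*(1-0.75)
  expect_equal(pj$x, 0.125, tolerance = 1e-6)
  expect_equal(post$g_exc - g1, 0.75 * 0.5, tolerance = 1e-4)
})

test_that("without spikes the STP variables relax to their fixed points", {
  sol <- build_event_solution(
    parse_variables("dx/dt = (1.0 - x)/tau_rec
                     du/dt = (U - u)/tau_facil", scope = "synapse"),
    state_names = c("x", "u"))
  st <- advance_event(list(x = 0.1, u = 0.9, tau_rec = 100, tau_facil = 50,
                           U = 0.5), 0, 1e7, sol)
  expect_equal(st$state$x, 1, tolerance = 1e-9)
  expect_equal(st$state$u, 0.5, tolerance = 1e-9)
})

test_that("IBCM converges to its fixed point under constant unit rates", {
  net <- network(dt = 1, seed = 1)
  pre <- population(net, 1L, hold_neuron())
  post <- population(net, 1L, hold_neuron())
  ib <- standard_synapse("IBCM")
  pj <- projection(net, pre, post, "exc", model = ib)
  connect_all_to_all(pj, 0.5)
  set_attribute(pj, "tau", 50)
  set_attribute(pre, "r", 1.0)
  set_attribute(post, "r", 1.0)
  simulate(net, 1000)
  theta_end <- pj$theta[1]
  expect_equal(theta_end, 1.0, tolerance = 1e-6)   # E[y^2] = 1
  w1 <- pj$w
  simulate(net, 100)
  expect_equal(pj$w, w1, tolerance = 1e-5)          # dw/dt -> 0
})

test_that("STDP traces at a pre/post pair match the analytic event sequence", {
  # pre at t, post at t + 10 ms: potentiation by A_plus w_max e^(-10/20)
  run_pair <- function(tpre, tpost) {
    net <- network(dt = 1, seed = 1)
    pre <- spike_source_array(net, list(c(tpre)))
    post <- spike_source_array(net, list(c(tpost)))
    pj <- projection(net, pre, post, "exc",
                     model = standard_synapse("STDP"))
    connect_all_to_all(pj, 0.5)
    simulate(net, max(tpre, tpost) + 5)
    pj$w - 0.5
  }
  expect_equal(run_pair(10, 20), 0.01 * exp(-10 / 20), tolerance = 1e-12)
  expect_equal(run_pair(20, 10), -0.01 * exp(-10 / 20), tolerance = 1e-12)
  # zero traces: an isolated pre event leaves w unchanged
  expect_equal(run_pair(10, 1000), 0, tolerance = 1e-12)
})

test_that("the STDP window recovered from isolated pairs has the declared time constants", {
  dts <- setdiff(seq(-40, 40, by = 5), 0)
  dw <- vapply(dts, function(d) {
    net <- network(dt = 1, seed = 1)
    t0 <- 50
    pre <- spike_source_array(net, list(c(t0)))
    post <- spike_source_array(net, list(c(t0 + d)))
    pj <- projection(net, pre, post, "exc",
                     model = standard_synapse("STDP"))
    connect_all_to_all(pj, 0.5)
    simulate(net, 120)
    pj$w - 0.5
  }, numeric(1))
  ltp <- dts > 0
  fit_p <- stats::lm(log(dw[ltp]) ~ dts[ltp])
  tau_p <- -1 / coef(fit_p)[2]
  fit_m <- stats::lm(log(-dw[!ltp]) ~ dts[!ltp])
  tau_m <- 1 / coef(fit_m)[2]
  expect_equal(unname(tau_p), 20, tolerance = 0.02)
  expect_equal(unname(tau_m), 20, tolerance = 0.02)
  # exponential LTP/LTD windows: signs split at zero lag
  expect_true(all(dw[ltp] > 0) && all(dw[!ltp] < 0))
})

test_that("event-driven trajectories match dense integration at every event", {
  # fixed pre/post spike trains; compare STDP at each event against a dense
  # (dt = 0.001 ms) scalar integration of the traces with the same event
  # times (pre events at arrival = spike + delay, post events at spike + dt)
  set.seed(42)
  pre_times <- sort(sample(5:400, 8))
  post_times <- sort(sample(5:400, 8))
  net <- network(dt = 1, seed = 1)
  pre <- spike_source_array(net, list(pre_times))
  post <- spike_source_array(net, list(post_times))
  pj <- projection(net, pre, post, "exc", model = standard_synapse("STDP"))
  connect_all_to_all(pj, 0.5)
  simulate(net, 450)

  # dense oracle
  tau <- 20; A <- 0.01; wmax <- 1
  events <- rbind(data.frame(t = pre_times + 1, kind = "pre"),
                  data.frame(t = post_times + 1, kind = "post"))
  events <- events[order(events$t, events$kind != "pre"), ]
  Apre <- Apost <- 0; w <- 0.5; t_last <- 0
  for (i in seq_len(nrow(events))) {
    el <- events$t[i] - t_last
    Apre <- dense_linear(Apre, -1 / tau, 0, el)
    Apost <- dense_linear(Apost, -1 / tau, 0, el)
    t_last <- events$t[i]
    if (events$kind[i] == "pre") {
      Apre <- Apre + A * wmax
      w <- min(max(w - Apost, 0), wmax)
    } else {
      Apost <- Apost + A * wmax
      w <- min(max(w + Apre, 0), wmax)
    }
  }
  expect_equal(pj$w, w, tolerance = 1e-5)
  expect_equal(pj$Apre, Apre, tolerance = 1e-5)
  expect_equal(pj$Apost, Apost, tolerance = 1e-5)

  # STP under a 10 Hz Poisson-like train
  stp_times <- sort(sample(5:900, 10))
  net2 <- network(dt = 1, seed = 1)
  pre2 <- spike_source_array(net2, list(stp_times))
  post2 <- population(net2, 1L, receiver_neuron())
  pj2 <- projection(net2, pre2, post2, "exc", model = standard_synapse("STP"))
  connect_all_to_all(pj2, 1.0)
  simulate(net2, 950)
  x <- 1; u <- 0.5; t_last <- 0
  for (ts in stp_times + 1) {
    el <- ts - t_last
    x <- dense_linear(x, -1 / 100, 1 / 100, el)
    u <- dense_linear(u, -1 / 0.01, 0.5 / 0.01, el)
    t_last <- ts
    x_new <- x * (1 - u)
    u <- u + 0.5 * (1 - u)
    x <- x_new
  }
  expect_equal(pj2$x, x, tolerance = 1e-5)
  expect_equal(pj2$u, u, tolerance = 1e-5)
})

test_that("the NMDA conductance stays in [0, 1] under random stimulation", {
  net <- network(dt = 0.5, seed = 13)
  pre <- poisson_population(net, 20L, rates = 80)
  post <- population(net, 1L, receiver_neuron())
  pj <- projection(net, pre, post, "exc", model = standard_synapse("NMDA"))
  connect_all_to_all(pj, 2.0)
  compile_network(net)
  ok <- TRUE
  for (k in 1:200) {
    simulate(net, 0.5)
    g <- pj$g
    ok <- ok && all(g >= 0 & g <= 1)
  }
  expect_true(ok)
  expect_gt(max(pj$g), 0)   # stimulation actually drove the synapse
})

test_that("unknown model names raise informative errors", {
  expect_error(standard_neuron("NoSuch"), "unknown standard neuron")
  expect_error(standard_synapse("NoSuch"), "unknown standard synapse")
  expect_type(model_text("Izhikevich"), "list")
})
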