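# Reference networks.
#
# Three complete example networks exercise the whole engine and provide the
# synthetic inputs for the test suite and the acceptance script:
#   * the pulse-coupled Izhikevich network (1000 neurons, 800 excitatory /
#     200 inhibitory, all-to-all, heterogeneous parameters),
#   * the conductance-based integrate-and-fire (COBA) benchmark network
#     (4000 neurons, 3200/800 split, 2% random connectivity, dt = 0.1 ms),
#   * a hybrid encode/decode demo (stepped rate source -> Poisson encoder ->
#     sliding-window decoder).

#' Pulse-coupled Izhikevich network
#'
#' 1000 Izhikevich neurons split into 800 excitatory and 200 inhibitory
#' units, reciprocally all-to-all connected.  Following the original
#' pulse-coupled recipe, excitatory units draw `c = -65 + 15 e^2`,
#' `d = 8 - 6 e^2` (e uniform in `[0,1]`) and receive noise amplitude 5;
#' inhibitory units draw `a = 0.02 + 0.08 i`, `b = 0.25 - 0.05 i` with noise
#' amplitude 2.  Weight ranges are exposed as parameters with the
#' conventional defaults (excitatory `U(0, 0.5)`, inhibitory `U(0, 1)` into
#' `g_inh`).
#'
#' @param seed Network seed.
#' @param weight_exc,weight_inh Weight initializers.
#' @param noise_exc,noise_inh Noise amplitudes (multiplying a standard
#'   normal draw per step and unit).
#' @param dt Step in ms.
#' @return List with `net`, `pop`, views `exc`/`inh`, the projections and a
#'   spike monitor `mon`.
#' @export
build_izhikevich_net <- function(seed = 42, weight_exc = Uniform(0, 0.5),
                                 weight_inh = Uniform(0, 1.0),
                                 noise_exc = 5.0, noise_inh = 2.0, dt = 1.0) {
  net <- network(dt = dt, seed = seed)
  pop <- population(net, 1000L, standard_neuron("Izhikevich"))
  exc <- pop[1:800]
  inh <- pop[801:1000]
  with_net_rng(net, {
    re <- stats::runif(800)
    ri <- stats::runif(200)
  })
  set_attribute(exc, "c", -65 + 15 * re^2)
  set_attribute(exc, "d", 8 - 6 * re^2)
  set_attribute(exc, "noise", noise_exc)
  set_attribute(inh, "a", 0.02 + 0.08 * ri)
  set_attribute(inh, "b", 0.25 - 0.05 * ri)
  set_attribute(inh, "noise", noise_inh)
  proj_exc <- projection(net, exc, pop, "exc")
  connect_all_to_all(proj_exc, weight_exc)
  proj_inh <- projection(net, inh, pop, "inh")
  connect_all_to_all(proj_inh, weight_inh)
  mon <- monitor(net, pop, "spike")
  list(net = net, pop = pop, exc = exc, inh = inh,
       proj_exc = proj_exc, proj_inh = proj_inh, mon = mon)
}

# Conductance-based integrate-and-fire neuron of the COBA benchmark.
# Physiological constants follow the standard benchmark description
# (pF / nS / mV / ms unit system): leak 10 nS to -60 mV, C = 200 pF
# (membrane tau 20 ms), threshold -50 mV, reset -60 mV, refractory 5 ms,
# exponentially decaying conductances (5 / 10 ms) with reversal potentials
# 0 / -80 mV.
coba_constants <- function() {
  list(C = 200, gL = 10, El = -60, Ee = 0, Ei = -80,
       taue = 5, taui = 10, Vt = -50, Vr = -60, refractory = 5,
       we = 6, wi = 67, v_init = c(-60, -50))
}

coba_neuron <- function(k = coba_constants()) {
  neuron_model(
    parameters = sprintf("
      C = %g : population
      gL = %g : population
      El = %g : population
      Ee = %g : population
      Ei = %g : population
      taue = %g : population
      taui = %g : population
      Vt = %g : population
      Vr = %g : population
      I = 0.0",
      k$C, k$gL, k$El, k$Ee, k$Ei, k$taue, k$taui, k$Vt, k$Vr),
    equations = sprintf("
      C * dv/dt = gL * (El - v) + g_exc * (Ee - v) + g_inh * (Ei - v) + I : init = %g
      taue * dg_exc/dt = -g_exc : exponential
      taui * dg_inh/dt = -g_inh : exponential", k$El),
    spike = "v > Vt",
    reset = "v = Vr",
    refractory = k$refractory,
    name = "COBA integrate-and-fire")
}

#' Conductance-based integrate-and-fire benchmark network
#'
#' `round(4000 * scale)` neurons (80% excitatory, 20% inhibitory) with
#' exponentially decaying conductance-based synapses, randomly connected
#' with probability 0.02 at dt = 0.1 ms and 0.1 ms delays.  Membrane
#' potentials start uniformly between reset and threshold.  When
#' `connectivity_dir` is given, the connectivity matrices are written there
#' on first use and reloaded afterwards, so several runs share identical
#' matrices.
#'
#' @param seed Network seed.
#' @param scale Size multiplier (1 = 4000 neurons).
#' @param dt Step in ms.
#' @param connectivity_dir Optional directory for shared connectivity files.
#' @param zero_weights Build with zero synaptic weights (leak dynamics only).
#' @param weight_scale Multiplier on the synaptic weights; scaled-down
#'   networks need stronger synapses (fewer inputs per neuron) to remain in
#'   the self-sustained regime, so `1 / scale` is a reasonable choice there.
#' @return List with `net`, `pop`, views `exc`/`inh`, projections and a
#'   spike monitor `mon`.
#' @export
build_coba_net <- function(seed = 42, scale = 1.0, dt = 0.1,
                           connectivity_dir = NULL, zero_weights = FALSE,
                           weight_scale = 1.0) {
  stopifnot(scale > 0)
  k <- coba_constants()
  n <- as.integer(round(4000 * scale))
  ne <- as.integer(round(0.8 * n))
  net <- network(dt = dt, seed = seed)
  pop <- population(net, n, coba_neuron(k))
  set_attribute(pop, "v", Uniform(k$v_init[1], k$v_init[2]))
  if (!zero_weights) {
    # randomized initial conductances kick the self-sustained regime
    set_attribute(pop, "g_exc", Uniform(0, 8 * k$we * weight_scale))
    set_attribute(pop, "g_inh", Uniform(0, 4 * k$wi * weight_scale))
  }
  exc <- pop[seq_len(ne)]
  inh <- pop[(ne + 1):n]
  we <- if (zero_weights) 0 else k$we * weight_scale
  wi <- if (zero_weights) 0 else k$wi * weight_scale
  proj_e <- projection(net, exc, pop, "exc")
  proj_i <- projection(net, inh, pop, "inh")
  f_e <- if (!is.null(connectivity_dir)) {
    file.path(connectivity_dir, sprintf("coba_exc_s%s_n%d.txt", seed, n))
  }
  f_i <- if (!is.null(connectivity_dir)) {
    file.path(connectivity_dir, sprintf("coba_inh_s%s_n%d.txt", seed, n))
  }
  if (!is.null(f_e) && file.exists(f_e) && file.exists(f_i)) {
    connect_from_file(proj_e, f_e)
    connect_from_file(proj_i, f_i)
    if (zero_weights) {
      set_attribute(proj_e, "w", 0)
      set_attribute(proj_i, "w", 0)
    }
  } else {
    connect_fixed_probability(proj_e, 0.02, we, delays = dt)
    connect_fixed_probability(proj_i, 0.02, wi, delays = dt)
    if (!is.null(f_e)) {
      save_connectivity(proj_e, f_e)
      save_connectivity(proj_i, f_i)
    }
  }
  mon <- monitor(net, pop, "spike")
  list(net = net, pop = pop, exc = exc, inh = inh,
       proj_exc = proj_e, proj_inh = proj_i, mon = mon)
}

#' Hybrid encode/decode demo
#'
#' A single rate-coded source steps through 0, 10, 50 and 100 Hz (250 ms
#' each), drives a Poisson encoder of `n_encode` units through unit weights,
#' and a sliding-window decoding projection (window `window` ms) reads the
#' spikes back into a single rate-coded neuron.
#'
#' @param seed Network seed.
#' @param n_encode Number of Poisson units.
#' @param n_decode Number of units feeding the decoder (first `n_decode`
#'   encoder units; default all).
#' @param window Decoding window in ms.
#' @param levels Rates of the four 250 ms steps, in Hz.
#' @return List with `net`, `source`, `encoder`, `decoder` populations, the
#'   projections, a spike monitor `mon_spikes` and a rate monitor `mon_rate`.
#' @export
build_hybrid_demo <- function(seed = 42, n_encode = 1000L,
                              n_decode = n_encode, window = 10,
                              levels = c(0, 10, 50, 100)) {
  net <- network(dt = 1.0, seed = seed)
  schedule <- sprintf(
    "r = if t < 250.0: %g else: if t < 500.0: %g else: if t < 750.0: %g else: %g",
    levels[1], levels[2], levels[3], levels[4])
  source <- population(net, 1L, neuron_model(equations = schedule,
                                             name = "stepped rate source"))
  encoder <- poisson_population(net, n_encode, target = "exc")
  enc_in <- projection(net, source, encoder, "exc")
  connect_all_to_all(enc_in, 1.0)
  decoder <- population(net, 1L, neuron_model(equations = "r = sum(exc)",
                                              name = "decoder readout"))
  dec <- decoding_projection(net, encoder[seq_len(n_decode)], decoder, "exc",
                             window = window)
  connect_all_to_all(dec, 1.0)
  mon_spikes <- monitor(net, encoder, "spike")
  mon_rate <- monitor(net, decoder, "r")
  list(net = net, source = source, encoder = encoder, decoder = decoder,
       enc_in = enc_in, dec = dec,
       mon_spikes = mon_spikes, mon_rate = mon_rate)
}

#' Run the hybrid demo and measure decoding errors
#'
#' Simulates the four 250 ms steps and computes the relative decoding error
#' for each non-zero level over its 250 ms segment.
#'
#' @inheritParams build_hybrid_demo
#' @return List with `trace` (decoded rate per ms), `spikes` (event data
#'   frame), and `epsilon` (named vector of decoding errors per level).
#' @export
run_hybrid_demo <- function(seed = 42, n_encode = 1000L,
                            n_decode = n_encode, window = 10,
                            levels = c(0, 10, 50, 100)) {
  fx <- build_hybrid_demo(seed, n_encode, n_decode, window, levels)
  simulate(fx$net, 1000)
  trace <- as.vector(monitor_get(fx$mon_rate, "r"))
  spikes <- monitor_get(fx$mon_spikes, "spike")
  eps <- numeric(0)
  for (i in seq_along(levels)) {
    if (levels[i] <= 0) next
    seg <- trace[((i - 1) * 250 + 1):(i * 250)]
    eps[[as.character(levels[i])]] <- decoding_error(seg, levels[i], dt = 1,
                                                     horizon_ms = 250)
  }
  list(trace = trace, spikes = spikes, epsilon = eps, fixture = fx)
}
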