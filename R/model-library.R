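# Library of standard neuron and synapse models.
#
# Spiking neurons follow the PyNN nomenclature (IF_curr_exp, IF_cond_exp,
# alpha-shaped variants, adaptive-exponential and Hodgkin-Huxley models,
# Izhikevich); the rate-coded side provides a noisy leaky integrator.
# Synapses cover the Hebbian family (Hebb, Oja, IBCM), short-term plasticity,
# the online STDP rule and the non-linear NMDA synapse.  Each entry is a
# plain text block fed to neuron_model()/synapse_model(), so the models also
# serve as reference DSL examples (model_text() exposes the sources).
#
# Conventions: membrane potentials in mV, times in ms; for the
# conductance-based models capacitances are in nF and conductances in uS so
# cm / g is in ms.  Alpha-shaped synapses use the conductance g_<target> as
# the spike-incremented auxiliary and shape the current in alpha_<target>
# (peak w at t = tau_syn after an isolated spike).

rs_neuron_library <- list(

  LeakyIntegrator = list(
    parameters = "
      tau = 10.0 : population
      B = 0.0
      noise = 0.0",
    equations = "
      tau * dr/dt + r = sum(exc) - sum(inh) + B + noise * Uniform(-1.0, 1.0) : min = 0.0"
  ),

  Izhikevich = list(
    parameters = "
      a = 0.02
      b = 0.2
      c = -65.0
      d = 8.0
      v_thresh = 30.0 : population
      i_offset = 0.0
      noise = 0.0",
    equations = "
      I = g_exc - g_inh + noise * Normal(0.0, 1.0) + i_offset
      dv/dt = 0.04 * v^2 + 5.0 * v + 140.0 - u + I : init = -65.0
      du/dt = a * (b * v - u) : init = -13.0",
    spike = "v > v_thresh",
    reset = "v = c
             u += d"
  ),

  IF_curr_exp = list(
    parameters = "
      v_rest = -65.0 : population
      cm = 1.0 : population
      tau_m = 20.0 : population
      tau_refrac = 0.1 : population
      tau_syn_E = 5.0 : population
      tau_syn_I = 5.0 : population
      v_thresh = -50.0 : population
      v_reset = -65.0 : population
      i_offset = 0.0",
    equations = "
      cm * dv/dt = cm / tau_m * (v_rest - v) + g_exc - g_inh + i_offset : init = -65.0
      tau_syn_E * dg_exc/dt = -g_exc : exponential
      tau_syn_I * dg_inh/dt = -g_inh : exponential",
    spike = "v > v_thresh",
    reset = "v = v_reset",
    refractory = "tau_refrac"
  ),

  IF_cond_exp = list(
    parameters = "
      v_rest = -65.0 : population
      cm = 1.0 : population
      tau_m = 20.0 : population
      tau_refrac = 0.1 : population
      tau_syn_E = 5.0 : population
      tau_syn_I = 5.0 : population
      e_rev_E = 0.0 : population
      e_rev_I = -70.0 : population
      v_thresh = -50.0 : population
      v_reset = -65.0 : population
      i_offset = 0.0",
    equations = "
      cm * dv/dt = cm / tau_m * (v_rest - v) + g_exc * (e_rev_E - v) + g_inh * (e_rev_I - v) + i_offset : init = -65.0
      tau_syn_E * dg_exc/dt = -g_exc : exponential
      tau_syn_I * dg_inh/dt = -g_inh : exponential",
    spike = "v > v_thresh",
    reset = "v = v_reset",
    refractory = "tau_refrac"
  ),

  IF_curr_alpha = list(
    parameters = "
      v_rest = -65.0 : population
      cm = 1.0 : population
      tau_m = 20.0 : population
      tau_refrac = 0.1 : population
      tau_syn_E = 5.0 : population
      tau_syn_I = 5.0 : population
      v_thresh = -50.0 : population
      v_reset = -65.0 : population
      i_offset = 0.0",
    equations = "
      cm * dv/dt = cm / tau_m * (v_rest - v) + alpha_exc - alpha_inh + i_offset : init = -65.0
      tau_syn_E * dg_exc/dt = -g_exc : exponential
      tau_syn_E * dalpha_exc/dt = exp(1.0) * g_exc - alpha_exc : exponential
      tau_syn_I * dg_inh/dt = -g_inh : exponential
      tau_syn_I * dalpha_inh/dt = exp(1.0) * g_inh - alpha_inh : exponential",
    spike = "v > v_thresh",
    reset = "v = v_reset",
    refractory = "tau_refrac"
  ),

  IF_cond_alpha = list(
    parameters = "
      v_rest = -65.0 : population
      cm = 1.0 : population
      tau_m = 20.0 : population
      tau_refrac = 0.1 : population
      tau_syn_E = 5.0 : population
      tau_syn_I = 5.0 : population
      e_rev_E = 0.0 : population
      e_rev_I = -70.0 : population
      v_thresh = -50.0 : population
      v_reset = -65.0 : population
      i_offset = 0.0",
    equations = "
      cm * dv/dt = cm / tau_m * (v_rest - v) + alpha_exc * (e_rev_E - v) + alpha_inh * (e_rev_I - v) + i_offset : init = -65.0
      tau_syn_E * dg_exc/dt = -g_exc : exponential
      tau_syn_E * dalpha_exc/dt = exp(1.0) * g_exc - alpha_exc : exponential
      tau_syn_I * dg_inh/dt = -g_inh : exponential
      tau_syn_I * dalpha_inh/dt = exp(1.0) * g_inh - alpha_inh : exponential",
    spike = "v > v_thresh",
    reset = "v = v_reset",
    refractory = "tau_refrac"
  ),

  EIF_cond_exp_isfa_ista = list(
    parameters = "
      v_rest = -70.6 : population
      cm = 0.281 : population
      tau_m = 9.37 : population
      tau_refrac = 0.1 : population
      tau_syn_E = 5.0 : population
      tau_syn_I = 5.0 : population
      e_rev_E = 0.0 : population
      e_rev_I = -80.0 : population
      tau_w = 144.0 : population
      a = 4.0 : population
      b = 0.0805 : population
      delta_T = 2.0 : population
      v_thresh = -50.4 : population
      v_reset = -70.6 : population
      v_spike = -40.0 : population
      i_offset = 0.0",
    equations = "
      I = g_exc * (e_rev_E - v) + g_inh * (e_rev_I - v) + i_offset
      tau_m * dv/dt = (v_rest - v) + delta_T * exp((v - v_thresh) / delta_T) + tau_m / cm * (I - w) : init = -70.6
      tau_w * dw/dt = a * (v - v_rest) - w
      tau_syn_E * dg_exc/dt = -g_exc : exponential
      tau_syn_I * dg_inh/dt = -g_inh : exponential",
    spike = "v > v_spike",
    reset = "v = v_reset
             w += b",
    refractory = "tau_refrac"
  ),

  EIF_cond_alpha_isfa_ista = list(
    parameters = "
      v_rest = -70.6 : population
      cm = 0.281 : population
      tau_m = 9.37 : population
      tau_refrac = 0.1 : population
      tau_syn_E = 5.0 : population
      tau_syn_I = 5.0 : population
      e_rev_E = 0.0 : population
      e_rev_I = -80.0 : population
      tau_w = 144.0 : population
      a = 4.0 : population
      b = 0.0805 : population
      delta_T = 2.0 : population
      v_thresh = -50.4 : population
      v_reset = -70.6 : population
      v_spike = -40.0 : population
      i_offset = 0.0",
    equations = "
      I = alpha_exc * (e_rev_E - v) + alpha_inh * (e_rev_I - v) + i_offset
      tau_m * dv/dt = (v_rest - v) + delta_T * exp((v - v_thresh) / delta_T) + tau_m / cm * (I - w) : init = -70.6
      tau_w * dw/dt = a * (v - v_rest) - w
      tau_syn_E * dg_exc/dt = -g_exc : exponential
      tau_syn_E * dalpha_exc/dt = exp(1.0) * g_exc - alpha_exc : exponential
      tau_syn_I * dg_inh/dt = -g_inh : exponential
      tau_syn_I * dalpha_inh/dt = exp(1.0) * g_inh - alpha_inh : exponential",
    spike = "v > v_spike",
    reset = "v = v_reset
             w += b",
    refractory = "tau_refrac"
  ),

  HH_cond_exp = list(
    parameters = "
      gbar_Na = 20.0 : population
      gbar_K = 6.0 : population
      gL = 0.01 : population
      cm = 0.2 : population
      v_offset = -63.0 : population
      e_rev_Na = 50.0 : population
      e_rev_K = -90.0 : population
      e_rev_leak = -65.0 : population
      e_rev_E = 0.0 : population
      e_rev_I = -80.0 : population
      tau_syn_E = 0.2 : population
      tau_syn_I = 2.0 : population
      i_offset = 0.0",
    equations = "
      vprev = v : init = -65.0
      alpha_m = 0.32 * (13.0 - v + v_offset) / (exp((13.0 - v + v_offset) / 4.0) - 1.0)
      beta_m = 0.28 * (v - v_offset - 40.0) / (exp((v - v_offset - 40.0) / 5.0) - 1.0)
      alpha_h = 0.128 * exp((17.0 - v + v_offset) / 18.0)
      beta_h = 4.0 / (1.0 + exp((40.0 - v + v_offset) / 5.0))
      alpha_n = 0.032 * (15.0 - v + v_offset) / (exp((15.0 - v + v_offset) / 5.0) - 1.0)
      beta_n = 0.5 * exp((10.0 - v + v_offset) / 40.0)
      dm/dt = alpha_m * (1.0 - m) - beta_m * m : init = 0.053, min = 0.0, max = 1.0
      dh/dt = alpha_h * (1.0 - h) - beta_h * h : init = 0.596, min = 0.0, max = 1.0
      dn/dt = alpha_n * (1.0 - n) - beta_n * n : init = 0.318, min = 0.0, max = 1.0
      cm * dv/dt = gL * (e_rev_leak - v) + gbar_Na * m^3 * h * (e_rev_Na - v) + gbar_K * n^4 * (e_rev_K - v) + g_exc * (e_rev_E - v) + g_inh * (e_rev_I - v) + i_offset : init = -65.0
      tau_syn_E * dg_exc/dt = -g_exc : exponential
      tau_syn_I * dg_inh/dt = -g_inh : exponential",
    spike = "v > 0.0 and vprev <= 0.0"
  )
)

rs_synapse_library <- list(

  Hebb = list(
    parameters = "eta = 0.01 : postsynaptic",
    equations = "dw/dt = eta * pre.r * post.r : min = 0.0"
  ),

  Oja = list(
    parameters = "
      eta = 0.01 : postsynaptic
      alpha = 1.0 : postsynaptic",
    equations = "dw/dt = eta * (pre.r * post.r - alpha * post.r^2 * w) : min = 0.0"
  ),

  IBCM = list(
    parameters = "tau = 2000.0 : postsynaptic",
    equations = "
      tau * dtheta/dt + theta = post.r^2 : postsynaptic
      dw/dt = post.r * (post.r - theta) * pre.r : min = 0.0"
  ),

  STP = list(
    parameters = "
      tau_rec = 100.0 : postsynaptic
      tau_facil = 0.01 : postsynaptic
      U = 0.5 : postsynaptic",
    equations = "
      dx/dt = (1.0 - x) / tau_rec : init = 1.0, event-driven
      du/dt = (U - u) / tau_facil : init = 0.5, event-driven",
    pre_spike = "
      g_target += w * u * x
      x = x * (1.0 - u)
      u = u + U * (1.0 - u)"
  ),

  STDP = list(
    parameters = "
      tau_plus = 20.0 : postsynaptic
      tau_minus = 20.0 : postsynaptic
      A_plus = 0.01 : postsynaptic
      A_minus = 0.01 : postsynaptic
      w_max = 1.0 : postsynaptic",
    equations = "
      tau_plus * dApre/dt = -Apre : event-driven
      tau_minus * dApost/dt = -Apost : event-driven",
    pre_spike = "
      g_target += w
      Apre = Apre + A_plus * w_max
      w = clip(w - Apost, 0.0, w_max)",
    post_spike = "
      Apost = Apost + A_minus * w_max
      w = clip(w + Apre, 0.0, w_max)"
  ),

  NMDA = list(
    parameters = "tau = 10.0 : postsynaptic",
    equations = "
      tau * dx/dt = -x
      tau * dg/dt = -g + x * (1.0 - g) : min = 0.0, max = 1.0",
    psp = "g",
    pre_spike = "x += w"
  )
)

#' Standard neuron models
#'
#' Returns one of the library neuron models, parsed and ready for
#' [population()].  `LeakyIntegrator` is the noisy rate-coded leaky
#' integrator (output `r`, excitatory input `sum(exc)`, baseline `B`,
#' uniform noise scaled by `noise`); `Izhikevich` the quadratic
#' adaptive model with instantaneous conductances; the `IF_*`, `EIF_*` and
#' `HH_cond_exp` models follow the PyNN parameterizations (exponential or
#' alpha-shaped currents/conductances).
#'
#' @param name One of `names(rs_neuron_library)`; see Details.
#' @return An `rs_neuron_model`.
#' @export
standard_neuron <- function(name) {
  spec <- rs_neuron_library[[name]]
  if (is.null(spec)) {
    stop("unknown standard neuron '", name, "'; available: ",
         paste(names(rs_neuron_library), collapse = ", "), call. = FALSE)
  }
  args <- spec
  args$name <- name
  do.call(neuron_model, args)
}

#' Standard synapse models
#'
#' `Hebb`, `Oja` and `IBCM` are rate-coded learning rules (the IBCM
#' threshold `theta` is the moving average of the squared post-synaptic
#' rate, computed once per post-synaptic neuron).  `STP` implements
#' short-term facilitation/depression with event-driven internal variables
#' `u`, `x` (conductance increment `w*u*x`, then `x <- x*(1-u)`,
#' `u <- u + U*(1-u)` using the pre-update values).  `STDP` is the online
#' trace rule: event-driven traces `Apre`/`Apost`, depression by `Apost` at
#' pre-synaptic spikes, potentiation by `Apre` at post-synaptic spikes, `w`
#' clipped to `[0, w_max]`.  `NMDA` is the non-linear continuous synapse:
#' `psp = g` summed every step.
#'
#' @param name One of `names(rs_synapse_library)`.
#' @return An `rs_synapse_model`.
#' @export
standard_synapse <- function(name) {
  spec <- rs_synapse_library[[name]]
  if (is.null(spec)) {
    stop("unknown standard synapse '", name, "'; available: ",
         paste(names(rs_synapse_library), collapse = ", "), call. = FALSE)
  }
  args <- spec
  args$name <- name
  do.call(synapse_model, args)
}

#' Names and sources of the library models
#'
#' @return `standard_models()`: list with `neurons` and `synapses` name
#'   vectors.  `model_text(name)`: the raw text blocks of one model.
#' @export
standard_models <- function() {
  list(neurons = names(rs_neuron_library),
       synapses = names(rs_synapse_library))
}

#' @rdname standard_models
#' @param name Model name.
#' @export
model_text <- function(name) {
  rs_neuron_library[[name]] %||% rs_synapse_library[[name]] %||%
    stop("unknown model: ", name, call. = FALSE)
}
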