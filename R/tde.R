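#' Time-difference-encoder neuron parameters
#'
#' Parameter set of the TDE unit: a facilitator synapse that sets an
#' exponentially decaying, dimensionless gain trace to 1, and a trigger
#' synapse whose excitatory post-synaptic conductance has amplitude
#' `w_syn * gain(t)` (reversal `e_ex_mv`), driving a leaky
#' integrate-and-fire soma. The synapse is conductance-based: with the
#' printed weight, capacitance and time constants a current-based EPSC of
#' 0.3 nA peaks only 6 mV above rest and can never reach the 10 mV-distant
#' threshold, so the weight is read in the conductance convention
#' (0.3 uS against a 0 mV reversal), under which an isolated
#' facilitator/trigger pair yields the expected burst of output spikes.
#'
#' @param w_syn synaptic weight, uS (default 0.3).
#' @param tau_ex_ms,tau_in_ms excitatory/inhibitory synaptic decay, ms
#'   (default 20 each; the inhibitory constant is carried for completeness
#'   but no inhibitory connection exists in the network).
#' @param tau_gain_ms facilitator gain decay, ms; defaults to `tau_ex_ms`.
#' @param c_m_nf membrane capacitance, nF (default 0.25).
#' @param tau_m_ms membrane time constant, ms (default 10).
#' @param tau_refrac_ms absolute refractory period, ms (default 1).
#' @param v_reset_mv,v_rest_mv,v_thresh_mv reset, resting and threshold
#'   potentials, mV (defaults -85, -60, -50).
#' @param e_ex_mv excitatory reversal potential, mV (default 0).
#' @param fac_delay_ms wiring delay added to every facilitator input, ms
#'   (default 1): it de-tunes units whose two inputs fire coincidently, e.g.
#'   units perpendicular to a moving bar.
#' @param dt_sim_ms simulation tick, ms (default 1). Input spikes are
#'   quantized to the tick; within one tick triggers are processed before
#'   facilitators. Membrane threshold crossings are located in closed form
#'   inside the tick, so spike counts are nearly tick-size independent.
#' @return a `tde_params` list.
#' @export
tde_params <- function(w_syn = 0.3, tau_ex_ms = 20, tau_in_ms = 20,
                       tau_gain_ms = tau_ex_ms, c_m_nf = 0.25,
                       tau_m_ms = 10, tau_refrac_ms = 1,
                       v_reset_mv = -85, v_rest_mv = -60, v_thresh_mv = -50,
                       e_ex_mv = 0, fac_delay_ms = 1, dt_sim_ms = 1) {
  p <- list(w_syn = w_syn, tau_ex_ms = tau_ex_ms, tau_in_ms = tau_in_ms,
            tau_gain_ms = tau_gain_ms, c_m_nf = c_m_nf, tau_m_ms = tau_m_ms,
            tau_refrac_ms = tau_refrac_ms, v_reset_mv = v_reset_mv,
            v_rest_mv = v_rest_mv, v_thresh_mv = v_thresh_mv,
            e_ex_mv = e_ex_mv, fac_delay_ms = fac_delay_ms,
            dt_sim_ms = dt_sim_ms)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), TRUE)))
    stop("all TDE parameters must be finite scalars")
  if (!(v_reset_mv <= v_rest_mv && v_rest_mv < v_thresh_mv))
    stop("require v_reset <= v_rest < v_thresh")
  if (any(c(tau_ex_ms, tau_in_ms, tau_gain_ms, tau_m_ms, c_m_nf,
            dt_sim_ms) <= 0) || tau_refrac_ms < 0 || fac_delay_ms < 0 ||
      w_syn < 0)
    stop("time constants, capacitance and weights must be positive")
  structure(p, class = "tde_params")
}

#' Simulate one TDE unit
#'
#' Runs the time-difference encoder on explicit facilitator and trigger
#' spike trains. A facilitator spike (delivered after `fac_delay_ms`) sets
#' the gain trace to 1 (set-and-replace, no accumulation), decaying with
#' `tau_gain_ms`; a trigger spike injects an EPSC of amplitude
#' `w_syn * gain` at its arrival. The number of output spikes encodes the
#' facilitator-to-trigger time difference: large for small positive
#' differences, zero for negative ones.
#'
#' @param fac_times,trig_times sorted numeric spike times, ms.
#' @param params a [tde_params()].
#' @return numeric vector of output spike times (ms).
#' @examples
#' p <- tde_params(fac_delay_ms = 0)
#' length(tde_response(100, 105, p))  # burst for a small time difference
#' length(tde_response(105, 100, p))  # 0: trigger before facilitation
#' @export
tde_response <- function(fac_times, trig_times, params = tde_params()) {
  stopifnot(inherits(params, "tde_params"))
  fac_times <- as.numeric(fac_times); trig_times <- as.numeric(trig_times)
  if (is.unsorted(fac_times) || is.unsorted(trig_times))
    stop("input spike trains must be sorted")
  if ((length(fac_times) && !all(is.finite(fac_times))) ||
      (length(trig_times) && !all(is.finite(trig_times))))
    stop("input spike times must be finite")
  cpp_tde_response(fac_times, trig_times, unclass(params))
}

#' TDE transfer curve over facilitator-trigger time differences
#'
#' Characterizes the encoder on isolated facilitator/trigger pairs: for each
#' time difference `dt` the facilitator fires at a reference time and the
#' trigger `dt` ms later (earlier for negative `dt`). By default the wiring
#' delay is removed (`fac_delay_ms = 0`) so the curve describes the encoder
#' proper — the time difference is measured at the synapses; network wiring
#' adds the delay back.
#'
#' @param params a [tde_params()].
#' @param dt_values numeric vector of time differences, ms.
#' @param strip_delay if `TRUE` (default) characterize with
#'   `fac_delay_ms = 0`.
#' @return data.frame with columns `dt_ms`, `n_spikes`, `first_latency_ms`
#'   (first output spike relative to the trigger; `NA` if no spike).
#' @export
tde_characterize <- function(params = tde_params(), dt_values,
                             strip_delay = TRUE) {
  stopifnot(inherits(params, "tde_params"), length(dt_values) > 0)
  if (strip_delay) params$fac_delay_ms <- 0
  t0 <- 100
  res <- lapply(dt_values, function(d) {
    out <- tde_response(t0, t0 + d, params)
    data.frame(dt_ms = d, n_spikes = length(out),
               first_latency_ms = if (length(out)) out[1] - (t0 + d) else NA_real_)
  })
  do.call(rbind, res)
}
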