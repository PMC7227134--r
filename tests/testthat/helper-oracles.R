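# Brute-force fixed-step oracles, independent of the package's closed-form
# event-driven kernels. Deliberately naive: forward Euler / per-step decay.

# TDE unit: forward-Euler at a fine step, same input semantics as the
# engine (inputs quantized to the step; triggers before facilitators).
tde_oracle <- function(fac, trig, p, dt = 0.01) {
  fd <- floor((fac + p$fac_delay_ms) / dt) * dt
  td <- floor(trig / dt) * dt
  if (!length(td)) return(numeric())
  t <- min(c(td, fd)); t_end <- max(td) + 200
  gl <- p$c_m_nf / p$tau_m_ms
  gain_t <- -Inf; g <- 0; V <- p$v_rest_mv; ref <- -Inf
  out <- numeric(); i_f <- 1; i_t <- 1
  while (t < t_end) {
    tn <- t + dt
    while (i_t <= length(td) && td[i_t] < tn - 1e-9) {
      if (is.finite(gain_t))
        g <- g + p$w_syn * exp(-(td[i_t] - gain_t) / p$tau_gain_ms)
      i_t <- i_t + 1
    }
    while (i_f <= length(fd) && fd[i_f] < tn - 1e-9) {
      gain_t <- fd[i_f]; i_f <- i_f + 1
    }
    if (ref > t) {
      V <- p$v_reset_mv
    } else {
      V <- V + (gl * (p$v_rest_mv - V) + g * (p$e_ex_mv - V)) / p$c_m_nf * dt
      if (V >= p$v_thresh_mv) {
        out <- c(out, tn); V <- p$v_reset_mv; ref <- tn + p$tau_refrac_ms
      }
    }
    g <- g * (1 - dt / p$tau_ex_ms)
    t <- tn
  }
  out
}

# RF leaky integrator: per-step exponential decay at a fine step, events
# added in their step, spike + reset on threshold. Membership recomputed
# from the RF bounding boxes, not from the scheme's pixel map.
rf_oracle_counts <- function(stream, scheme, dt = 0.01) {
  ev <- stream$events
  rfs <- scheme$rfs
  dec <- exp(-dt / scheme$tau_rf_ms)
  vapply(seq_len(nrow(rfs)), function(i) {
    inside <- ev$x >= rfs$x0[i] & ev$x < rfs$x0[i] + rfs$size[i] &
      ev$y >= rfs$y0[i] & ev$y < rfs$y0[i] + rfs$size[i]
    tt <- ev$t[inside]
    if (!length(tt)) return(0L)
    bins <- floor(tt / dt)
    n_steps <- max(bins) + 1L
    add <- tabulate(bins + 1L, nbins = n_steps) / rfs$rnf[i]
    M <- 0; spikes <- 0L
    for (k in seq_len(n_steps)) {
      M <- M * dec + add[k]
      if (M >= scheme$threshold) { spikes <- spikes + 1L; M <- 0 }
    }
    spikes
  }, 0L)
}
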