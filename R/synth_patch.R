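#' Parameters of the synthetic patch-clamp cell
#'
#' A leaky exponential-integrate-and-fire membrane augmented with one
#' non-inactivating, Boltzmann-gated K+ conductance representing the
#' dendrotoxin-sensitive (Kv1-type) current.  Because the conductance
#' activates around `kv_half` (well above rest), it leaves passive
#' properties and rheobase nearly untouched but suppresses firing at large
#' current injections.
#'
#' @param leak_ns Leak conductance (nS); input resistance is ~1/leak.
#' @param e_leak_mv Leak reversal / resting potential (mV).
#' @param c_pf Membrane capacitance (pF).
#' @param vt_mv,delta_t_mv EIF soft threshold and slope factor (mV).
#' @param v_peak_mv,v_reset_mv,ahp_mv,refractory_ms Spike shape: peak cut,
#'   reset, after-hyperpolarisation depth below reset, refractory (ms).
#' @param g_kv_ns DTX-sensitive K+ conductance (nS); 0 removes it.
#' @param kv_half_mv,kv_slope_mv Boltzmann half-activation and slope (mV).
#' @param e_k_mv K+ reversal (mV).
#' @param kv_tau_ms Kv activation time constant (ms); activation builds up
#'   across spikes, so the conductance brakes firing mainly at high rates.
#' @param upstroke_cap_pa Cap on the exponential spike-initiation drive
#'   (pA), giving a finite, conductance-sensitive peak dV/dt.
#' @param epsc_rate_hz,epsc_amp_pa,epsc_rise_ms,epsc_decay_ms Spontaneous
#'   EPSC process for gap-free mode.
#' @param noise_sd_mv Membrane voltage noise (current clamp, mV/sqrt(ms)).
#' @param noise_sd_pa Current noise (voltage clamp / gap-free, pA).
#' @param dt_ms Integration step; must be <= 0.1 ms.
#' @param seed Integer seed.
#' @export
patch_sim_params <- function(leak_ns = 1, e_leak_mv = -70, c_pf = 50,
                             vt_mv = -45, delta_t_mv = 2,
                             v_peak_mv = 30, v_reset_mv = -55, ahp_mv = 10,
                             refractory_ms = 2,
                             g_kv_ns = 5, kv_half_mv = -22, kv_slope_mv = 3.5,
                             e_k_mv = -90, kv_tau_ms = 8,
                             upstroke_cap_pa = 15000,
                             epsc_rate_hz = 2, epsc_amp_pa = 20,
                             epsc_rise_ms = 1.5, epsc_decay_ms = 10,
                             noise_sd_mv = 0, noise_sd_pa = 0,
                             dt_ms = 0.05, seed = 1L) {
  stop_if(c_pf <= 0, "capacitance must be > 0")
  stop_if(g_kv_ns < 0, "g_kv must be >= 0")
  stop_if(epsc_decay_ms <= epsc_rise_ms, "epsc_decay must exceed epsc_rise")
  stop_if(dt_ms > 0.1, "timestep must be <= 0.1 ms for integration accuracy")
  p <- as.list(environment())
  check_finite(p, "patch_sim_params")
  structure(p, class = "patch_sim_params")
}

# steady-state Boltzmann activation
kv_activation <- function(v, params) {
  1 / (1 + exp(-(v - params$kv_half_mv) / params$kv_slope_mv))
}

#' Ground-truth steady-state DTX-sensitive current
#'
#' @param v_mv Command potential(s), mV.
#' @param params A [patch_sim_params()].
#' @return Current (pA).
#' @export
kv_current_truth <- function(v_mv, params) {
  params$g_kv_ns * kv_activation(v_mv, params) * (v_mv - params$e_k_mv)
}

#' Simulate a patch-clamp sweep set
#'
#' Three protocol shapes mirroring the experimental ones:
#' `current_steps` (current clamp, -20 to 200 pA in 10 pA increments, 1 s
#' steps) integrates the EIF + Kv model; `voltage_steps` (-80 to 50 mV in
#' 10 mV increments from a -60 mV hold, 1 s) returns the clamped ionic
#' current with first-order Kv activation kinetics; `gap_free` returns a
#' -60 mV hold with Poisson spontaneous EPSCs of bi-exponential shape.
#' Setting `drug_applied = TRUE` blocks the Kv conductance (alpha-DTX).
#'
#' @param params A [patch_sim_params()].
#' @param protocol One of `"current_steps"`, `"voltage_steps"`,
#'   `"gap_free"`.
#' @param drug_applied Simulate the post-DTX condition (g_kv blocked).
#' @param duration_s Gap-free duration (s).
#' @param step_range Overrides the default step vector (pA or mV).
#' @return list of class `sweep_set`: `mode`, `time_ms`, `sweeps` (list of
#'   numeric traces; mV for current clamp, pA otherwise), `steps` (injected
#'   pA or command mV per sweep), `window_ms` (step on/off), `sampling_hz`,
#'   `meta` (access resistance / holding current series), `truth`.
#' @export
gen_patch_cell <- function(params, protocol = c("current_steps",
                                                "voltage_steps", "gap_free"),
                           drug_applied = FALSE, duration_s = 60,
                           step_range = NULL) {
  protocol <- match.arg(protocol)
  stop_if(!inherits(params, "patch_sim_params"), "invalid params")
  set.seed(params$seed + 1000 * drug_applied)
  gkv <- if (drug_applied) 0 else params$g_kv_ns
  dt <- params$dt_ms
  meta <- list(access_mohm = c(12, 12.5, 12.8),
               holding_pa = c(-20, -21, -20.5))

  if (protocol == "current_steps") {
    steps <- step_range %||% seq(-20, 200, by = 10)
    pre <- 200; on <- 1000; post <- 300
    n <- round((pre + on + post) / dt)
    time_ms <- (seq_len(n) - 1) * dt
    inj <- function(amp) ifelse(time_ms >= pre & time_ms < pre + on, amp, 0)
    sweeps <- list(); spikes <- list()
    for (i in seq_along(steps)) {
      out <- eif_integrate(inj(steps[i]), dt, params$c_pf, params$leak_ns,
                           params$e_leak_mv, params$vt_mv, params$delta_t_mv,
                           params$v_peak_mv, params$v_reset_mv, params$ahp_mv,
                           0.5, params$refractory_ms,
                           gkv, params$kv_half_mv, params$kv_slope_mv,
                           params$e_k_mv, params$kv_tau_ms,
                           params$upstroke_cap_pa, params$noise_sd_mv,
                           params$e_leak_mv)
      sweeps[[i]] <- out$v_mv
      spikes[[i]] <- out$spike_ms
    }
    truth <- list(params = params, g_kv_applied = gkv,
                  spike_ms = spikes,
                  tau_ms = params$c_pf / params$leak_ns,
                  r_in_gohm = 1 / params$leak_ns)
    return(structure(list(mode = "current_clamp", time_ms = time_ms,
                          sweeps = sweeps, steps = steps,
                          window_ms = c(pre, pre + on),
                          sampling_hz = 1000 / dt, meta = meta,
                          truth = truth), class = "sweep_set"))
  }

  if (protocol == "voltage_steps") {
    steps <- step_range %||% seq(-80, 50, by = 10)
    hold <- -60
    pre <- 100; on <- 1000; post <- 100
    n <- round((pre + on + post) / dt)
    time_ms <- (seq_len(n) - 1) * dt
    sweeps <- lapply(steps, function(vs) {
      v <- ifelse(time_ms >= pre & time_ms < pre + on, vs, hold)
      n_inf <- kv_activation(v, params)
      # first-order activation towards n_inf at each clamp level
      nact <- numeric(n)
      nact[1] <- kv_activation(hold, params)
      alpha <- dt / params$kv_tau_ms
      for (i in 2:n) nact[i] <- nact[i - 1] +
          (n_inf[i] - nact[i - 1]) * alpha
      i_ion <- params$leak_ns * (v - params$e_leak_mv) +
        gkv * nact * (v - params$e_k_mv)
      i_ion + rnorm(n, 0, params$noise_sd_pa)
    })
    truth <- list(params = params, g_kv_applied = gkv,
                  kv_iv_pa = kv_current_truth(steps, params))
    return(structure(list(mode = "voltage_clamp", time_ms = time_ms,
                          sweeps = sweeps, steps = steps,
                          window_ms = c(pre, pre + on),
                          sampling_hz = 1000 / dt, meta = meta,
                          truth = truth), class = "sweep_set"))
  }

  # gap-free sEPSC recording at -60 mV
  dt_gf <- max(dt, 0.1)
  n <- round(duration_s * 1000 / dt_gf)
  time_ms <- (seq_len(n) - 1) * dt_gf
  hold <- -60
  i_hold <- params$leak_ns * (hold - params$e_leak_mv) +
    gkv * kv_activation(hold, params) * (hold - params$e_k_mv)
  n_ev <- rpois(1, params$epsc_rate_hz * duration_s)
  ev_t <- sort(runif(n_ev, 0, duration_s * 1000 - 100))
  ev_a <- params$epsc_amp_pa * rlnorm(n_ev, 0, 0.2)
  tpl_t <- seq(0, 8 * params$epsc_decay_ms, by = dt_gf)
  tpl <- (1 - exp(-tpl_t / params$epsc_rise_ms)) *
    exp(-tpl_t / params$epsc_decay_ms)
  tpl <- tpl / max(tpl)
  trace <- rep(i_hold, n)
  for (k in seq_len(n_ev)) {
    i0 <- floor(ev_t[k] / dt_gf) + 1
    idx <- i0:min(n, i0 + length(tpl) - 1)
    trace[idx] <- trace[idx] - ev_a[k] * tpl[seq_along(idx)]
  }
  trace <- trace + rnorm(n, 0, params$noise_sd_pa)
  truth <- list(params = params, event_ms = ev_t, event_amp_pa = ev_a)
  structure(list(mode = "gap_free", time_ms = time_ms,
                 sweeps = list(trace), steps = hold,
                 window_ms = c(0, duration_s * 1000),
                 sampling_hz = 1000 / dt_gf, meta = meta, truth = truth),
            class = "sweep_set")
}
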