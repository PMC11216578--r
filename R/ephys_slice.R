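#' Recording quality control
#'
#' A recording fails if access resistance exceeds 20 MOhm at any
#' checkpoint, or if access resistance or holding current changes by more
#' than 20% relative to the first checkpoint.
#'
#' @param access_mohm Access-resistance series (MOhm).
#' @param holding_pa Holding-current series (pA).
#' @param ra_limit,change_limit Absolute Ra limit (MOhm) and relative
#'   change limit.
#' @return list with `pass` and `reasons` (character).
#' @export
qc_recording <- function(access_mohm, holding_pa,
                         ra_limit = 20, change_limit = 0.2) {
  if (is.null(access_mohm) || is.null(holding_pa) ||
      !length(access_mohm) || !length(holding_pa))
    return(list(pass = FALSE, reasons = "unverifiable: missing QC series"))
  reasons <- character(0)
  if (any(access_mohm > ra_limit))
    reasons <- c(reasons, sprintf("access resistance > %g MOhm", ra_limit))
  if (max(abs(access_mohm - access_mohm[1])) / access_mohm[1] > change_limit)
    reasons <- c(reasons, "access resistance changed by > 20%")
  if (abs(holding_pa[1]) > 1e-9 &&
      max(abs(holding_pa - holding_pa[1])) / abs(holding_pa[1]) > change_limit)
    reasons <- c(reasons, "holding current changed by > 20%")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Detect action potentials in a current-clamp trace
#'
#' A spike is an upward crossing of dV/dt >= 20 V/s followed by the voltage
#' exceeding 0 mV within 2 ms, with a 1 ms refractory period.  The spike
#' time is the voltage peak.
#'
#' @param time_ms Sample times (ms).
#' @param v_mv Membrane voltage (mV).
#' @param dvdt_threshold Threshold (V/s = mV/ms).
#' @param confirm_mv,confirm_ms Peak confirmation level and window.
#' @param refractory_ms Minimum spacing between spikes.
#' @param waveform_ms Waveform window around the peak, `c(before, after)`.
#' @return list with `spike_ms`, `waveforms` (list of data.frames `t_ms`,
#'   `v_mv`), `clipped` flag.
#' @export
detect_action_potentials <- function(time_ms, v_mv, dvdt_threshold = 20,
                                     confirm_mv = 0, confirm_ms = 2,
                                     refractory_ms = 1,
                                     waveform_ms = c(2, 5)) {
  dt <- time_ms[2] - time_ms[1]
  stop_if(dt > 0.1 + 1e-9, "sampling must be >= 10 kHz")
  dvdt <- c(0, diff(v_mv) / dt)
  up <- which(dvdt >= dvdt_threshold & c(0, dvdt[-length(dvdt)]) <
                dvdt_threshold)
  n_conf <- round(confirm_ms / dt)
  spike_idx <- integer(0)
  last_peak <- -Inf
  for (i in up) {
    win <- i:min(length(v_mv), i + n_conf)
    if (max(v_mv[win]) > confirm_mv) {
      pk <- win[which.max(v_mv[win])]
      if (time_ms[pk] - last_peak >= refractory_ms) {
        spike_idx <- c(spike_idx, pk)
        last_peak <- time_ms[pk]
      }
    }
  }
  nb <- round(waveform_ms[1] / dt); na <- round(waveform_ms[2] / dt)
  waveforms <- lapply(spike_idx, function(pk) {
    idx <- max(1, pk - nb):min(length(v_mv), pk + na)
    data.frame(t_ms = time_ms[idx] - time_ms[pk], v_mv = v_mv[idx])
  })
  clipped <- mean(v_mv >= max(v_mv) - 1e-9) > 0.05
  list(spike_ms = time_ms[spike_idx], waveforms = waveforms,
       clipped = clipped)
}

#' Passive membrane properties from a current-step sweep set
#'
#' RMP is the mean pre-step voltage; input resistance comes from the
#' least-squares slope of the steady-state voltage deflection against
#' injected current over the hyperpolarising steps (steady state = final
#' 200 ms of the 1 s step); the membrane time constant is a
#' single-exponential fit of the onset relaxation of the -20 pA (or -10 pA)
#' step over the first 300 ms (excluding the first 2 ms); capacitance is
#' C_m = tau / R_in; rheobase is the first current step that elicits at
#' least one action potential.
#'
#' @param sweep_set A current-clamp `sweep_set` (see [gen_patch_cell()]).
#' @return list with `rmp_mv`, `r_in_gohm`, `tau_ms`, `c_m_pf`,
#'   `rheobase_pa`.
#' @export
passive_properties <- function(sweep_set) {
  stop_if(sweep_set$mode != "current_clamp", "needs current-clamp sweeps")
  t <- sweep_set$time_ms
  w <- sweep_set$window_ms
  pre_idx <- t < w[1]
  ss_idx <- t >= w[2] - 200 & t < w[2]
  hyper <- which(sweep_set$steps < 0)
  stop_if(length(hyper) < 2, "need >= 2 hyperpolarising steps")
  rmp <- mean(vapply(sweep_set$sweeps, function(v) mean(v[pre_idx]),
                     numeric(1)))
  dv <- vapply(hyper, function(i)
    mean(sweep_set$sweeps[[i]][ss_idx]) - mean(sweep_set$sweeps[[i]][pre_idx]),
    numeric(1))
  r_in <- unname(coef(lm(dv ~ 0 + sweep_set$steps[hyper]))[1])  # mV/pA = GOhm

  fit_i <- which(sweep_set$steps %in% c(-20, -10))
  tau <- NA_real_
  if (length(fit_i)) {
    i <- fit_i[1]
    v <- sweep_set$sweeps[[i]]
    sel <- t >= w[1] + 2 & t < w[1] + 300
    tf <- t[sel] - w[1]
    vf <- v[sel]
    v0 <- mean(v[pre_idx]); vinf <- mean(v[ss_idx])
    tau <- tryCatch({
      fit <- nls(vf ~ vi + (v0 - vi) * exp(-tf / tau),
                 start = list(vi = vinf, tau = 20),
                 control = nls.control(warnOnly = TRUE))
      unname(coef(fit)["tau"])
    }, error = function(e) NA_real_)
  }
  c_m <- if (!is.na(tau) && r_in > 0) tau / r_in else NA_real_  # ms/GOhm = pF

  rheo <- NA_real_
  for (i in order(sweep_set$steps)) {
    if (sweep_set$steps[i] <= 0) next
    det <- detect_action_potentials(t, sweep_set$sweeps[[i]])
    if (length(det$spike_ms) > 0) { rheo <- sweep_set$steps[i]; break }
  }
  list(rmp_mv = rmp, r_in_gohm = r_in, tau_ms = tau, c_m_pf = c_m,
       rheobase_pa = rheo)
}

#' Current-frequency (F-I) curve
#'
#' Spike count and firing rate over the 1 s step for every injected
#' current.
#'
#' @inheritParams passive_properties
#' @return data.frame with `current_pa`, `n_spikes`, `rate_hz`.
#' @export
fi_curve <- function(sweep_set) {
  stop_if(sweep_set$mode != "current_clamp", "needs current-clamp sweeps")
  t <- sweep_set$time_ms
  w <- sweep_set$window_ms
  counts <- vapply(seq_along(sweep_set$steps), function(i) {
    det <- detect_action_potentials(t, sweep_set$sweeps[[i]])
    sum(det$spike_ms >= w[1] & det$spike_ms < w[2])
  }, numeric(1))
  data.frame(current_pa = sweep_set$steps, n_spikes = counts,
             rate_hz = counts / ((w[2] - w[1]) / 1000))
}

#' Action-potential kinetics at rheobase
#'
#' Per-spike amplitude (peak-value convention), threshold (voltage at the
#' first dV/dt >= 20 V/s crossing), width at half-peak (between threshold
#' and peak levels), after-hyperpolarisation depth, 10-90% rise time,
#' repolarisation decay constant, and the phase-plane trace (V, dV/dt).
#'
#' @param waveforms List of spike waveforms from
#'   [detect_action_potentials()].
#' @param dvdt_threshold Threshold-crossing criterion (V/s).
#' @return data.frame, one row per usable spike, with a `phase_plane`
#'   attribute (list of data.frames `v_mv`, `dvdt`).
#' @export
ap_kinetics <- function(waveforms, dvdt_threshold = 20) {
  rows <- list(); planes <- list()
  for (wf in waveforms) {
    dt <- wf$t_ms[2] - wf$t_ms[1]
    v <- wf$v_mv
    dvdt <- c(0, diff(v) / dt)
    pk <- which.max(v)
    if (pk <= 2 || pk >= length(v) - 2) next  # truncated waveform
    thr_i <- which(dvdt[seq_len(pk)] >= dvdt_threshold)[1]
    if (is.na(thr_i)) next
    thr <- v[thr_i]
    vmax <- v[pk]
    half <- (thr + vmax) / 2
    above <- which(v >= half)
    width <- (max(above) - min(above)) * dt
    post <- v[pk:length(v)]
    ahp <- thr - min(post)
    lo <- thr + 0.1 * (vmax - thr); hi <- thr + 0.9 * (vmax - thr)
    i_lo <- which(v[seq_len(pk)] >= lo)[1]
    i_hi <- which(v[seq_len(pk)] >= hi)[1]
    rise <- (i_hi - i_lo) * dt
    dec_idx <- pk:(pk + min(length(post), round(2 / dt)) - 1)
    dv_dec <- v[dec_idx] - min(post)
    usable <- dv_dec > 0.05 * (vmax - min(post))
    dec_tau <- if (sum(usable) > 3) {
      tt <- (dec_idx[usable] - pk) * dt
      -1 / unname(coef(lm(log(dv_dec[usable]) ~ tt))[2])
    } else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      v_max_mv = vmax, threshold_mv = thr, width_ms = width,
      ahp_mv = ahp, rise_ms = rise, decay_tau_ms = dec_tau,
      peak_dvdt = max(dvdt))
    planes[[length(planes) + 1]] <- data.frame(v_mv = v, dvdt = dvdt)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(v_max_mv = numeric(0), threshold_mv = numeric(0),
               width_ms = numeric(0), ahp_mv = numeric(0),
               rise_ms = numeric(0), decay_tau_ms = numeric(0),
               peak_dvdt = numeric(0))
  attr(out, "phase_plane") <- planes
  out
}

#' Dendrotoxin-sensitive current by subtraction
#'
#' Averages 2-3 repeats of the voltage-step protocol per condition,
#' subtracts the post-drug average trace from the baseline average per
#' step, and quantifies each step as the maximal deflection of the
#' subtracted trace during the 1 s step in either direction (signed), also
#' expressed as a current density after division by the membrane
#' capacitance.
#'
#' @param baseline,post_drug A voltage-clamp `sweep_set` or a list of
#'   repeats.
#' @param c_m_pf Membrane capacitance (pF).
#' @param settle_ms Portion of the step skipped before taking the maximal
#'   deflection (lets activation reach steady state).
#' @return list with `table` (data.frame `step_mv`, `deflection_pa`,
#'   `density_pa_pf`), `subtracted` (list of traces), `time_ms`.
#' @export
dtx_sensitive_current <- function(baseline, post_drug, c_m_pf,
                                  settle_ms = 50) {
  as_list <- function(x) if (inherits(x, "sweep_set")) list(x) else x
  bl <- as_list(baseline); dr <- as_list(post_drug)
  stop_if(!all(vapply(c(bl, dr), function(s)
    s$mode == "voltage_clamp", logical(1))), "needs voltage-clamp sweeps")
  steps <- bl[[1]]$steps
  ok <- all(vapply(c(bl, dr), function(s)
    length(s$steps) == length(steps) && all(s$steps == steps), logical(1)))
  stop_if(!ok, "step protocols do not match")
  avg <- function(sets, i) Reduce(`+`, lapply(sets, function(s)
    s$sweeps[[i]])) / length(sets)
  t <- bl[[1]]$time_ms
  w <- bl[[1]]$window_ms
  sel <- t >= w[1] + settle_ms & t < w[2]
  subtracted <- lapply(seq_along(steps), function(i)
    avg(bl, i) - avg(dr, i))
  defl <- vapply(subtracted, function(tr) {
    seg <- tr[sel]
    seg[which.max(abs(seg))]
  }, numeric(1))
  list(table = data.frame(step_mv = steps, deflection_pa = defl,
                          density_pa_pf = defl / c_m_pf),
       subtracted = subtracted, time_ms = t)
}

#' Detect spontaneous EPSCs in a gap-free recording
#'
#' Matched-filter detection against a bi-exponential template after
#' running-median baseline removal.  Candidate events must exceed the
#' matched-filter threshold and have an estimated amplitude of at least
#' `amp_sd_factor` times the baseline noise SD.  Each event is summarised
#' by amplitude, 10-90% rise time and a single-exponential decay constant.
#'
#' @param sweep_set A gap-free `sweep_set`, or a numeric trace (then give
#'   `sampling_hz`).
#' @param rise_ms,decay_ms Template kinetics.
#' @param z_threshold Matched-filter detection threshold (in noise SDs of
#'   the filtered trace).
#' @param amp_sd_factor Amplitude criterion (times baseline noise SD).
#' @param sampling_hz Sampling rate when a bare trace is supplied.
#' @return list with `events` (data.frame `time_ms`, `amplitude_pa`,
#'   `rise_ms`, `decay_ms`), `frequency_hz`, `noise_sd_pa`, `flagged`.
#' @export
detect_sepscs <- function(sweep_set, rise_ms = 1.5, decay_ms = 10,
                          z_threshold = 4, amp_sd_factor = 3,
                          sampling_hz = NULL) {
  if (inherits(sweep_set, "sweep_set")) {
    stop_if(sweep_set$mode != "gap_free", "needs a gap-free recording")
    trace <- sweep_set$sweeps[[1]]
    fs <- sweep_set$sampling_hz
  } else {
    trace <- sweep_set
    stop_if(is.null(sampling_hz), "sampling_hz required for a bare trace")
    fs <- sampling_hz
  }
  dt <- 1000 / fs
  n <- length(trace)
  duration_s <- n * dt / 1000
  k <- min(n - (1 - n %% 2), 2 * floor(100 / dt) + 1)  # ~200 ms, odd
  base <- stats::runmed(trace, k)
  d <- base - trace  # inward (negative) deflections become positive
  drift <- max(abs(diff(range(base))))
  flagged <- drift > 10 * mad(d)
  noise_sd <- mad(d)
  tpl_t <- seq(0, 5 * decay_ms, by = dt)
  tpl <- (1 - exp(-tpl_t / rise_ms)) * exp(-tpl_t / decay_ms)
  tpl <- tpl / max(tpl)
  score <- as.numeric(stats::filter(c(d, rep(0, length(tpl) - 1)),
                                    rev(tpl), sides = 1))
  score <- score[length(tpl):(n + length(tpl) - 1)]
  z <- score / (noise_sd * sqrt(sum(tpl^2)))
  min_sep <- max(decay_ms, 5) / dt
  # local maxima of the matched-filter output above threshold, separated by
  # at least min_sep (keeps overlapping events apart)
  is_peak <- z >= z_threshold &
    z >= c(-Inf, z[-n]) & z > c(z[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) > 1) {
    keep <- rep(TRUE, length(cand))
    last <- 1
    for (j in 2:length(cand)) {
      if (cand[j] - cand[last] < min_sep) {
        if (z[cand[j]] > z[cand[last]]) keep[last] <- FALSE else
          keep[j] <- FALSE
        if (keep[j]) last <- j
      } else last <- j
    }
    cand <- cand[keep]
  }
  events <- list()
  for (start in cand) {
    win <- start:min(n, start + round(2 * decay_ms / dt))
    amp <- max(d[win])
    if (amp >= amp_sd_factor * noise_sd) {
      pk <- win[which.max(d[win])]
      lo <- 0.1 * amp; hi <- 0.9 * amp
      pre <- d[start:pk]
      i_lo <- which(pre >= lo)[1]; i_hi <- which(pre >= hi)[1]
      rise <- if (!is.na(i_lo) && !is.na(i_hi)) (i_hi - i_lo) * dt
      else NA_real_
      dec_seg <- d[pk:min(n, pk + round(4 * decay_ms / dt))]
      usable <- dec_seg > 0.05 * amp
      dec <- if (sum(usable) > 3) {
        tt <- (which(usable) - 1) * dt
        -1 / unname(coef(lm(log(dec_seg[usable]) ~ tt))[2])
      } else NA_real_
      events[[length(events) + 1]] <- data.frame(
        time_ms = (start - 1) * dt, amplitude_pa = amp,
        rise_ms = rise, decay_ms = dec)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time_ms = numeric(0), amplitude_pa = numeric(0),
               rise_ms = numeric(0), decay_ms = numeric(0))
  list(events = ev, frequency_hz = nrow(ev) / duration_s,
       noise_sd_pa = noise_sd, flagged = flagged)
}

#' Evoked EPSC train amplitudes
#'
#' Per-pulse peak amplitude (baseline just before each pulse minus the
#' post-pulse current minimum) and amplitudes relative to the first pulse,
#' for a 10 Hz optogenetic stimulation train.
#'
#' @param sweeps List of stimulus-locked current traces (pA), or a single
#'   trace.
#' @param time_ms Shared time base (ms).
#' @param pulse_ms Pulse onset times (ms).
#' @param window_ms Post-pulse search window (ms).
#' @return data.frame with `pulse`, `amplitude_pa`, `relative_amplitude`.
#' @export
epsc_train_analysis <- function(sweeps, time_ms, pulse_ms, window_ms = 80) {
  if (is.numeric(sweeps)) sweeps <- list(sweeps)
  stop_if(length(pulse_ms) > 1 && min(diff(pulse_ms)) < window_ms,
          "pulse windows overlap: reduce window_ms or check the train rate")
  avg <- Reduce(`+`, sweeps) / length(sweeps)
  amps <- vapply(pulse_ms, function(p0) {
    basel <- mean(avg[time_ms >= p0 - 2 & time_ms < p0])
    seg <- avg[time_ms >= p0 & time_ms < p0 + window_ms]
    basel - min(seg)
  }, numeric(1))
  data.frame(pulse = seq_along(pulse_ms), amplitude_pa = amps,
             relative_amplitude = amps / amps[1])
}

#' Split cells by baseline firing frequency
#'
#' Two-class 1-D k-means on baseline rates; the high-rate class is labelled
#' putative inhibitory (tonically active) and the low-rate class putative
#' excitatory.  If the two centroids differ by less than `guard_hz` the
#' cohort is treated as a single low-rate class with a warning.
#'
#' @param rates_hz Baseline firing rates (Hz), one per cell.
#' @param guard_hz Minimum centroid separation (Hz).
#' @return factor with levels `putative_excitatory`, `putative_inhibitory`.
#' @export
classify_baseline_activity <- function(rates_hz, guard_hz = 10) {
  lv <- c("putative_excitatory", "putative_inhibitory")
  if (length(unique(rates_hz)) < 2 || var(rates_hz) < 1e-12)
    return(factor(rep(lv[1], length(rates_hz)), levels = lv))
  km <- kmeans(rates_hz, centers = 2, nstart = 5)
  if (abs(diff(range(km$centers))) < guard_hz) {
    warning("baseline rates look unimodal; assigning all cells to the ",
            "low-rate class")
    return(factor(rep(lv[1], length(rates_hz)), levels = lv))
  }
  hi <- which.max(km$centers)
  factor(ifelse(km$cluster == hi, lv[2], lv[1]), levels = lv)
}
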