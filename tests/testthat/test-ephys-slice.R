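test_that("QC applies the access-resistance and drift rules", {
  expect_true(qc_recording(c(15, 17), c(-30, -33))$pass)
  expect_false(qc_recording(c(15, 21), c(-30, -31))$pass)        # Ra > 20
  expect_false(qc_recording(c(15, 19), c(-30, -31))$pass)        # 26% rise
  expect_false(qc_recording(c(15, 16), c(-30, -40))$pass)        # 33% hold
  q <- qc_recording(NULL, NULL)
  expect_false(q$pass)
  expect_match(q$reasons, "unverifiable")
})

test_that("passive properties recover the ground-truth RC membrane", {
  p <- patch_sim_params(leak_ns = 1, c_pf = 50, seed = 4)
  cs <- gen_patch_cell(p, "current_steps")
  pp <- passive_properties(cs)
  expect_equal(pp$rmp_mv, -70, tolerance = 0.5)
  expect_equal(pp$r_in_gohm, 1, tolerance = 0.05)
  expect_equal(pp$tau_ms, 50, tolerance = 2.5)
  expect_equal(pp$c_m_pf, 50, tolerance = 2.5)
  # unit consistency: tau = R * C by construction of the estimate
  expect_equal(pp$tau_ms, pp$r_in_gohm * pp$c_m_pf, tolerance = 1e-9)
  # recovery across randomised cells, within 5%
  set.seed(30)
  for (i in 1:5) {
    g <- runif(1, 0.7, 2); cc <- runif(1, 30, 90)
    ps <- patch_sim_params(leak_ns = g, c_pf = cc, seed = 100 + i)
    prop <- passive_properties(gen_patch_cell(ps, "current_steps"))
    expect_equal(prop$r_in_gohm, 1 / g, tolerance = 0.05 / g)
    expect_equal(prop$tau_ms, cc / g, tolerance = 0.05 * cc / g)
    expect_equal(prop$c_m_pf, cc, tolerance = 0.05 * cc)
  }
})

test_that("spike detection matches the generator's spike times", {
  p <- patch_sim_params(seed = 2)
  cs <- gen_patch_cell(p, "current_steps")
  for (i in which(cs$steps %in% c(0, 60, 120, 200))) {
    det <- detect_action_potentials(cs$time_ms, cs$sweeps[[i]])
    expect_equal(length(det$spike_ms), length(cs$truth$spike_ms[[i]]))
  }
  # flat trace: none
  flat <- detect_action_potentials(seq(0, 100, 0.05),
                                   rep(-70, length(seq(0, 100, 0.05))))
  expect_equal(length(flat$spike_ms), 0)
})

test_that("the Kv conductance brakes firing at strong injections", {
  p_hi <- patch_sim_params(g_kv_ns = 10, seed = 2)
  p_lo <- patch_sim_params(g_kv_ns = 0, seed = 2)
  fi_hi <- fi_curve(gen_patch_cell(p_hi, "current_steps"))
  fi_lo <- fi_curve(gen_patch_cell(p_lo, "current_steps"))
  expect_lt(fi_hi$n_spikes[fi_hi$current_pa == 120],
            fi_lo$n_spikes[fi_lo$current_pa == 120])
  # rheobase (first non-zero count) unchanged
  rheo <- function(fi) fi$current_pa[fi$n_spikes > 0][1]
  expect_equal(rheo(fi_hi), rheo(fi_lo))
  # noiseless F-I is monotone non-decreasing
  expect_true(all(diff(fi_lo$n_spikes) >= 0))
  # sub-rheobase steps give zero
  expect_true(all(fi_lo$n_spikes[fi_lo$current_pa < rheo(fi_lo)] == 0))
})

test_that("AP kinetics follow waveform geometry", {
  # symmetric triangular spike: width at half-peak is half the base width
  dt <- 0.05
  up <- seq(-60, 40, length.out = 41)       # 2 ms rise, dV/dt = 50 V/s
  down <- seq(40, -60, length.out = 41)[-1]
  wf <- data.frame(t_ms = (seq_along(c(up, down)) - 21) * dt,
                   v_mv = c(up, down))
  kin <- ap_kinetics(list(wf))
  expect_equal(nrow(kin), 1)
  base_width <- 4  # ms from threshold crossing up to the symmetric fall
  expect_equal(kin$width_ms, base_width / 2, tolerance = 0.15)
  # amplitude reported by the peak-value convention
  expect_equal(kin$v_max_mv, 40)
  expect_equal(kin$threshold_mv, -60, tolerance = 3)
  # higher g_kv lowers the peak of the phase plane (noiseless model)
  pk <- vapply(c(0, 10, 20), function(g) {
    p <- patch_sim_params(g_kv_ns = g, seed = 3)
    cs <- gen_patch_cell(p, "current_steps")
    i <- which(cs$steps == 120)
    mean(ap_kinetics(detect_action_potentials(cs$time_ms,
                                              cs$sweeps[[i]])$waveforms)$peak_dvdt)
  }, numeric(1))
  expect_true(all(diff(pk) < 0))
})

test_that("DTX subtraction recovers the Boltzmann I-V", {
  p <- patch_sim_params(g_kv_ns = 5, c_pf = 50, seed = 6)
  base <- gen_patch_cell(p, "voltage_steps")
  drug <- gen_patch_cell(p, "voltage_steps", drug_applied = TRUE)
  dtx <- dtx_sensitive_current(base, drug, c_m_pf = 50)
  truth <- kv_current_truth(dtx$table$step_mv, p)
  big <- abs(truth) > 1
  expect_true(all(abs(dtx$table$deflection_pa[big] - truth[big]) /
                    abs(truth[big]) < 0.05))
  expect_equal(dtx$table$density_pa_pf, dtx$table$deflection_pa / 50)
  # identical inputs -> exactly zero
  z <- dtx_sensitive_current(base, base, 50)
  expect_true(all(z$table$deflection_pa == 0))
  # doubling the conductance doubles the density curve
  p2 <- patch_sim_params(g_kv_ns = 10, c_pf = 50, seed = 6)
  dtx2 <- dtx_sensitive_current(gen_patch_cell(p2, "voltage_steps"),
                                gen_patch_cell(p2, "voltage_steps",
                                               drug_applied = TRUE), 50)
  expect_equal(dtx2$table$deflection_pa[big], 2 * dtx$table$deflection_pa[big],
               tolerance = 1e-6)
  # protocol mismatch rejected
  short <- gen_patch_cell(p, "voltage_steps", step_range = seq(-80, 0, 10))
  expect_error(dtx_sensitive_current(base, short, 50), "match")
})

test_that("sEPSC detection recovers frequency and amplitude", {
  p <- patch_sim_params(epsc_rate_hz = 2, epsc_amp_pa = 20,
                        noise_sd_pa = 2, seed = 11)
  gf <- gen_patch_cell(p, "gap_free", duration_s = 60)
  det <- detect_sepscs(gf)
  n_true <- length(gf$truth$event_ms)
  expect_lt(abs(nrow(det$events) - n_true), 2.5 * sqrt(n_true))
  # amplitudes within ~10% at this SNR (amp 20 pA vs 2 pA noise)
  expect_equal(median(det$events$amplitude_pa), 20, tolerance = 2.5)
  expect_equal(median(det$events$rise_ms), 1.5, tolerance = 1)
  # event-free noise: false positives below 0.1 Hz
  pn <- patch_sim_params(epsc_rate_hz = 1e-9, noise_sd_pa = 2, seed = 12)
  gn <- gen_patch_cell(pn, "gap_free", duration_s = 60)
  expect_lt(detect_sepscs(gn)$frequency_hz, 0.1)
})

test_that("EPSC train analysis normalises to the first pulse", {
  dt <- 0.1
  t_ms <- seq(0, 1100, by = dt)
  pulses <- seq(50, 950, by = 100)            # 10 pulses at 10 Hz
  mk_train <- function(ratio) {
    tr <- rep(0, length(t_ms))
    for (k in seq_along(pulses)) {
      idx <- t_ms >= pulses[k] & t_ms < pulses[k] + 30
      tr[idx] <- tr[idx] - 100 * ratio^(k - 1) *
        exp(-(t_ms[idx] - pulses[k]) / 8)
    }
    tr
  }
  flat <- epsc_train_analysis(mk_train(1), t_ms, pulses)
  expect_equal(flat$relative_amplitude, rep(1, 10), tolerance = 1e-6)
  dep <- epsc_train_analysis(mk_train(0.9), t_ms, pulses)
  expect_equal(dep$relative_amplitude[1], 1)
  expect_equal(dep$relative_amplitude[10], 0.9^9, tolerance = 0.02)
  expect_error(epsc_train_analysis(mk_train(1), t_ms, seq(50, 500, 50)),
               "overlap")
})

test_that("baseline firing splits cells into the two classes", {
  r <- classify_baseline_activity(c(120, 123, 1.0, 0.9))
  expect_equal(as.character(r),
               c("putative_inhibitory", "putative_inhibitory",
                 "putative_excitatory", "putative_excitatory"))
  expect_true(all(classify_baseline_activity(rep(0, 6)) ==
                    "putative_excitatory"))
  expect_warning(classify_baseline_activity(c(1, 2, 3, 4)), "unimodal")
  # synthetic bimodal cohort: exact recovery
  set.seed(5)
  rates <- c(rlnorm(10, log(100), 0.2), rlnorm(14, log(1), 0.4))
  cl <- classify_baseline_activity(rates)
  expect_equal(as.character(cl),
               rep(c("putative_inhibitory", "putative_excitatory"),
                   c(10, 14)))
})
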