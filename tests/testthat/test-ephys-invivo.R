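test_that("CSD recovers the laminar inflection depth", {
  depths <- seq(0, 1550, by = 50)
  blk <- gen_flash_lfp(depths, 525, noise_sd = 0, seed = 1)
  dp <- compute_csd(blk$lfp, blk$depths, blk$times_s)
  expect_equal(dp$inflection_depth, 525, tolerance = 1e-6)
  expect_equal(dp$flag, "ok")
  expect_equal(dp$ssc_bounds, c(225, 625), tolerance = 1e-6)
  # noisy block: within one channel spacing
  blkn <- gen_flash_lfp(depths, 725, noise_sd = 0.3, seed = 9)
  dpn <- compute_csd(blkn$lfp, blkn$depths, blkn$times_s)
  expect_lt(abs(dpn$inflection_depth - 725), 50)
  # quadratic potential: constant CSD, no transition
  phi <- outer(depths^2 / 1e4, rep(1, 20))
  dq <- compute_csd(phi, depths, seq(0, 0.19, by = 0.01))
  expect_equal(dq$flag, "no_transition")
  expect_true(is.na(dq$inflection_depth))
  # swapped source/sink amplitudes flag polarity inversion
  sw <- gen_flash_lfp(depths, 525, source_amp = -1, sink_amp = -1)
  expect_equal(compute_csd(sw$lfp, sw$depths, sw$times_s)$flag,
               "polarity_inverted")
  expect_error(compute_csd(phi[1:4, ], depths[1:4], seq(0, 0.19, 0.01)),
               ">= 5 channels")
})

test_that("flash LFP generation is seed-deterministic", {
  a <- gen_flash_lfp(seq(0, 1550, 50), 500, noise_sd = 1, seed = 3)
  b <- gen_flash_lfp(seq(0, 1550, 50), 500, noise_sd = 1, seed = 3)
  expect_identical(a$lfp, b$lfp)
})

test_that("unit layers partition the probe span around the inflection depth", {
  d <- c(100, 300, 524, 626, 1200)
  expect_equal(assign_layer(d, 525),
               c("other", "sSC", "sSC", "idSC", "idSC"))
})

test_that("PSTH equals the event-averaged binned rate", {
  # single spike at lag 0 with one event: 1 / binwidth in the first bin
  ps <- compute_psth(0.001, events = 0, window = c(0, 0.1), bin_ms = 16.7)
  expect_equal(ps$rate_hz[1], 1 / 0.0167)
  expect_true(all(ps$rate_hz[-1] == 0))
  # no spikes: zero everywhere
  expect_true(all(compute_psth(numeric(0), 0:4)$rate_hz == 0))
  # homogeneous 10 Hz train: flat near 10 Hz
  set.seed(6)
  st <- sort(runif(2000, 0, 200))
  ps <- compute_psth(st, events = seq(10, 180, by = 10), window = c(0, 1))
  expect_equal(mean(ps$rate_hz), 10, tolerance = 0.8)
  expect_error(compute_psth(1, numeric(0)), "non-empty")
})

test_that("responsiveness p-values are calibrated and powerful", {
  # null: stationary Poisson units give uniform p-values
  null_p <- vapply(1:60, function(i) {
    set.seed(i)
    st <- sort(runif(rpois(1, 400), 0, 100))
    test_responsiveness(st, events = seq(35, 95, 6), window = c(0, 2),
                        recording_span = 100, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 0.01)
  # power: a strong loom transient is detected
  hits <- vapply(1:15, function(i) {
    lst <- loom_bout_stimulus(seed = i)
    u <- gen_visual_unit(visual_unit_params(loom_peak = 60, seed = i), lst)
    test_responsiveness(u$spike_times, lst$onsets, c(0, 0.7),
                        recording_span = lst$duration_s, seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # empty train
  expect_equal(test_responsiveness(numeric(0), 0:5, c(0, 1),
                                   recording_span = 10)$p, 1)
})

test_that("response clustering finds the CH-elbow and recovers mixtures", {
  set.seed(3)
  tmpl <- rbind(c(rep(5, 10), rep(0, 10)), c(rep(0, 10), rep(5, 10)))
  x <- tmpl[rep(1:2, each = 20), ] + matrix(rnorm(40 * 20, 0, 0.3), 40)
  cl <- cluster_responses(x, seed = 1)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$cluster[1:20])), 1)
  expect_equal(length(unique(cl$cluster[21:40])), 1)
  expect_false(cl$cluster[1] == cl$cluster[21])
  # identical rows
  expect_equal(cluster_responses(matrix(1, 5, 3))$k, 1)
  # fixed seed -> identical labels
  expect_identical(cluster_responses(x, seed = 5)$cluster,
                   cluster_responses(x, seed = 5)$cluster)
})

test_that("STA recovers centre, polarity and has sensible SNR", {
  stim <- fix_checker()
  u_on <- gen_visual_unit(visual_unit_params(rf_center = c(8, 9),
                                             rf_polarity = "ON", seed = 2),
                          stim)
  rf <- sta_receptive_field(u_on$spike_times, stim)
  expect_lte(max(abs(rf$center - c(8, 9))), 1)
  expect_equal(rf$polarity, "ON")
  u_off <- gen_visual_unit(visual_unit_params(rf_center = c(10, 7),
                                              rf_polarity = "OFF", seed = 3),
                           stim)
  rf_off <- sta_receptive_field(u_off$spike_times, stim)
  expect_equal(rf_off$polarity, "OFF")
  # OFF centre pixel is negative at the peak lag
  expect_lt(rf_off$spatial[which.max(abs(rf_off$spatial))], 0)
  # a spike-shuffled control scores below the tuned unit and fails the
  # 80th-percentile population criterion
  set.seed(5)
  sh <- sort(runif(length(u_on$spike_times), 0, 300))
  rf_sh <- sta_receptive_field(sh, stim)
  expect_lt(rf_sh$snr_db, rf$snr_db)
  pop <- c(rf$snr_db, rf_off$snr_db, rf_sh$snr_db, rf_sh$snr_db + 0.5,
           rf_sh$snr_db - 0.5)
  expect_false(flag_responsive_rf(pop)[3])
  # clock misalignment is rejected
  expect_error(sta_receptive_field(c(1, 500), stim), "misaligned")
  # low spike count flagged
  expect_true(sta_receptive_field(u_on$spike_times[1:20],
                                  stim)$low_confidence)
})

test_that("DSI follows its defining formula and flags degenerate input", {
  expect_equal(dsi_index(10, 5), 1 / 3)
  expect_equal(dsi_index(10, 0), 1)
  expect_equal(dsi_index(7, 7), 0)
  expect_true(is.na(dsi_index(0, 0)))
  # scaling invariance of the ratio
  expect_equal(dsi_index(30, 15), dsi_index(10, 5))
})

test_that("direction tuning normalises to baseline and finds D_p/D_np", {
  gst <- grating_stimulus(seed = 3)
  # deterministic rates: 20 Hz at 90 deg, 5 Hz at 270, 2 elsewhere
  rates <- setNames(rep(0, 8), as.character(seq(0, 315, 45)))
  rates["90"] <- 20; rates["270"] <- 5
  sp <- gratings_spikes(gst, rates, baseline_hz = 2)
  dt <- direction_selectivity(sp, gst)
  expect_equal(dt$pref_direction, 90)
  # normalised responses 20/2 and 5/2 give DSI (10 - 2.5)/(10 + 2.5)
  expect_equal(dt$dsi, 0.6, tolerance = 0.05)
  # untuned synthetic units fall below the DS population threshold
  set.seed(9)
  dsis <- vapply(1:12, function(i) {
    u <- gen_visual_unit(visual_unit_params(tuning_kappa = 0, resp_amp = 20,
                                            seed = i), gst)
    direction_selectivity(u$spike_times, gst)$dsi
  }, numeric(1))
  u_t <- gen_visual_unit(visual_unit_params(tuning_kappa = 4, resp_amp = 40,
                                            pref_direction = 135, seed = 50),
                         gst)
  d_t <- direction_selectivity(u_t$spike_times, gst)
  flags <- flag_direction_selective(c(dsis, d_t$dsi))
  expect_true(flags[13])
  expect_lte(mean(flags[1:12]), 0.25)
})

test_that("loom metrics recover the transient kernel", {
  lst <- loom_bout_stimulus(seed = 6)
  u <- gen_visual_unit(visual_unit_params(baseline_rate = 2, loom_peak = 80,
                                          loom_latency = 0.3,
                                          loom_decay = 0.06, seed = 6), lst)
  lmets <- loom_response_metrics(u$spike_times, lst$onsets)
  expect_equal(lmets$time_to_peak_s, 0.3, tolerance = 0.08)
  expect_gt(lmets$max_rate_hz, lmets$mean_rate_hz)
  expect_equal(length(lmets$per_loom_rate_hz), 5)
  # constant-rate unit: earliest-bin tie rule puts the peak in bin 1
  st <- seq(0.001, 40, by = 0.0167 / 4)  # 4 spikes every bin
  lm0 <- loom_response_metrics(st, bout_onsets = c(0, 10))
  expect_equal(lm0$time_to_peak_s, 0.0167 / 2, tolerance = 1e-3)
  # no spikes
  lme <- loom_response_metrics(numeric(0), 0)
  expect_equal(lme$mean_rate_hz, 0)
  expect_true(is.na(lme$time_to_peak_s))
})

test_that("motion classification separates bimodal energy and gates reps", {
  set.seed(12)
  energy <- c(rnorm(300, 1, 0.1), rnorm(300, 10, 0.5))
  m <- classify_motion(energy)
  expect_equal(m$moving, rep(c(FALSE, TRUE), each = 300))
  expect_true(all(!classify_motion(rep(3, 100))$moving))
  # 60% moving frames in a repetition -> running
  rep_idx <- rep(1:2, each = 10)
  mv <- c(rnorm(6, 10), rnorm(4, 1), rnorm(2, 10), rnorm(8, 1))
  m2 <- classify_motion(mv, rep_idx)
  expect_true(m2$running_reps[["1"]])
  expect_false(m2$running_reps[["2"]])
})

test_that("pupil diameter is the fitted ellipse major axis", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- cbind(3 + 2 * cos(th), -1 + 2 * sin(th))
  ell <- cbind(4 * cos(th), 2 * sin(th))
  set.seed(4)
  noisy <- ell + matrix(rnorm(length(ell), 0, 0.02), ncol = 2)
  colin <- cbind(1:6, 2 * (1:6))
  pd <- pupil_diameter(list(circ, ell, noisy, colin, circ[1:3, ]))
  expect_equal(pd$diameter[1], 4, tolerance = 1e-6)
  expect_equal(pd$diameter[2], 8, tolerance = 1e-6)
  expect_equal(pd$diameter[3], 8, tolerance = 0.16)  # within 2%
  expect_true(pd$flagged[4])
  expect_true(pd$flagged[5])
})
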