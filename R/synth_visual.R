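#' Visual stimulus descriptors for the synthetic unit generator
#'
#' Helpers building the stimulus descriptions consumed by
#' [gen_visual_unit()]: a shifting white-noise checkerboard, a full-field
#' flash block, loom bouts, drifting gratings/bars, and a grey screen.
#'
#' @param nx,ny Checker grid size (checker units).
#' @param duration_s Stimulus duration (s).
#' @param rate_hz Checker update rate (Hz, default 20).
#' @param seed Seed for the checker pattern.
#' @return A list with `kind` and kind-specific fields.
#' @export
checker_stimulus <- function(nx = 20, ny = 20, duration_s = 600,
                             rate_hz = 20, seed = 1L) {
  set.seed(seed)
  nt <- round(duration_s * rate_hz)
  frames <- array(sample(c(-1, 1), nx * ny * nt, replace = TRUE),
                  dim = c(nx, ny, nt))
  list(kind = "checker", frames = frames, dt = 1 / rate_hz,
       times = (seq_len(nt) - 1) / rate_hz, nx = nx, ny = ny)
}

#' @rdname checker_stimulus
#' @param n_reps Stimulus repetitions.
#' @param off_s,on_s Flash OFF / ON durations (s).
#' @param gap_s Grey gap between repetitions (s).
#' @export
flash_stimulus <- function(n_reps = 10, off_s = 0.5, on_s = 1, gap_s = 3) {
  period <- off_s + on_s + off_s + gap_s
  onsets <- 30 + (seq_len(n_reps) - 1) * period
  list(kind = "flash", onsets = onsets, off_s = off_s, on_s = on_s,
       duration_s = max(onsets) + period, baseline_s = 30)
}

#' @rdname checker_stimulus
#' @param n_looms Looms per bout.
#' @param loom_dur Single-loom duration (s).
#' @export
loom_bout_stimulus <- function(n_reps = 10, n_looms = 5, loom_dur = 0.75,
                               seed = 1L) {
  set.seed(seed)
  gaps <- runif(n_reps, 10, 30)
  onsets <- 30 + cumsum(gaps) - gaps[1]
  list(kind = "loom", onsets = onsets, n_looms = n_looms,
       loom_dur = loom_dur, duration_s = max(onsets) + n_looms * loom_dur + 30,
       baseline_s = 30)
}

#' @rdname checker_stimulus
#' @param directions Drift directions (deg).
#' @param reps Repetitions per direction.
#' @param trial_s Presentation length per direction trial (s).
#' @export
grating_stimulus <- function(directions = seq(0, 315, by = 45), reps = 2,
                             trial_s = 2, seed = 1L) {
  set.seed(seed)
  sched <- expand.grid(rep = seq_len(reps), direction = directions)
  sched <- sched[sample(nrow(sched)), ]
  sched$onset_s <- 30 + (seq_len(nrow(sched)) - 1) * (trial_s + 1)
  list(kind = "gratings", schedule = sched, trial_s = trial_s,
       duration_s = max(sched$onset_s) + trial_s + 1, baseline_s = 30)
}

#' @rdname checker_stimulus
#' @export
grey_stimulus <- function(duration_s = 60) {
  list(kind = "grey", duration_s = duration_s)
}

#' Ground-truth parameters of a synthetic visual unit
#'
#' @param baseline_rate Spontaneous rate (Hz).
#' @param rf_center Receptive-field centre, checker coordinates (x, y).
#' @param rf_radius Gaussian RF radius (checker units).
#' @param rf_polarity `"ON"` or `"OFF"`.
#' @param rf_gain Linear drive gain (Hz per unit stimulus projection).
#' @param tuning_kappa Von Mises concentration of direction tuning.
#' @param pref_direction Preferred direction (deg, in `[0, 360)`).
#' @param resp_amp Peak added rate for gratings (Hz).
#' @param loom_peak,loom_latency,loom_decay Loom transient: peak added rate
#'   (Hz), time-to-peak within a loom (s), Gaussian half-width (s).
#' @param depth Unit depth (um).
#' @param seed Seed for spike generation.
#' @export
visual_unit_params <- function(baseline_rate = 5, rf_center = c(10, 10),
                               rf_radius = 1.5, rf_polarity = c("ON", "OFF"),
                               rf_gain = 4, tuning_kappa = 2,
                               pref_direction = 0, resp_amp = 20,
                               loom_peak = 40, loom_latency = 0.3,
                               loom_decay = 0.1, depth = 300, seed = 1L) {
  rf_polarity <- match.arg(rf_polarity)
  stop_if(baseline_rate < 0 || resp_amp < 0 || loom_peak < 0,
          "rates must be >= 0")
  stop_if(pref_direction < 0 || pref_direction >= 360,
          "pref_direction must be in [0, 360)")
  structure(list(baseline_rate = baseline_rate, rf_center = rf_center,
                 rf_radius = rf_radius, rf_polarity = rf_polarity,
                 rf_gain = rf_gain, tuning_kappa = tuning_kappa,
                 pref_direction = pref_direction, resp_amp = resp_amp,
                 loom_peak = loom_peak, loom_latency = loom_latency,
                 loom_decay = loom_decay, depth = depth,
                 seed = as.integer(seed)),
            class = "visual_unit_params")
}

# spikes from a piecewise-constant rate (Hz) on a uniform grid
sample_inhomogeneous <- function(rate, dt, t0 = 0) {
  counts <- rpois(length(rate), pmax(rate, 0) * dt)
  idx <- rep(seq_along(rate), counts)
  if (!length(idx)) return(numeric(0))
  sort(t0 + (idx - 1) * dt + runif(length(idx)) * dt)
}

#' Simulate a visual unit's spike train for one stimulus
#'
#' Inhomogeneous-Poisson spiking.  For checker stimuli the rate is a
#' rectified-linear function of the projection of each frame onto the
#' ground-truth Gaussian receptive field; for gratings the added rate
#' follows von Mises direction tuning; for loom bouts a Gaussian transient
#' kernel repeats within every loom; flash adds an onset transient; grey is
#' homogeneous at baseline.
#'
#' @param params A [visual_unit_params()].
#' @param stimulus A stimulus descriptor (see [checker_stimulus()]).
#' @return list with `spike_times` (s, strictly increasing), `stimulus`,
#'   `truth` (the params) and `duration_s`.
#' @export
gen_visual_unit <- function(params, stimulus) {
  stop_if(!inherits(params, "visual_unit_params"), "invalid params")
  stop_if(is.null(stimulus$kind) ||
            !stimulus$kind %in% c("checker", "flash", "loom", "gratings",
                                  "grey"),
          "unknown stimulus kind")
  set.seed(params$seed)
  sgn <- if (params$rf_polarity == "ON") 1 else -1
  spikes <- switch(
    stimulus$kind,
    grey = sample_inhomogeneous(rep(params$baseline_rate,
                                    round(stimulus$duration_s * 100)), 0.01),
    checker = {
      gx <- seq_len(stimulus$nx); gy <- seq_len(stimulus$ny)
      w <- outer(gx, gy, function(a, b)
        exp(-((a - params$rf_center[1])^2 + (b - params$rf_center[2])^2) /
              (2 * params$rf_radius^2)))
      w <- sgn * w / sqrt(sum(w^2))
      drive <- apply(stimulus$frames, 3, function(f) sum(w * f))
      rate <- pmax(0, params$baseline_rate + params$rf_gain * drive)
      sample_inhomogeneous(rate, stimulus$dt)
    },
    flash = {
      dt <- 0.005
      tt <- seq(0, stimulus$duration_s, by = dt)
      rate <- rep(params$baseline_rate, length(tt))
      for (on in stimulus$onsets + stimulus$off_s) {
        rel <- tt - on
        k <- rel >= 0 & rel < 0.5
        rate[k] <- rate[k] + params$loom_peak * exp(-rel[k] / 0.1)
      }
      sample_inhomogeneous(rate, dt)
    },
    loom = {
      dt <- 0.005
      tt <- seq(0, stimulus$duration_s, by = dt)
      rate <- rep(params$baseline_rate, length(tt))
      for (on in stimulus$onsets) {
        for (l in seq_len(stimulus$n_looms) - 1) {
          rel <- tt - (on + l * stimulus$loom_dur)
          k <- rel >= 0 & rel < stimulus$loom_dur
          rate[k] <- rate[k] + params$loom_peak *
            exp(-(rel[k] - params$loom_latency)^2 /
                  (2 * params$loom_decay^2))
        }
      }
      sample_inhomogeneous(rate, dt)
    },
    gratings = {
      dt <- 0.01
      tt <- seq(0, stimulus$duration_s, by = dt)
      rate <- rep(params$baseline_rate, length(tt))
      for (r in seq_len(nrow(stimulus$schedule))) {
        on <- stimulus$schedule$onset_s[r]
        th <- stimulus$schedule$direction[r]
        dang <- (th - params$pref_direction) * pi / 180
        amp <- params$resp_amp * exp(params$tuning_kappa * (cos(dang) - 1))
        k <- tt >= on & tt < on + stimulus$trial_s
        rate[k] <- rate[k] + amp
      }
      sample_inhomogeneous(rate, dt)
    })
  list(spike_times = spikes, stimulus = stimulus, truth = params,
       duration_s = stimulus$duration_s %||%
         (length(stimulus$times) * stimulus$dt))
}

#' Synthetic flash-locked laminar LFP block
#'
#' Builds a laminar LFP by double-integrating a template current source
#' density with a source above and a sink below the ground-truth inflection
#' depth (so that the plain second-difference estimator recovers the
#' template exactly in the noiseless case), repeated over flash
#' presentations with independent noise.
#'
#' @param depth_grid Uniformly spaced channel depths (um, increasing
#'   downward).
#' @param inflection_depth Ground-truth source-to-sink transition depth (um).
#' @param noise_sd Additive LFP noise SD (same units as the LFP).
#' @param seed Integer seed.
#' @param n_reps Flash repetitions (default 10).
#' @param source_amp,sink_amp Amplitudes of the source and sink lobes;
#'   swapping their signs produces a polarity-inverted profile.
#' @return list with `lfp` (channel x time x rep array), `depths`,
#'   `times_s`, and `truth` (inflection depth).
#' @export
gen_flash_lfp <- function(depth_grid, inflection_depth, noise_sd = 0,
                          seed = 1L, n_reps = 10,
                          source_amp = 1, sink_amp = 1) {
  h <- diff(depth_grid)
  stop_if(length(depth_grid) < 5, "need >= 5 channels")
  stop_if(max(abs(h - h[1])) > 1e-6, "depth grid must be uniformly spaced")
  stop_if(inflection_depth <= min(depth_grid) ||
            inflection_depth >= max(depth_grid),
          "inflection depth must lie inside the channel span")
  set.seed(seed)
  h <- h[1]
  z <- depth_grid
  delta <- 1.5 * h; s <- h
  csd_profile <- source_amp * exp(-(z - (inflection_depth - delta))^2 /
                                    (2 * s^2)) -
    sink_amp * exp(-(z - (inflection_depth + delta))^2 / (2 * s^2))
  times <- seq(0, 0.2, by = 0.002)
  kern <- exp(-(times - 0.04)^2 / (2 * 0.01^2))
  csd <- outer(csd_profile, kern)
  # phi such that -(second difference)/h^2 equals the template exactly
  phi <- apply(csd, 2, function(ct) {
    g <- -h * cumsum(ct)
    cumsum(c(0, g[-length(g)])) * h
  })
  lfp <- array(0, dim = c(length(z), length(times), n_reps))
  for (r in seq_len(n_reps))
    lfp[, , r] <- phi + matrix(rnorm(length(phi), 0, noise_sd), nrow(phi))
  list(lfp = lfp, depths = z, times_s = times,
       truth = list(inflection_depth = inflection_depth,
                    csd_profile = csd_profile))
}
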