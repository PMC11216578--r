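# Shared fixtures, built once per test run.

# small checker stimulus reused by the STA tests
fix_checker <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- checker_stimulus(nx = 16, ny = 16,
                                               duration_s = 300, seed = 42)
    val
  }
})

# a straight-line trajectory sampled at 60 Hz
line_trajectory <- function(from, to, speed, frame_rate = 60, pad_s = 0) {
  d <- sqrt(sum((to - from)^2))
  n <- ceiling(d / (speed / frame_rate))
  f <- seq(0, 1, length.out = n + 1)
  x <- from[1] + f * (to[1] - from[1])
  y <- from[2] + f * (to[2] - from[2])
  if (pad_s > 0) {
    np <- round(pad_s * frame_rate)
    x <- c(x, rep(tail(x, 1), np))
    y <- c(y, rep(tail(y, 1), np))
  }
  data.frame(time_s = (seq_along(x) - 1) / frame_rate, x_cm = x, y_cm = y)
}

# deterministic gratings spike train: fixed within-trial rates per direction
gratings_spikes <- function(stimulus, rates_by_dir, baseline_hz = 2) {
  sched <- stimulus$schedule
  sp <- seq(0.05, 29.95, by = 1 / baseline_hz)  # regular baseline train
  for (r in seq_len(nrow(sched))) {
    k <- rates_by_dir[as.character(sched$direction[r])]
    if (k > 0)
      sp <- c(sp, sched$onset_s[r] +
                seq(0, stimulus$trial_s - 1e-6, length.out = k * stimulus$trial_s))
  }
  sort(sp)
}
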