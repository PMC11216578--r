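#' Parameters for the synthetic looming-escape session generator
#'
#' Defines a 4-state (shelter / explore / arrest / escape) locomotion agent
#' in the standard 32 cm arena.  Exploration speed follows a mean-reverting
#' (Ornstein-Uhlenbeck) positive process; an escape is a straight run back
#' to the shelter whose speed follows a raised-cosine bump peaking at the
#' drawn peak speed; an arrest is a transient locomotor stop.  Escape
#' latency is drawn from a log-normal distribution so that genotype presets
#' differ in both timing and vigour.
#'
#' @param genotype Preset name: `"wildtype"` (fast, vigorous, reliable
#'   first-loom escapes) or `"mutant"` (delayed, less vigorous, frequent
#'   arrests).  Presets are anchored to the scales printed for the two
#'   genotypes in the source experiments (latency medians 0.3 vs 1.5 s,
#'   peak escape speeds near 63 vs 50 cm/s, exploration speed near 7.5 cm/s).
#' @param arena An [arena_config()].
#' @param session_length Seconds of tracked time per day (default 540,
#'   i.e. three 180 s closed-loop tests).
#' @param escape_latency_median,escape_latency_shape Median (s) and log-sd
#'   of the log-normal reaction-time distribution.
#' @param escape_prob_per_loom Per-loom escape hazard in `[0, 1]`; the bout
#'   escape probability is `1 - (1 - p)^n_looms`.
#' @param arrest_prob Probability of an arrest on a stimulated, non-escape
#'   trial.
#' @param peak_speed_mean,peak_speed_sd Escape peak ("vigour") speed draw
#'   (cm/s).
#' @param explore_speed_mean,explore_speed_tau,explore_speed_sigma OU
#'   exploration-speed process: mean (cm/s), relaxation time (s), noise
#'   intensity (cm/s per sqrt(s)).
#' @param exits_per_session Expected shelter exits per session day.
#' @param adaptation_factor Per-day multiplier on the exit rate.
#' @param tracking_noise_sd Isotropic centroid tracking noise (cm).
#' @param n_looms Looms per triggered bout.
#' @param seed Integer seed; the generator is a pure function of
#'   (params, seed).
#' @return An object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(genotype = c("wildtype", "mutant"),
                                arena = arena_config(),
                                session_length = 540,
                                escape_latency_median = NULL,
                                escape_latency_shape = 0.5,
                                escape_prob_per_loom = NULL,
                                arrest_prob = NULL,
                                peak_speed_mean = NULL,
                                peak_speed_sd = 8,
                                explore_speed_mean = 7.5,
                                explore_speed_tau = 1,
                                explore_speed_sigma = 3,
                                exits_per_session = 8,
                                adaptation_factor = 1,
                                tracking_noise_sd = 0.02,
                                n_looms = 5,
                                seed = 1L) {
  genotype <- match.arg(genotype)
  preset <- if (genotype == "wildtype") {
    list(lat = 0.3, p = 0.9, arr = 0.05, vp = 63)
  } else {
    list(lat = 1.5, p = 0.3, arr = 0.5, vp = 50)
  }
  p <- list(
    genotype = genotype, arena = arena, session_length = session_length,
    escape_latency_median = escape_latency_median %||% preset$lat,
    escape_latency_shape = escape_latency_shape,
    escape_prob_per_loom = escape_prob_per_loom %||% preset$p,
    arrest_prob = arrest_prob %||% preset$arr,
    peak_speed_mean = peak_speed_mean %||% preset$vp,
    peak_speed_sd = peak_speed_sd,
    explore_speed_mean = explore_speed_mean,
    explore_speed_tau = explore_speed_tau,
    explore_speed_sigma = explore_speed_sigma,
    exits_per_session = exits_per_session,
    adaptation_factor = adaptation_factor,
    tracking_noise_sd = tracking_noise_sd,
    n_looms = n_looms, seed = as.integer(seed))
  check_finite(p[!(names(p) %in% c("genotype", "arena"))], "behavior_sim_params")
  stop_if(p$escape_prob_per_loom < 0 || p$escape_prob_per_loom > 1 ||
            p$arrest_prob < 0 || p$arrest_prob > 1,
          "probabilities must lie in [0, 1]")
  stop_if(p$escape_latency_median <= 0, "latency median must be > 0")
  stop_if(arena$trigger_radius >= arena$arena_side / 2 + arena$shelter_side,
          "trigger radius incompatible with arena")
  structure(p, class = "behavior_sim_params")
}

# fold a coordinate into [lo, hi] by reflection
fold_coord <- function(z, lo, hi) {
  w <- hi - lo
  z <- (z - lo) %% (2 * w)
  ifelse(z > w, 2 * w - z, z) + lo
}

# OU speed + diffusing-heading wander of n frames from pos0; positions are
# reflected into the arena and kept outside the dilated shelter footprint
sim_wander <- function(n, pos0, params) {
  cfg <- params$arena
  dt <- 1 / cfg$frame_rate
  if (n <= 0) return(list(x = numeric(0), y = numeric(0), v_end = NULL))
  v <- numeric(n)
  v[1] <- max(0.2, rnorm(1, params$explore_speed_mean, 2))
  eta <- rnorm(n)
  a <- dt / params$explore_speed_tau
  for (i in seq_len(n)[-1]) {
    v[i] <- max(0.2, v[i - 1] + (params$explore_speed_mean - v[i - 1]) * a +
                  params$explore_speed_sigma * sqrt(dt) * eta[i])
  }
  theta <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 1, 0, 2.2 * sqrt(dt))))
  dx <- v * dt * cos(theta)
  dy <- v * dt * sin(theta)
  half <- cfg$arena_side / 2 - 0.4
  # the agent slides along the dilated shelter boundary instead of entering
  # it, so an exploration bout is a single, well-defined out-of-shelter
  # episode; walls mirror the step.  Per-step handling keeps frame-to-frame
  # displacements bounded by the drawn speed.
  r_min <- cfg$shelter_side / 2 + cfg$exit_hysteresis + 0.3
  sx <- cfg$shelter_center[1]; sy <- cfg$shelter_center[2]
  x <- numeric(n); y <- numeric(n)
  px <- pos0[1]; py <- pos0[2]
  for (i in seq_len(n)) {
    nx <- px + dx[i]; ny <- py + dy[i]
    if (nx > half) nx <- 2 * half - nx else if (nx < -half) nx <- -2 * half - nx
    if (ny > half) ny <- 2 * half - ny else if (ny < -half) ny <- -2 * half - ny
    rx <- nx - sx; ry <- ny - sy
    r <- sqrt(rx^2 + ry^2)
    if (r < r_min) {
      prx <- px - sx; pry <- py - sy
      pr <- max(sqrt(prx^2 + pry^2), 1e-9)
      ux <- prx / pr; uy <- pry / pr
      step_r <- (nx - px) * ux + (ny - py) * uy
      nx <- px + (nx - px) - step_r * ux
      ny <- py + (ny - py) - step_r * uy
      rx <- nx - sx; ry <- ny - sy
      r <- max(sqrt(rx^2 + ry^2), 1e-9)
      if (r < r_min) {
        nx <- sx + rx / r * r_min
        ny <- sy + ry / r * r_min
      }
    }
    x[i] <- nx; y[i] <- ny
    px <- nx; py <- ny
  }
  list(x = x, y = y)
}

# straight constant-speed path from `from` towards `to`, ending when within
# `stop_dist` of `to` (always emits at least one frame)
sim_run <- function(from, to, speed, stop_dist, frame_rate) {
  u <- to - from
  d_tot <- sqrt(sum(u^2))
  u <- u / max(d_tot, 1e-9)
  n <- max(1, ceiling((d_tot - stop_dist) / (speed / frame_rate)))
  s <- seq_len(n) * speed / frame_rate
  list(x = from[1] + u[1] * s, y = from[2] + u[2] * s)
}

#' Simulate a closed-loop looming-escape session
#'
#' Generates a tracked session (60 Hz centroid plus snout and back-paw
#' points), the stimulus log produced by the closed-loop trigger rule
#' (outward crossing of the trigger radius with a 30 s refractory period),
#' and a full ground-truth record: per-frame latent state, per-trial
#' outcome, true reaction time and peak speed, and exit episodes.
#'
#' On each stimulated trial the agent escapes with probability
#' `1 - (1 - escape_prob_per_loom)^n_looms`; otherwise it arrests with
#' probability `arrest_prob` or continues exploring.  The true reaction time
#' of an escape is the time from stimulus onset to the peak of the
#' raised-cosine escape speed bump (a drawn hazard delay plus half the bump
#' width), so the downstream reaction-time estimator can be scored exactly.
#'
#' @param params A [behavior_sim_params()].
#' @param n_days Number of consecutive session days (>= 1).
#' @param stimulus_kind `"loom"` or `"laser"`; recorded in the stimulus log.
#' @return A list with elements `session` (data.frame: day, time_s, x_cm,
#'   y_cm, snout_x, snout_y, back_x, back_y), `stim_log` (day, onset_s,
#'   kind), `truth` (list: `states` character per frame, `trials`
#'   data.frame, `exits` data.frame per day) and `params`.
#' @export
gen_ler_session <- function(params, n_days = 1,
                            stimulus_kind = c("loom", "laser")) {
  stimulus_kind <- match.arg(stimulus_kind)
  stop_if(!inherits(params, "behavior_sim_params"), "invalid params")
  stop_if(n_days < 1, "n_days must be >= 1")
  cfg <- params$arena
  fr <- cfg$frame_rate
  dt <- 1 / fr
  set.seed(params$seed)

  loom_dur <- 0.75
  p_escape <- 1 - (1 - params$escape_prob_per_loom)^params$n_looms
  door <- cfg$shelter_center + c(0, cfg$shelter_side / 2)   # towards arena
  r_leave <- cfg$shelter_side / 2 + cfg$exit_hysteresis + 0.3
  leave_to <- cfg$shelter_center + c(0, r_leave)

  all_frames <- list(); all_trials <- list(); all_exits <- list()
  all_stim <- list()

  for (day in seq_len(n_days)) {
    n_target <- round(params$session_length * fr)
    exits_day <- params$exits_per_session *
      params$adaptation_factor^(day - 1)
    shelter_mean <- max(3, params$session_length / max(exits_day, 0.5) - 21)
    xs <- ys <- numeric(0); st <- character(0)
    trials <- list(); stim <- list()
    last_onset <- -Inf
    n_exits <- 0L

    add <- function(seg_x, seg_y, seg_st) {
      xs <<- c(xs, seg_x); ys <<- c(ys, seg_y); st <<- c(st, seg_st)
    }
    t_now <- function() length(xs) * dt

    while (length(xs) < n_target) {
      # shelter stay
      n_sh <- max(round(fr * 1), round(fr * rexp(1, 1 / shelter_mean)))
      add(cfg$shelter_center[1] + rnorm(n_sh, 0, 0.03),
          cfg$shelter_center[2] + rnorm(n_sh, 0, 0.03),
          rep("shelter", n_sh))
      if (length(xs) >= n_target) break

      # deterministic leave: centre -> just beyond the dilated boundary
      lv <- sim_run(cfg$shelter_center, leave_to, 9, 0, fr)
      lv_in <- in_shelter(lv$x, lv$y, cfg)
      add(lv$x, lv$y, ifelse(lv_in, "shelter", "explore"))
      n_exits <- n_exits + 1L
      pos <- c(tail(xs, 1), tail(ys, 1))

      # exploration bout
      n_b <- round(fr * min(120, max(4, rexp(1, 1 / 18))))
      w <- sim_wander(n_b, pos, params)
      d <- shelter_distance(w$x, w$y, cfg)
      d_prev <- c(shelter_distance(pos[1], pos[2], cfg), d[-length(d)])
      cross <- which(d > cfg$trigger_radius & d_prev <= cfg$trigger_radius)
      t_base <- t_now()   # time of the frame after the last appended one
      elig <- cross[t_base + (cross - 1) * dt - last_onset >= cfg$refractory]

      if (length(elig) == 0) {
        add(w$x, w$y, rep("explore", n_b))
      } else {
        k <- elig[1]
        add(w$x[seq_len(k)], w$y[seq_len(k)], rep("explore", k))
        onset <- t_now() - dt   # time of the crossing frame
        last_onset <- onset
        stim[[length(stim) + 1]] <-
          data.frame(day = day, onset_s = onset, kind = stimulus_kind)
        pos_k <- c(w$x[k], w$y[k])
        u <- runif(1)
        if (u < p_escape) {
          rt_target <- rlnorm(1, log(params$escape_latency_median),
                              params$escape_latency_shape)
          vp <- max(25, rnorm(1, params$peak_speed_mean, params$peak_speed_sd))
          w0 <- 2 * max(d[k] - cfg$shelter_side / 2, 2) / vp
          delay <- max(0, rt_target - w0 / 2)
          nd <- round(delay * fr)
          if (nd > 0) {
            idx <- k + seq_len(min(nd, n_b - k))
            if (length(idx) > 0)
              add(w$x[idx], w$y[idx], rep("explore", length(idx)))
            short <- nd - length(idx)
            if (short > 0) {
              ext <- sim_wander(short, c(tail(xs, 1), tail(ys, 1)), params)
              add(ext$x, ext$y, rep("explore", short))
            }
          }
          start <- c(tail(xs, 1), tail(ys, 1))
          d_run <- shelter_distance(start[1], start[2], cfg)
          bump_w <- 2 * d_run / vp
          tt <- seq_len(ceiling(bump_w * fr)) * dt
          sp <- vp / 2 * (1 - cos(2 * pi * pmin(tt, bump_w) / bump_w))
          uvec <- (cfg$shelter_center - start) / d_run
          disp <- cumsum(sp * dt)
          ex <- start[1] + uvec[1] * disp
          ey <- start[2] + uvec[2] * disp
          # the run completes its deceleration inside the shelter, so the
          # speed peak sits clearly before entry and decays smoothly
          inside <- in_shelter(ex, ey, cfg)
          entry <- if (any(inside)) which(inside)[1] else length(ex)
          lab <- rep("escape", length(ex))
          if (entry < length(ex)) lab[(entry + 1):length(ex)] <- "shelter"
          add(ex, ey, lab)
          true_rt <- (nd + which.max(sp)) * dt
          trials[[length(trials) + 1]] <- data.frame(
            day = day, onset_s = onset, outcome = "escape",
            reaction_time_s = true_rt, peak_speed = max(sp),
            dist_at_onset = d[k])
        } else if (u < p_escape + (1 - p_escape) * params$arrest_prob) {
          n_pre <- round(runif(1, 0.1, 0.25) * fr)
          idx <- k + seq_len(min(n_pre, n_b - k))
          if (length(idx) > 0)
            add(w$x[idx], w$y[idx], rep("explore", length(idx)))
          pos_a <- c(tail(xs, 1), tail(ys, 1))
          n_a <- round(runif(1, 1.2, 3) * fr)
          add(pos_a[1] + rnorm(n_a, 0, 0.02),
              pos_a[2] + rnorm(n_a, 0, 0.02), rep("arrest", n_a))
          trials[[length(trials) + 1]] <- data.frame(
            day = day, onset_s = onset, outcome = "arrest",
            reaction_time_s = NA_real_, peak_speed = NA_real_,
            dist_at_onset = d[k])
        } else {
          idx <- k + seq_len(n_b - k)
          if (length(idx) > 0)
            add(w$x[idx], w$y[idx], rep("explore", length(idx)))
          trials[[length(trials) + 1]] <- data.frame(
            day = day, onset_s = onset, outcome = "none",
            reaction_time_s = NA_real_, peak_speed = NA_real_,
            dist_at_onset = d[k])
        }
      }

      # return to shelter centre unless the escape already ended inside
      if (tail(st, 1) != "escape") {
        pos_r <- c(tail(xs, 1), tail(ys, 1))
        rt <- sim_run(pos_r, cfg$shelter_center, 12, 0, fr)
        rt_in <- in_shelter(rt$x, rt$y, cfg)
        add(rt$x, rt$y, ifelse(rt_in, "shelter", "explore"))
      }
    }

    keep <- seq_len(n_target)
    xs <- xs[keep]; ys <- ys[keep]; st <- st[keep]
    tr <- if (length(trials)) do.call(rbind, trials) else
      data.frame(day = integer(0), onset_s = numeric(0),
                 outcome = character(0), reaction_time_s = numeric(0),
                 peak_speed = numeric(0), dist_at_onset = numeric(0))
    # drop trials whose response window was truncated by session end
    tr <- tr[tr$onset_s + 10 <= params$session_length - 2 * dt &
               tr$onset_s >= 3, , drop = FALSE]
    sg <- if (length(stim)) do.call(rbind, stim) else
      data.frame(day = integer(0), onset_s = numeric(0), kind = character(0))
    all_frames[[day]] <- data.frame(day = day,
                                    time_s = (seq_len(n_target) - 1) * dt,
                                    x = xs, y = ys, state = st)
    all_trials[[day]] <- tr
    all_stim[[day]] <- sg
    all_exits[[day]] <- data.frame(day = day, n_exits = n_exits)
  }

  frames <- do.call(rbind, all_frames)
  # tracking noise on the reported centroid only (latent states untouched)
  x_obs <- frames$x + rnorm(nrow(frames), 0, params$tracking_noise_sd)
  y_obs <- frames$y + rnorm(nrow(frames), 0, params$tracking_noise_sd)
  # heading from smoothed displacement; snout/back 1.5 cm fore/aft
  dx <- c(0, diff(frames$x)); dy <- c(0, diff(frames$y))
  dx <- as.numeric(stats::filter(dx, rep(1 / 5, 5), sides = 2))
  dy <- as.numeric(stats::filter(dy, rep(1 / 5, 5), sides = 2))
  dx[is.na(dx)] <- 0; dy[is.na(dy)] <- 0
  nrm <- sqrt(dx^2 + dy^2)
  ok <- nrm > 1e-6
  ux <- rep(0, length(dx)); uy <- rep(-1, length(dy))
  ux[ok] <- dx[ok] / nrm[ok]; uy[ok] <- dy[ok] / nrm[ok]
  # carry last heading through stationary stretches
  for (i in seq_along(ux)[-1]) {
    if (!ok[i]) { ux[i] <- ux[i - 1]; uy[i] <- uy[i - 1] }
  }
  session <- data.frame(
    day = frames$day, time_s = frames$time_s,
    x_cm = x_obs, y_cm = y_obs,
    snout_x = x_obs + 1.5 * ux, snout_y = y_obs + 1.5 * uy,
    back_x = x_obs - 1.5 * ux, back_y = y_obs - 1.5 * uy)

  list(session = session,
       stim_log = do.call(rbind, all_stim),
       truth = list(states = frames$state,
                    trials = do.call(rbind, all_trials),
                    exits = do.call(rbind, all_exits)),
       params = params)
}
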