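#' Smoothed locomotion speed from a tracked trajectory
#'
#' Frame-to-frame displacement rate smoothed with a centred moving mean over
#' an 83 ms window (5 frames at 60 Hz; the window is rounded to the nearest
#' odd frame count).  Edge frames use shrinking windows so the series has
#' the same length as the trajectory.
#'
#' @param trajectory data.frame with `time_s`, `x_cm`, `y_cm`.
#' @param window_ms Smoothing window (ms).
#' @return data.frame with `time_s` and `speed` (cm/s).
#' @export
compute_speed <- function(trajectory, window_ms = 83) {
  stop_if(nrow(trajectory) < 2, "need at least 2 frames")
  dts <- diff(trajectory$time_s)
  stop_if(any(dts <= 0), "timestamps must be strictly increasing")
  disp <- sqrt(diff(trajectory$x_cm)^2 + diff(trajectory$y_cm)^2)
  raw <- c(disp[1] / dts[1], disp / dts)
  fr <- 1 / median(dts)
  w <- round(window_ms / 1000 * fr)
  if (w %% 2 == 0) w <- w + c(-1, 1)[which.min(abs(w + c(-1, 1) -
                                                     window_ms / 1000 * fr))]
  w <- max(1, w)
  half <- (w - 1) / 2
  n <- length(raw)
  cs <- cumsum(c(0, raw))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  data.frame(time_s = trajectory$time_s, speed = sm)
}

#' Emulate the closed-loop stimulus trigger
#'
#' Re-derives the stimulus log from a trajectory using the closed-loop rule:
#' a stimulus starts at the first outward crossing of the trigger radius
#' (distance from the shelter centre) with at least `refractory` seconds
#' since the previous onset.
#'
#' @param trajectory data.frame with `time_s`, `x_cm`, `y_cm`.
#' @param config An [arena_config()].
#' @return data.frame with column `onset_s`.
#' @export
emulate_closed_loop <- function(trajectory, config) {
  half <- config$arena_side / 2
  x <- trajectory$x_cm; y <- trajectory$y_cm
  if (any(abs(x) > half | abs(y) > half, na.rm = TRUE)) {
    warning("trajectory leaves arena bounds; clamping for distance computation")
    x <- pmin(pmax(x, -half), half)
    y <- pmin(pmax(y, -half), half)
  }
  d <- shelter_distance(x, y, config)
  out <- d > config$trigger_radius
  cross <- which(out[-1] & !out[-length(out)]) + 1L
  onsets <- numeric(0)
  last <- -Inf
  for (i in cross) {
    ti <- trajectory$time_s[i]
    if (ti - last >= config$refractory) {
      onsets <- c(onsets, ti)
      last <- ti
    }
  }
  data.frame(onset_s = onsets)
}

#' Classify a single stimulated trial as escape or no-response
#'
#' A trial is an escape if the animal returned to the shelter within 7 s of
#' stimulus onset and reached a smoothed speed of at least 20 cm/s between
#' onset and shelter entry.  The reaction time is the time from onset to the
#' maximum of the speed trace in that interval, and the loom presentation
#' containing that peak gives the looms-to-escape category (`"1"`..`"5"`,
#' `">5"`, or `"NR"`).  Loom windows are half-open
#' `[(i-1) * 0.75, i * 0.75)` s.
#'
#' @param onset_s Stimulus onset (s).
#' @param speed A speed series from [compute_speed()].
#' @param in_shelter Logical vector (same frames) marking shelter occupancy.
#' @param return_limit,vigour_threshold Escape criteria: maximum return
#'   latency (s) and minimum peak speed (cm/s).
#' @param loom_dur,n_looms Loom presentation duration (s) and count.
#' @param pre,post Analysis window around onset (s).
#' @return One-row data.frame with `onset_s`, `is_escape`, `reaction_time`,
#'   `max_escape_speed`, `looms_to_escape`, `valid`.
#' @export
classify_escape <- function(onset_s, speed, in_shelter,
                            return_limit = 7, vigour_threshold = 20,
                            loom_dur = 0.75, n_looms = 5,
                            pre = 3, post = 10) {
  t <- speed$time_s
  stop_if(length(in_shelter) != length(t),
          "occupancy series must match the speed series")
  stop_if(onset_s - pre < t[1] - 1e-9 || onset_s + post > tail(t, 1) + 1e-9,
          "trial window not fully covered by the speed series")
  i0 <- which(t >= onset_s)[1]
  res <- data.frame(onset_s = onset_s, is_escape = FALSE,
                    reaction_time = NA_real_, max_escape_speed = NA_real_,
                    looms_to_escape = "NR", valid = TRUE,
                    stringsAsFactors = FALSE)
  if (in_shelter[i0]) {
    res$valid <- FALSE
    return(res)
  }
  post_idx <- which(t > onset_s & t <= onset_s + post)
  entry_rel <- which(in_shelter[post_idx])
  entry_i <- if (length(entry_rel)) post_idx[entry_rel[1]] else NA_integer_
  returned <- !is.na(entry_i) && t[entry_i] - onset_s <= return_limit
  if (returned) {
    seg <- post_idx[post_idx <= entry_i]
    vmax <- max(speed$speed[seg])
    res$max_escape_speed <- vmax
    if (vmax >= vigour_threshold) {
      res$is_escape <- TRUE
      rt <- t[seg[which.max(speed$speed[seg])]] - onset_s
      res$reaction_time <- rt
      res$looms_to_escape <- if (rt >= n_looms * loom_dur) ">5" else
        as.character(min(n_looms, floor(rt / loom_dur) + 1L))
    }
  }
  res
}

#' Speed at and immediately after stimulus onset
#'
#' `s_at` is the mean speed within +/- 50 ms of onset; `s_im` is the mean
#' speed 300 to 800 ms after onset.
#'
#' @inheritParams classify_escape
#' @return c(s_at, s_im).
#' @export
onset_speeds <- function(onset_s, speed) {
  t <- speed$time_s
  s_at <- mean(speed$speed[t >= onset_s - 0.05 & t <= onset_s + 0.05])
  s_im <- mean(speed$speed[t >= onset_s + 0.3 & t <= onset_s + 0.8])
  c(s_at = s_at, s_im = s_im)
}

#' Categorise the immediate speed change of stimulated trials
#'
#' Each trial is labelled `increase`, `decrease` or `no_change` depending on
#' whether `s_im` lies more than one pooled standard deviation above, below,
#' or within one SD of `s_at`.  The SD is that of the `s_at` values pooled
#' across all trials of the same genotype.  Also returns
#' `log10(s_im / s_at)` (the log immediate speed change).
#'
#' @param s_at,s_im Numeric vectors of onset and immediate speeds (cm/s).
#' @param genotype Factor/character of the same length.
#' @return data.frame with `s_at`, `s_im`, `genotype`, `category`,
#'   `log_speed_ratio`; the per-genotype SDs are in attribute `"sd"`.
#' @export
immediate_speed_change <- function(s_at, s_im, genotype) {
  stop_if(length(s_at) != length(s_im) || length(s_at) != length(genotype),
          "inputs must have equal length")
  genotype <- as.character(genotype)
  sds <- tapply(s_at, genotype, sd)
  stop_if(any(is.na(sds)), "need >= 2 trials per genotype for the SD rule")
  sd_i <- sds[genotype]
  diffv <- s_im - s_at
  category <- ifelse(diffv > sd_i, "increase",
                     ifelse(diffv < -sd_i, "decrease", "no_change"))
  lr <- ifelse(s_at > 0, log10(s_im / s_at), NA_real_)
  if (any(s_at <= 0)) warning("s_at <= 0: log speed ratio undefined for ",
                              sum(s_at <= 0), " trial(s)")
  out <- data.frame(s_at = s_at, s_im = s_im, genotype = genotype,
                    category = factor(category, c("increase", "decrease",
                                                  "no_change")),
                    log_speed_ratio = lr)
  attr(out, "sd") <- sds
  out
}

#' Detect shelter-exit episodes
#'
#' A full-body exit is approximated by the centroid crossing the shelter
#' boundary dilated by `exit_hysteresis` cm, with re-entry scored at the
#' undilated boundary (hysteresis avoids double counting boundary jitter).
#' Each exit is annotated with its maximum straight-line distance from the
#' shelter centre, duration, and whether the threat zone (beyond the
#' trigger radius) was entered.
#'
#' @inheritParams emulate_closed_loop
#' @return list with `exits` (data.frame: start_s, end_s, duration_s,
#'   max_distance, threat_zone), `n_exits`, `interbout_s`.
#' @export
detect_shelter_exits <- function(trajectory, config) {
  n <- nrow(trajectory)
  empty <- list(exits = data.frame(start_s = numeric(0), end_s = numeric(0),
                                   duration_s = numeric(0),
                                   max_distance = numeric(0),
                                   threat_zone = logical(0)),
                n_exits = 0L, interbout_s = numeric(0))
  if (n == 0) return(empty)
  inside <- in_shelter(trajectory$x_cm, trajectory$y_cm, config)
  beyond <- !in_shelter(trajectory$x_cm, trajectory$y_cm, config,
                        dilate = config$exit_hysteresis)
  d <- shelter_distance(trajectory$x_cm, trajectory$y_cm, config)
  t <- trajectory$time_s
  out <- FALSE
  rows <- list(); start_i <- NA_integer_
  for (i in seq_len(n)) {
    if (!out && beyond[i]) {
      out <- TRUE
      start_i <- i
    } else if (out && inside[i]) {
      seg <- start_i:(i - 1)
      rows[[length(rows) + 1]] <- data.frame(
        start_s = t[start_i], end_s = t[i],
        duration_s = t[i] - t[start_i],
        max_distance = max(d[seg]),
        threat_zone = any(d[seg] > config$trigger_radius))
      out <- FALSE
    }
  }
  if (out) {  # session ends mid-exit
    seg <- start_i:n
    rows[[length(rows) + 1]] <- data.frame(
      start_s = t[start_i], end_s = t[n], duration_s = t[n] - t[start_i],
      max_distance = max(d[seg]),
      threat_zone = any(d[seg] > config$trigger_radius))
  }
  if (!length(rows)) return(empty)
  ex <- do.call(rbind, rows)
  list(exits = ex, n_exits = nrow(ex),
       interbout_s = if (nrow(ex) > 1)
         ex$start_s[-1] - ex$end_s[-nrow(ex)] else numeric(0))
}

#' Occupancy and exploration-speed metrics
#'
#' Percentage of frames out of the shelter, inside the central disc
#' (`center_radius` around the arena centre) and beyond the edge radius,
#' plus mean and maximum smoothed speed, over the first `max_min` minutes.
#'
#' @inheritParams emulate_closed_loop
#' @param max_min Analysis span (minutes, default 10).
#' @return One-row data.frame.
#' @export
occupancy_metrics <- function(trajectory, config, max_min = 10) {
  span <- trajectory$time_s - trajectory$time_s[1]
  if (tail(span, 1) < max_min * 60 - 1e-9)
    warning("session shorter than ", max_min, " min; using available span")
  keep <- span <= max_min * 60
  tr <- trajectory[keep, , drop = FALSE]
  inside <- in_shelter(tr$x_cm, tr$y_cm, config)
  dc <- sqrt(tr$x_cm^2 + tr$y_cm^2)
  sp <- compute_speed(tr)$speed
  data.frame(pct_time_out = mean(!inside) * 100,
             pct_time_center = mean(dc <= config$center_radius) * 100,
             pct_time_edge = mean(dc > config$edge_radius) * 100,
             mean_speed = mean(sp), max_speed = max(sp))
}

#' Positional covariates at stimulus onset
#'
#' Distance to the shelter centre, instantaneous (smoothed) speed, and the
#' heading angle at the stimulus-onset frame.  The heading angle is the
#' angle between the body axis (back-paw midpoint to snout) and the line
#' from the back-paw midpoint to the shelter centre: 0 deg means facing the
#' shelter, 180 deg facing directly away.
#'
#' @param onset_s Stimulus onset (s).
#' @param session Tracked session data.frame (columns `time_s`, `x_cm`,
#'   `y_cm`, and optionally `snout_x/y`, `back_x/y`).
#' @param config An [arena_config()].
#' @param speed Optional precomputed speed series.
#' @return One-row data.frame with `distance_to_shelter`, `speed_at_onset`,
#'   `heading_angle` (deg, `NA` if body points are missing).
#' @export
positional_covariates <- function(onset_s, session, config, speed = NULL) {
  i <- which(session$time_s >= onset_s)[1]
  stop_if(is.na(i), "onset outside session span")
  d <- shelter_distance(session$x_cm[i], session$y_cm[i], config)
  sp <- if (!is.null(speed)) speed$speed[i] else NA_real_
  heading <- NA_real_
  if (all(c("snout_x", "snout_y", "back_x", "back_y") %in% names(session)) &&
      !anyNA(unlist(session[i, c("snout_x", "snout_y", "back_x", "back_y")]))) {
    b <- c(session$back_x[i], session$back_y[i])
    body <- c(session$snout_x[i], session$snout_y[i]) - b
    to_shelter <- config$shelter_center - b
    cosang <- sum(body * to_shelter) /
      (sqrt(sum(body^2)) * sqrt(sum(to_shelter^2)))
    heading <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  data.frame(distance_to_shelter = d, speed_at_onset = sp,
             heading_angle = heading)
}

#' Escape-trajectory directedness
#'
#' Ratio of the path length actually travelled between stimulus onset and
#' shelter re-entry to the shortest straight-line distance from the animal
#' to the shelter edge at onset; 1 means a perfectly direct escape.
#'
#' @inheritParams positional_covariates
#' @param entry_s Time of shelter re-entry (s).
#' @return Directedness ratio (>= 1 up to tracking noise), or `NA` if the
#'   animal was within the shelter radius at onset.
#' @export
escape_directedness <- function(onset_s, entry_s, session, config) {
  seg <- session$time_s >= onset_s & session$time_s <= entry_s
  stop_if(sum(seg) < 2, "no trajectory between onset and entry")
  x <- session$x_cm[seg]; y <- session$y_cm[seg]
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  shortest <- shelter_distance(x[1], y[1], config) - config$shelter_side / 2
  if (shortest <= 0) return(NA_real_)
  path / shortest
}

#' Aggregate per-trial metrics to animal and genotype level
#'
#' Behavioural metrics are averaged across escape trials within each animal
#' first, then across animals within genotype.  Animals without any escape
#' are excluded from reaction-time and vigour averages but retained in
#' loom/exit counts.  Also builds the per-day adaptation series and the
#' response-category contingency table used for the chi-squared test.
#'
#' @param trials data.frame with columns `animal`, `genotype`, `day`,
#'   `is_escape`, `reaction_time`, `max_escape_speed`, and optionally
#'   `category` (from [immediate_speed_change()]).
#' @param exits Optional data.frame `animal`, `genotype`, `n_exits`.
#' @return list with `per_animal`, `per_genotype`, `per_day`, `contingency`
#'   (or `NULL` if no categories), and `exit_correlation` input table.
#' @export
aggregate_cohort <- function(trials, exits = NULL) {
  stop_if(!all(c("animal", "genotype", "is_escape") %in% names(trials)),
          "trials must carry animal, genotype and is_escape labels")
  esc <- trials[trials$is_escape, , drop = FALSE]
  animals <- unique(trials[, c("animal", "genotype")])
  per_animal <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    a <- animals$animal[i]
    ta <- trials[trials$animal == a, , drop = FALSE]
    ea <- esc[esc$animal == a, , drop = FALSE]
    data.frame(animal = a, genotype = animals$genotype[i],
               n_trials = nrow(ta), n_escapes = nrow(ea),
               looms_triggered = nrow(ta),
               mean_reaction_time = if (nrow(ea)) mean(ea$reaction_time)
               else NA_real_,
               mean_max_speed = if (nrow(ea)) mean(ea$max_escape_speed)
               else NA_real_)
  }))
  per_genotype <- do.call(rbind, lapply(split(per_animal,
                                              per_animal$genotype),
                                        function(g) data.frame(
    genotype = g$genotype[1], n_animals = nrow(g),
    mean_reaction_time = mean(g$mean_reaction_time, na.rm = TRUE),
    mean_max_speed = mean(g$mean_max_speed, na.rm = TRUE),
    mean_looms = mean(g$looms_triggered))))
  rownames(per_genotype) <- NULL
  per_day <- if ("day" %in% names(trials) && nrow(esc)) {
    ag <- stats::aggregate(reaction_time ~ genotype + day, data = esc, mean)
    ag[order(ag$genotype, ag$day), ]
  } else NULL
  contingency <- if ("category" %in% names(trials)) {
    table(trials$genotype, trials$category)
  } else NULL
  exit_correlation <- if (!is.null(exits)) {
    merge(per_animal, exits[, c("animal", "n_exits")], by = "animal")
  } else NULL
  list(per_animal = per_animal, per_genotype = per_genotype,
       per_day = per_day, contingency = contingency,
       exit_correlation = exit_correlation)
}
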