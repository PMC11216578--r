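#' Current source density and laminar inflection depth
#'
#' The CSD is the negative second spatial difference of the trial-averaged
#' LFP (Vaknin-style edge padding duplicates the first and last channels so
#' every channel gets an estimate).  The inflection depth (ID) is the
#' source-to-sink sign transition of the CSD profile averaged over an early
#' post-flash window; laminar bounds follow from it: superficial SC spans
#' ID - 300 um to ID + 100 um, intermediate/deep SC lies below ID + 100 um
#' (depth increasing downward).
#'
#' @param lfp Channel x time x repetition array (or channel x time matrix).
#' @param depths Uniformly spaced channel depths (um).
#' @param times_s Sample times (s) relative to flash onset.
#' @param early_window Window (s) in which to locate the transition.
#' @param smooth_channels Width (channels, odd) of an optional spatial
#'   boxcar applied to the CSD; 1 disables smoothing.
#' @return list of class `depth_profile`: `csd` (channel x time), `depths`,
#'   `profile`, `inflection_depth` (`NA` when flagged), `flag`
#'   (`"ok"`, `"no_transition"`, `"polarity_inverted"`), `ssc_bounds`.
#' @export
compute_csd <- function(lfp, depths, times_s,
                        early_window = c(0, 0.1), smooth_channels = 1) {
  stop_if(length(depths) < 5, "need >= 5 channels for the second difference")
  h <- diff(depths)
  stop_if(max(abs(h - h[1])) > 1e-6, "channels must be equally spaced")
  h <- h[1]
  phi <- if (length(dim(lfp)) == 3) apply(lfp, c(1, 2), mean) else lfp
  pad <- rbind(phi[1, ], phi, phi[nrow(phi), ])
  csd <- -(pad[seq_len(nrow(phi)), ] - 2 * phi +
             pad[seq_len(nrow(phi)) + 2, ]) / h^2
  if (smooth_channels > 1) {
    k <- rep(1 / smooth_channels, smooth_channels)
    csd <- apply(csd, 2, function(col)
      as.numeric(stats::filter(col, k, sides = 2, circular = FALSE)))
    csd[is.na(csd)] <- 0
  }
  win <- times_s >= early_window[1] & times_s <= early_window[2]
  profile <- rowMeans(csd[, win, drop = FALSE])
  n <- length(profile)
  # transitions are searched on interior channels only: the padded edge
  # estimates are extrapolations and can carry spurious sign flips
  interior <- 2:(n - 2)
  down <- interior[profile[interior] > 0 & profile[interior + 1] < 0]
  up <- interior[profile[interior] < 0 & profile[interior + 1] > 0]
  flag <- "ok"; id <- NA_real_
  if (length(down)) {
    drop_size <- profile[down] - profile[down + 1]
    k <- down[which.max(drop_size)]
    # linear interpolation of the zero crossing between channels k, k+1
    id <- depths[k] + h * profile[k] / (profile[k] - profile[k + 1])
  } else if (length(up)) {
    flag <- "polarity_inverted"
  } else {
    flag <- "no_transition"
  }
  structure(list(csd = csd, depths = depths, profile = profile,
                 inflection_depth = id, flag = flag,
                 ssc_bounds = if (!is.na(id)) c(id - 300, id + 100)
                 else c(NA_real_, NA_real_)),
            class = "depth_profile")
}

#' Assign a laminar layer from depth and inflection depth
#'
#' @param depth Unit depth(s), um.
#' @param inflection_depth Inflection depth from [compute_csd()].
#' @return Character vector: `"sSC"`, `"idSC"` or `"other"`.
#' @export
assign_layer <- function(depth, inflection_depth) {
  ifelse(depth < inflection_depth - 300, "other",
         ifelse(depth <= inflection_depth + 100, "sSC", "idSC"))
}

#' Event-aligned peristimulus time histogram
#'
#' Mean firing rate across events in fixed bins (default 16.7 ms).
#'
#' @param spike_times Spike times (s).
#' @param events Event onset times (s).
#' @param window Peri-event window (s), `c(start, end)`.
#' @param bin_ms Bin width (ms).
#' @return data.frame with `bin_start_s`, `bin_mid_s`, `rate_hz`.
#' @export
compute_psth <- function(spike_times, events, window = c(0, 1),
                         bin_ms = 16.7) {
  stop_if(length(events) == 0, "events must be non-empty")
  bw <- bin_ms / 1000
  edges <- seq(window[1], window[2] + 1e-12, by = bw)
  if (tail(edges, 1) < window[2]) edges <- c(edges, tail(edges, 1) + bw)
  counts <- rep(0, length(edges) - 1)
  for (ev in events) {
    rel <- spike_times - ev
    rel <- rel[rel >= edges[1] & rel < tail(edges, 1)]
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges),
                                  nbins = length(counts))
  }
  data.frame(bin_start_s = edges[-length(edges)],
             bin_mid_s = edges[-length(edges)] + bw / 2,
             rate_hz = counts / (length(events) * bw))
}

#' Stimulus-locked responsiveness test
#'
#' A ZETA-style temporal-deviation test: the statistic is the maximal
#' absolute deviation of the event-locked spike-time empirical CDF (pooled
#' across events within the response window) from the uniform CDF, scaled
#' by sqrt(n).  Significance comes from a circular-shift resampling null:
#' the whole spike train is rotated by random offsets and the statistic
#' recomputed; the p-value is the permutation fraction
#' `(1 + #{null >= observed}) / (n_resample + 1)`.  A unit is responsive at
#' p < 0.05.
#'
#' @param spike_times Spike times (s) over the whole recording.
#' @param events Stimulus onsets (s).
#' @param window Response window after each event (s), e.g. `c(0, 0.7)` for
#'   the first loom or `c(0, 2)` for the flash.
#' @param recording_span Total span (s) for the circular shift; defaults to
#'   `max(spike_times, events + window)`.
#' @param n_resample Number of null resamples.
#' @param seed Seed for the resampling.
#' @return list with `p`, `statistic`, `responsive`.
#' @export
test_responsiveness <- function(spike_times, events, window = c(0, 2),
                                recording_span = NULL, n_resample = 100,
                                seed = 1L) {
  stop_if(length(events) == 0, "events must be non-empty")
  span <- recording_span %||% max(c(spike_times, max(events) + window[2]))
  dev_stat <- function(st) {
    rel <- unlist(lapply(events, function(ev) {
      r <- st - ev
      r[r >= window[1] & r < window[2]]
    }))
    n <- length(rel)
    if (n == 0) return(0)
    u <- sort((rel - window[1]) / (window[2] - window[1]))
    d <- max(pmax(abs(u - (seq_len(n) - 1) / n), abs(u - seq_len(n) / n)))
    sqrt(n) * d
  }
  obs <- dev_stat(spike_times)
  if (length(spike_times) == 0)
    return(list(p = 1, statistic = 0, responsive = FALSE))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_resample), function(i) {
    dev_stat((spike_times + runif(1, 0, span)) %% span)
  }, numeric(1))
  p <- (1 + sum(null_stats >= obs)) / (n_resample + 1)
  list(p = p, statistic = obs, responsive = p < 0.05)
}

# Calinski-Harabasz index for a given k-means fit
ch_index <- function(x, cluster) {
  x <- as.matrix(x)
  k <- length(unique(cluster))
  n <- nrow(x)
  if (k < 2) return(NA_real_)
  gm <- colMeans(x)
  b <- 0; w <- 0
  for (g in unique(cluster)) {
    xi <- x[cluster == g, , drop = FALSE]
    cm <- colMeans(xi)
    b <- b + nrow(xi) * sum((cm - gm)^2)
    w <- w + sum(sweep(xi, 2, cm)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Cluster unit response profiles
#'
#' K-means clustering of responsive units' response vectors, with the
#' number of clusters chosen from the Calinski-Harabasz index: the elbow is
#' operationalised as the smallest k whose CH index is within 10% of the
#' maximum over the candidate range.  Units from all genotypes are pooled
#' before clustering and split afterwards.
#'
#' @param responses Units x features numeric matrix.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param seed Seed for k-means initialisation.
#' @return list with `cluster` (integer labels), `k`, `ch` (named CH index
#'   per candidate k).
#' @export
cluster_responses <- function(responses, k_range = 2:10, seed = 1L) {
  responses <- as.matrix(responses)
  stop_if(nrow(responses) < 2, "need >= 2 units")
  if (all(apply(responses, 2, function(col) max(col) - min(col)) < 1e-12))
    return(list(cluster = rep(1L, nrow(responses)), k = 1L, ch = NULL))
  k_range <- k_range[k_range < nrow(responses)]
  set.seed(seed)
  fits <- lapply(k_range, function(k)
    kmeans(responses, centers = k, nstart = 10, iter.max = 50))
  ch <- vapply(fits, function(f) ch_index(responses, f$cluster), numeric(1))
  names(ch) <- k_range
  ok <- which(ch >= 0.9 * max(ch, na.rm = TRUE))
  k_sel <- ok[1]
  list(cluster = fits[[k_sel]]$cluster, k = k_range[k_sel], ch = ch)
}

#' Spike-triggered-average receptive field
#'
#' Averages the checker stimulus over a peri-spike lag window.  The
#' receptive-field centre is the pixel with the highest variance across
#' lags; the spatial map is cropped around it, and the field is summarised
#' by its signal-to-noise ratio `10*log10(max_power / noise_power)` (centre
#' pixel power over the variance of a 5-pixel border of the crop), its
#' polarity (sign of the centre-pixel mean across lags) and its half-peak
#' radius.
#'
#' @param spike_times Spike times (s).
#' @param stimulus A [checker_stimulus()].
#' @param lag_window Peri-spike lags to average (s), default 0 to 0.25.
#' @param crop_px Crop side (stimulus pixels); clipped to the grid.
#' @param min_spikes Below this spike count the fit is flagged
#'   low-confidence.
#' @return list of class `receptive_field`: `sta` (x, y, lag array),
#'   `center` (pixel coords), `spatial` (cropped map at the peak lag),
#'   `snr_db`, `polarity`, `radius_px`, `n_spikes`, `low_confidence`.
#' @export
sta_receptive_field <- function(spike_times, stimulus,
                                lag_window = c(0, 0.25), crop_px = 160,
                                min_spikes = 50) {
  stop_if(stimulus$kind != "checker", "STA needs a checker stimulus")
  span <- c(0, length(stimulus$times) * stimulus$dt)
  stop_if(any(spike_times < span[1] | spike_times > span[2] + 1),
          "spikes outside the stimulus span: clocks misaligned?")
  nt <- dim(stimulus$frames)[3]
  counts <- tabulate(findInterval(spike_times, stimulus$times), nbins = nt)
  n_spikes <- sum(counts)
  lags <- seq(floor(lag_window[1] / stimulus$dt),
              max(1, ceiling(lag_window[2] / stimulus$dt)) - 1)
  m <- matrix(stimulus$frames, ncol = nt)  # pixels x frames
  sta <- vapply(lags, function(l) {
    c_shift <- c(counts[(l + 1):nt], rep(0, l))
    as.numeric(m %*% c_shift) / max(n_spikes, 1)
  }, numeric(nrow(m)))
  sta_arr <- array(sta, dim = c(stimulus$nx, stimulus$ny, length(lags)))
  pix_var <- apply(sta_arr, c(1, 2), var)
  center <- which(pix_var == max(pix_var), arr.ind = TRUE)[1, ]
  center_trace <- sta_arr[center[1], center[2], ]
  best_lag <- which.max(abs(center_trace))
  spat_full <- sta_arr[, , best_lag]
  halfc <- min(floor(crop_px / 2),
               center[1] - 1, stimulus$nx - center[1],
               center[2] - 1, stimulus$ny - center[2])
  halfc <- max(halfc, 6)
  xr <- max(1, center[1] - halfc):min(stimulus$nx, center[1] + halfc)
  yr <- max(1, center[2] - halfc):min(stimulus$ny, center[2] + halfc)
  spatial <- spat_full[xr, yr, drop = FALSE]
  border <- 1:min(5, floor(min(dim(spatial)) / 3))
  bmask <- matrix(FALSE, nrow(spatial), ncol(spatial))
  bmask[border, ] <- TRUE; bmask[nrow(spatial) - border + 1, ] <- TRUE
  bmask[, border] <- TRUE; bmask[, ncol(spatial) - border + 1] <- TRUE
  max_power <- spat_full[center[1], center[2]]^2
  noise_power <- var(spatial[bmask])
  snr_db <- 10 * log10(max_power / noise_power)
  polarity <- if (mean(center_trace) >= 0) "ON" else "OFF"
  # half-peak width through the centre row and column
  peak <- spat_full[center[1], center[2]]
  row_prof <- spat_full[, center[2]] / peak
  col_prof <- spat_full[center[1], ] / peak
  half_width <- function(prof, c0) {
    above <- prof >= 0.5
    lo <- c0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- c0; while (hi < length(prof) && above[hi + 1]) hi <- hi + 1
    hi - lo + 1
  }
  radius <- mean(c(half_width(row_prof, center[1]),
                   half_width(col_prof, center[2]))) / 2
  structure(list(sta = sta_arr, center = unname(center), spatial = spatial,
                 snr_db = snr_db, polarity = polarity, radius_px = radius,
                 n_spikes = n_spikes, low_confidence = n_spikes < min_spikes),
            class = "receptive_field")
}

#' Flag visually responsive receptive fields within a population
#'
#' Responsive units are those whose STA signal-to-noise ratio reaches the
#' 80th percentile of all superficial-SC units or above.
#'
#' @param snr_db Numeric vector of SNRs (dB) for the reference population.
#' @param percentile Percentile threshold (default 0.8).
#' @return Logical vector.
#' @export
flag_responsive_rf <- function(snr_db, percentile = 0.8) {
  snr_db >= quantile(snr_db, percentile, na.rm = TRUE, type = 7)
}

#' Direction selectivity index
#'
#' `DSI = (D_p - D_np) / (D_p + D_np)` for a preferred response `d_p` and
#' the response 180 degrees away `d_np`; with non-negative responses it
#' ranges from 1 (fully selective, zero nonpreferred response) down to 0.
#'
#' @param d_p,d_np Baseline-normalised responses in the preferred and
#'   opposite directions.
#' @return The index, or `NA` (flagged) when `d_p + d_np == 0`.
#' @export
dsi_index <- function(d_p, d_np) {
  ifelse(d_p + d_np > 0, (d_p - d_np) / (d_p + d_np), NA_real_)
}

#' Direction tuning and selectivity index
#'
#' For each drift direction the mean rate across trials is normalised to
#' the baseline rate in the 30 s before stimulus onset.  The preferred
#' direction D_p is the direction with the greatest normalised response and
#' D_np the response 180 degrees away; DSI = (D_p - D_np) / (D_p + D_np).
#'
#' @param spike_times Spike times (s).
#' @param stimulus A [grating_stimulus()].
#' @return list of class `direction_tuning`: `tuning` (data.frame
#'   direction, norm_response), `pref_direction`, `dsi` (`NA` flagged when
#'   D_p + D_np = 0), `baseline_hz`.
#' @export
direction_selectivity <- function(spike_times, stimulus) {
  stop_if(stimulus$kind != "gratings", "needs a gratings stimulus")
  sched <- stimulus$schedule
  dirs <- sort(unique(sched$direction))
  stop_if(length(dirs) < 8 || min(table(sched$direction)) < 2,
          "need 8 directions x >= 2 repetitions")
  t0 <- min(sched$onset_s)
  baseline <- sum(spike_times >= t0 - 30 & spike_times < t0) / 30
  rates <- vapply(dirs, function(d) {
    on <- sched$onset_s[sched$direction == d]
    mean(vapply(on, function(o)
      sum(spike_times >= o & spike_times < o + stimulus$trial_s) /
        stimulus$trial_s, numeric(1)))
  }, numeric(1))
  norm <- if (baseline > 0) rates / baseline else rates
  pref_i <- which.max(norm)
  null_dir <- (dirs[pref_i] + 180) %% 360
  np_i <- which.min(abs(((dirs - null_dir + 180) %% 360) - 180))
  dp <- norm[pref_i]; dnp <- norm[np_i]
  dsi <- dsi_index(dp, dnp)
  structure(list(tuning = data.frame(direction = dirs, norm_response = norm),
                 pref_direction = dirs[pref_i], d_p = dp, d_np = dnp,
                 dsi = dsi, baseline_hz = baseline),
            class = "direction_tuning")
}

#' Direction-selectivity population flag
#'
#' DS units have a DSI in the 80th percentile or higher of all sSC units.
#'
#' @param dsi Numeric vector of DSIs.
#' @param percentile Percentile threshold (default 0.8).
#' @export
flag_direction_selective <- function(dsi, percentile = 0.8) {
  dsi >= quantile(dsi, percentile, na.rm = TRUE, type = 7)
}

#' Loom-response metrics
#'
#' Per-unit loom statistics over a bout schedule (default 5 looms of 750 ms
#' per bout, 10 repetitions): the mean rate (average over every individual
#' loom window), the maximum rate (per-loom PSTH maximum averaged across
#' looms and repetitions), the mean time-to-peak within a loom (ties broken
#' to the earliest bin), and the 5-point per-loom adaptation profile.
#'
#' @param spike_times Spike times (s).
#' @param bout_onsets Bout onset times (s).
#' @param n_looms,loom_dur Looms per bout and loom duration (s).
#' @param bin_ms PSTH bin (ms).
#' @return list with `mean_rate_hz`, `max_rate_hz`, `time_to_peak_s`,
#'   `per_loom_rate_hz`, `n_bouts_used`.
#' @export
loom_response_metrics <- function(spike_times, bout_onsets, n_looms = 5,
                                  loom_dur = 0.75, bin_ms = 16.7) {
  stop_if(length(bout_onsets) == 0, "bout schedule required")
  if (length(spike_times) == 0)
    return(list(mean_rate_hz = 0, max_rate_hz = 0,
                time_to_peak_s = NA_real_,
                per_loom_rate_hz = rep(0, n_looms),
                n_bouts_used = length(bout_onsets)))
  bw <- bin_ms / 1000
  nb <- ceiling(loom_dur / bw)
  mean_rates <- matrix(NA_real_, length(bout_onsets), n_looms)
  max_rates <- ttp <- mean_rates
  for (r in seq_along(bout_onsets)) {
    for (l in seq_len(n_looms)) {
      on <- bout_onsets[r] + (l - 1) * loom_dur
      rel <- spike_times - on
      rel <- rel[rel >= 0 & rel < loom_dur]
      counts <- tabulate(pmin(floor(rel / bw) + 1, nb), nbins = nb)
      rate <- counts / bw
      mean_rates[r, l] <- length(rel) / loom_dur
      max_rates[r, l] <- max(rate)
      ttp[r, l] <- if (any(counts > 0))
        (which.max(rate) - 0.5) * bw else NA_real_
    }
  }
  list(mean_rate_hz = mean(mean_rates),
       max_rate_hz = mean(max_rates),
       time_to_peak_s = mean(ttp, na.rm = TRUE),
       per_loom_rate_hz = colMeans(mean_rates),
       n_bouts_used = length(bout_onsets))
}

#' Classify running from frame-difference energy
#'
#' One-dimensional 2-class k-means on the per-frame pixel-difference
#' energy; the class with the higher mean is "moving".  A repetition counts
#' as running when more than half of its frames are moving.
#'
#' @param energy Per-frame motion energy.
#' @param rep_index Optional integer vector assigning frames to stimulus
#'   repetitions.
#' @return list with `moving` (logical per frame), `prop_moving`, and (if
#'   `rep_index` given) `running_reps` (logical per repetition).
#' @export
classify_motion <- function(energy, rep_index = NULL) {
  stop_if(length(energy) < 2, "need >= 2 frames")
  if (var(energy) < 1e-12) {
    moving <- rep(FALSE, length(energy))
  } else {
    km <- kmeans(energy, centers = 2, nstart = 5)
    moving <- km$cluster == which.max(km$centers)
  }
  out <- list(moving = moving, prop_moving = mean(moving))
  if (!is.null(rep_index)) {
    out$running_reps <- tapply(moving, rep_index, function(m) mean(m) > 0.5)
  }
  out
}

# direct least-squares conic (ellipse) fit, Fitzgibbon-style
fit_ellipse <- function(x, y) {
  stop_if(length(x) < 5, "need >= 5 boundary points")
  # collinear points cannot define an ellipse
  if (sd(x) < 1e-9 || sd(y) < 1e-9 ||
      abs(cor(x, y)) > 1 - 1e-9) return(NULL)
  mx <- mean(x); my <- mean(y); s <- max(sd(x), sd(y), 1e-9)
  xs <- (x - mx) / s; ys <- (y - my) / s
  d <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  sc <- t(d) %*% d
  # tiny ridge keeps the scatter matrix invertible when the points lie
  # exactly on a conic
  sc <- sc + diag(1e-10 * mean(diag(sc)), 6)
  cmat <- matrix(0, 6, 6)
  cmat[1, 3] <- 2; cmat[3, 1] <- 2; cmat[2, 2] <- -1
  sol <- tryCatch(solve(sc, cmat), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  eig <- eigen(sol)
  # eigenvector with a'Ca > 0 (valid ellipse)
  vals <- apply(Re(eig$vectors), 2, function(v)
    as.numeric(t(v) %*% cmat %*% v))
  ok <- which(vals > 1e-12)
  if (!length(ok)) return(NULL)
  a <- Re(eig$vectors[, ok[which.max(Re(eig$values[ok]))]])
  names(a) <- c("A", "B", "C", "D", "E", "F")
  # semi-axes from the conic (in scaled coords), then unscale
  A <- a["A"]; B <- a["B"] / 2; C <- a["C"]; D <- a["D"] / 2
  E <- a["E"] / 2; F0 <- a["F"]
  den <- B^2 - A * C
  if (abs(den) < 1e-14) return(NULL)
  x0 <- (C * D - B * E) / den
  y0 <- (A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F0 * B^2 - 2 * B * D * E - A * C * F0)
  tmp <- sqrt((A - C)^2 + 4 * B^2)
  ax1 <- sqrt(abs(num / (den * (tmp - (A + C)))))
  ax2 <- sqrt(abs(num / (den * (-tmp - (A + C)))))
  list(center = c(mx + x0 * s, my + y0 * s),
       semi_axes = sort(c(ax1, ax2) * s, decreasing = TRUE))
}

#' Pupil diameter from tracked boundary points
#'
#' Fits an ellipse (direct least squares) to the tracked points around the
#' pupil in each frame; the diameter is the major-axis length.  Frames with
#' fewer than 5 points or degenerate (collinear) geometry are flagged NA.
#'
#' @param points_per_frame List of data.frames/matrices with columns x, y.
#' @return data.frame with `frame`, `diameter`, `flagged`.
#' @export
pupil_diameter <- function(points_per_frame) {
  out <- lapply(seq_along(points_per_frame), function(i) {
    p <- as.matrix(points_per_frame[[i]])
    if (nrow(p) < 5)
      return(data.frame(frame = i, diameter = NA_real_, flagged = TRUE))
    fit <- tryCatch(fit_ellipse(p[, 1], p[, 2]), error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$semi_axes)) ||
        fit$semi_axes[1] <= 0)
      return(data.frame(frame = i, diameter = NA_real_, flagged = TRUE))
    data.frame(frame = i, diameter = 2 * fit$semi_axes[1], flagged = FALSE)
  })
  do.call(rbind, out)
}
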