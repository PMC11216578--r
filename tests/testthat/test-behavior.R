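cfg <- arena_config()

test_that("speed is a centred moving mean of the displacement rate", {
  # stationary
  tr <- data.frame(time_s = (0:99) / 60, x_cm = 0, y_cm = 0)
  expect_true(all(compute_speed(tr)$speed == 0))
  # uniform 10 cm/s
  tr <- data.frame(time_s = (0:199) / 60, x_cm = (0:199) * 10 / 60, y_cm = 0)
  sp <- compute_speed(tr)$speed
  expect_equal(sp[5:195], rep(10, 191), tolerance = 1e-10)
  # single-frame 30 cm jump at 60 Hz: raw spike 1800 cm/s spread over the
  # 5-frame window gives 360 cm/s
  x <- rep(0, 100); x[51:100] <- 30
  tr <- data.frame(time_s = (0:99) / 60, x_cm = x, y_cm = 0)
  expect_equal(max(compute_speed(tr)$speed), 1800 / 5)
  # brute-force windowed mean on a random walk
  set.seed(4)
  tr <- data.frame(time_s = (0:499) / 60, x_cm = cumsum(rnorm(500, 0, 0.2)),
                   y_cm = cumsum(rnorm(500, 0, 0.2)))
  sp <- compute_speed(tr)$speed
  raw <- c(0, sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2) * 60)
  raw[1] <- raw[2]
  brute <- vapply(seq_along(raw), function(i)
    mean(raw[max(1, i - 2):min(length(raw), i + 2)]), numeric(1))
  expect_equal(sp, brute, tolerance = 1e-12)
  expect_error(compute_speed(data.frame(time_s = c(0, 0, 1),
                                        x_cm = 0:2, y_cm = 0)),
               "increasing")
})

test_that("closed-loop trigger fires on outward crossings with refractoriness", {
  # never leaves the shelter
  tr <- data.frame(time_s = (0:599) / 60,
                   x_cm = cfg$shelter_center[1],
                   y_cm = cfg$shelter_center[2])
  expect_equal(nrow(emulate_closed_loop(tr, cfg)), 0)
  # two crossings 10 s apart -> one onset
  out <- cfg$shelter_center + c(0, 12)
  tr <- rbind(line_trajectory(cfg$shelter_center, out, 20, pad_s = 1),
              line_trajectory(out, cfg$shelter_center, 20),
              line_trajectory(cfg$shelter_center, out, 20, pad_s = 8))
  tr$time_s <- (seq_len(nrow(tr)) - 1) / 60
  log <- emulate_closed_loop(tr, cfg)
  expect_equal(nrow(log), 1)
  # same crossings 31 s apart -> two onsets
  tr2 <- rbind(line_trajectory(cfg$shelter_center, out, 20, pad_s = 1),
               line_trajectory(out, cfg$shelter_center, 20, pad_s = 31),
               line_trajectory(cfg$shelter_center, out, 20, pad_s = 2))
  tr2$time_s <- (seq_len(nrow(tr2)) - 1) / 60
  expect_equal(nrow(emulate_closed_loop(tr2, cfg)), 2)
})

test_that("escape classification applies the return and vigour criteria", {
  # constructed trial: onset at 5 s; speed bump peaking at rt; entry time set
  make_trial <- function(rt, peak, entry) {
    t <- seq(0, 20, by = 1 / 60)
    speed <- data.frame(time_s = t,
                        speed = peak * exp(-(t - 5 - rt)^2 / (2 * 0.15^2)))
    occ <- t >= 5 + entry
    list(speed = speed, occ = occ)
  }
  tr <- make_trial(1.0, 25, 6.5)   # returns at 6.5 s, peak 25 -> escape
  res <- classify_escape(5, tr$speed, tr$occ)
  expect_true(res$is_escape)
  expect_equal(res$reaction_time, 1.0, tolerance = 0.02)
  expect_equal(res$looms_to_escape, "2")
  # same return, peak 15 -> no response
  tr <- make_trial(1.0, 15, 6.5)
  res <- classify_escape(5, tr$speed, tr$occ)
  expect_false(res$is_escape)
  expect_equal(res$looms_to_escape, "NR")
  # late return (8 s) -> no escape despite vigour
  tr <- make_trial(1.0, 40, 8)
  expect_false(classify_escape(5, tr$speed, tr$occ)$is_escape)
  # reaction time 2.0 s falls in the third 750 ms loom window
  tr <- make_trial(2.0, 40, 2.6)
  expect_equal(classify_escape(5, tr$speed, tr$occ)$looms_to_escape, "3")
  # boundary: rt exactly 0.75 belongs to the second loom
  tr <- make_trial(0.75, 40, 1.2)
  expect_equal(classify_escape(5, tr$speed, tr$occ)$looms_to_escape, "2")
  # already in shelter at onset -> invalid
  tr <- make_trial(1, 40, -1)
  expect_false(classify_escape(5, tr$speed, tr$occ)$valid)
})

test_that("raising the vigour threshold never adds escapes", {
  set.seed(11)
  p <- behavior_sim_params("mutant", seed = 77)
  sim <- gen_ler_session(p)
  sp <- compute_speed(sim$session)
  occ <- loomlab:::in_shelter(sim$session$x_cm, sim$session$y_cm, p$arena)
  counts <- vapply(c(10, 20, 30, 40), function(thr)
    sum(vapply(sim$truth$trials$onset_s, function(o)
      classify_escape(o, sp, occ, vigour_threshold = thr)$is_escape,
      logical(1))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("immediate speed change categories follow the pooled-SD rule", {
  # s_im == s_at -> no change
  r <- immediate_speed_change(c(10, 12, 11, 9), c(10, 12, 11, 9),
                              rep("wt", 4))
  expect_true(all(r$category == "no_change"))
  # pooled SD ~2: +5 is an increase
  s_at <- c(10, 12, 8, 10)
  r <- immediate_speed_change(s_at, s_at + c(5, 0, -5, 0.5), rep("wt", 4))
  expect_equal(as.character(r$category),
               c("increase", "no_change", "decrease", "no_change"))
  expect_equal(r$log_speed_ratio[2], 0)
  # partition property: every trial gets exactly one category
  set.seed(2)
  r <- immediate_speed_change(runif(50, 5, 15), runif(50, 0, 30),
                              rep(c("a", "b"), 25))
  expect_equal(sum(table(r$category)), 50)
})

test_that("shelter exits use the dilated-boundary hysteresis rule", {
  expect_equal(detect_shelter_exits(
    data.frame(time_s = (0:99) / 60, x_cm = 0, y_cm = cfg$shelter_center[2]),
    cfg)$n_exits, 0)
  # one loop to the far corner and back crosses the threat zone
  corner <- c(14, 14)
  tr <- rbind(line_trajectory(cfg$shelter_center, corner, 20),
              line_trajectory(corner, cfg$shelter_center, 20, pad_s = 0.5))
  tr$time_s <- (seq_len(nrow(tr)) - 1) / 60
  ex <- detect_shelter_exits(tr, cfg)
  expect_equal(ex$n_exits, 1)
  expect_true(ex$exits$threat_zone[1])
  expect_equal(ex$exits$max_distance[1],
               sqrt(sum((corner - cfg$shelter_center)^2)), tolerance = 0.2)
  # boundary jitter within the hysteresis band is not an exit
  half <- cfg$shelter_side / 2
  y <- cfg$shelter_center[2] + half + c(rep(c(0.5, 1.5), 20), -1)
  tr <- data.frame(time_s = seq_along(y) / 60, x_cm = 0, y_cm = y)
  expect_equal(detect_shelter_exits(tr, cfg)$n_exits, 0)
})

test_that("occupancy metrics match geometry", {
  tr <- data.frame(time_s = (0:599) / 60, x_cm = 0, y_cm = 0)  # arena centre
  occ <- suppressWarnings(occupancy_metrics(tr, cfg))
  expect_equal(occ$pct_time_center, 100)
  expect_equal(occ$pct_time_edge, 0)
  tr <- data.frame(time_s = (0:599) / 60, x_cm = cfg$shelter_center[1],
                   y_cm = cfg$shelter_center[2])
  expect_equal(suppressWarnings(occupancy_metrics(tr, cfg))$pct_time_out, 0)
  # uniform random positions cover the centre disc in proportion to area
  set.seed(8)
  n <- 60000
  tr <- data.frame(time_s = (seq_len(n) - 1) / 60,
                   x_cm = runif(n, -16, 16), y_cm = runif(n, -16, 16))
  occ <- suppressWarnings(occupancy_metrics(tr, cfg, max_min = Inf))
  expect_equal(occ$pct_time_center, 100 * pi * 7^2 / 32^2, tolerance = 0.1)
  expect_warning(occupancy_metrics(tr[1:100, ], cfg), "shorter")
})

test_that("heading angle follows the body-axis geometry", {
  mk <- function(back, snout) {
    data.frame(time_s = 0, x_cm = back[1], y_cm = back[2],
               snout_x = snout[1], snout_y = snout[2],
               back_x = back[1], back_y = back[2])
  }
  s <- cfg$shelter_center
  # facing the shelter
  expect_equal(positional_covariates(0, mk(s + c(0, 8), s + c(0, 6)),
                                     cfg)$heading_angle, 0)
  # facing directly away
  expect_equal(positional_covariates(0, mk(s + c(0, 8), s + c(0, 10)),
                                     cfg)$heading_angle, 180)
  # right angle
  expect_equal(positional_covariates(0, mk(s + c(0, 8), s + c(2, 8)),
                                     cfg)$heading_angle, 90)
  # missing body points: heading NA, distance still reported
  ses <- mk(s + c(0, 8), c(NA, NA))
  pc <- positional_covariates(0, ses, cfg)
  expect_true(is.na(pc$heading_angle))
  expect_equal(pc$distance_to_shelter, 8)
})

test_that("cohort aggregation averages within animal then genotype", {
  tr <- data.frame(animal = c("a1", "a1", "a2", "a3"),
                   genotype = c("wt", "wt", "wt", "wt"),
                   day = 1, is_escape = c(TRUE, TRUE, TRUE, FALSE),
                   reaction_time = c(0.3, 0.5, 0.8, NA),
                   max_escape_speed = c(60, 70, 50, NA))
  agg <- aggregate_cohort(tr)
  pa <- agg$per_animal
  expect_equal(pa$mean_reaction_time[pa$animal == "a1"], 0.4)
  # zero-escape animal excluded from RT means, kept in loom counts
  expect_true(is.na(pa$mean_reaction_time[pa$animal == "a3"]))
  expect_equal(pa$looms_triggered[pa$animal == "a3"], 1)
  # genotype mean averages animal means (0.4 and 0.8), not trials
  expect_equal(agg$per_genotype$mean_reaction_time, 0.6)
})
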