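#' Read and write tracked sessions and stimulus logs
#'
#' Tracked sessions use a plain CSV dialect with columns `time_s`, `x_cm`,
#' `y_cm`, `snout_x`, `snout_y`, `back_x`, `back_y` (plus `day` when
#' multi-day); stimulus logs use `onset_s` (plus `day`, `kind`).
#'
#' @param session,stim_log Data frames as produced by [gen_ler_session()].
#' @param path File path.
#' @return Readers return the data.frame; writers return the path
#'   invisibly.
#' @export
write_tracked_session <- function(session, path) {
  write.csv(session, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracked_session
#' @export
read_tracked_session <- function(path) {
  x <- read.csv(path)
  need <- c("time_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(x))
  stop_if(length(miss) > 0,
          paste("missing column(s):", paste(miss, collapse = ", ")))
  x
}

#' @rdname write_tracked_session
#' @export
write_stimulus_log <- function(stim_log, path) {
  write.csv(stim_log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracked_session
#' @export
read_stimulus_log <- function(path) {
  x <- read.csv(path)
  stop_if(!"onset_s" %in% names(x), "missing column(s): onset_s")
  x
}

#' Serialise a sweep set to a plain-text container
#'
#' Sweeps are written as one long CSV (`sweep`, `step`, `time_ms`, `value`)
#' with the protocol metadata in a commented header, so sweep sets survive
#' text-only round trips.
#'
#' @param sweep_set A `sweep_set` (see [gen_patch_cell()]).
#' @param path File path.
#' @export
write_sweepset <- function(sweep_set, path) {
  hdr <- c(sprintf("# mode=%s", sweep_set$mode),
           sprintf("# sampling_hz=%g", sweep_set$sampling_hz),
           sprintf("# window_ms=%g,%g", sweep_set$window_ms[1],
                   sweep_set$window_ms[2]))
  long <- do.call(rbind, lapply(seq_along(sweep_set$sweeps), function(i)
    data.frame(sweep = i,
               step = sweep_set$steps[min(i, length(sweep_set$steps))],
               time_ms = sweep_set$time_ms,
               value = sweep_set$sweeps[[i]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweepset
#' @export
read_sweepset <- function(path) {
  hdr <- readLines(path, n = 3)
  kv <- sub("^# ", "", hdr)
  mode <- sub("mode=", "", kv[1])
  fs <- as.numeric(sub("sampling_hz=", "", kv[2]))
  win <- as.numeric(strsplit(sub("window_ms=", "", kv[3]), ",")[[1]])
  long <- read.csv(path, comment.char = "#")
  sweeps <- lapply(split(long$value, long$sweep), identity)
  steps <- vapply(split(long$step, long$sweep), function(s) s[1], numeric(1))
  structure(list(mode = mode,
                 time_ms = long$time_ms[long$sweep == long$sweep[1]],
                 sweeps = unname(sweeps), steps = unname(steps),
                 window_ms = win, sampling_hz = fs, meta = NULL,
                 truth = NULL),
            class = "sweep_set")
}

#' Read/write a peptidoform matrix as TSV
#'
#' Layout: first columns `peptidoform`, `protein`, `unique`, `is_phospho`;
#' remaining columns are samples (log10 intensities).
#'
#' @param pep Output of [gen_peptidoform_matrix()] (or a list with
#'   `matrix` + `mapping`).
#' @param path File path.
#' @export
write_peptidoforms <- function(pep, path) {
  df <- cbind(pep$mapping, as.data.frame(pep$matrix))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peptidoforms
#' @export
read_peptidoforms <- function(path) {
  df <- read.csv(path, sep = "\t")
  meta_cols <- c("peptidoform", "protein", "unique", "is_phospho")
  stop_if(!all(meta_cols %in% names(df)),
          "missing peptidoform mapping columns")
  m <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(m) <- df$peptidoform
  list(matrix = m, mapping = df[, meta_cols])
}

#' Load and validate a session bundle
#'
#' @param session_path,stim_path CSV paths.
#' @param meta Named list of labels (animal, genotype, day, ...).
#' @return list with `session`, `stim_log`, `meta`.
#' @export
load_session_bundle <- function(session_path, stim_path, meta = list()) {
  session <- read_tracked_session(session_path)
  stim <- read_stimulus_log(stim_path)
  span <- range(session$time_s)
  bad <- which(stim$onset_s < span[1] | stim$onset_s > span[2])
  stop_if(length(bad) > 0,
          paste("stimulus onset(s) outside the session span at row(s):",
                paste(bad, collapse = ", ")))
  list(session = session, stim_log = stim, meta = meta)
}

#' Run the simulate-and-analyse behaviour pipeline
#'
#' Drives the behaviour stage end to end from a config (a YAML file path
#' or an equivalent list): simulates a session per animal, re-derives the
#' stimulus log with the closed-loop rule, classifies every trial, and
#' writes per-trial and per-animal TSV tables.  Deterministic given the
#' config seeds.
#'
#' @param config List or YAML path with fields `out_dir`, `seed`, and
#'   `animals` (list of `id`, `genotype`, optional `n_days`).
#' @return Invisibly, a list with `trials` and `summary` data frames (also
#'   written to `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stop_if(is.null(config$out_dir) || is.null(config$animals),
          "config needs out_dir and animals")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base_seed <- config$seed %||% 1L
  cfg <- arena_config()
  all_trials <- list()
  exits <- list()
  for (i in seq_along(config$animals)) {
    an <- config$animals[[i]]
    params <- behavior_sim_params(genotype = an$genotype,
                                  seed = base_seed + i)
    sim <- gen_ler_session(params, n_days = an$n_days %||% 1)
    for (day in unique(sim$session$day)) {
      ses <- sim$session[sim$session$day == day, , drop = FALSE]
      sp <- compute_speed(ses)
      occ <- in_shelter(ses$x_cm, ses$y_cm, cfg)
      log_d <- sim$stim_log[sim$stim_log$day == day, , drop = FALSE]
      for (onset in log_d$onset_s) {
        tr <- classify_escape(onset, sp, occ)
        tr$animal <- an$id; tr$genotype <- an$genotype; tr$day <- day
        all_trials[[length(all_trials) + 1]] <- tr
      }
      ex <- detect_shelter_exits(ses, cfg)
      exits[[length(exits) + 1]] <- data.frame(
        animal = an$id, genotype = an$genotype, day = day,
        n_exits = ex$n_exits)
    }
  }
  trials <- if (length(all_trials)) do.call(rbind, all_trials) else
    stop("no stimulated trials produced; increase session length",
         call. = FALSE)
  agg <- aggregate_cohort(
    data.frame(animal = trials$animal, genotype = trials$genotype,
               day = trials$day, is_escape = trials$is_escape,
               reaction_time = trials$reaction_time,
               max_escape_speed = trials$max_escape_speed),
    exits = do.call(rbind, exits))
  write.table(trials, file.path(config$out_dir, "trials.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(agg$per_animal, file.path(config$out_dir, "per_animal.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(trials = trials, summary = agg))
}
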