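# Orchestration: figure-level run configurations and the end-to-end
# generate -> simulate -> analyse pipeline.

#' Run configuration reproducing one figure-level experimental design
#'
#' Returns the fully specified configuration (experiment, session condition
#' grid, session sizes, observer count and preset) matching the design
#' behind each of the figure-level experimental designs:
#'
#' * `F3A` — bar search with monocular items (|O| = 1), 4 observers.
#' * `F3B` — the 9:1 eye-dominance session (|O| = 0.8) with random item
#'   depth, 4 observers.
#' * `F5` — the 23 x 23 bar search, 9 interleaved conditions, 6 observers.
#' * `F6` — the 17 x 17 letter search, 8 conditions, 5 observers.
#' * `F7A` — binocular singleton among monocular bars, 4 observers.
#' * `F7B` — monocular singleton among binocular bars (static), with the
#'   lustre-aversion observer.
#' * `F8` — as `F7B` but with the singleton's monocularity removed after
#'   the initial 0.15 s.
#' * `F9` — the single-strength variant of `F7B` (the monocular item's
#'   max(C_L, C_R) matches the binocular bars').
#' * `F10` — the 14 x 14 heterogeneous-contrast letter search, 10
#'   conditions, 45 trials each, 9 observers.
#'
#' @param figure_id One of the ids above.
#' @return A list of class `"ocu_runconfig"`: `figure`, `config`
#'   (an [experiment_config()]), `n_observers`, `preset` (name),
#'   `normalize` policy, and `reach_radius`.
#' @export
reproduce_design <- function(figure_id = c("F3A", "F3B", "F5", "F6", "F7A",
                                           "F7B", "F8", "F9", "F10")) {
  if (!figure_id[1] %in% c("F3A", "F3B", "F5", "F6", "F7A", "F7B", "F8",
                           "F9", "F10")) {
    stop("unknown figure id '", figure_id[1], "'; valid ids: F3A, F3B, F5, ",
         "F6, F7A, F7B, F8, F9, F10", call. = FALSE)
  }
  figure_id <- match.arg(figure_id)
  spec <- switch(
    figure_id,
    F3A = list(config = experiment_config("E1", e1_session = list(
                 scheme = "shared", O_mag = 1)),
               n_observers = 4, preset = "paper_like_E1"),
    F3B = list(config = experiment_config("E1", e1_session = list(
                 scheme = "shared", O_mag = 0.8, disparity = TRUE)),
               n_observers = 4, preset = "paper_like_E1"),
    F5 = list(config = experiment_config("E2"),
              n_observers = 6, preset = "paper_like_E2"),
    F6 = list(config = experiment_config("E3"),
              n_observers = 5, preset = "paper_like_E3"),
    F7A = list(config = experiment_config("E1", e1_session = list(
                 scheme = "unbalanced_background", O_mag = 1)),
               n_observers = 4, preset = "paper_like_E1"),
    F7B = list(config = experiment_config("E1", e1_session = list(
                 scheme = "balanced_background", O_mag = 1)),
               n_observers = 4, preset = "aversion_static"),
    F8 = list(config = experiment_config("E1", e1_session = list(
                scheme = "balanced_background", O_mag = 1,
                transient = "abrupt", delta_t = 0.15)),
              n_observers = 4, preset = "aversion_transient"),
    F9 = list(config = experiment_config("E1", e1_session = list(
                scheme = "balanced_background", O_mag = 1,
                strength = "single")),
              n_observers = 4, preset = "aversion_static"),
    F10 = list(config = experiment_config("E4"),
               n_observers = 9, preset = "paper_like_E4")
  )
  structure(c(list(figure = figure_id), spec,
              list(normalize = "auto", reach_radius = 1.5)),
            class = "ocu_runconfig")
}

#' @export
print.ocu_runconfig <- function(x, ...) {
  cat("<ocu_runconfig>", x$figure, ":", x$config$experiment, "design,",
      x$n_observers, "observers, preset", x$preset, "\n")
  invisible(x)
}

#' Serialise / restore a run configuration as JSON
#'
#' @param rc An `ocu_runconfig`.
#' @param path JSON file path.
#' @return `path` (write) or an `ocu_runconfig` (read).
#' @export
write_run_config <- function(rc, path) {
  jsonlite::write_json(list(figure = rc$figure,
                            n_observers = rc$n_observers,
                            preset = rc$preset, normalize = rc$normalize,
                            reach_radius = rc$reach_radius),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rc <- reproduce_design(j$figure)
  rc$n_observers <- j$n_observers
  rc$preset <- j$preset
  rc$normalize <- j$normalize
  rc$reach_radius <- j$reach_radius
  rc
}

#' Run the full generate - simulate - analyse pipeline
#'
#' Simulates the configured cohort, applies trial exclusion, summarises
#' every observer-condition cell, normalises by baseline according to the
#' policy (`"auto"`: normalise when the between-observer coefficient of
#' variation of baseline RT exceeds 0.25), and runs the condition-contrast
#' t-tests.  With `out_dir`, writes the trial log, summary and test CSVs,
#' an RT figure, optionally the first trial's stereo PNG pair, and a
#' manifest listing every output file with its MD5 hash.  The bundle is a
#' deterministic function of `(rc, seed)`.
#'
#' @param rc An [reproduce_design()] configuration.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @param raster Also write the first trial's stereo PNG pair.
#' @return A list of class `"ocu_run"`: `trials`, `summaries`, `tests`,
#'   `normalized` (logical), `seed`, `rc`, and `files` (when written).
#' @export
run_pipeline <- function(rc, seed = 1, out_dir = NULL, raster = FALSE) {
  stopifnot(inherits(rc, "ocu_runconfig"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir)) {
      stop("cannot create output directory ", out_dir, call. = FALSE)
    }
  }
  params <- observer_preset(rc$preset)
  log <- simulate_cohort(rc$config, rc$n_observers, params,
                         master_seed = seed)
  excl <- exclude_trials(log)
  summ <- summarize_conditions(excl)
  base_rt <- dplyr::filter(summ, .data$condition == "baseline")$mean_rt_button
  cv <- stats::sd(base_rt) / mean(base_rt)
  do_norm <- switch(rc$normalize, on = TRUE, off = FALSE,
                    auto = isTRUE(cv > 0.25))
  by <- if (rc$config$experiment == "E4") character(0) else "O_mag"
  if (do_norm) summ <- normalize_by_baseline(summ, by = by)
  has_di <- "DI" %in% log$condition
  tests <- cueing_tests(excl, contrasts = if (has_di) {
    c("DI-DC", "baseline-DC", "DI-baseline")
  } else "baseline-DC")
  files <- character(0)
  if (!is.null(out_dir)) {
    p_tr <- file.path(out_dir, "trials.csv")
    utils::write.csv(log[setdiff(names(log), "gaze")], p_tr,
                     row.names = FALSE)
    p_su <- file.path(out_dir, "summaries.csv")
    utils::write.csv(summ, p_su, row.names = FALSE)
    p_te <- file.path(out_dir, "tests.csv")
    utils::write.csv(tests, p_te, row.names = FALSE)
    p_fig <- file.path(out_dir, "rt_by_condition.png")
    ggplot2::ggsave(p_fig, autoplot(summ), width = 7, height = 5, dpi = 150)
    files <- c(p_tr, p_su, p_te, p_fig)
    if (raster) {
      sched <- schedule_session(rc$config,
                                seed = (seed * 1009 + 9973) %% 2147483647)
      tr <- generate_trial_from_schedule(rc$config, sched[1, ])
      files <- c(files, write_stereo_png(
        tr, file.path(out_dir, "trial0001"), ppd = 4))
    }
    p_log <- file.path(out_dir, "run_log.txt")
    writeLines(c(paste("figure:", rc$figure),
                 paste("seed:", seed),
                 paste("observers:", rc$n_observers),
                 paste("preset:", rc$preset),
                 paste("normalized:", do_norm)), p_log)
    files <- c(files, p_log)
    manifest <- tibble::tibble(file = basename(files),
                               md5 = unname(tools::md5sum(files)))
    p_man <- file.path(out_dir, "manifest.csv")
    utils::write.csv(manifest, p_man, row.names = FALSE)
    files <- c(files, p_man)
  }
  structure(list(trials = excl, summaries = summ, tests = tests,
                 normalized = do_norm, seed = seed, rc = rc, files = files),
            class = "ocu_run")
}

#' @export
print.ocu_run <- function(x, ...) {
  cat("<ocu_run>", x$rc$figure, "seed", x$seed, ":",
      nrow(x$trials), "trials,", nrow(x$summaries), "condition cells\n")
  sig <- dplyr::filter(x$tests, .data$significant)
  if (nrow(sig) > 0) {
    cat("  significant contrasts:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s (|O| = %.3g): diff = %+.3f s, p = %.3g\n",
                  sig$contrast[i], sig$O_mag[i], sig$estimate[i],
                  sig$p.value[i]))
    }
  } else cat("  no significant contrasts\n")
  invisible(x)
}
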