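# Reaction-time analysis pipeline: trial exclusion, condition summaries,
# baseline normalisation, saccade scoring, median splits, paired tests.

cond_keys <- function(trials) {
  intersect(c("observer_id", "condition", "O_mag", "transient_mode",
              "delta_t"), names(trials))
}

#' Exclude incorrect and outlier trials
#'
#' Applies the trial-exclusion rule per observer and condition: incorrect
#' button presses are removed first; then, with mean `m` and standard
#' deviation `s` computed over the correct trials' RTs *before* any outlier
#' removal, trials with `rt < rt_min` (default 0.2 s) or `rt > m + k s`
#' (default `k = 3`, strict inequality) are excluded.  The rule is a single
#' pass: `m` and `s` are never recomputed after removals.
#'
#' @param trials Trial-log tibble with `rt_button_s` and `correct` columns;
#'   grouping uses whichever of `observer_id`, `condition`, `O_mag`,
#'   `transient_mode`, `delta_t` are present.
#' @param rt_min Lower RT bound (s).
#' @param sd_mult Upper-bound multiplier `k`.
#' @return `trials` with logical `kept` and character `exclude_reason`
#'   (`NA`, `"incorrect"`, `"rt_too_short"`, `"rt_outlier_3sd"`) columns.
#' @export
exclude_trials <- function(trials, rt_min = 0.2, sd_mult = 3) {
  stopifnot(all(c("rt_button_s", "correct") %in% names(trials)))
  keys <- cond_keys(trials)
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      .m = mean(.data$rt_button_s[.data$correct]),
      .s = stats::sd(.data$rt_button_s[.data$correct]),
      .s = ifelse(is.na(.data$.s), 0, .data$.s),
      exclude_reason = dplyr::case_when(
        !.data$correct ~ "incorrect",
        .data$rt_button_s < rt_min ~ "rt_too_short",
        .data$rt_button_s > .data$.m + sd_mult * .data$.s ~ "rt_outlier_3sd",
        TRUE ~ NA_character_),
      kept = is.na(.data$exclude_reason)) |>
    dplyr::ungroup() |>
    dplyr::select(-".m", -".s")
}

#' Classify the lateral direction of the first saccade
#'
#' A first saccade is erroneous when its horizontal displacement from the
#' central fixation has the opposite sign to the target's side of the
#' perceived array.  Saccades with |dx| below `threshold` (default 0.1 deg)
#' are unclassified (`NA`) and drop out of the saccade error rate.
#'
#' @param trials Trial-log tibble with `first_saccade_x_deg` and
#'   `target_side`.
#' @param threshold Minimum |dx| (deg) for classification.
#' @return Logical vector (`TRUE` = erroneous, `NA` = unclassified).
#' @export
first_saccade_error <- function(trials, threshold = 0.1) {
  dx <- trials$first_saccade_x_deg
  ifelse(is.na(dx) | abs(dx) < threshold, NA,
         (dx > 0) != (trials$target_side == "right"))
}

#' Time for the gaze to reach the target
#'
#' Returns the time of the first fixation event within `reach_radius` of
#' the target's perceived position, or `NA` if the gaze never reaches the
#' target before the trial ends.
#'
#' @param gaze Fixation-event tibble (`t_s`, `x_deg`, `y_deg`).
#' @param target_x,target_y Target's perceived position (deg).
#' @param reach_radius Reach radius (deg; default 1.5).
#' @return A time in seconds, or `NA_real_`.
#' @export
gaze_reach_rt <- function(gaze, target_x, target_y, reach_radius = 1.5) {
  d <- sqrt((gaze$x_deg - target_x)^2 + (gaze$y_deg - target_y)^2)
  hit <- which(d <= reach_radius)
  if (length(hit) == 0) NA_real_ else gaze$t_s[hit[1]]
}

#' Per-condition behavioural summaries
#'
#' Means and standard errors over the kept trials of each observer and
#' condition; the button error rate is the number of incorrect trials as a
#' fraction of all the condition's trials; the first-saccade error rate is
#' computed over classifiable saccades; gaze-RT statistics use the same
#' kept pool additionally excluding trials whose gaze never reached the
#' target.  Conditions whose kept pool is empty are flagged
#' (`n_kept = 0`, `NA` means).
#'
#' @param trials Output of [exclude_trials()].
#' @return A tibble of class `"ocu_summary"`, one row per observer and
#'   condition.
#' @export
summarize_conditions <- function(trials) {
  stopifnot("kept" %in% names(trials))
  keys <- cond_keys(trials)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  trials |>
    dplyr::mutate(.fs_err = first_saccade_error(trials)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_kept = sum(.data$kept),
      mean_rt_button = if (sum(.data$kept) > 0) {
        mean(.data$rt_button_s[.data$kept])
      } else NA_real_,
      sem_rt_button = sem(.data$rt_button_s[.data$kept]),
      mean_rt_gaze = {
        gz <- .data$gaze_rt_s[.data$kept & .data$gaze_reached_target]
        if (length(gz) > 0) mean(gz) else NA_real_
      },
      sem_rt_gaze = sem(.data$gaze_rt_s[.data$kept & .data$gaze_reached_target]),
      error_rate_button = mean(!.data$correct),
      error_rate_first_saccade = {
        cls <- .data$.fs_err[!is.na(.data$.fs_err)]
        if (length(cls) > 0) mean(cls) else NA_real_
      },
      .groups = "drop") |>
    structure(class = c("ocu_summary", class(tibble::tibble())))
}

#' Normalise condition RTs by each observer's baseline
#'
#' Divides each observer's mean RT in a condition by the same observer's
#' mean RT in the corresponding baseline condition, so the baseline's own
#' normalised RT is exactly 1.  By default the baseline is matched within
#' the same `|O|` family (`by = "O_mag"`); designs with a single session
#' baseline (all non-targets balanced, as in the heterogeneous-contrast
#' letter design) use `by = character(0)` so every condition shares the
#' observer's unique baseline.
#'
#' @param summaries An `ocu_summary` tibble.
#' @param by Columns (besides `observer_id`) defining the baseline family.
#' @return `summaries` with a `normalized_rt` column.
#' @export
normalize_by_baseline <- function(summaries, by = "O_mag") {
  base <- dplyr::filter(summaries, .data$condition == "baseline")
  key <- c("observer_id", by)
  base <- dplyr::select(base, dplyr::all_of(key),
                        .baseline_rt = "mean_rt_button")
  out <- dplyr::left_join(summaries, base, by = key)
  if (any(is.na(out$.baseline_rt))) {
    miss <- dplyr::filter(out, is.na(.data$.baseline_rt))
    stop("no baseline condition for family: ",
         paste(unique(paste(miss$observer_id,
                            if ("O_mag" %in% by) miss$O_mag else "",
                            sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  out |>
    dplyr::mutate(normalized_rt = ifelse(.data$condition == "baseline", 1,
                                         .data$mean_rt_button / .data$.baseline_rt)) |>
    dplyr::select(-".baseline_rt") |>
    structure(class = c("ocu_summary", class(tibble::tibble())))
}

#' Depth median split of targets
#'
#' Labels each trial's target `"far"` when its depth (from its binocular
#' disparity under the convention `d = x_R - x_L`; larger, uncrossed
#' disparity is farther) is farther than the median item depth of that
#' trial's array, and `"near"` otherwise (exact-median ties are labelled
#' near by default).  Accepts either a trial log carrying
#' `target_disparity` / `median_disparity` columns or a single `ocu_trial`
#' (whose all-zero-disparity arrays are unlabelled).
#'
#' @param trials Trial-log tibble, or an `ocu_trial`.
#' @param tie Label for exact-median ties (`"near"` by default).
#' @return Character vector (`"near"` / `"far"` / `NA`).
#' @export
depth_split <- function(trials, tie = "near") {
  if (inherits(trials, "ocu_trial")) {
    it <- trials$items
    if (all(it$disparity == 0)) return(NA_character_)
    tgt <- it$disparity[it$role %in% c("target", "both")]
    med <- stats::median(it$disparity)
    return(if (tgt > med) "far" else if (tgt < med) "near" else tie)
  }
  d <- trials$target_disparity
  m <- trials$median_disparity
  ifelse(is.na(d) | is.na(m), NA_character_,
         ifelse(d > m, "far", ifelse(d < m, "near", tie)))
}

#' Luminance-contrast median split of targets
#'
#' Labels each trial's target `"strong"` when its binocular contrast sum
#' exceeds the trial's median contrast sum over all items, and `"weak"`
#' otherwise (ties are weak by default).
#'
#' @param trials Trial-log tibble with `target_csum` and `median_csum`, or
#'   an `ocu_trial`.
#' @param tie Label for exact-median ties (`"weak"` by default).
#' @return Character vector (`"strong"` / `"weak"` / `NA`).
#' @export
contrast_split <- function(trials, tie = "weak") {
  if (inherits(trials, "ocu_trial")) {
    it <- trials$items
    tgt <- it$C_sum[it$role %in% c("target", "both")]
    med <- stats::median(it$C_sum)
    return(if (tgt > med) "strong" else if (tgt < med) "weak" else tie)
  }
  cs <- trials$target_csum
  m <- trials$median_csum
  ifelse(is.na(cs) | is.na(m), NA_character_,
         ifelse(cs > m, "strong", ifelse(cs < m, "weak", tie)))
}

#' Matched-sample t-test between two conditions
#'
#' Two-sided paired t-test on per-observer condition means (`df = n - 1`),
#' the significance criterion being `p < 0.05`.  Zero differences give
#' `t = 0, p = 1`; nonzero differences with zero variance are degenerate
#' and reported with `p = 0`.
#'
#' @param a,b Equal-length paired numeric vectors (per-observer means),
#'   `n >= 2`.
#' @return An object of class `"ocu_ttest"` with fields `estimate`
#'   (mean of `a - b`), `statistic`, `df`, `p.value`, `significant`,
#'   `degenerate`, `n`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            !anyNA(a), !anyNA(b))
  d <- a - b
  n <- length(d)
  if (all(d == 0)) {
    res <- list(estimate = 0, statistic = 0, df = n - 1, p.value = 1,
                degenerate = FALSE)
  } else if (stats::sd(d) == 0) {
    res <- list(estimate = mean(d), statistic = sign(mean(d)) * Inf,
                df = n - 1, p.value = 0, degenerate = TRUE)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(estimate = unname(tt$estimate),
                statistic = unname(tt$statistic),
                df = unname(tt$parameter), p.value = tt$p.value,
                degenerate = FALSE)
  }
  res$significant <- res$p.value < 0.05
  res$n <- n
  class(res) <- "ocu_ttest"
  res
}

#' @export
print.ocu_ttest <- function(x, ...) {
  cat(sprintf(
    "Matched-sample t-test: mean difference %.4g, t(%d) = %.3g, p = %.4g%s%s\n",
    x$estimate, x$df, x$statistic, x$p.value,
    if (x$significant) " *" else "",
    if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname paired_t
#' @param x An `ocu_ttest`.
#' @param ... Unused.
#' @export
tidy.ocu_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic,
                 df = x$df, p.value = x$p.value,
                 significant = x$significant, degenerate = x$degenerate)
}

#' @rdname paired_t
#' @export
glance.ocu_ttest <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, p.value = x$p.value,
                 significant = x$significant)
}

#' Condition-contrast t-tests across a cohort
#'
#' Convenience wrapper: computes per-observer mean RTs from an excluded
#' trial log, then runs the matched-sample t-test for each requested
#' dichoptic contrast within each `|O|` / transient family.
#'
#' @param trials Output of [exclude_trials()] for a whole cohort.
#' @param contrasts Character vector of contrasts among
#'   `"DI-DC"`, `"baseline-DC"`, `"DI-baseline"`.
#' @return A tibble with one row per family and contrast (mean difference,
#'   t, df, p, significance).
#' @export
cueing_tests <- function(trials, contrasts = c("DI-DC", "baseline-DC")) {
  keys <- setdiff(cond_keys(trials), "observer_id")
  fam <- setdiff(keys, "condition")
  means <- trials |>
    dplyr::filter(.data$kept) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("observer_id", keys)))) |>
    dplyr::summarise(rt = mean(.data$rt_button_s), .groups = "drop")
  fam_tbl <- means |>
    dplyr::filter(.data$condition != "baseline") |>
    dplyr::select(dplyr::all_of(fam)) |>
    dplyr::distinct()
  observers <- sort(unique(means$observer_id))
  pull_means <- function(cond, fam_row) {
    sel <- dplyr::filter(means, .data$condition == cond)
    matched <- dplyr::semi_join(sel, fam_row, by = fam)
    # designs with one session-wide baseline (e.g. a single balanced
    # baseline shared by all transient/|O| families) match it to every cell
    if (nrow(matched) == 0 && cond == "baseline") matched <- sel
    matched <- dplyr::arrange(matched, .data$observer_id)
    if (!identical(matched$observer_id, observers)) return(NULL)
    matched$rt
  }
  purrr::map_dfr(contrasts, function(ct) {
    parts <- strsplit(ct, "-", fixed = TRUE)[[1]]
    purrr::map_dfr(seq_len(nrow(fam_tbl)), function(i) {
      va <- pull_means(parts[1], fam_tbl[i, ])
      vb <- pull_means(parts[2], fam_tbl[i, ])
      if (is.null(va) || is.null(vb)) return(NULL)
      dplyr::bind_cols(fam_tbl[i, ], tibble::tibble(contrast = ct),
                       tidy(paired_t(va, vb)))
    })
  })
}
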