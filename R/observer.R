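#' Parameters of the saliency-capture synthetic observer
#'
#' The observer is phenomenological: it turns a search trial into a
#' first-saccade choice by a softmax over per-item priorities, then into a
#' button press with latency costs and multiplicative noise.  It exists so
#' the analysis pipeline can be exercised on data whose condition structure
#' matches the behavioural effects of interest (congruent-singleton
#' speed-up and incongruent slow-down growing with ocularity contrast,
#' lustre-driven aversion to persistent unbalanced singletons, near/far and
#' strong/weak contrast biases); it is not a cortical circuit model.
#'
#' @param w_ori Weight of orientation/identity contrast in priority.
#' @param w_oc Weight of ocularity contrast.
#' @param oc_threshold Minimum ocularity contrast producing attraction.
#' @param w_lum Weight of relative luminance-contrast deviation.
#' @param w_near Weight of the near-depth bias (nearness rank in \[0, 1\]).
#' @param aversion Lustre-aversion coefficient, subtracted for an ocularly
#'   unbalanced item among balanced items whose imbalance persists beyond
#'   `tau_percept`.
#' @param tau_percept Latency (s) below which a transient ocularity evades
#'   the aversion (percept formation is slower than saliency).
#' @param capture_temperature Softmax temperature for first-saccade
#'   targeting (must be positive).
#' @param t_saccade Mean first-saccade latency (s).
#' @param t_move Travel-plus-fixation cost of each corrective saccade (s).
#' @param t_decide Decision time added once gaze settles (s).
#' @param rt_noise_sd Log-scale SD of the multiplicative RT noise.
#' @param lapse Probability of flipping the button side (a response lapse).
#' @param heavy_tail_prob Probability that a trial's RT is inflated by a
#'   heavy-tail factor (injects outliers for the exclusion rule).
#' @param heavy_tail_scale Range of the uniform heavy-tail RT multiplier.
#' @return A list of class `"ocu_observer"`.
#' @export
observer_params <- function(w_ori = 2, w_oc = 2.5, oc_threshold = 0.5,
                            w_lum = 0, w_near = 0, aversion = 0,
                            tau_percept = 0.2, capture_temperature = 0.25,
                            t_saccade = 0.22, t_move = 0.15,
                            t_decide = 0.18, rt_noise_sd = 0.18,
                            lapse = 0.03, heavy_tail_prob = 0.01,
                            heavy_tail_scale = c(3, 6)) {
  stopifnot(w_ori >= 0, w_oc >= 0, oc_threshold >= 0, w_lum >= 0,
            w_near >= 0, aversion >= 0, tau_percept >= 0,
            capture_temperature > 0, t_saccade >= 0, t_move >= 0,
            t_decide >= 0, rt_noise_sd >= 0, lapse >= 0, lapse <= 0.5,
            heavy_tail_prob >= 0, heavy_tail_prob < 1)
  structure(as.list(environment()), class = "ocu_observer")
}

#' Shipped observer presets
#'
#' * `paper_like_E1` ... `paper_like_E4` — presets whose simulated cohorts
#'   reproduce the qualitative effect structure of the four experimental
#'   designs (stronger capture for larger ocularity contrast; depth and
#'   contrast biases active only in the heterogeneous-contrast letter
#'   design).
#' * `null` — ocularity-blind observer (`w_oc = 0`); congruent/incongruent
#'   reaction-time distributions are exchangeable by construction.
#' * `aversion_static`, `aversion_transient` — lustre-aversion observers
#'   for the monocular-singleton-among-binocular-bars sessions: the
#'   aversion coefficient exactly cancels the ocularity attraction of a
#'   persistently unbalanced singleton, so a static singleton is
#'   behaviourally neutral while a brief one (removed before
#'   `tau_percept`) still captures gaze.
#'
#' @param name Preset name.
#' @return An [observer_params()] object.
#' @export
observer_preset <- function(name = c("paper_like_E2", "paper_like_E1",
                                     "paper_like_E3", "paper_like_E4",
                                     "null", "aversion_static",
                                     "aversion_transient")) {
  name <- match.arg(name)
  switch(
    name,
    paper_like_E2 = observer_params(w_ori = 2, w_oc = 2.5),
    paper_like_E1 = observer_params(w_ori = 1.6, w_oc = 2.5),
    paper_like_E3 = observer_params(w_ori = 0.8, w_oc = 2.5,
                                    t_decide = 0.25),
    paper_like_E4 = observer_params(w_ori = 0.5, w_oc = 2.5,
                                    oc_threshold = 0.25, w_lum = 0.3,
                                    w_near = 0.4, aversion = 0.875,
                                    t_decide = 0.25),
    null = observer_params(w_ori = 2, w_oc = 0),
    aversion_static = observer_params(w_ori = 1.6, w_oc = 2.5,
                                      aversion = 2.5 * (1 - 0.5)),
    aversion_transient = observer_params(w_ori = 1.6, w_oc = 2.5,
                                         aversion = 2.5 * (1 - 0.5))
  )
}

#' @export
print.ocu_observer <- function(x, ...) {
  cat("<ocu_observer> w_ori", x$w_ori, "w_oc", x$w_oc,
      "threshold", x$oc_threshold, "aversion", x$aversion,
      "temperature", x$capture_temperature, "\n")
  invisible(x)
}

# Does an item's unique ocularity persist beyond the perceptual latency?
ocularity_persists <- function(transient_mode, delta_t, tau_percept) {
  transient_mode == "static" |
    (!is.na(delta_t) & delta_t > tau_percept)
}

#' Per-item attentional priorities of a trial
#'
#' Computes each item's priority as the sum of an orientation/identity
#' contrast term (the item's tilt or glyph differs from the array mode), an
#' ocularity-contrast term `w_oc * max(0, dO - oc_threshold)` with
#' `dO = |O_i - median O of the other items|` at array onset, a relative
#' luminance-contrast term, a near-depth bias proportional to the item's
#' nearness rank, and minus the lustre-aversion term for an ocularly
#' unbalanced item among balanced items whose imbalance persists beyond
#' `tau_percept`.  Priorities are finite and deterministic given the trial.
#'
#' @param trial An `ocu_trial`.
#' @param params An [observer_params()].
#' @return Numeric vector of priorities, one per item (in `trial$items`
#'   order).
#' @export
item_priority <- function(trial, params) {
  stopifnot(inherits(trial, "ocu_trial"), inherits(params, "ocu_observer"))
  it <- trial$items
  n <- nrow(it)
  # orientation / identity singleton term
  feat <- if (trial$config$item_kind == "bar") it$tilt else it$identity
  mode_feat <- names(sort(table(feat), decreasing = TRUE))[1]
  ori_term <- params$w_ori * (as.character(feat) != mode_feat)
  # ocularity contrast vs the median of the other items
  dO <- vapply(seq_len(n),
               function(i) abs(it$O[i] - stats::median(it$O[-i])), 0)
  oc_term <- params$w_oc * pmax(0, dO - params$oc_threshold)
  # relative luminance-contrast deviation
  lum_term <- if (params$w_lum > 0) {
    params$w_lum * (it$C_sum - mean(it$C_sum)) / mean(it$C_sum)
  } else 0
  # nearness rank: crossed disparity (negative d) is nearer
  near_term <- if (params$w_near > 0) {
    params$w_near * (rank(-it$disparity) - 1) / (n - 1)
  } else 0
  balanced_ctx <- stats::median(abs(it$O[it$role == "background"])) == 0
  unbal <- abs(it$O) > 0 & balanced_ctx
  persists <- ocularity_persists(it$transient_mode, it$delta_t,
                                 params$tau_percept)
  # items that keep their session-long ocularity are "persistent" even with
  # a static profile; only transiently unbalanced items evade the aversion
  av_term <- params$aversion * (unbal & persists)
  as.numeric(ori_term + oc_term + lum_term + near_term - av_term)
}

# Priorities of the target and singleton classes relative to a zero
# background, for sessions whose background items share one priority.
# Exactly matches item_priority() for such trials (asserted in tests).
class_priorities <- function(condition, O_mag, transient_mode, delta_t,
                             scheme, params) {
  dO_sing <- switch(scheme,
                    shared = 2 * O_mag,
                    balanced_background = O_mag,
                    unbalanced_background = O_mag)
  attract <- params$w_oc * pmax(0, dO_sing - params$oc_threshold)
  # aversion needs an unbalanced singleton in a balanced context
  unbal <- scheme == "balanced_background" & O_mag > 0
  persists <- ocularity_persists(transient_mode, delta_t, params$tau_percept)
  avert <- params$aversion * (unbal & persists)
  sing_extra <- ifelse(condition == "baseline", 0, attract - avert)
  list(
    p_target = params$w_ori + ifelse(condition == "DC", sing_extra, 0),
    p_singleton = ifelse(condition == "DI", sing_extra, NA_real_)
  )
}

#' Simulate one behavioural trial
#'
#' Draws the first saccade target by a softmax over [item_priority()]
#' values at the observer's capture temperature.  If the first-selected
#' item is not the target, a corrective saccade to the target follows at
#' cost `t_move`.  The button side is the side of the finally attended
#' item's perceived position, flipped with probability `lapse`; the button
#' RT is the last saccade time plus `t_decide`, under multiplicative
#' lognormal noise (with an occasional heavy-tail inflation).  The gaze
#' trace records the fixation sequence from the central fixation point.
#'
#' @param trial An `ocu_trial`.
#' @param params An [observer_params()].
#' @return A one-row tibble (trial-log schema) with a `gaze` list-column
#'   holding the fixation events (`t_s`, `x_deg`, `y_deg`).
#' @export
simulate_trial <- function(trial, params) {
  pri <- item_priority(trial, params)
  it <- trial$items
  w <- exp((pri - max(pri)) / params$capture_temperature)
  if (all(pri == pri[1])) {
    captured <- sample.int(nrow(it), 1)  # degenerate: uniform capture
  } else {
    captured <- sample.int(nrow(it), 1, prob = w)
  }
  tgt <- which(it$role %in% c("target", "both"))
  t1 <- max(0.08, stats::rnorm(1, params$t_saccade, 0.03))
  gaze <- tibble::tibble(t_s = 0, x_deg = 0, y_deg = 0)
  gaze <- dplyr::bind_rows(gaze, tibble::tibble(
    t_s = t1, x_deg = it$x[captured], y_deg = it$y[captured]))
  t_final <- t1
  if (captured != tgt) {
    t_final <- t1 + params$t_move
    gaze <- dplyr::bind_rows(gaze, tibble::tibble(
      t_s = t_final, x_deg = it$x[tgt], y_deg = it$y[tgt]))
  }
  rt <- (t_final + params$t_decide) *
    exp(stats::rnorm(1, 0, params$rt_noise_sd))
  if (stats::runif(1) < params$heavy_tail_prob) {
    rt <- rt * stats::runif(1, params$heavy_tail_scale[1],
                            params$heavy_tail_scale[2])
  }
  side <- ifelse(it$x[tgt] >= 0, "right", "left")
  if (stats::runif(1) < params$lapse) {
    side <- setdiff(c("left", "right"), side)
  }
  tibble::tibble(
    condition = trial$condition, O_mag = trial$O_mag,
    transient_mode = trial$transient_mode, delta_t = trial$delta_t,
    target_side = trial$target_side,
    rt_button_s = rt, button = side,
    correct = side == trial$target_side,
    first_saccade_t_s = t1,
    first_saccade_x_deg = it$x[captured],
    first_saccade_y_deg = it$y[captured],
    gaze_reached_target = TRUE,
    gaze_rt_s = t_final,
    target_disparity = it$disparity[tgt],
    median_disparity = stats::median(it$disparity),
    target_csum = it$C_sum[tgt],
    median_csum = stats::median(it$C_sum),
    gaze = list(gaze)
  )
}

#' Simulate a full session for one observer
#'
#' Runs the synthetic observer over every trial of a session schedule.
#' Two routes produce identical priority structure:
#' * `"fast"` — a vectorised class-based route that collapses the softmax
#'   over items into target / singleton / background classes.  It is exact
#'   whenever all background items share one priority, i.e. for sessions
#'   with a constant binocular contrast sum and `w_lum = w_near = 0`.
#' * `"full"` — regenerates every scene with
#'   [generate_trial_from_schedule()] and calls [simulate_trial()]
#'   per item; required for the heterogeneous-contrast letter design (E4)
#'   or observers with luminance/depth biases.
#'
#' `"auto"` picks fast when it is exact.
#'
#' @param schedule A [schedule_session()] tibble.
#' @param config The matching [experiment_config()].
#' @param params An [observer_params()].
#' @param method `"auto"`, `"fast"`, or `"full"`.
#' @return A tibble with one row per trial (trial-log schema).
#' @export
simulate_session <- function(schedule, config, params,
                             method = c("auto", "fast", "full")) {
  method <- match.arg(method)
  fast_ok <- params$w_lum == 0 && params$w_near == 0 &&
    config$luminance_model != "increment_letters"
  if (method == "auto") method <- if (fast_ok) "fast" else "full"
  if (method == "fast" && !fast_ok) {
    stop("the fast route is exact only with w_lum = w_near = 0 and a ",
         "homogeneous-contrast display; use method = \"full\"", call. = FALSE)
  }
  if (method == "full") {
    out <- purrr::map(seq_len(nrow(schedule)), function(i) {
      tr <- generate_trial_from_schedule(config, schedule[i, ])
      simulate_trial(tr, params)
    })
    return(dplyr::mutate(dplyr::bind_rows(out),
                         trial = schedule$trial, .before = 1))
  }
  n <- nrow(schedule)
  scheme <- if (config$experiment == "E4") "balanced_background"
            else if (config$experiment == "E1") config$e1_session$scheme
            else "shared"
  cp <- class_priorities(schedule$condition, schedule$O_mag,
                         schedule$transient_mode, schedule$delta_t,
                         scheme, params)
  tau <- params$capture_temperature
  n_items <- schedule$n_items
  has_sing <- schedule$condition == "DI"
  w_t <- exp(cp$p_target / tau)
  w_s <- ifelse(has_sing, exp(cp$p_singleton / tau), 0)
  w_b <- (n_items - 1 - has_sing) * 1  # exp(0 / tau)
  z <- w_t + w_s + w_b
  u <- stats::runif(n) * z
  captured <- ifelse(u < w_t, "target",
              ifelse(u < w_t + w_s, "singleton", "background"))
  # background captures land on a random grid cell
  bg_idx <- captured == "background"
  bx <- by <- numeric(n)
  if (any(bg_idx)) {
    gg <- make_grid(config)
    j <- sample.int(nrow(gg), sum(bg_idx), replace = TRUE)
    bx[bg_idx] <- gg$x[j]; by[bg_idx] <- gg$y[j]
  }
  fx <- ifelse(captured == "target", schedule$target_x,
        ifelse(captured == "singleton", schedule$singleton_x, bx))
  fy <- ifelse(captured == "target", schedule$target_y,
        ifelse(captured == "singleton", schedule$singleton_y, by))
  t1 <- pmax(0.08, stats::rnorm(n, params$t_saccade, 0.03))
  hit <- captured == "target"
  t_final <- t1 + ifelse(hit, 0, params$t_move)
  rt <- (t_final + params$t_decide) *
    exp(stats::rnorm(n, 0, params$rt_noise_sd))
  ht <- stats::runif(n) < params$heavy_tail_prob
  rt[ht] <- rt[ht] * stats::runif(sum(ht), params$heavy_tail_scale[1],
                                  params$heavy_tail_scale[2])
  flip <- stats::runif(n) < params$lapse
  side <- ifelse(xor(schedule$target_side == "right", flip), "right", "left")
  tibble::tibble(
    trial = schedule$trial,
    condition = schedule$condition, O_mag = schedule$O_mag,
    transient_mode = schedule$transient_mode, delta_t = schedule$delta_t,
    target_side = schedule$target_side,
    rt_button_s = rt, button = side, correct = side == schedule$target_side,
    first_saccade_t_s = t1, first_saccade_x_deg = fx,
    first_saccade_y_deg = fy,
    gaze_reached_target = TRUE, gaze_rt_s = t_final,
    target_disparity = NA_real_, median_disparity = NA_real_,
    target_csum = 1, median_csum = 1
  )
}

#' Simulate a cohort of observers
#'
#' Gives each observer an independent substream seeded from `master_seed`
#' (documented scheme: observer `i` uses
#' `(master_seed * 1009 + i * 9973) mod (2^31 - 1)` for the schedule and
#' the following state for the behaviour), builds each observer their own
#' randomised session, and concatenates the trial logs.  Two cohorts with
#' the same master seed are identical.
#'
#' @param config An [experiment_config()].
#' @param observers Number of observers, or a list of [observer_params()]
#'   (one per observer).
#' @param params Shared [observer_params()] used when `observers` is a
#'   count.
#' @param master_seed Integer master seed.
#' @param method Passed to [simulate_session()].
#' @return A trial-log tibble with an `observer_id` column.
#' @export
simulate_cohort <- function(config, observers, params = observer_preset(),
                            master_seed = 1, method = "auto") {
  plist <- if (is.list(observers) && !inherits(observers, "ocu_observer") &&
               inherits(observers[[1]], "ocu_observer")) {
    observers
  } else {
    rep(list(params), observers)
  }
  logs <- purrr::imap(plist, function(p, i) {
    seed_i <- (as.numeric(master_seed) * 1009 + i * 9973) %% 2147483647
    sched <- schedule_session(config, seed = seed_i)
    set.seed((seed_i + 1) %% 2147483647)
    simulate_session(sched, config, p, method = method) |>
      dplyr::mutate(observer_id = paste0("obs", i), .before = 1)
  })
  dplyr::bind_rows(logs)
}

#' Write a trial log and per-trial eye traces as CSV
#'
#' The trial log drops the `gaze` list-column; when present, each trial's
#' fixation events are written as `trace_<observer>_<trial>.csv` files with
#' columns `t_s`, `x_deg`, `y_deg`.
#'
#' @param log A trial-log tibble.
#' @param dir Output directory (created if needed).
#' @return The trial-log CSV path, invisibly.
#' @export
write_trial_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- log[setdiff(names(log), "gaze")]
  path <- file.path(dir, "trials.csv")
  utils::write.csv(flat, path, row.names = FALSE)
  if ("gaze" %in% names(log)) {
    obs <- if ("observer_id" %in% names(log)) log$observer_id else "obs1"
    purrr::pwalk(list(log$gaze, obs, log$trial), function(g, o, tr) {
      utils::write.csv(g, file.path(dir, sprintf("trace_%s_%04d.csv", o, tr)),
                       row.names = FALSE)
    })
  }
  invisible(path)
}
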