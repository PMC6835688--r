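#' Configuration for one of the four dichoptic search experiments
#'
#' Returns the full stimulus-side configuration of a search experiment:
#' grid geometry, item kind and size, positional jitter bound, disparity
#' range, target-placement constraints, session condition grid, and the
#' luminance model.  The four built-in designs are:
#'
#' * `E1` — orientation search among bright bars (+/-10 deg from horizontal)
#'   on a black background; 22 x 30 grid over 46 x 34 deg; jitter up to
#'   0.24 deg; target about 15 deg eccentric, at least 12 deg horizontally.
#'   Session variants select the dichoptic scheme (see `e1_session`).
#' * `E2` — orientation search among dark bars (+/-45 deg) on a 110 cd/m2
#'   white background; 23 x 23 grid over 18.4 x 18.4 deg; jitter 0.05 deg;
#'   disparity within (-0.21, 0.21) deg; target in rows 4-20, closest to a
#'   circle of radius 10 grid units, at least 6 grid units horizontal;
#'   9 interleaved conditions (baseline/DC/DI x |O| in {1/5, 1/3, 3/5}),
#'   50 trials each.
#' * `E3` — letter search (`T` among `L`s), dark letters; 17 x 17 grid over
#'   18.6 x 18.6 deg; jitter 0.064 deg; target rows 4-14, radius 7, at
#'   least 5 horizontal; 8 conditions (baseline/DC x |O| in
#'   {1/5, 1/3, 1/2, 3/5}), 50 trials each.
#' * `E4` — letter search with light letters on a 43 cd/m2 grey background
#'   and heterogeneous luminance contrasts; 14 x 14 grid over
#'   18.3 x 18.3 deg; jitter 0.077 deg; target rows 4-11, horizontal
#'   offset 2-5 and radius 3-6 grid units; 10 conditions (one baseline with
#'   all items at O = 0, plus DC cells crossing |O| with a static profile
#'   or a smooth decay starting at 0.1 or 0.5 s), 45 trials each.
#'
#' @param experiment `"E1"`, `"E2"`, `"E3"`, or `"E4"`.
#' @param trials_per_condition Overrides the design's per-condition trial
#'   count (e.g. 20 for E1's observer LZ).
#' @param e1_session For E1 only, a list with elements `scheme` (one of
#'   `"shared"` for all-items-same-|O| sessions, `"balanced_background"`
#'   for a monocular singleton among binocular bars,
#'   `"unbalanced_background"` for a binocular singleton among monocular
#'   bars), `O_mag` (session ocularity magnitude, 1 for monocular, 0.8 for
#'   the 9:1 eye-dominance session), `strength` (`"double"`: constant
#'   C_L + C_R across bars; `"single"`: the monocular item's max(C_L, C_R)
#'   matches the binocular bars'), `transient` (`"static"` or `"abrupt"`),
#'   and `delta_t` (abrupt offset time, 0.15 s), plus `disparity` (logical,
#'   TRUE for the random-depth session).
#' @param radius_tol Tolerance (grid units) around the target-placement
#'   circle for E2/E3: cells whose radial distance is within `radius_tol`
#'   of the best achievable are all eligible.  0 keeps only the exact
#'   minimisers.
#' @return A list of class `"ocu_config"`.
#' @export
experiment_config <- function(experiment = c("E1", "E2", "E3", "E4"),
                              trials_per_condition = NULL,
                              e1_session = NULL,
                              radius_tol = 0) {
  experiment <- match.arg(experiment)
  base <- switch(
    experiment,
    E1 = list(
      rows = 22, cols = 30, extent_x = 46, extent_y = 34,
      item_kind = "bar", item_size = c(1.1, 0.12), bar_tilt = 10,
      jitter_bound = 0.24, disparity_half_range = 0.3,
      target_placement = list(kind = "eccentricity", min_horizontal_deg = 12,
                              ecc_range_deg = c(13.5, 16.5)),
      viewing_distance = 40,
      fixation = list(diameter = 0.3, duration = 1.2),
      anchor_style = "dots+corner_disks", dot_size = 0.12,
      trials_per_condition = 50,
      luminance_model = "bright_bar", L_balanced = 24,
      display = display_config("increment", L_o = 0, L_1 = 48,
                               optic_attenuation = 7 / 8)
    ),
    E2 = list(
      rows = 23, cols = 23, extent_x = 18.4, extent_y = 18.4,
      item_kind = "bar", item_size = c(0.6, 0.085), bar_tilt = 45,
      jitter_bound = 0.05, disparity_half_range = 0.21,
      target_placement = list(kind = "annulus", row_band = c(4, 20),
                              radius = 10, min_horizontal = 6),
      viewing_distance = 57,
      fixation = list(diameter = 0.3, duration = 1.2),
      anchor_style = "dots+frame", dot_size = 0.17,
      trials_per_condition = 50,
      luminance_model = "decrement",
      display = display_config("decrement", L_bg = 110)
    ),
    E3 = list(
      rows = 17, cols = 17, extent_x = 18.6, extent_y = 18.6,
      item_kind = "letter", item_size = c(0.7, 0.7), stroke = 0.085,
      bar_tilt = 0,
      jitter_bound = 0.064, disparity_half_range = 0.21,
      target_placement = list(kind = "annulus", row_band = c(4, 14),
                              radius = 7, min_horizontal = 5),
      viewing_distance = 57,
      fixation = list(diameter = 0.3, duration = 1.2),
      anchor_style = "dots+frame", dot_size = 0.17,
      trials_per_condition = 50,
      luminance_model = "decrement",
      display = display_config("decrement", L_bg = 110)
    ),
    E4 = list(
      rows = 14, cols = 14, extent_x = 18.3, extent_y = 18.3,
      item_kind = "letter", item_size = c(0.75, 0.75), stroke = 0.1,
      bar_tilt = 0,
      jitter_bound = 0.077, disparity_half_range = 0.21,
      target_placement = list(kind = "band", row_band = c(4, 11),
                              horizontal_band = c(2, 5),
                              radial_band = c(3, 6)),
      viewing_distance = 57,
      fixation = list(diameter = 0.3, duration = 1.2),
      anchor_style = "dots+frame", dot_size = 0.17,
      trials_per_condition = 45,
      luminance_model = "increment_letters",
      display = display_config("increment", L_o = 43, L_1 = 67)
    )
  )
  base$experiment <- experiment
  base$radius_tol <- radius_tol
  if (!is.null(trials_per_condition)) {
    base$trials_per_condition <- trials_per_condition
  }
  if (experiment == "E1") {
    sess <- list(scheme = "shared", O_mag = 1, strength = "double",
                 transient = "static", delta_t = 0.15, disparity = FALSE)
    if (!is.null(e1_session)) sess[names(e1_session)] <- e1_session
    stopifnot(sess$scheme %in% c("shared", "balanced_background",
                                 "unbalanced_background"),
              sess$strength %in% c("double", "single"),
              sess$transient %in% c("static", "abrupt"))
    base$e1_session <- sess
  }
  base$condition_grid <- default_condition_grid(base)
  structure(base, class = "ocu_config")
}

#' @export
print.ocu_config <- function(x, ...) {
  cat("<ocu_config>", x$experiment, ":", x$rows, "x", x$cols,
      x$item_kind, "array over", x$extent_x, "x", x$extent_y, "deg\n")
  cat("  conditions:", nrow(x$condition_grid),
      "; trials per condition:", x$trials_per_condition, "\n")
  invisible(x)
}

# Interleaved condition grid of a session, one row per condition cell.
default_condition_grid <- function(config) {
  ex <- config$experiment
  if (ex == "E1") {
    tibble::tibble(condition = c("baseline", "DC", "DI"),
                   O_mag = config$e1_session$O_mag,
                   transient_mode = config$e1_session$transient,
                   delta_t = ifelse(config$e1_session$transient == "static",
                                    NA_real_, config$e1_session$delta_t))
  } else if (ex == "E2") {
    tidyr::expand_grid(condition = c("baseline", "DC", "DI"),
                       O_mag = c(1 / 5, 1 / 3, 3 / 5)) |>
      dplyr::mutate(transient_mode = "static", delta_t = NA_real_)
  } else if (ex == "E3") {
    tidyr::expand_grid(condition = c("baseline", "DC"),
                       O_mag = c(1 / 5, 1 / 3, 1 / 2, 3 / 5)) |>
      dplyr::mutate(transient_mode = "static", delta_t = NA_real_)
  } else {
    dplyr::bind_rows(
      tibble::tibble(condition = "baseline", O_mag = 0,
                     transient_mode = "static", delta_t = NA_real_),
      tidyr::expand_grid(condition = "DC", O_mag = c(1 / 5, 1 / 3, 3 / 5),
                         profile = c("static", "smooth_0.1", "smooth_0.5")) |>
        dplyr::mutate(
          transient_mode = ifelse(profile == "static", "static", "smooth"),
          delta_t = dplyr::case_when(profile == "smooth_0.1" ~ 0.1,
                                     profile == "smooth_0.5" ~ 0.5,
                                     TRUE ~ NA_real_)) |>
        dplyr::select(-"profile")
    )
  }
}

#' Regular grid of item centres
#'
#' Lays out `rows x cols` centres, centred on the origin, with x rightward
#' and y upward and the grid indexed 1-based from the top-left.  The
#' bounding box of the centres spans exactly (`extent_x`, `extent_y`), so
#' the spacing is `extent / (n - 1)` along each axis.
#'
#' @param config An [experiment_config()].
#' @return A tibble with columns `row`, `col`, `x`, `y` (deg).
#' @export
make_grid <- function(config) {
  rows <- config$rows; cols <- config$cols
  stopifnot(rows >= 1, cols >= 1)
  if (cols == 1 && config$extent_x != 0) {
    stop("a single-column grid must have extent_x = 0", call. = FALSE)
  }
  if (rows == 1 && config$extent_y != 0) {
    stop("a single-row grid must have extent_y = 0", call. = FALSE)
  }
  sx <- if (cols > 1) config$extent_x / (cols - 1) else 0
  sy <- if (rows > 1) config$extent_y / (rows - 1) else 0
  tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols)) |>
    dplyr::mutate(x = (.data$col - (cols + 1) / 2) * sx,
                  y = ((rows + 1) / 2 - .data$row) * sy)
}

#' Apply independent uniform positional jitter to grid positions
#'
#' Each coordinate is displaced by an independent uniform draw in
#' `[-bound, +bound]`, with the experiment's jitter bound (E1: 0.24 deg,
#' E2: 0.05, E3: 0.064, E4: 0.077).  Grid indices are retained.
#'
#' @param grid A tibble from [make_grid()].
#' @param config An [experiment_config()] (its `jitter_bound` is used).
#' @return `grid` with `x`, `y` jittered.
#' @export
jitter_positions <- function(grid, config) {
  b <- config$jitter_bound
  n <- nrow(grid)
  dplyr::mutate(grid,
                x = .data$x + stats::runif(n, -b, b),
                y = .data$y + stats::runif(n, -b, b))
}

#' Eligible target cells of an experiment's placement constraint
#'
#' Enumerates the grid cells that satisfy the experiment's target-placement
#' constraint.  Radial and horizontal distances are measured in grid units
#' from the array centre `((rows + 1) / 2, (cols + 1) / 2)`; E1 measures in
#' degrees instead.  For the circle-based constraints (E2, E3) the eligible
#' set consists of the cells whose radial distance is within `radius_tol`
#' grid units of the best achievable `|distance - radius|`.
#'
#' @param config An [experiment_config()].
#' @return A tibble of `row`, `col` cells (non-empty, or an error).
#' @export
target_feasible_set <- function(config) {
  g <- make_grid(config)
  cr <- (config$rows + 1) / 2
  cc <- (config$cols + 1) / 2
  g <- dplyr::mutate(g,
                     drow = .data$row - cr, dcol = .data$col - cc,
                     rdist = sqrt(.data$drow^2 + .data$dcol^2))
  tp <- config$target_placement
  feas <- switch(
    tp$kind,
    eccentricity = dplyr::filter(
      g, abs(.data$x) >= tp$min_horizontal_deg,
      sqrt(.data$x^2 + .data$y^2) >= tp$ecc_range_deg[1],
      sqrt(.data$x^2 + .data$y^2) <= tp$ecc_range_deg[2]),
    annulus = {
      cand <- dplyr::filter(g, .data$row >= tp$row_band[1],
                            .data$row <= tp$row_band[2],
                            abs(.data$dcol) >= tp$min_horizontal)
      if (nrow(cand) > 0) {
        dev <- abs(cand$rdist - tp$radius)
        cand[dev <= min(dev) + config$radius_tol, ]
      } else cand
    },
    band = dplyr::filter(g, .data$row >= tp$row_band[1],
                         .data$row <= tp$row_band[2],
                         abs(.data$dcol) >= tp$horizontal_band[1],
                         abs(.data$dcol) <= tp$horizontal_band[2],
                         .data$rdist >= tp$radial_band[1],
                         .data$rdist <= tp$radial_band[2])
  )
  if (nrow(feas) == 0) {
    stop("target placement constraint admits no grid cell", call. = FALSE)
  }
  dplyr::select(feas, "row", "col", "x", "y")
}

#' Sample a target grid position
#'
#' Draws uniformly from [target_feasible_set()].
#'
#' @param config An [experiment_config()].
#' @return A one-row tibble with `row`, `col`, `x`, `y`.
#' @export
choose_target_position <- function(config) {
  feas <- target_feasible_set(config)
  feas[sample.int(nrow(feas), 1), ]
}

#' Place the non-target ocularity singleton of a DI trial
#'
#' The default policy mirrors the target's grid position across the
#' vertical midline (`col -> cols + 1 - col`), guaranteeing the opposite
#' lateral half of the perceived array at matched eccentricity.  The
#' `"sample"` policy instead draws uniformly from all cells in the opposite
#' lateral half.  If the mirror cell coincides with the target (only
#' possible for an on-axis target, which the placement constraints
#' exclude), the sampling policy is used as a fallback.
#'
#' @param target One-row tibble with the target's `row`, `col`.
#' @param config An [experiment_config()].
#' @param policy `"mirror"` (default) or `"sample"`.
#' @return A one-row tibble with the singleton's `row`, `col`.
#' @export
choose_singleton_position <- function(target, config,
                                      policy = c("mirror", "sample")) {
  policy <- match.arg(policy)
  cc <- (config$cols + 1) / 2
  mirror_col <- config$cols + 1 - target$col
  if (policy == "mirror" && !(mirror_col == target$col)) {
    return(tibble::tibble(row = target$row, col = mirror_col))
  }
  g <- make_grid(config)
  target_left <- target$col < cc
  opp <- dplyr::filter(g, if (target_left) .data$col > cc else .data$col < cc)
  opp[sample.int(nrow(opp), 1), c("row", "col")]
}

#' Assign item identities (orientations or glyphs)
#'
#' Bar experiments: the background tilt is drawn as +tilt or -tilt from
#' horizontal with equal probability and the target receives the opposite
#' tilt.  Letter experiments: the target is a `T` and every other item an
#' `L`, drawn upright.
#'
#' @param items Items tibble containing a `role` column (exactly one row
#'   with role `"target"` or `"both"`).
#' @param config An [experiment_config()].
#' @return `items` with `identity` (chr) and `tilt` (deg) columns.
#' @export
assign_identities <- function(items, config) {
  is_target <- items$role %in% c("target", "both")
  stopifnot(sum(is_target) == 1)
  if (config$item_kind == "bar") {
    bg_tilt <- sample(c(-1, 1), 1) * config$bar_tilt
    dplyr::mutate(items, identity = "bar",
                  tilt = ifelse(is_target, -bg_tilt, bg_tilt))
  } else {
    dplyr::mutate(items, identity = ifelse(is_target, "T", "L"), tilt = 0)
  }
}

#' Assign per-item ocularity for a dichoptic condition
#'
#' Three schemes cover all session designs:
#' * `"shared"` — every item has the same |O| (= `O_mag`); in a baseline
#'   trial all items share one ocularity sign (drawn per trial), while in a
#'   DC/DI trial the singleton (target or designated non-target) carries
#'   the unique sign.
#' * `"balanced_background"` — all non-singleton items are ocularly
#'   balanced (O = 0) and the singleton has `O = +/-O_mag` (E4's target;
#'   the monocular-among-binocular E1 sessions with `O_mag = 1`).
#' * `"unbalanced_background"` — all non-singleton items share
#'   `O = +/-O_mag` and the singleton is balanced (O = 0; the
#'   binocular-among-monocular E1 sessions).
#'
#' Binocular contrast sums default to 1 for every item (`"double"`
#' strength: C_L + C_R constant across bars).  Under `"single"` strength,
#' monocular items (|O| = 1) get `C_sum = 0.5`, matching their single-eye
#' contrast max(C_L, C_R) to that of the balanced items.
#'
#' @param items Items tibble with a `role` column.
#' @param condition `"baseline"`, `"DC"`, or `"DI"`.
#' @param O_mag Ocularity magnitude of the session/trial, in \[0, 1\].
#' @param scheme See above.
#' @param strength `"double"` or `"single"`.
#' @param sign Optional +1/-1 fixing the singleton's (or baseline items')
#'   ocularity sign; drawn at random when `NULL`.
#' @return `items` with columns `O`, `s_L`, `s_R`, `C_sum`.
#' @export
assign_ocularity <- function(items, condition, O_mag,
                             scheme = c("shared", "balanced_background",
                                        "unbalanced_background"),
                             strength = c("double", "single"),
                             sign = NULL) {
  scheme <- match.arg(scheme)
  strength <- match.arg(strength)
  if (O_mag < 0 || O_mag > 1) stop("O_mag must lie in [0, 1]", call. = FALSE)
  sgn <- if (is.null(sign)) sample(c(-1, 1), 1) else sign
  is_singleton <- switch(condition,
                         baseline = rep(FALSE, nrow(items)),
                         DC = items$role %in% c("target", "both"),
                         DI = items$role == "singleton")
  if (condition != "baseline") stopifnot(sum(is_singleton) == 1)
  O <- switch(
    scheme,
    shared = if (condition == "baseline") rep(sgn * O_mag, nrow(items))
             else ifelse(is_singleton, sgn * O_mag, -sgn * O_mag),
    balanced_background = ifelse(is_singleton, sgn * O_mag, 0),
    unbalanced_background = ifelse(is_singleton, 0, sgn * O_mag)
  )
  C_sum <- rep(1, nrow(items))
  if (strength == "single") C_sum[abs(O) == 1] <- 0.5
  dplyr::mutate(items, O = O, s_L = (1 + O) / 2, s_R = (1 - O) / 2,
                C_sum = C_sum)
}

#' Assign random disparities and per-eye positions
#'
#' Each item gets an independent uniform disparity in the experiment's
#' range, except for the zero-disparity items in the left-most and
#' right-most grid columns.  Disparity follows the convention
#' `d = x_right_eye - x_left_eye` (negative = crossed = nearer than
#' fixation): the monocular images are shifted by half the magnitude in
#' opposite horizontal directions, so the mean of the per-eye positions is
#' the perceived position.
#'
#' @param items Items tibble with `col` and `x` columns.
#' @param config An [experiment_config()]; `disparity_half_range` may be 0
#'   to disable depth (E1 sessions without random depth).
#' @return `items` with `disparity`, `x_L`, `x_R` columns.
#' @export
assign_disparity <- function(items, config) {
  r <- config$disparity_half_range
  if (config$experiment == "E1" && !isTRUE(config$e1_session$disparity)) r <- 0
  n <- nrow(items)
  d <- if (r > 0) stats::runif(n, -r, r) else rep(0, n)
  d[items$col == 1 | items$col == config$cols] <- 0
  dplyr::mutate(items, disparity = d,
                x_L = .data$x - d / 2, x_R = .data$x + d / 2)
}

#' Vergence-anchoring primitives of a search array
#'
#' A task-irrelevant binocular dot is placed at the centre of mass of every
#' 2 x 2 neighbourhood of (jittered) item positions, giving
#' `(rows - 1) * (cols - 1)` dots.  E1 additionally places four binocular
#' corner disks (0.5 deg diameter) outside the array; E2-E4 instead
#' enclose the array with a rectangular frame 10% larger than the array
#' extent.  All anchors are binocular with zero disparity.
#'
#' @param items Items tibble with `row`, `col`, `x`, `y`.
#' @param config An [experiment_config()].
#' @return A tibble with `type` (`"dot"`, `"disk"`, `"frame"`), `x`, `y`,
#'   `size` (deg; for the frame, `size_x`/`size_y` give the extent), and
#'   `disparity` (always 0).
#' @export
place_vergence_anchors <- function(items, config) {
  rows <- config$rows; cols <- config$cols
  xm <- matrix(NA_real_, rows, cols)
  ym <- matrix(NA_real_, rows, cols)
  xm[cbind(items$row, items$col)] <- items$x
  ym[cbind(items$row, items$col)] <- items$y
  dot_x <- (xm[-rows, -cols] + xm[-rows, -1] + xm[-1, -cols] + xm[-1, -1]) / 4
  dot_y <- (ym[-rows, -cols] + ym[-rows, -1] + ym[-1, -cols] + ym[-1, -1]) / 4
  dots <- tibble::tibble(type = "dot", x = as.vector(dot_x),
                         y = as.vector(dot_y), size = config$dot_size,
                         size_x = NA_real_, size_y = NA_real_, disparity = 0)
  extras <- if (config$anchor_style == "dots+corner_disks") {
    margin <- 1
    cx <- config$extent_x / 2 + margin
    cy <- config$extent_y / 2 + margin
    tibble::tibble(type = "disk",
                   x = c(-cx, cx, -cx, cx), y = c(cy, cy, -cy, -cy),
                   size = 0.5, size_x = NA_real_, size_y = NA_real_,
                   disparity = 0)
  } else {
    tibble::tibble(type = "frame", x = 0, y = 0, size = NA_real_,
                   size_x = 1.1 * config$extent_x,
                   size_y = 1.1 * config$extent_y, disparity = 0)
  }
  dplyr::bind_rows(dots, extras)
}

#' Heterogeneous luminance contrasts for the increment letter display
#'
#' Draws the per-letter luminance fluctuations of the increment (E4-style)
#' display: non-target letters get `x ~ U(-0.3, 0.3)` (open), the target
#' `x ~ U(-0.2, 0.2)` (open).  The whole-trial draw is accepted only when
#' the target's binocular contrast sum is strictly between the minimum and
#' maximum of all items' sums; otherwise all fluctuations are redrawn.  In
#' units of the luminance scale `L_1`, a non-target's contrast sum is
#' `1 + 2x` and the target's is `1 + x`, so both have expectation 1:
#' averaged over trials the target's contrast sum equals the non-targets'.
#'
#' @param items Items tibble with a `role` column.
#' @param max_resample Cap on whole-trial redraws (error if exceeded).
#' @return `items` with `lum_jitter` and `C_sum` (units of `L_1`) columns.
#' @export
assign_contrast_heterogeneity_e4 <- function(items, max_resample = 1e4) {
  is_target <- items$role %in% c("target", "both")
  stopifnot(sum(is_target) == 1)
  n <- nrow(items)
  for (attempt in seq_len(max_resample)) {
    x <- draw_luminance_jitter(n, 0.3)
    x[is_target] <- draw_luminance_jitter(1, 0.2)
    C_sum <- ifelse(is_target, 1 + x, 1 + 2 * x)
    ct <- C_sum[is_target]
    if (ct > min(C_sum) && ct < max(C_sum)) {
      items$lum_jitter <- x
      items$C_sum <- C_sum
      return(items)
    }
  }
  stop("contrast-heterogeneity resampling cap exceeded", call. = FALSE)
}

# Per-eye luminances for each item under the experiment's luminance model.
assign_luminance <- function(items, config) {
  model <- config$luminance_model
  if (model == "bright_bar") {
    L_sum <- 2 * config$L_balanced * items$C_sum
    dplyr::mutate(items, lum_L = .data$s_L * L_sum, lum_R = .data$s_R * L_sum)
  } else if (model == "decrement") {
    dplyr::mutate(items,
                  lum_L = decrement_luminance(.data$s_L, config$display),
                  lum_R = decrement_luminance(.data$s_R, config$display))
  } else {
    # increment letters: target formula L_o + L_1 * s * (1 + x); non-targets
    # L_o + L_1 * (0.5 + x) in both eyes.
    is_target <- items$role %in% c("target", "both")
    L_o <- config$display$L_o; L_1 <- config$display$L_1
    x <- items$lum_jitter
    items$lum_L <- ifelse(is_target, L_o + L_1 * items$s_L * (1 + x),
                          L_o + L_1 * (0.5 + x))
    items$lum_R <- ifelse(is_target, L_o + L_1 * items$s_R * (1 + x),
                          L_o + L_1 * (0.5 + x))
    items
  }
}

#' Generate one complete dichoptic search trial
#'
#' Builds the full scene description of a trial: jittered item positions,
#' identities, per-item ocularity and contrast sums, disparities with
#' per-eye positions, per-eye luminances, the transient profile of the
#' singleton, and the vergence anchors.  Generation is a pure function of
#' `(config, condition, O_mag, transient, seed)`.
#'
#' @param config An [experiment_config()].
#' @param condition `"baseline"`, `"DC"`, or `"DI"`.
#' @param O_mag Ocularity magnitude (ignored for schemes that fix it).
#' @param transient_mode `"static"`, `"abrupt"`, or `"smooth"` for the
#'   singleton's ocularity profile.
#' @param delta_t Decay-start time (s) for non-static profiles.
#' @param seed Integer seed making the trial reproducible.
#' @param singleton_policy Passed to [choose_singleton_position()].
#' @param target_pos,singleton_pos Optional one-row tibbles (`row`, `col`)
#'   fixing the placements (as when regenerating a scheduled trial);
#'   sampled when `NULL`.
#' @return An object of class `"ocu_trial"`: a list with `items` and
#'   `anchors` tibbles plus condition metadata.
#' @export
generate_trial <- function(config, condition = "baseline",
                           O_mag = NULL, transient_mode = "static",
                           delta_t = NA_real_, seed = NULL,
                           singleton_policy = "mirror",
                           target_pos = NULL, singleton_pos = NULL,
                           sign = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scheme <- if (config$experiment == "E4") "balanced_background"
            else if (config$experiment == "E1") config$e1_session$scheme
            else "shared"
  strength <- if (config$experiment == "E1") config$e1_session$strength else "double"
  if (is.null(O_mag)) {
    O_mag <- if (config$experiment == "E1") config$e1_session$O_mag else 3 / 5
  }
  items <- make_grid(config) |> jitter_positions(config)
  target <- if (is.null(target_pos)) choose_target_position(config) else target_pos
  items$role <- "background"
  items$role[items$row == target$row & items$col == target$col] <- "target"
  if (condition == "DI") {
    sing <- if (is.null(singleton_pos)) {
      choose_singleton_position(target, config, policy = singleton_policy)
    } else singleton_pos
    items$role[items$row == sing$row & items$col == sing$col] <- "singleton"
  }
  if (condition == "DC") {
    items$role[items$role == "target"] <- "both"
  }
  items <- items |>
    assign_identities(config) |>
    assign_ocularity(condition, O_mag, scheme = scheme, strength = strength,
                     sign = sign) |>
    assign_disparity(config)
  if (config$luminance_model == "increment_letters") {
    items <- assign_contrast_heterogeneity_e4(items)
  } else {
    items$lum_jitter <- 0
  }
  items <- assign_luminance(items, config)
  # Only the ocularity singleton carries a non-static profile: the transient
  # sessions remove (or decay) its unique ocularity during the trial.
  unique_item <- items$role %in% c("both", "singleton",
                                   if (config$experiment == "E4") "target")
  items$transient_mode <- ifelse(unique_item & condition != "baseline",
                                 transient_mode, "static")
  items$delta_t <- ifelse(items$transient_mode == "static", NA_real_, delta_t)
  items$item <- seq_len(nrow(items))
  anchors <- place_vergence_anchors(items, config)
  target_row <- items[items$role %in% c("target", "both"), ]
  structure(
    list(experiment = config$experiment, condition = condition,
         O_mag = O_mag, transient_mode = transient_mode, delta_t = delta_t,
         target_side = if (target_row$x >= 0) "right" else "left",
         seed = seed, items = items, anchors = anchors, config = config),
    class = "ocu_trial")
}

#' @export
print.ocu_trial <- function(x, ...) {
  cat("<ocu_trial>", x$experiment, x$condition,
      sprintf("|O| = %.3g", x$O_mag), "; target", x$target_side, ";",
      nrow(x$items), "items,", nrow(x$anchors), "anchors\n")
  invisible(x)
}

#' Ocularity contrast between the singleton and the background items
#'
#' The ocularity contrast of a DC/DI trial is the absolute difference
#' between the singleton's ocularity and the shared ocularity of the other
#' items (their median), evaluated at array onset.  For the shared-|O|
#' designs this equals `2 |O|`; for a balanced background it equals `|O|`.
#'
#' @param trial An `ocu_trial`.
#' @return A single number (0 for baseline trials).
#' @export
ocularity_contrast <- function(trial) {
  stopifnot(inherits(trial, "ocu_trial"))
  it <- trial$items
  sing <- it$role %in% c("both", "singleton",
                         if (trial$experiment == "E4") "target")
  if (trial$condition == "baseline" || !any(sing)) return(0)
  abs(it$O[sing][1] - stats::median(it$O[!sing]))
}

#' Build the randomised trial schedule of a session
#'
#' Replicates each cell of the session's condition grid
#' `trials_per_condition` times and shuffles the order uniformly with the
#' session seed.  Trial-level randomisations (target position, singleton
#' position, ocularity sign, per-trial seed) are drawn per trial, so the
#' schedule fully determines the session: `generate_trial()` on a schedule
#' row reproduces the exact scene.
#'
#' @param config An [experiment_config()].
#' @param seed Session seed (integer).
#' @param singleton_policy Passed to [choose_singleton_position()].
#' @return A tibble with one row per trial: `trial`, `condition`, `O_mag`,
#'   `transient_mode`, `delta_t`, target and singleton grid positions and
#'   perceived coordinates, `target_side`, `O_sign`, `n_items`, `seed`.
#' @export
schedule_session <- function(config, seed = 1, singleton_policy = "mirror") {
  set.seed(seed)
  grid_cells <- config$condition_grid
  n_per <- config$trials_per_condition
  sched <- grid_cells[rep(seq_len(nrow(grid_cells)), each = n_per), ]
  sched <- sched[sample.int(nrow(sched)), ]
  n <- nrow(sched)
  feas <- target_feasible_set(config)
  tpos <- feas[sample.int(nrow(feas), n, replace = TRUE), ]
  cols <- config$cols
  if (singleton_policy == "mirror") {
    sing_row <- tpos$row
    sing_col <- cols + 1 - tpos$col
    sing_x <- -tpos$x
    sing_y <- tpos$y
  } else {
    g <- make_grid(config)
    cc <- (cols + 1) / 2
    sing_row <- sing_col <- integer(n)
    sing_x <- sing_y <- numeric(n)
    for (i in seq_len(n)) {
      opp <- g[if (tpos$col[i] < cc) g$col > cc else g$col < cc, ]
      j <- sample.int(nrow(opp), 1)
      sing_row[i] <- opp$row[j]; sing_col[i] <- opp$col[j]
      sing_x[i] <- opp$x[j]; sing_y[i] <- opp$y[j]
    }
  }
  sched <- dplyr::mutate(
    tibble::as_tibble(sched),
    trial = seq_len(n),
    target_row = tpos$row, target_col = tpos$col,
    target_x = tpos$x, target_y = tpos$y,
    target_side = ifelse(tpos$x >= 0, "right", "left"),
    singleton_row = ifelse(.data$condition == "DI", sing_row, NA_integer_),
    singleton_col = ifelse(.data$condition == "DI", sing_col, NA_integer_),
    singleton_x = ifelse(.data$condition == "DI", sing_x, NA_real_),
    singleton_y = ifelse(.data$condition == "DI", sing_y, NA_real_),
    O_sign = sample(c(-1, 1), n, replace = TRUE),
    n_items = config$rows * config$cols,
    seed = sample.int(.Machine$integer.max - 1, n)
  )
  dplyr::relocate(sched, "trial")
}

#' Regenerate the full scene of one scheduled trial
#'
#' Rebuilds the exact `ocu_trial` described by one row of a
#' [schedule_session()] tibble, using the row's per-trial seed, placements,
#' and ocularity sign.
#'
#' @param config The [experiment_config()] the schedule was built from.
#' @param row A one-row tibble from the schedule.
#' @return An `ocu_trial`.
#' @export
generate_trial_from_schedule <- function(config, row) {
  stopifnot(nrow(row) == 1)
  sr <- as.list(row)
  generate_trial(
    config, condition = sr$condition, O_mag = sr$O_mag,
    transient_mode = sr$transient_mode, delta_t = sr$delta_t,
    seed = sr$seed,
    target_pos = tibble::tibble(row = sr$target_row, col = sr$target_col),
    singleton_pos = if (identical(sr$condition, "DI")) {
      tibble::tibble(row = sr$singleton_row, col = sr$singleton_col)
    } else NULL,
    sign = sr$O_sign)
}

#' Write a session manifest CSV
#'
#' One row per trial of a schedule, in the session's presentation order.
#'
#' @param schedule A tibble from [schedule_session()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_manifest <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}
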