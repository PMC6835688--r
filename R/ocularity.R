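#' Ocularity from per-eye input contrasts
#'
#' The ocularity of a search item summarises the relative strength of its
#' inputs to the two eyes.  Writing `C_L` and `C_R` for the dimensionless
#' input contrasts to the left and right eye (both in \[0, 1\]), the eye
#' weights are `s_L = C_L / (C_L + C_R)` and `s_R = 1 - s_L`, and the
#' ocularity value is `O = s_L - s_R`.  A monocular item has `O = 1` or
#' `O = -1`; an ocularly balanced item has `O = 0`; a left-eye-dominant item
#' has `O > 0`.
#'
#' @param contrasts A data frame with numeric columns `C_L` and `C_R`, each
#'   in \[0, 1\].  A pair with `C_L + C_R = 0` describes an invisible item
#'   and is rejected.
#' @return The input tibble with columns `s_L`, `s_R`, and `O` appended.
#' @examples
#' ocularity_from_contrasts(data.frame(C_L = c(0.5, 0.9), C_R = c(0.5, 0.1)))
#' @export
ocularity_from_contrasts <- function(contrasts) {
  stopifnot(is.data.frame(contrasts), all(c("C_L", "C_R") %in% names(contrasts)))
  C_L <- contrasts$C_L
  C_R <- contrasts$C_R
  if (any(C_L < 0 | C_L > 1 | C_R < 0 | C_R > 1)) {
    stop("per-eye contrasts must lie in [0, 1]", call. = FALSE)
  }
  if (any(C_L + C_R <= 0)) {
    stop("C_L + C_R must be positive: a zero-sum pair is an invisible item",
         call. = FALSE)
  }
  s_L <- C_L / (C_L + C_R)
  dplyr::mutate(tibble::as_tibble(contrasts),
                s_L = s_L, s_R = 1 - s_L, O = 2 * s_L - 1)
}

#' Per-eye contrasts from an ocularity value and a binocular contrast sum
#'
#' Inverts the ocularity definition: given `O` and the binocular summation
#' `C_sum = C_L + C_R`, returns `C_L = C_sum * (1 + O) / 2` and
#' `C_R = C_sum * (1 - O) / 2`.  Round-trips exactly through
#' [ocularity_from_contrasts()].
#'
#' @param spec A data frame with numeric columns `O` (in \[-1, 1\]) and
#'   `C_sum` (in (0, 2\]); each resulting per-eye contrast must stay in
#'   \[0, 1\].
#' @return The input tibble with columns `C_L` and `C_R` appended.
#' @examples
#' contrasts_from_ocularity(data.frame(O = 3 / 5, C_sum = 1))
#' @export
contrasts_from_ocularity <- function(spec) {
  stopifnot(is.data.frame(spec), all(c("O", "C_sum") %in% names(spec)))
  O <- spec$O
  C_sum <- spec$C_sum
  if (any(abs(O) > 1)) stop("|O| must not exceed 1", call. = FALSE)
  if (any(C_sum <= 0 | C_sum > 2)) {
    stop("C_sum must lie in (0, 2]", call. = FALSE)
  }
  C_L <- C_sum * (1 + O) / 2
  C_R <- C_sum * (1 - O) / 2
  if (any(C_L > 1 + 1e-12 | C_R > 1 + 1e-12)) {
    stop("resulting per-eye contrast exceeds 1; reduce C_sum or |O|",
         call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(spec),
                C_L = pmin(C_L, 1), C_R = pmin(C_R, 1))
}

#' Display configuration for a dichoptic experiment
#'
#' Captures the luminance conventions of the two display polarities used in
#' the search experiments: dark items on a light background (`decrement`,
#' background 110 cd/m2 by default) and light items on a dark or grey
#' background (`increment`, with background level `L_o` and luminance scale
#' `L_1`).  All luminances are screen-side values; `optic_attenuation`
#' records the fraction of screen luminance lost along the optical path
#' (goggles, mirrors) as metadata only and is never applied to outputs.
#'
#' @param polarity `"decrement"` or `"increment"`.
#' @param L_bg Background luminance of the decrement display (cd/m2).
#' @param L_o Background luminance of the increment display (cd/m2).
#' @param L_1 Luminance scale of the increment display (cd/m2).
#' @param C_sum_default Default binocular contrast sum assigned to items.
#' @param optic_attenuation Fraction of screen luminance lost before the eye,
#'   in \[0, 1); metadata only.
#' @return A list of class `"ocu_display"`.
#' @export
display_config <- function(polarity = c("decrement", "increment"),
                           L_bg = 110, L_o = 43, L_1 = 67,
                           C_sum_default = 1, optic_attenuation = 0) {
  polarity <- match.arg(polarity)
  stopifnot(L_bg >= 0, L_o >= 0, L_1 >= 0,
            optic_attenuation >= 0, optic_attenuation < 1)
  structure(
    list(polarity = polarity, L_bg = L_bg, L_o = L_o, L_1 = L_1,
         C_sum_default = C_sum_default, optic_attenuation = optic_attenuation),
    class = "ocu_display"
  )
}

#' @export
print.ocu_display <- function(x, ...) {
  cat("<ocu_display> polarity:", x$polarity, "\n")
  if (x$polarity == "decrement") {
    cat("  background", x$L_bg, "cd/m2; item luminance L_bg * (1 - s)\n")
  } else {
    cat("  background", x$L_o, "cd/m2; scale L_1 =", x$L_1, "cd/m2\n")
  }
  cat("  default C_sum", x$C_sum_default,
      "; optic attenuation", x$optic_attenuation, "(metadata)\n")
  invisible(x)
}

#' Item luminance on a decrement (dark-on-light) display
#'
#' On the decrement displays the bars and letters are dark on a white
#' background, and the monocular luminance of an item is `L_bg * (1 - s)`
#' for the eye with weight `s`: the dominant eye sees the darker (higher
#' contrast) image.
#'
#' @param s Eye weight(s) in \[0, 1\].
#' @param display An `ocu_display` with `polarity = "decrement"`.
#' @return Luminance(s) in cd/m2.
#' @examples
#' decrement_luminance(c(0.5, 0.8), display_config("decrement"))
#' @export
decrement_luminance <- function(s, display = display_config("decrement")) {
  if (display$polarity != "decrement") {
    stop("decrement_luminance() needs a decrement-polarity display", call. = FALSE)
  }
  stopifnot(all(s >= 0 & s <= 1))
  display$L_bg * (1 - s)
}

#' Stroke luminance of a non-target item on the increment letter display
#'
#' On the increment letter display, a zero-ocularity non-target letter has
#' monocular stroke luminance `L_o + L_1 * (0.5 + x)` in both eyes, where
#' `x` is that letter's random luminance fluctuation, drawn strictly inside
#' (-0.3, 0.3).
#'
#' @param x Luminance fluctuation(s), each strictly inside (-0.3, 0.3).
#' @param display An `ocu_display` with `polarity = "increment"`.
#' @return Luminance(s) in cd/m2 (identical for the two eyes).
#' @export
increment_luminance_nontarget <- function(x, display = display_config("increment")) {
  if (display$polarity != "increment") {
    stop("increment_luminance_nontarget() needs an increment-polarity display",
         call. = FALSE)
  }
  if (any(abs(x) >= 0.3)) {
    stop("non-target luminance fluctuation must lie strictly inside (-0.3, 0.3)",
         call. = FALSE)
  }
  display$L_o + display$L_1 * (0.5 + x)
}

#' Stroke luminance of the target on the increment letter display
#'
#' The target letter's monocular stroke luminance is
#' `L_o + L_1 * s * (1 + x)` for the eye with weight `s`; the target's
#' fluctuation `x` is shared by the two eyes and drawn strictly inside
#' (-0.2, 0.2).  The two eyes' increments sum to `L_1 * (1 + x)` regardless
#' of the ocularity, so the binocular contrast sum is ocularity-invariant.
#'
#' @param s Eye weight(s) in \[0, 1\].
#' @param x Luminance fluctuation(s), each strictly inside (-0.2, 0.2).
#' @param display An `ocu_display` with `polarity = "increment"`.
#' @return Luminance(s) in cd/m2.
#' @export
increment_luminance_target <- function(s, x, display = display_config("increment")) {
  if (display$polarity != "increment") {
    stop("increment_luminance_target() needs an increment-polarity display",
         call. = FALSE)
  }
  stopifnot(all(s >= 0 & s <= 1))
  if (any(abs(x) >= 0.2)) {
    stop("target luminance fluctuation must lie strictly inside (-0.2, 0.2)",
         call. = FALSE)
  }
  display$L_o + display$L_1 * s * (1 + x)
}

#' Per-eye screen luminance of a bright bar on a dark background
#'
#' For the bright-bar display (black background), the luminance delivered to
#' each eye is proportional to that eye's input contrast, so an item with
#' binocular luminance sum `L_sum` delivers `s * L_sum` to the eye with
#' weight `s`.  An ocularly balanced bar of 24 cd/m2 per eye therefore fixes
#' `L_sum = 48` cd/m2, and a 9:1 eye-dominance bar delivers 43.2 and
#' 4.8 cd/m2 to its dominant and non-dominant eye.
#'
#' @param s Eye weight(s) in \[0, 1\].
#' @param L_balanced Per-eye luminance of the ocularly balanced reference
#'   bar (cd/m2); the constant binocular sum is `2 * L_balanced`.
#' @return Luminance(s) in cd/m2.
#' @examples
#' bright_bar_luminance(c(0.9, 0.1), L_balanced = 24)
#' @export
bright_bar_luminance <- function(s, L_balanced = 24) {
  stopifnot(all(s >= 0 & s <= 1), L_balanced >= 0)
  2 * L_balanced * s
}

#' Temporal profile of an item's ocularity
#'
#' Three profiles are supported: `static` (the ocularity never changes),
#' `abrupt` (the ocularity drops to zero at `delta_t` seconds after array
#' onset, as when a monocular singleton becomes binocular after the initial
#' 0.15 s), and `smooth` (the ocularity decays continuously to zero over the
#' window from `delta_t` to `delta_t + decay_window`, designed so observers
#' do not perceive the change).
#'
#' @param mode `"static"`, `"abrupt"`, or `"smooth"`.
#' @param delta_t Onset-to-decay-start time in seconds (required positive
#'   for the abrupt and smooth modes).
#' @param decay_window Duration of the smooth decay (s); fixed at 0.1 s.
#' @return A list of class `"ocu_transient"`.
#' @export
transient_profile <- function(mode = c("static", "abrupt", "smooth"),
                              delta_t = NA_real_, decay_window = 0.1) {
  mode <- match.arg(mode)
  if (mode != "static") {
    if (!is.finite(delta_t) || delta_t <= 0) {
      stop("delta_t must be a positive time for abrupt/smooth profiles",
           call. = FALSE)
    }
  }
  if (mode == "smooth" && decay_window != 0.1) {
    stop("the smooth decay window is fixed at 0.1 s", call. = FALSE)
  }
  structure(list(mode = mode, delta_t = delta_t, decay_window = decay_window),
            class = "ocu_transient")
}

#' Ocularity of an item as a function of time since array onset
#'
#' Evaluates an item's time-varying ocularity under a [transient_profile()].
#' The binocular contrast sum is unchanged at all times: only the split
#' between the eyes evolves.  The smooth ramp is a raised cosine,
#' `O(t) = O0 * (1 + cos(pi * (t - delta_t) / 0.1)) / 2`, which is C1 at
#' both ends of the decay window (a `"linear"` ramp is available for
#' comparison); both ramps pass through `O0 / 2` at the window midpoint.
#'
#' @param t Time(s) since stimulus onset, in seconds (non-negative).
#' @param O0 Initial ocularity value(s).
#' @param profile A [transient_profile()].
#' @param ramp Shape of the smooth decay: `"cosine"` (default) or
#'   `"linear"`.
#' @return Ocularity value(s) at `t`.
#' @examples
#' pr <- transient_profile("smooth", delta_t = 0.1)
#' ocularity_at_time(c(0.05, 0.15, 0.25), O0 = 1, profile = pr)
#' @export
ocularity_at_time <- function(t, O0, profile, ramp = c("cosine", "linear")) {
  ramp <- match.arg(ramp)
  stopifnot(inherits(profile, "ocu_transient"))
  if (any(t < 0)) stop("time since onset must be non-negative", call. = FALSE)
  switch(
    profile$mode,
    static = O0 + 0 * t,
    abrupt = ifelse(t < profile$delta_t, O0, 0),
    smooth = {
      u <- (t - profile$delta_t) / profile$decay_window
      frac <- ifelse(u <= 0, 1,
              ifelse(u >= 1, 0,
                     if (ramp == "cosine") (1 + cos(pi * u)) / 2 else 1 - u))
      O0 * frac
    }
  )
}

#' Draw luminance-fluctuation values from an open interval
#'
#' Draws uniform values strictly inside `(-bound, bound)` by rejection
#' sampling, so boundary values never occur (the fluctuation ranges are
#' stated as open intervals).
#'
#' @param n Number of draws.
#' @param bound Half-width of the open interval (0.3 for non-targets, 0.2
#'   for the target).
#' @return Numeric vector of length `n`.
#' @export
draw_luminance_jitter <- function(n, bound) {
  stopifnot(n >= 0, bound > 0)
  x <- stats::runif(n, -bound, bound)
  while (any(bad <- (abs(x) >= bound))) {
    x[bad] <- stats::runif(sum(bad), -bound, bound)
  }
  x
}
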