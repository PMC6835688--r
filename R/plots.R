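#' Bar chart of condition mean RTs with SEM error bars
#'
#' Plots each dichoptic condition's mean button-press RT (or normalised
#' RT when present and `normalized = TRUE`), averaged across observers,
#' with standard-error-of-the-mean error bars, facetted by the `|O|` /
#' transient family.
#'
#' @param object An `ocu_summary` tibble (from [summarize_conditions()],
#'   optionally through [normalize_by_baseline()]).
#' @param normalized Plot `normalized_rt` instead of raw RT when present.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocu_summary <- function(object, normalized = FALSE, ...) {
  value_col <- if (normalized && "normalized_rt" %in% names(object)) {
    "normalized_rt"
  } else "mean_rt_button"
  fam <- intersect(c("O_mag", "transient_mode", "delta_t"), names(object))
  across_obs <- object |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("condition", fam)))) |>
    dplyr::summarise(
      m = mean(.data[[value_col]], na.rm = TRUE),
      sem = stats::sd(.data[[value_col]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[value_col]]))),
      .groups = "drop") |>
    dplyr::mutate(family = interaction(
      dplyr::across(dplyr::all_of(fam)), drop = TRUE, sep = " / "))
  ggplot2::ggplot(across_obs,
                  ggplot2::aes(x = .data$condition, y = .data$m,
                               fill = .data$condition)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$sem,
                                        ymax = .data$m + .data$sem),
                           width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$family)) +
    ggplot2::labs(x = NULL,
                  y = if (value_col == "normalized_rt") "normalized RT"
                      else "RT (s)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one eye's rendered image of a trial
#'
#' @param trial An `ocu_trial`.
#' @param t Time since onset (s).
#' @param eye `"left"` or `"right"`.
#' @param ppd Pixels per degree.
#' @return A ggplot object showing the grayscale raster.
#' @export
plot_stimulus <- function(trial, t = 0, eye = "left", ppd = 4) {
  img <- render_dichoptic(trial, t = t, eye = eye, ppd = ppd)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
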