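# Rasterisation of dichoptic scenes: one grayscale luminance image per eye.

# Per-eye item luminances at time t since onset, honouring each item's
# transient ocularity profile (the contrast sum never changes).
item_luminance_at_time <- function(trial, t) {
  it <- trial$items
  config <- trial$config
  O_t <- it$O
  moving <- it$transient_mode != "static"
  if (any(moving)) {
    for (i in which(moving)) {
      pr <- transient_profile(it$transient_mode[i], delta_t = it$delta_t[i])
      O_t[i] <- ocularity_at_time(t, it$O[i], pr)
    }
  }
  s_L <- (1 + O_t) / 2
  s_R <- 1 - s_L
  model <- config$luminance_model
  if (model == "bright_bar") {
    L_sum <- 2 * config$L_balanced * it$C_sum
    list(L = s_L * L_sum, R = s_R * L_sum)
  } else if (model == "decrement") {
    list(L = decrement_luminance(s_L, config$display),
         R = decrement_luminance(s_R, config$display))
  } else {
    is_target <- it$role %in% c("target", "both")
    L_o <- config$display$L_o; L_1 <- config$display$L_1
    x <- it$lum_jitter
    list(L = ifelse(is_target, L_o + L_1 * s_L * (1 + x), L_o + L_1 * (0.5 + x)),
         R = ifelse(is_target, L_o + L_1 * s_R * (1 + x), L_o + L_1 * (0.5 + x)))
  }
}

paint_rect <- function(img, px, py, cx, cy, len, wid, tilt_deg) {
  # rotated-rectangle mask over the pixel lattice; tilt from horizontal
  th <- tilt_deg * pi / 180
  dx <- outer(rep(1, length(py)), px - cx)
  dy <- outer(py - cy, rep(1, length(px)))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

item_mask <- function(px, py, x, y, kind, identity, tilt, size, stroke) {
  if (kind == "bar") {
    paint_rect(NULL, px, py, x, y, size[1], size[2], tilt)
  } else if (identity == "T") {
    top <- paint_rect(NULL, px, py, x, y + size[1] / 2 - stroke / 2,
                      size[2], stroke, 0)
    stem <- paint_rect(NULL, px, py, x, y, stroke, size[1], 0)
    top | stem
  } else {
    left <- paint_rect(NULL, px, py, x - size[2] / 2 + stroke / 2, y,
                       stroke, size[1], 0)
    bottom <- paint_rect(NULL, px, py, x, y - size[1] / 2 + stroke / 2,
                         size[2], stroke, 0)
    left | bottom
  }
}

#' Render one eye's image of a dichoptic trial
#'
#' Draws the vergence anchors and every item at its per-eye position with
#' its per-eye luminance at time `t` (items with transient ocularity
#' profiles are evaluated through their profile; the binocular contrast sum
#' never changes).  The luminance-to-grayscale mapping is linear, with
#' `max_luminance` mapping to 1 (255 when written as 8-bit PNG).
#' Rendering is deterministic given the trial and raster settings.
#'
#' @param trial An `ocu_trial` from [generate_trial()].
#' @param t Time since array onset (s).
#' @param eye `"left"` or `"right"`.
#' @param ppd Pixels per degree.
#' @param max_luminance Luminance mapped to white; defaults to the maximum
#'   of the background and all item/anchor luminances in the scene.
#' @param margin Canvas margin (deg) beyond the anchor frame / disks.
#' @return A numeric matrix in \[0, 1\] (rows = top-to-bottom pixels).
#' @export
render_dichoptic <- function(trial, t = 0, eye = c("left", "right"),
                             ppd = 4, max_luminance = NULL, margin = 0.5) {
  eye <- match.arg(eye)
  config <- trial$config
  it <- trial$items
  lum <- item_luminance_at_time(trial, t)
  lum_e <- if (eye == "left") lum$L else lum$R
  x_e <- if (eye == "left") it$x_L else it$x_R
  bg <- switch(config$luminance_model,
               bright_bar = 0,
               decrement = config$display$L_bg,
               increment_letters = config$display$L_o)
  anchor_lum <- switch(config$luminance_model,
                       bright_bar = 2 * config$L_balanced,
                       decrement = 0,
                       increment_letters = config$display$L_o +
                         1.5 * config$display$L_1)
  half_w <- 1.1 * config$extent_x / 2 + margin + 1
  half_h <- 1.1 * config$extent_y / 2 + margin + 1
  px <- seq(-half_w, half_w, by = 1 / ppd)
  py <- seq(half_h, -half_h, by = -1 / ppd)
  img <- matrix(bg, nrow = length(py), ncol = length(px))
  an <- trial$anchors
  for (i in seq_len(nrow(an))) {
    if (an$type[i] == "frame") {
      w <- an$size_x[i]; h <- an$size_y[i]; thick <- 0.1
      m <- (abs(outer(rep(1, length(py)), px) ) <= w / 2 + thick &
            abs(outer(py, rep(1, length(px)))) <= h / 2 + thick) &
           !(abs(outer(rep(1, length(py)), px)) < w / 2 &
             abs(outer(py, rep(1, length(px)))) < h / 2)
      img[m] <- anchor_lum
    } else if (an$type[i] == "disk") {
      r <- an$size[i] / 2
      m <- outer((py - an$y[i])^2, (px - an$x[i])^2, `+`) <= r^2
      img[m] <- anchor_lum
    } else {
      m <- paint_rect(NULL, px, py, an$x[i], an$y[i],
                      an$size[i], an$size[i], 0)
      img[m] <- anchor_lum
    }
  }
  clipped <- 0L
  size <- config$item_size
  stroke <- config$stroke %||% 0.1
  for (i in seq_len(nrow(it))) {
    if (lum_e[i] == bg && config$luminance_model == "bright_bar") next
    if (abs(x_e[i]) > half_w || abs(it$y[i]) > half_h) clipped <- clipped + 1L
    m <- item_mask(px, py, x_e[i], it$y[i], config$item_kind,
                   it$identity[i], it$tilt[i], size, stroke)
    img[m] <- lum_e[i]
  }
  if (clipped > 0) {
    warning(sprintf("%d item(s) extend outside the canvas and were clipped",
                    clipped), call. = FALSE)
  }
  if (is.null(max_luminance)) {
    max_luminance <- max(bg, anchor_lum, lum$L, lum$R)
  }
  pmin(pmax(img / max_luminance, 0), 1)
}

#' Write the stereo pair of a trial as PNG files
#'
#' Writes `<prefix>_L.png` and `<prefix>_R.png` (8-bit grayscale, linear
#' mapping with `max_luminance` at 255), and optionally a side-by-side
#' stereogram `<prefix>_LR.png`.
#'
#' @inheritParams render_dichoptic
#' @param prefix Path prefix for the output files.
#' @param side_by_side Also write the concatenated stereogram.
#' @return Character vector of the files written, invisibly.
#' @export
write_stereo_png <- function(trial, prefix, t = 0, ppd = 4,
                             max_luminance = NULL, side_by_side = FALSE) {
  iml <- render_dichoptic(trial, t, "left", ppd, max_luminance)
  imr <- render_dichoptic(trial, t, "right", ppd, max_luminance)
  fl <- paste0(prefix, "_L.png"); fr <- paste0(prefix, "_R.png")
  png::writePNG(iml, fl)
  png::writePNG(imr, fr)
  files <- c(fl, fr)
  if (side_by_side) {
    fb <- paste0(prefix, "_LR.png")
    png::writePNG(cbind(iml, imr), fb)
    files <- c(files, fb)
  }
  invisible(files)
}
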