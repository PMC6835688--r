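# Shared fixtures: all built in code at test time.

# small abstract grid for geometry tests (other fields unused by make_grid)
small_grid_config <- function(rows = 3, cols = 3, extent = 2) {
  cfg <- experiment_config("E2")
  cfg$rows <- rows
  cfg$cols <- cols
  cfg$extent_x <- if (cols > 1) extent else 0
  cfg$extent_y <- if (rows > 1) extent else 0
  cfg
}

# random correct/incorrect RT pool for exclusion-rule tests
random_pool <- function(id, n = NULL) {
  n <- n %||% sample(2:10, 1)
  tibble::tibble(
    observer_id = paste0("p", id),
    condition = "DC",
    rt_button_s = round(stats::runif(n, 0.05, 1.2), 3),
    correct = stats::runif(n) < 0.85
  )
}

# independent brute-force implementation of the exclusion rule
brute_force_exclude <- function(pool, rt_min = 0.2, sd_mult = 3) {
  rts <- pool$rt_button_s
  ok <- pool$correct
  m <- mean(rts[ok])
  s <- stats::sd(rts[ok])
  if (is.na(s)) s <- 0
  reason <- rep(NA_character_, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (!ok[i]) {
      reason[i] <- "incorrect"
    } else if (rts[i] < rt_min) {
      reason[i] <- "rt_too_short"
    } else if (rts[i] > m + sd_mult * s) {
      reason[i] <- "rt_outlier_3sd"
    }
  }
  reason
}

# closed-form paired t-test (textbook formulas, no stats::t.test)
closed_form_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = tstat,
       p.value = 2 * stats::pt(-abs(tstat), df = n - 1))
}
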