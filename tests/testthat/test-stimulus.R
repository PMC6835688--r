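test_that("grids are centred lattices spanning the stated extent", {
  g <- make_grid(small_grid_config(3, 3, 2))
  expect_equal(nrow(g), 9)
  expect_setequal(g$x, c(-1, 0, 1))
  expect_setequal(g$y, c(-1, 0, 1))
  # top-left cell is (row 1, col 1) at (-extent/2, +extent/2)
  expect_equal(g[g$row == 1 & g$col == 1, c("x", "y")],
               tibble::tibble(x = -1, y = 1))

  g2 <- make_grid(experiment_config("E2"))
  expect_equal(g2[g2$row == 1 & g2$col == 1, ]$x, -9.2)
  expect_equal(g2[g2$row == 1 & g2$col == 1, ]$y, 9.2)

  row_cfg <- small_grid_config(1, 5, 4)
  g3 <- make_grid(row_cfg)
  expect_true(all(g3$y == 0))
  bad <- small_grid_config(1, 5, 4)
  bad$extent_y <- 1
  expect_error(make_grid(bad), "single-row")
})

test_that("positional jitter is bounded by the experiment's limit", {
  cfg <- experiment_config("E2")
  g <- make_grid(cfg)
  set.seed(11)
  deltas <- replicate(20, {
    j <- jitter_positions(g, cfg)
    max(abs(c(j$x - g$x, j$y - g$y)))
  })
  expect_true(all(deltas <= 0.05))
  expect_gt(max(deltas), 0.045)

  cfg0 <- cfg
  cfg0$jitter_bound <- 0
  expect_equal(jitter_positions(g, cfg0), g)
})

test_that("target placement honours each experiment's constraints", {
  feas2 <- target_feasible_set(experiment_config("E2"))
  expect_true(all(feas2$row >= 4 & feas2$row <= 20))
  expect_true(all(abs(feas2$col - 12) >= 6))
  r2 <- sqrt((feas2$row - 12)^2 + (feas2$col - 12)^2)
  expect_equal(r2, rep(10, nrow(feas2)))  # exact 10-unit circle cells exist

  feas3 <- target_feasible_set(experiment_config("E3"))
  r3 <- sqrt((feas3$row - 9)^2 + (feas3$col - 9)^2)
  expect_equal(r3, rep(7, nrow(feas3)))
  expect_true(all(abs(feas3$col - 9) >= 5))
  # a tolerance band widens the eligible set
  feas3w <- target_feasible_set(experiment_config("E3", radius_tol = 0.5))
  expect_gt(nrow(feas3w), nrow(feas3))

  feas4 <- target_feasible_set(experiment_config("E4"))
  d4 <- sqrt((feas4$row - 7.5)^2 + (feas4$col - 7.5)^2)
  expect_true(all(d4 >= 3 & d4 <= 6))
  expect_true(all(abs(feas4$col - 7.5) >= 2 & abs(feas4$col - 7.5) <= 5))
  expect_true(all(feas4$row >= 4 & feas4$row <= 11))

  feas1 <- target_feasible_set(experiment_config("E1"))
  ecc <- sqrt(feas1$x^2 + feas1$y^2)
  expect_true(all(abs(feas1$x) >= 12))
  expect_true(all(ecc >= 13.5 & ecc <= 16.5))

  infeasible <- experiment_config("E2")
  infeasible$target_placement$row_band <- c(11, 13)
  infeasible$target_placement$min_horizontal <- 20
  expect_error(target_feasible_set(infeasible), "no grid cell")
})

test_that("DI singletons land in the opposite lateral half", {
  cfg <- experiment_config("E2")
  set.seed(5)
  for (i in 1:25) {
    tgt <- choose_target_position(cfg)
    mir <- choose_singleton_position(tgt, cfg)
    expect_equal(mir$row, tgt$row)
    expect_equal(mir$col, cfg$cols + 1 - tgt$col)
  }
  # mirrored eccentricity is preserved exactly on the unjittered grid
  g <- make_grid(cfg)
  tgt <- choose_target_position(cfg)
  mir <- choose_singleton_position(tgt, cfg)
  xt <- g$x[g$row == tgt$row & g$col == tgt$col]
  xs <- g$x[g$row == mir$row & g$col == mir$col]
  expect_equal(abs(xs), abs(xt))
  expect_true(xs * xt < 0)

  # sampling policy: always the opposite perceived half
  for (i in 1:200) {
    tgt <- choose_target_position(cfg)
    smp <- choose_singleton_position(tgt, cfg, policy = "sample")
    xs <- g$x[g$row == smp$row & g$col == smp$col]
    xt <- g$x[g$row == tgt$row & g$col == tgt$col]
    expect_true(xs * xt < 0)
  }
})

test_that("identities make the target the unique odd item", {
  set.seed(2)
  tr1 <- generate_trial(experiment_config("E1"), "baseline", seed = 1)
  tilts <- tr1$items$tilt
  tgt <- tr1$items$role == "target"
  expect_true(all(abs(tilts) == 10))
  expect_equal(length(unique(tilts[!tgt])), 1)
  expect_equal(tilts[tgt], -tilts[!tgt][1])

  tr2 <- generate_trial(experiment_config("E2"), "baseline", seed = 2)
  expect_true(all(abs(tr2$items$tilt) == 45))

  tr3 <- generate_trial(experiment_config("E3"), "baseline", seed = 3)
  expect_equal(sum(tr3$items$identity == "T"), 1)
  expect_equal(sum(tr3$items$identity == "L"), 288)
})

test_that("ocularity assignment encodes the dichoptic conditions", {
  # 9:1 eye-dominance session: every bar has s_L = 9 s_R or s_R = 9 s_L
  cfg_dom <- experiment_config("E1", e1_session = list(scheme = "shared",
                                                       O_mag = 0.8))
  tr <- generate_trial(cfg_dom, "DI", seed = 4)
  it <- tr$items
  expect_true(all(abs(it$s_L - 9 * it$s_R) < 1e-12 |
                  abs(it$s_R - 9 * it$s_L) < 1e-12))
  sing <- it$role == "singleton"
  expect_equal(sum(sign(it$O) != sign(it$O[!sing][1])), 1)
  expect_true(sing[sign(it$O) != sign(it$O[!sing][1])])

  # E4 baseline: all items balanced
  tr4 <- generate_trial(experiment_config("E4"), "baseline", O_mag = 0,
                        seed = 5)
  expect_true(all(tr4$items$O == 0))

  # DC at |O| = 1/5: target eye weight 0.6 or 0.4
  tr5 <- generate_trial(experiment_config("E2"), "DC", O_mag = 1 / 5,
                        seed = 6)
  s_t <- tr5$items$s_L[tr5$items$role == "both"]
  expect_true(abs(s_t - 0.6) < 1e-12 || abs(s_t - 0.4) < 1e-12)

  expect_error(generate_trial(experiment_config("E2"), "DC", O_mag = 1.5),
               "O_mag")
})

test_that("single-strength sessions halve the monocular item's C_sum", {
  cfg <- experiment_config("E1", e1_session = list(
    scheme = "balanced_background", O_mag = 1, strength = "single"))
  tr <- generate_trial(cfg, "DC", seed = 8)
  it <- tr$items
  mono <- abs(it$O) == 1
  expect_equal(sum(mono), 1)
  expect_equal(unique(it$C_sum[!mono]), 1)
  expect_equal(it$C_sum[mono], 0.5)
  # matched max(C_L, C_R): one-eye luminance equals the binocular per-eye one
  expect_equal(max(it$lum_L[mono], it$lum_R[mono]),
               max(it$lum_L[!mono]))

  cfg_d <- experiment_config("E1", e1_session = list(
    scheme = "balanced_background", O_mag = 1, strength = "double"))
  tr_d <- generate_trial(cfg_d, "DC", seed = 8)
  expect_equal(unique(tr_d$items$C_sum), 1)
})

test_that("disparities are bounded, zero at border columns, and symmetric", {
  tr <- generate_trial(experiment_config("E2"), "baseline", seed = 9)
  it <- tr$items
  expect_true(all(abs(it$disparity) <= 0.21))
  expect_true(all(it$disparity[it$col %in% c(1, 23)] == 0))
  expect_true(any(it$disparity != 0))
  expect_equal((it$x_L + it$x_R) / 2, it$x, tolerance = 1e-9)
  expect_equal(it$x_R - it$x_L, it$disparity, tolerance = 1e-12)
})

test_that("vergence anchors tile the array and are binocular", {
  cfg <- small_grid_config(3, 3, 2)
  g <- make_grid(cfg)
  g$role <- "background"
  an <- place_vergence_anchors(g, cfg)
  expect_equal(sum(an$type == "dot"), 4)
  expect_true(all(an$disparity == 0))

  tr <- generate_trial(experiment_config("E2"), "baseline", seed = 10)
  an2 <- tr$anchors
  expect_equal(sum(an2$type == "dot"), 22 * 22)
  fr <- an2[an2$type == "frame", ]
  expect_equal(fr$size_x, 1.1 * 18.4)

  tr1 <- generate_trial(experiment_config("E1"), "baseline", seed = 10)
  expect_equal(sum(tr1$anchors$type == "dot"), 21 * 29)
  expect_equal(sum(tr1$anchors$type == "disk"), 4)
})

test_that("heterogeneous-contrast draws keep the target strictly interior", {
  cfg <- experiment_config("E4")
  set.seed(12)
  diffs <- replicate(400, {
    tr <- generate_trial(cfg, "DC", O_mag = 3 / 5)
    it <- tr$items
    ct <- it$C_sum[it$role == "both"]
    expect_gt(ct, min(it$C_sum))
    expect_lt(ct, max(it$C_sum))
    ct - mean(it$C_sum[it$role != "both"])
  })
  # both formulas have expectation 1 (in units of the luminance scale)
  expect_lt(abs(mean(diffs)), 0.02)
  tr <- generate_trial(cfg, "DC", O_mag = 3 / 5, seed = 1)
  expect_equal(sum(tr$items$role == "background"), 195)
})

test_that("session schedules have the printed sizes and are reproducible", {
  s2 <- schedule_session(experiment_config("E2"), seed = 21)
  expect_equal(nrow(s2), 450)
  expect_true(all(table(s2$condition, s2$O_mag) == 50))

  s3 <- schedule_session(experiment_config("E3"), seed = 21)
  expect_equal(nrow(s3), 400)
  expect_equal(nrow(dplyr::distinct(s3[, c("condition", "O_mag")])), 8)

  s4 <- schedule_session(experiment_config("E4"), seed = 21)
  expect_equal(nrow(s4), 10 * 45)

  expect_identical(s2, schedule_session(experiment_config("E2"), seed = 21))
  expect_false(identical(
    s2$seed, schedule_session(experiment_config("E2"), seed = 22)$seed))

  # a scheduled trial regenerates bit-identically
  tr_a <- generate_trial_from_schedule(experiment_config("E2"), s2[7, ])
  tr_b <- generate_trial_from_schedule(experiment_config("E2"), s2[7, ])
  expect_identical(tr_a$items, tr_b$items)
})

test_that("condition structure invariants hold across generated trials", {
  set.seed(33)
  for (ex in c("E1", "E2", "E3")) {
    cfg <- experiment_config(ex)
    grid <- cfg$condition_grid
    for (i in seq_len(min(nrow(grid), 6))) {
      tr <- generate_trial(cfg, grid$condition[i], grid$O_mag[i])
      it <- tr$items
      expect_equal(length(unique(it$C_sum)), 1)  # constant within trial
      if (grid$condition[i] != "baseline" && cfg$experiment != "E4") {
        uniq <- sign(it$O) != sign(it$O[it$role == "background"][1])
        expect_equal(sum(uniq), 1)
        expect_true(it$role[uniq] %in%
                      if (grid$condition[i] == "DC") "both" else "singleton")
      } else if (grid$condition[i] == "baseline") {
        expect_equal(length(unique(it$O)), 1)
      }
    }
  }
})
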