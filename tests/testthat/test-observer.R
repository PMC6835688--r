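test_that("priorities rank the orientation and ocularity singletons", {
  cfg <- experiment_config("E2")
  p_ori <- observer_params(w_ori = 1, w_oc = 0, lapse = 0)

  tr_base <- generate_trial(cfg, "baseline", O_mag = 3 / 5, seed = 1)
  pri <- item_priority(tr_base, p_ori)
  tgt <- tr_base$items$role == "target"
  expect_true(all(pri[tgt] > pri[!tgt]))

  # adding an ocularity term raises the DC target above its baseline level
  p_oc <- observer_params(w_ori = 1, w_oc = 2, oc_threshold = 0.5)
  tr_dc <- generate_trial(cfg, "DC", O_mag = 3 / 5, seed = 1)
  pri_dc <- item_priority(tr_dc, p_oc)
  expect_gt(pri_dc[tr_dc$items$role == "both"], max(pri[tgt]))
  expect_equal(pri_dc[tr_dc$items$role == "both"], 1 + 2 * (1.2 - 0.5))

  # a persistent unbalanced singleton among balanced items is averted
  cfg_av <- experiment_config("E1", e1_session = list(
    scheme = "balanced_background", O_mag = 1))
  pav <- observer_preset("aversion_static")
  tr_di <- generate_trial(cfg_av, "DI", seed = 2)
  pri_av <- item_priority(tr_di, pav)
  sing <- tr_di$items$role == "singleton"
  expect_equal(pri_av[sing], 0)  # attraction exactly cancelled
  expect_lt(pri_av[sing], pri_av[tr_di$items$role == "target"])
})

test_that("class-based priorities agree with the per-item route", {
  p <- observer_preset("paper_like_E2")
  cfg <- experiment_config("E2")
  for (cond in c("baseline", "DC", "DI")) {
    tr <- generate_trial(cfg, cond, O_mag = 3 / 5, seed = 7)
    pri <- item_priority(tr, p)
    cp <- ocusearch:::class_priorities(cond, 3 / 5, "static", NA_real_,
                                       "shared", p)
    expect_equal(pri[tr$items$role %in% c("target", "both")],
                 cp$p_target)
    if (cond == "DI") {
      expect_equal(pri[tr$items$role == "singleton"], cp$p_singleton)
    }
    expect_true(all(pri[tr$items$role == "background"] == 0))
  }
  # transient aversion schemes agree too
  cfg_av <- experiment_config("E1", e1_session = list(
    scheme = "balanced_background", O_mag = 1, transient = "abrupt",
    delta_t = 0.15))
  pav <- observer_preset("aversion_transient")
  tr <- generate_trial(cfg_av, "DC", transient_mode = "abrupt",
                       delta_t = 0.15, seed = 3)
  cp <- ocusearch:::class_priorities("DC", 1, "abrupt", 0.15,
                                     "balanced_background", pav)
  expect_equal(item_priority(tr, pav)[tr$items$role == "both"], cp$p_target)
})

test_that("simulated trials and cohorts are deterministic and well-formed", {
  cfg <- experiment_config("E2")
  p <- observer_preset("paper_like_E2")
  tr <- generate_trial(cfg, "DI", O_mag = 3 / 5, seed = 5)
  set.seed(99); bt1 <- simulate_trial(tr, p)
  set.seed(99); bt2 <- simulate_trial(tr, p)
  expect_identical(bt1, bt2)

  g <- bt1$gaze[[1]]
  expect_equal(unlist(g[1, ]), c(t_s = 0, x_deg = 0, y_deg = 0))
  expect_true(all(diff(g$t_s) > 0))
  expect_gt(bt1$rt_button_s, 0)

  log1 <- simulate_cohort(cfg, 2, p, master_seed = 17)
  log2 <- simulate_cohort(cfg, 2, p, master_seed = 17)
  expect_identical(log1, log2)
  expect_equal(nrow(log1), 2 * 450)
  expect_equal(sort(unique(log1$observer_id)), c("obs1", "obs2"))
})

test_that("an ocularity-blind observer yields exchangeable conditions", {
  cfg <- experiment_config("E2")
  p0 <- observer_preset("null")
  log <- simulate_cohort(cfg, 4, p0, master_seed = 23)
  hi <- log[abs(log$O_mag - 0.6) < 1e-9, ]
  ks <- suppressWarnings(stats::ks.test(
    hi$rt_button_s[hi$condition == "DI"],
    hi$rt_button_s[hi$condition == "DC"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a forced incongruent capture costs a corrective saccade", {
  cfg <- experiment_config("E2")
  # near-zero temperature and huge ocularity weight: the DI singleton always
  # captures the first saccade, so gaze RT exceeds the DC trial's
  p_hard <- observer_params(w_ori = 2, w_oc = 50, oc_threshold = 0,
                            capture_temperature = 0.01, lapse = 0,
                            rt_noise_sd = 0, heavy_tail_prob = 0)
  tr_di <- generate_trial(cfg, "DI", O_mag = 3 / 5, seed = 31)
  tr_dc <- generate_trial(cfg, "DC", O_mag = 3 / 5, seed = 31)
  set.seed(1); bt_di <- simulate_trial(tr_di, p_hard)
  set.seed(1); bt_dc <- simulate_trial(tr_dc, p_hard)
  sing_x <- tr_di$items$x[tr_di$items$role == "singleton"]
  expect_equal(bt_di$first_saccade_x_deg, sing_x)
  expect_gt(bt_di$rt_button_s, bt_dc$rt_button_s)
  expect_true(bt_di$correct)  # lapse = 0: button follows the attended target
})
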