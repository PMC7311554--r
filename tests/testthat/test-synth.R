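test_that("trial tables respect the within-subject design", {
  sp <- experiment_spec(n_participants = 3)
  tr <- generate_trials(sp, seed = 51)
  for (p in unique(tr$participant)) {
    for (ctx in c("ingroup", "outgroup")) {
      sub <- tr[tr$participant == p & tr$context == ctx, ]
      expect_equal(sum(sub$trial_type == "target"), 28)
      expect_equal(sum(sub$trial_type == "filler"), 12)
    }
    expect_setequal(tr$trial[tr$participant == p], 1:80)
  }
  expect_true(all(tr$beta[tr$context == "ingroup"] == 1))
  expect_true(all(tr$beta[tr$context == "outgroup"] == 0.5))
  expect_identical(generate_trials(sp, seed = 51), tr)
})

test_that("trial payoffs respect dominance, cost, benefit, and sum constraints", {
  sp <- experiment_spec(n_participants = 5)
  tr <- generate_trials(sp, seed = 52)
  expect_true(all(tr$own_selfish > tr$other_selfish))
  expect_true(all(tr$own_prosocial > tr$other_prosocial))
  expect_true(all(tr$own_selfish > tr$own_prosocial))
  expect_true(all(tr$other_prosocial > tr$other_selfish))
  sums <- abs((tr$own_selfish + tr$other_selfish) -
                (tr$own_prosocial + tr$other_prosocial))
  expect_true(all(sums > 0.005))
})

test_that("pooled target payoffs reproduce the study statistics", {
  sp <- experiment_spec(n_participants = 90)  # 90 x 56 = 5040 target trials
  tr <- generate_trials(sp, seed = 53)
  tg <- tr[tr$trial_type == "target", ]
  own <- c(tg$own_selfish, tg$own_prosocial)
  oth <- c(tg$other_selfish, tg$other_prosocial)
  expect_equal(mean(own), 7.18, tolerance = 0.1 / 7.18)
  expect_true(all(own >= 2.40 & own <= 10))
  expect_true(all(oth >= 0.10 & oth <= 7.80))
  expect_equal(sd(own), 2.04, tolerance = 0.05)
})

test_that("payoff-law moment matching is exact in closed form", {
  law <- match_payoff_law(7.18, 2.04, 2.40, 10)
  m <- (7.18 - 2.4) / 7.6
  expect_equal(law$shape1 / (law$shape1 + law$shape2), m)
  v <- law$shape1 * law$shape2 /
    ((law$shape1 + law$shape2)^2 * (law$shape1 + law$shape2 + 1))
  expect_equal(sqrt(v) * 7.6, 2.04, tolerance = 1e-9)
  expect_error(match_payoff_law(7.18, 5, 2.40, 10), "infeasible")
})

test_that("participants carry in-range preferences and clear flags", {
  sp <- experiment_spec(n_participants = 40)
  parts <- generate_participants(sp, seed = 54)
  expect_equal(nrow(parts), 40)
  expect_true(all(parts$svo_angle > -16 & parts$svo_angle < 61))
  expect_false(any(parts$wrong_outgroup | parts$outgroup_preferred |
                     parts$demand_failed | parts$missing_gaze))
  expect_true(all(parts$layout_cell %in% layout_cells()))
})

test_that("noiseless gaze reproduces planted centroids exactly", {
  lay <- generate_layout("id_top.pay_middle")
  plan <- data.frame(aoi = c("payoff_own_left", "group_id"),
                     duration = c(300, 250))
  g <- generate_gaze(plan, lay, sigma_px = 0, seed = 61)
  fx <- assign_fixations(detect_fixations(g), lay)
  expect_equal(nrow(fx), 2)
  expect_identical(fx$aoi, plan$aoi)
  truth <- attr(g, "truth")
  expect_equal(fx$x, truth$x)
  expect_equal(fx$y, truth$y)
  expect_equal(fx$duration, plan$duration, tolerance = 1000 / 120)
})

test_that("fixations below the minimum duration are not recovered", {
  lay <- generate_layout("id_top.pay_middle")
  plan <- data.frame(aoi = c("payoff_own_left", "coin", "sum_left"),
                     duration = c(300, 40, 300))
  g <- generate_gaze(plan, lay, sigma_px = 0, seed = 62)
  fx <- assign_fixations(detect_fixations(g), lay)
  expect_identical(fx$aoi, c("payoff_own_left", "sum_left"))
})

test_that("consecutive same-AOI plan entries are merged before emission", {
  lay <- generate_layout("id_top.pay_middle")
  plan <- data.frame(aoi = c("coin", "coin", "group_id"),
                     duration = c(100, 150, 200))
  g <- generate_gaze(plan, lay, sigma_px = 0, seed = 63)
  truth <- attr(g, "truth")
  expect_equal(nrow(truth), 2)
  expect_equal(truth$duration, c(250, 200))
})

test_that("the gaze round trip recovers planted dwell sequences across seeds", {
  lay <- generate_layout("id_bottom.pay_top")
  ok <- 0
  set.seed(64)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    aois <- character(k)
    aois[1] <- sample(lay$name, 1)
    for (j in 2:k) aois[j] <- sample(setdiff(lay$name, aois[j - 1]), 1)
    plan <- data.frame(aoi = aois, duration = runif(k, 150, 500))
    g <- generate_gaze(plan, lay, sigma_px = runif(1, 0, 4))
    fx <- assign_fixations(detect_fixations(g), lay)
    if (identical(fx$aoi, plan$aoi) &&
          all(abs(fx$duration - plan$duration) < 25)) ok <- ok + 1
  }
  expect_gte(ok, 39)
})

test_that("a full experiment is reproducible from its seed", {
  sp <- experiment_spec(n_participants = 2, n_target = 3, n_filler = 1)
  e1 <- generate_experiment(sp, seed = 71)
  e2 <- generate_experiment(sp, seed = 71)
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$trials, e2$trials)
})
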