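test_that("control regressors match the declared arithmetic", {
  tr <- data.frame(own_selfish = 7.50, other_selfish = 5.20,
                   own_prosocial = 6.90, other_prosocial = 6.10)
  out <- derive_regressors(tr)
  expect_equal(out$disadvantage, 8)
  expect_equal(out$efficiency, 0.30)
  # identical options and a costless prosocial choice
  same <- derive_regressors(data.frame(own_selfish = 5, other_selfish = 2,
                                       own_prosocial = 5,
                                       other_prosocial = 2))
  expect_equal(same$disadvantage, 0)
  expect_equal(same$efficiency, 0)
  free <- derive_regressors(data.frame(own_selfish = 5, other_selfish = 2,
                                       own_prosocial = 5,
                                       other_prosocial = 3))
  expect_equal(free$disadvantage, 0)
  # undefined when the selfish option pays nothing
  zero <- derive_regressors(data.frame(own_selfish = 0, other_selfish = 0,
                                       own_prosocial = 0,
                                       other_prosocial = 1))
  expect_true(is.na(zero$disadvantage))
})

test_that("the logistic fit recovers a closed-form odds ratio", {
  # balanced two-by-two design with no participant heterogeneity:
  # cell probabilities chosen so the contingency odds ratio is known
  set.seed(81)
  n <- 200; per <- 40
  d <- data.frame(participant = rep(seq_len(n), each = per),
                  context = rep(rep(c("ingroup", "outgroup"), each = per / 2),
                                n),
                  svo_angle = 0)
  p_in <- 0.6; p_out <- 0.3
  pr <- ifelse(d$context == "ingroup", p_in, p_out)
  d$choice_prosocial <- rbinom(nrow(d), 1, pr)
  d$disadvantage <- 0; d$efficiency <- 0
  fit <- fit_models(d, "prosocial_choice", fast = TRUE)
  tab <- table(d$context, d$choice_prosocial)
  or_closed <- (tab["ingroup", "1"] * tab["outgroup", "0"]) /
    (tab["ingroup", "0"] * tab["outgroup", "1"])
  expect_equal(fit$or[fit$term == "group_c"], or_closed, tolerance = 0.02)
})

test_that("model estimates are invariant to predictor re-centering", {
  met <- make_cohort(n_participants = 12, seed = 7)
  f1 <- fit_models(met, "prosocial_choice", fast = TRUE)
  met2 <- met
  met2$svo_angle <- met2$svo_angle + 10  # absorbed by internal centering
  f2 <- fit_models(met2, "prosocial_choice", fast = TRUE)
  i1 <- f1[f1$term == "svo_c:group_c", ]
  i2 <- f2[f2$term == "svo_c:group_c", ]
  expect_equal(i1$z, i2$z, tolerance = 1e-6)
  expect_equal(i1$estimate, i2$estimate, tolerance = 1e-8)
})

test_that("a planted outgroup discount surfaces as an ingroup odds ratio above one", {
  for (s in c(1, 2)) {
    met <- make_cohort(n_participants = 50, seed = 100 + s)
    fit <- fit_models(met, "prosocial_choice", fast = TRUE)
    g <- fit[fit$term == "group_c", ]
    expect_gt(g$or, 1)
    expect_gt(g$z, 2)
  }
})

test_that("effort models run on every declared outcome", {
  met <- make_cohort(n_participants = 10, seed = 9)
  for (oc in c("attention_own", "log_rt", "log_nfix", "prop_inspected")) {
    fit <- fit_models(met, oc)
    expect_true(all(c("(Intercept)", "svo_c", "group_c", "trial_c",
                      "svo_c:group_c") %in% fit$term))
    expect_true(is.finite(fit$z[fit$term == "group_c"]))
    expect_identical(attr(fit, "outcome"), oc)
  }
  # random-slope variant fits as well
  fit_rs <- fit_models(met, "log_rt", random_slope = TRUE)
  expect_true("group_c" %in% fit_rs$term)
})

test_that("power simulation rejects near the nominal rate without effects", {
  fr <- power_frame()
  res <- power_simulation(fr, n_grid = 20, n_reps = 150, seeds = 1)
  expect_true(all(res$power > 0.005 & res$power < 0.12))
})

test_that("power orders main effects far above a weak interaction", {
  fr <- power_frame(b_svo = 0.06, b_group = 0.9, b_interaction = 0.008)
  res <- power_simulation(fr, n_grid = 20, n_reps = 150, seeds = 1)
  expect_gt(res$power[res$term == "group"], 0.9)
  expect_lt(res$power[res$term == "interaction"], 0.5)
})
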