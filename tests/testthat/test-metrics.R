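fix_row <- function(aoi, category, duration, x = 0, y = 0)
  data.frame(onset = 0, duration = duration, x = x, y = y,
             n_samples = 6, aoi = aoi, category = category)

lay <- generate_layout("id_top.pay_top")

assigned_fixture <- function() {
  # hand-built trial: dwell sums are known by construction
  rbind(fix_row("payoff_own_left", "payoff_own", 300),
        fix_row("payoff_own_right", "payoff_own", 200),
        fix_row("payoff_other_left", "payoff_other", 250),
        fix_row("difference_left", "difference", 100),
        fix_row("group_id", "group_id", 150),
        fix_row("coin", "coin", 50),
        fix_row("none", "none", 80))
}

test_that("trial metrics reproduce hand-computed dwell sums", {
  m <- trial_metrics(assigned_fixture(), lay, rt_ms = 1500)
  expect_equal(m$n_fixations, 7)
  expect_equal(m$n_inspected, 6)
  expect_equal(m$prop_inspected, 6 / 15)
  expect_equal(m$dwell_own, 500)
  expect_equal(m$dwell_other, 250)
  expect_equal(m$attention_own, 100 * 500 / 750)
  expect_equal(m$attention_own_all, 100 * 500 / 850)
  expect_equal(m$share_group, 150 / 200)
  expect_equal(m$share_coin, 50 / 200)
  expect_equal(m$share_code, 0)
  expect_equal(m$prop_fix_on_info, 6 / 7)
  expect_true(m$group_info_attended)
  expect_false(m$attention_flag)
  # shares sum to one; dwell cannot exceed the response time here
  expect_equal(m$share_group + m$share_coin + m$share_code, 1)
  expect_lte(m$dwell_own + m$dwell_other, m$rt_ms)
})

test_that("degenerate attention patterns are flagged or pinned", {
  all_own <- rbind(fix_row("payoff_own_left", "payoff_own", 400),
                   fix_row("payoff_own_right", "payoff_own", 100))
  expect_equal(trial_metrics(all_own, lay, 900)$attention_own, 100)
  no_pay <- fix_row("group_id", "group_id", 300)
  m <- trial_metrics(no_pay, lay, 900)
  expect_true(is.na(m$attention_own))
  expect_true(m$attention_flag)
  uniform <- rbind(fix_row("group_id", "group_id", 120),
                   fix_row("coin", "coin", 120),
                   fix_row("code", "code", 120))
  mu <- trial_metrics(uniform, lay, 900)
  expect_equal(c(mu$share_group, mu$share_coin, mu$share_code),
               rep(1 / 3, 3))
})

test_that("raw-sample gaze counts for group attendance regardless of fixations", {
  fx <- fix_row("payoff_own_left", "payoff_own", 300)
  g_aoi <- lay[lay$category == "group_id", ]
  gaze <- data.frame(x = g_aoi$x0 + 5, y = g_aoi$y0 + 5)
  expect_true(trial_metrics(fx, lay, 900, gaze = gaze)$group_info_attended)
  expect_false(trial_metrics(fx, lay, 900,
                             gaze = data.frame(x = 0, y = 0))$group_info_attended)
})

toy_trials <- function() {
  d <- data.frame(participant = rep("p1", 18),
                  rt_ms = rep(2000, 18),
                  prop_fix_on_info = rep(0.8, 18),
                  group_info_attended = rep(TRUE, 18))
  d$rt_ms[15] <- 150        # too fast
  d$prop_fix_on_info[16] <- 0.4  # fixations off the information
  d$rt_ms[17] <- 20000      # beyond mean + 3 SD of the survivors
  d$group_info_attended[18] <- FALSE  # process-analysis exclusion only
  d$id <- seq_len(18)
  p2 <- data.frame(participant = "p2", rt_ms = 2000,
                   prop_fix_on_info = 0.8, group_info_attended = TRUE,
                   id = 19:20)
  rbind(d, p2)
}

test_that("exclusion rules remove exactly the planted violators", {
  parts <- data.frame(participant = c("p1", "p2"),
                      wrong_outgroup = c(FALSE, TRUE))
  ex <- apply_exclusions(toy_trials(), parts)
  expect_setequal(ex$choice_trials$id, c(1:14, 18))
  expect_setequal(ex$process_trials$id, 1:14)
  r <- ex$report
  expect_equal(r$participants_excluded, 1)
  expect_equal(r$trials_from_excluded_participants, 2)
  expect_equal(r$fixation_share, 1)
  expect_equal(r$rt_too_fast, 1)
  expect_equal(r$rt_too_slow, 1)
  expect_equal(r$group_unattended, 1)
  expect_equal(r$n_choice, 15)
  expect_equal(r$n_process, 14)
})

test_that("exclusion is idempotent with frozen response-time statistics", {
  ex <- apply_exclusions(toy_trials())
  again <- apply_exclusions(ex$choice_trials, rt_stats = ex$rt_stats)
  expect_equal(nrow(again$choice_trials), nrow(ex$choice_trials))
  expect_equal(again$report$rt_too_fast + again$report$rt_too_slow +
                 again$report$fixation_share, 0)
})

test_that("a clean dataset passes the filter untouched", {
  d <- data.frame(participant = "p1", rt_ms = rnorm(40, 2000, 100),
                  prop_fix_on_info = 0.9, group_info_attended = TRUE)
  ex <- apply_exclusions(d)
  expect_equal(nrow(ex$choice_trials), 40)
  expect_equal(ex$report$prop_retained, 1)
})

test_that("diagnostic attention contrast recovers the planted identity bias", {
  met <- make_cohort(n_participants = 12, seed = 5)
  # simulator default biases identity dwell 3:1:1 toward group membership;
  # the unconditioned identity-dwell trials recover the bias itself
  dc <- diagnostic_attention_contrast(met)
  expect_equal(unname(dc$means["group"]), 0.6, tolerance = 0.05)
  expect_equal(unname(dc$means["coin"]), 0.2, tolerance = 0.05)
  expect_equal(unname(dc$means["code"]), 0.2, tolerance = 0.05)
  expect_lt(dc$test$p.value, 0.001)
  # restricting to group-attended trials can only raise the group share
  ex <- apply_exclusions(met)
  dcp <- diagnostic_attention_contrast(ex$process_trials)
  expect_gte(dcp$means[["group"]], dc$means[["group"]] - 0.01)
  # degenerate single trial: all identity dwell on the coin
  one <- data.frame(participant = "p9", share_group = 0, share_coin = 1,
                    share_code = 0)
  expect_equal(unname(diagnostic_attention_contrast(one)$means),
               c(0, 1, 0))
})
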