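#' Derive choice-model control variables from a trial's options
#'
#' Two controls enter the generosity model alongside social preference
#' and group context:
#' \describe{
#'   \item{disadvantage}{percentage of own payoff given up by choosing
#'     the prosocial option:
#'     `100 * (own_selfish - own_prosocial) / own_selfish`. Undefined
#'     (flagged `NA`) when the selfish own payoff is zero.}
#'   \item{efficiency}{difference in joint outcome between the prosocial
#'     and selfish option:
#'     `(own_prosocial + other_prosocial) - (own_selfish + other_selfish)`.}
#' }
#'
#' @param trials A data.frame with columns `own_selfish`, `other_selfish`,
#'   `own_prosocial`, `other_prosocial`.
#' @return `trials` with added numeric columns `disadvantage` and
#'   `efficiency`.
#' @examples
#' derive_regressors(data.frame(own_selfish = 7.5, other_selfish = 5.2,
#'                              own_prosocial = 6.9, other_prosocial = 6.1))
#' @export
derive_regressors <- function(trials) {
  need <- c("own_selfish", "other_selfish", "own_prosocial",
            "other_prosocial")
  stopifnot(all(need %in% names(trials)))
  dis <- ifelse(trials$own_selfish == 0, NA_real_,
                100 * (trials$own_selfish - trials$own_prosocial) /
                  trials$own_selfish)
  trials$disadvantage <- dis
  trials$efficiency <- (trials$own_prosocial + trials$other_prosocial) -
    (trials$own_selfish + trials$other_selfish)
  trials
}

center <- function(x) x - mean(x, na.rm = TRUE)

tidy_fit <- function(fit, logistic, n_obs, outcome) {
  co <- summary(fit)$coefficients
  out <- data.frame(term = rownames(co),
                    estimate = co[, "Estimate"],
                    se = co[, "Std. Error"],
                    z = co[, 3],
                    row.names = NULL)
  out$p <- 2 * stats::pnorm(-abs(out$z))
  if (logistic) out$or <- exp(out$estimate)
  msgs <- fit@optinfo$conv$lme4$messages
  attr(out, "converged") <- is.null(msgs) || length(msgs) == 0
  attr(out, "n_obs") <- n_obs
  attr(out, "outcome") <- outcome
  out
}

#' Fit the choice, attention, and effort mixed models
#'
#' Mixed-effects repeated-measures regressions with a participant random
#' intercept, mirroring the study's model families. All predictors are
#' centered before fitting. Outcomes:
#' \describe{
#'   \item{prosocial_choice}{logistic model of `choice_prosocial` on
#'     centered SVO angle, group setting (0 = outgroup, 1 = ingroup), and
#'     their interaction, controlling for the percentage of disadvantage
#'     and efficiency; estimates are also reported as odds ratios.}
#'   \item{attention_own, log_rt, log_nfix, prop_inspected}{linear models
#'     on SVO angle, group, their interaction, and trial index. Response
#'     times enter as log seconds, fixation counts as log counts.}
#' }
#'
#' @param metrics A trial-level dataset (from the gaze pipeline or
#'   [simulate_cohort()]), after exclusions; must contain `participant`,
#'   `context`, `svo_angle`, the outcome's column, and for the choice
#'   model `disadvantage`/`efficiency` (added by [derive_regressors()] if
#'   absent).
#' @param outcome One of `"prosocial_choice"`, `"attention_own"`,
#'   `"log_rt"`, `"log_nfix"`, `"prop_inspected"`.
#' @param random_slope If `TRUE`, add a random slope for group setting.
#' @param fast For the logistic model, use `nAGQ = 0` (much faster,
#'   slightly cruder); used by simulation-heavy procedures.
#'
#' @return A data.frame of coefficients (`term`, `estimate`, `se`, `z`,
#'   `p`, and `or` for the logistic model) with attributes `converged`,
#'   `n_obs`, `outcome`. Non-convergence is flagged, not raised.
#' @export
fit_models <- function(metrics,
                       outcome = c("prosocial_choice", "attention_own",
                                   "log_rt", "log_nfix",
                                   "prop_inspected"),
                       random_slope = FALSE, fast = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("participant", "context", "svo_angle") %in%
                  names(metrics)))
  d <- metrics
  d$svo_c <- center(d$svo_angle)
  d$group_c <- center(as.integer(d$context == "ingroup"))
  re <- if (random_slope) "(1 + group_c | participant)"
        else "(1 | participant)"

  if (outcome == "prosocial_choice") {
    if (!all(c("disadvantage", "efficiency") %in% names(d)))
      d <- derive_regressors(d)
    d$dis_c <- center(d$disadvantage)
    d$eff_c <- center(d$efficiency)
    f <- stats::as.formula(paste(
      "choice_prosocial ~ svo_c * group_c + dis_c + eff_c +", re))
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(f, data = d, family = stats::binomial,
                  nAGQ = if (fast) 0L else 1L)))
    return(tidy_fit(fit, logistic = TRUE, n_obs = nrow(d),
                    outcome = outcome))
  }

  d$y <- switch(outcome,
                attention_own = d$attention_own,
                log_rt = log(d$rt_ms / 1000),
                log_nfix = log(d$n_fixations),
                prop_inspected = d$prop_inspected)
  d <- d[is.finite(d$y), ]
  d$trial_c <- if ("trial" %in% names(d)) center(d$trial) else 0
  f <- stats::as.formula(paste("y ~ svo_c * group_c + trial_c +", re))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = d, REML = FALSE)))
  tidy_fit(fit, logistic = FALSE, n_obs = nrow(d), outcome = outcome)
}

#' Define a generative sampling frame for the power procedure
#'
#' Coefficients are on the logistic (log-odds) scale of the prosocial
#' choice model with centered predictors: `svo` in degrees (centered),
#' `group` coded -0.5/0.5 (out/in).
#'
#' @param intercept Log-odds of a prosocial choice at the predictor means.
#' @param b_svo,b_group,b_interaction Fixed-effect coefficients.
#' @param re_sd SD of the participant random intercept.
#' @param svo_sd SD of the (centered) SVO angles across participants.
#' @param n_trials_per_context Trials per participant per group context.
#' @return A list of class `power_frame`.
#' @export
power_frame <- function(intercept = 0, b_svo = 0, b_group = 0,
                        b_interaction = 0, re_sd = 1, svo_sd = 15,
                        n_trials_per_context = 28) {
  structure(list(intercept = intercept, b_svo = b_svo, b_group = b_group,
                 b_interaction = b_interaction, re_sd = re_sd,
                 svo_sd = svo_sd,
                 n_trials_per_context = n_trials_per_context),
            class = "power_frame")
}

simulate_from_frame <- function(frame, n) {
  svo <- stats::rnorm(n, 0, frame$svo_sd)
  u <- stats::rnorm(n, 0, frame$re_sd)
  per <- frame$n_trials_per_context
  idx <- rep(seq_len(n), each = 2L * per)
  grp <- rep(rep(c(-0.5, 0.5), each = per), n)
  eta <- frame$intercept + u[idx] + frame$b_svo * svo[idx] +
    frame$b_group * grp + frame$b_interaction * svo[idx] * grp
  data.frame(participant = idx,
             svo_c = svo[idx] - mean(svo),
             group_c = grp,
             y = stats::rbinom(length(eta), 1L, stats::plogis(eta)))
}

#' Monte Carlo simulation-based power analysis
#'
#' For each sample size in `n_grid`, repeatedly simulates choice data from
#' the sampling frame, refits the mixed logistic model, and records
#' two-sided Wald rejections at level `alpha` for the SVO, group, and
#' interaction terms. Power is the rejection rate over `n_reps`
#' replications; the procedure runs under each seed in `seeds` so the
#' stability of the estimates across seeds can be inspected.
#'
#' @param frame A [power_frame()].
#' @param n_grid Participant counts to evaluate.
#' @param n_reps Replications per sample size (default 500).
#' @param alpha Two-sided significance level.
#' @param seeds Integer seeds; one full run per seed.
#' @param nAGQ Integration setting passed to `lme4::glmer` (0 is fast and
#'   adequate for rejection-rate estimation).
#'
#' @return A data.frame with columns `seed`, `n`, `term`
#'   (`svo`/`group`/`interaction`), `power`, `n_reps`.
#' @export
power_simulation <- function(frame, n_grid, n_reps = 500, alpha = 0.05,
                             seeds = c(1L, 2L), nAGQ = 0L) {
  stopifnot(inherits(frame, "power_frame"))
  out <- list()
  for (s in seeds) {
    set.seed(s)
    for (n in n_grid) {
      rej <- matrix(NA, n_reps, 3,
                    dimnames = list(NULL, c("svo", "group", "interaction")))
      for (r in seq_len(n_reps)) {
        d <- simulate_from_frame(frame, n)
        fit <- try(suppressMessages(suppressWarnings(
          lme4::glmer(y ~ svo_c * group_c + (1 | participant),
                      data = d, family = stats::binomial,
                      nAGQ = nAGQ))), silent = TRUE)
        if (inherits(fit, "try-error")) next
        z <- summary(fit)$coefficients[, "z value"]
        p <- 2 * stats::pnorm(-abs(z))
        rej[r, ] <- p[c("svo_c", "group_c", "svo_c:group_c")] < alpha
      }
      pw <- colMeans(rej, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        seed = s, n = n, term = names(pw), power = unname(pw),
        n_reps = n_reps)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
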