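info_categories <- c("payoff_own", "payoff_other", "difference", "sum",
                     "group_id", "coin", "code")

#' Trial-level attention and effort metrics
#'
#' Aggregates AOI-assigned fixations of one trial into the dependent
#' measures of the choice, attention and effort analyses:
#' \describe{
#'   \item{n_fixations}{number of detected fixations.}
#'   \item{n_inspected}{distinct AOIs (payoff cells, row labels, identity
#'     items) fixated at least once.}
#'   \item{prop_inspected}{`n_inspected` over the number of AOIs on
#'     screen.}
#'   \item{attention_own}{dwell on own-payoff AOIs as a percentage of
#'     dwell on own- plus other-payoff AOIs; `NA` (flagged) when no payoff
#'     dwell exists. `attention_own_all` uses all eight payoff cells as
#'     the denominator as a sensitivity variant.}
#'   \item{share_group / share_coin / share_code}{identity-box dwell
#'     shares (sum to 1 when identity dwell is positive).}
#'   \item{prop_fix_on_info}{share of fixations landing on payoff or
#'     identity AOIs; feeds the 50 percent exclusion rule.}
#'   \item{group_info_attended}{whether the group-membership AOI received
#'     any gaze sample (if `gaze` is given, any raw sample in the AOI
#'     counts regardless of fixation status; otherwise any fixation).}
#' }
#'
#' @param fixations AOI-assigned fixations of one trial
#'   (see [assign_fixations()]).
#' @param layout The [aoi_layout()] of the trial.
#' @param rt_ms Response time of the trial in ms.
#' @param gaze Optional raw samples of the trial (columns `x`, `y`), used
#'   only for `group_info_attended`.
#' @return A one-row data.frame of metrics.
#' @export
trial_metrics <- function(fixations, layout, rt_ms, gaze = NULL) {
  stopifnot(inherits(layout, "aoi_layout"))
  if (!"category" %in% names(fixations))
    stop("fixations must be AOI-assigned first (see assign_fixations)",
         call. = FALSE)
  dwell_by <- function(cat) {
    sum(fixations$duration[fixations$category %in% cat])
  }
  dwell_own <- dwell_by("payoff_own")
  dwell_other <- dwell_by("payoff_other")
  dwell_payoff_all <- dwell_by(c("payoff_own", "payoff_other",
                                 "difference", "sum"))
  dwell_group <- dwell_by("group_id")
  dwell_coin <- dwell_by("coin")
  dwell_code <- dwell_by("code")
  dwell_id <- dwell_group + dwell_coin + dwell_code

  pay <- dwell_own + dwell_other
  attention_own <- if (pay > 0) 100 * dwell_own / pay else NA_real_
  attention_own_all <- if (dwell_payoff_all > 0)
    100 * dwell_own / dwell_payoff_all else NA_real_

  on_info <- fixations$category %in% info_categories
  n_fix <- nrow(fixations)
  prop_fix_on_info <- if (n_fix > 0) mean(on_info) else NA_real_

  inspected <- unique(fixations$aoi[fixations$aoi != "none"])
  group_aoi <- layout$name[layout$category == "group_id"]
  attended <- if (!is.null(gaze)) {
    any(vapply(group_aoi, function(nm) {
      k <- which(layout$name == nm)
      any(gaze$x >= layout$x0[k] & gaze$x < layout$x0[k] + layout$w[k] &
            gaze$y >= layout$y0[k] & gaze$y < layout$y0[k] + layout$h[k])
    }, logical(1)))
  } else {
    any(fixations$category == "group_id")
  }

  data.frame(
    rt_ms = rt_ms,
    n_fixations = n_fix,
    n_inspected = length(inspected),
    prop_inspected = length(inspected) / nrow(layout),
    dwell_own = dwell_own,
    dwell_other = dwell_other,
    attention_own = attention_own,
    attention_own_all = attention_own_all,
    dwell_group = dwell_group,
    dwell_coin = dwell_coin,
    dwell_code = dwell_code,
    share_group = if (dwell_id > 0) dwell_group / dwell_id else NA_real_,
    share_coin = if (dwell_id > 0) dwell_coin / dwell_id else NA_real_,
    share_code = if (dwell_id > 0) dwell_code / dwell_id else NA_real_,
    prop_fix_on_info = prop_fix_on_info,
    group_info_attended = attended,
    attention_flag = !(pay > 0)
  )
}

#' Apply the preregistration-style exclusion rules
#'
#' Exclusion proceeds in the declared order:
#' \enumerate{
#'   \item participants flagged for a failed manipulation or demand check
#'     (wrong outgroup named, outgroup identified with or liked at least
#'     as much as the ingroup, demand-check failure) are removed entirely;
#'   \item trials with fewer than 50 percent of fixations on payoff and
#'     identity AOIs are dropped;
#'   \item on the survivors, the pooled mean and SD of response time are
#'     computed, and trials faster than `rt_min` ms or slower than
#'     mean + `rt_sd_mult` * SD are dropped;
#'   \item for process analyses only, trials in which the group-membership
#'     AOI received no gaze at all are additionally dropped.
#' }
#'
#' @param trials A data.frame of trial metrics; must contain `participant`,
#'   `rt_ms`, `prop_fix_on_info`, and (for the process subset)
#'   `group_info_attended`.
#' @param participants Optional data.frame with `participant` plus logical
#'   flag columns among `wrong_outgroup`, `outgroup_preferred`,
#'   `demand_failed`, `missing_gaze`.
#' @param rt_min Lower response-time bound in ms.
#' @param rt_sd_mult SD multiplier of the upper response-time bound.
#' @param rt_stats Optional frozen `c(mean, sd)` pair; when supplied the
#'   upper cut uses it instead of re-estimating, which makes re-application
#'   idempotent.
#'
#' @return A list with `choice_trials` (rules 1-3 applied),
#'   `process_trials` (additionally rule 4), `report` (counts per rule),
#'   `rt_cutoff`, and `rt_stats` (the mean/SD actually used).
#' @export
apply_exclusions <- function(trials, participants = NULL, rt_min = 200,
                             rt_sd_mult = 3, rt_stats = NULL) {
  stopifnot(all(c("participant", "rt_ms", "prop_fix_on_info") %in%
                  names(trials)))
  report <- list(n_input = nrow(trials))

  flagged <- character(0)
  if (!is.null(participants)) {
    flags <- c("wrong_outgroup", "outgroup_preferred", "demand_failed",
               "missing_gaze")
    present <- intersect(flags, names(participants))
    if (length(present) > 0) {
      bad <- rowSums(as.data.frame(participants[present]) == TRUE,
                     na.rm = TRUE) > 0
      flagged <- as.character(participants$participant[bad])
    }
  }
  report$participants_excluded <- length(flagged)
  keep <- !(as.character(trials$participant) %in% flagged)
  report$trials_from_excluded_participants <- sum(!keep)
  trials <- trials[keep, ]

  low_info <- !is.na(trials$prop_fix_on_info) &
    trials$prop_fix_on_info < 0.5
  report$fixation_share <- sum(low_info)
  trials <- trials[!low_info, ]

  if (is.null(rt_stats)) {
    rt_stats <- c(mean = mean(trials$rt_ms), sd = stats::sd(trials$rt_ms))
  } else {
    rt_stats <- c(mean = rt_stats[[1]], sd = rt_stats[[2]])
  }
  cutoff <- rt_stats[["mean"]] + rt_sd_mult * rt_stats[["sd"]]
  too_fast <- trials$rt_ms < rt_min
  too_slow <- trials$rt_ms > cutoff
  report$rt_too_fast <- sum(too_fast)
  report$rt_too_slow <- sum(too_slow)
  trials <- trials[!(too_fast | too_slow), ]
  report$n_choice <- nrow(trials)

  process <- trials
  if ("group_info_attended" %in% names(trials)) {
    un <- !(trials$group_info_attended %in% TRUE)
    report$group_unattended <- sum(un)
    process <- trials[!un, ]
  } else {
    report$group_unattended <- NA_integer_
  }
  report$n_process <- nrow(process)
  report$prop_retained <- report$n_choice / report$n_input

  list(choice_trials = trials, process_trials = process,
       report = report, rt_cutoff = cutoff, rt_stats = rt_stats)
}

#' Write an exclusion report as JSON
#'
#' @param exclusions The list returned by [apply_exclusions()].
#' @param path Output file path.
#' @export
write_exclusion_report <- function(exclusions, path) {
  jsonlite::write_json(c(exclusions$report,
                         list(rt_cutoff = exclusions$rt_cutoff)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Diagnostic versus undiagnostic identity attention
#'
#' The identity box shows one diagnostic item (the partner's group
#' membership) next to two undiagnostic negative controls (a coin toss and
#' a personal code). This contrast asks whether attention is specifically
#' directed at the diagnostic item: per participant, the mean dwell shares
#' on the three items are computed over trials with positive identity
#' dwell, and the group-membership share is compared against the mean of
#' the two undiagnostic shares with a paired t-test.
#'
#' @param trials Trial metrics (process subset) with columns `participant`,
#'   `share_group`, `share_coin`, `share_code`.
#' @return A list with `by_participant` (per-participant mean shares),
#'   `means` (grand means of the three shares), and `test` (paired t-test
#'   of group vs. mean undiagnostic share; `NULL` with fewer than two
#'   participants).
#' @export
diagnostic_attention_contrast <- function(trials) {
  stopifnot(all(c("participant", "share_group", "share_coin",
                  "share_code") %in% names(trials)))
  ok <- stats::complete.cases(trials[c("share_group", "share_coin",
                                       "share_code")])
  trials <- trials[ok, ]
  agg <- stats::aggregate(
    trials[c("share_group", "share_coin", "share_code")],
    by = list(participant = trials$participant), FUN = mean)
  test <- NULL
  if (nrow(agg) >= 2) {
    undiag <- (agg$share_coin + agg$share_code) / 2
    test <- stats::t.test(agg$share_group, undiag, paired = TRUE)
  }
  list(by_participant = agg,
       means = c(group = mean(agg$share_group),
                 coin = mean(agg$share_coin),
                 code = mean(agg$share_code)),
       test = test)
}
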