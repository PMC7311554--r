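#' Parameters of the attentional drift-diffusion simulator
#'
#' Evidence (the Relative Decision Value, RDV) accumulates in discrete
#' `dt`-ms Euler-Maruyama steps with drift
#' `d * (U_attended - theta * U_unattended)` signed toward the currently
#' fixated option, Gaussian noise `sigma * sqrt(dt)`, and absorbing
#' boundaries at `+/- boundary`; the first boundary crossing determines
#' the choice and, plus `ndt` ms of non-decision time, the response time.
#' Fixations alternate between the two options with log-normal durations.
#'
#' Defaults: `theta = 0.95` keeps the gaze advantage of the attended
#' option mild relative to the utility differences of the allocation
#' task (utilities are on the raw EUR scale, around 5-7, so aggressive
#' discounting would let the common utility level swamp the difference);
#' `d = 0.0025` per ms per utility unit and `sigma = 0.02` per sqrt-ms
#' with `boundary = 1` place mean decision times around 1-2.5 s and leave
#' response times sensitive to utility differences in the 0.05-0.7 range
#' the allocation trials produce.
#'
#' @param d Drift scale, evidence per ms per utility unit (> 0).
#' @param sigma Noise scale per sqrt-ms (> 0).
#' @param theta Attentional discount of the unattended option, in [0, 1];
#'   `theta = 1` removes gaze dependence (plain DDM).
#' @param boundary Absorbing boundary (> 0).
#' @param ndt Non-decision time, ms.
#' @param fix_meanlog,fix_sdlog Log-normal fixation-duration parameters
#'   (ms scale).
#' @param dt Integration step, ms.
#' @param max_time Censoring horizon, ms.
#' @return A list of class `addm_params`.
#' @export
addm_params <- function(d = 0.0025, sigma = 0.02, theta = 0.95,
                        boundary = 1, ndt = 300,
                        fix_meanlog = log(300), fix_sdlog = 0.4,
                        dt = 1, max_time = 8000) {
  stopifnot(d > 0, sigma > 0, boundary > 0, dt > 0, max_time > 0,
            theta >= 0, theta <= 1, ndt >= 0)
  structure(list(d = d, sigma = sigma, theta = theta, boundary = boundary,
                 ndt = ndt, fix_meanlog = fix_meanlog,
                 fix_sdlog = fix_sdlog, dt = dt, max_time = max_time),
            class = "addm_params")
}

#' Simulate one attentional drift-diffusion trial
#'
#' @param u_left,u_right Utilities of the left and right options (from
#'   [utility()]).
#' @param params An [addm_params()].
#' @param first_fix Which option receives the first fixation: `"random"`
#'   (uniform), `"left"`, or `"right"`.
#' @param single_fixation If `TRUE`, the first fixation lasts until the
#'   horizon, so the drift never switches (used for the plain-DDM limit).
#'
#' @return A list with `choice` (`"left"`/`"right"`), `rt` (ms, including
#'   non-decision time), `fixations` (data.frame of `option`, `duration`
#'   as realized, the last one truncated at the crossing), and `censored`.
#' @export
simulate_addm_trial <- function(u_left, u_right, params = addm_params(),
                                first_fix = c("random", "left", "right"),
                                single_fixation = FALSE) {
  first_fix <- match.arg(first_fix)
  att_left <- switch(first_fix,
                     random = stats::runif(1) < 0.5,
                     left = TRUE, right = FALSE)
  dt <- params$dt
  sdt <- params$sigma * sqrt(dt)
  max_steps <- ceiling(params$max_time / dt)
  rdv <- 0
  elapsed <- 0L
  fix_opt <- character(0)
  fix_dur <- numeric(0)
  censored <- FALSE
  choice <- NA_character_

  repeat {
    mu <- if (att_left) params$d * (u_left - params$theta * u_right)
          else -params$d * (u_right - params$theta * u_left)
    m <- if (single_fixation) max_steps - elapsed
         else min(max_steps - elapsed,
                  max(1L, round(stats::rlnorm(1, params$fix_meanlog,
                                              params$fix_sdlog) / dt)))
    path <- rdv + cumsum(mu * dt + sdt * stats::rnorm(m))
    hit <- which(abs(path) >= params$boundary)
    if (length(hit) > 0) {
      k <- hit[1]
      choice <- if (path[k] > 0) "left" else "right"
      fix_opt <- c(fix_opt, if (att_left) "left" else "right")
      fix_dur <- c(fix_dur, k * dt)
      elapsed <- elapsed + k
      break
    }
    rdv <- path[m]
    fix_opt <- c(fix_opt, if (att_left) "left" else "right")
    fix_dur <- c(fix_dur, m * dt)
    elapsed <- elapsed + m
    if (elapsed >= max_steps) {
      censored <- TRUE
      choice <- if (rdv >= 0) "left" else "right"
      break
    }
    att_left <- !att_left
  }
  list(choice = choice, rt = elapsed * dt + params$ndt,
       fixations = data.frame(option = fix_opt, duration = fix_dur),
       censored = censored)
}

#' Simulate a cohort of participants through the full task
#'
#' Runs the attentional drift-diffusion process on every trial of a trial
#' table (see [generate_trials()]), attaching a plausible fixation
#' micro-structure: each option-level fixation is directed at one concrete
#' payoff cell of the attended option (sampled from `payoff_bias`), and
#' with probability `p_attend_group` the trial opens with two to four
#' identity-box fixations whose targets follow `identity_bias`
#' (group-membership item vs. the two undiagnostic controls). The output
#' uses the same schema as the gaze-pipeline trial metrics, so downstream
#' analyses are agnostic about whether data came from real gaze or from
#' the simulator.
#'
#' @param participants A data.frame with `participant` and `svo_angle`.
#' @param trials A trial table with columns `participant`, `trial`,
#'   `context`, `beta`, `own_selfish`, `other_selfish`, `own_prosocial`,
#'   `other_prosocial`, `prosocial_side`.
#' @param params An [addm_params()].
#' @param p_attend_group Probability that a trial includes any gaze on the
#'   identity box (trials without it later fall to the process-analysis
#'   exclusion).
#' @param identity_bias Unnormalized dwell bias over (group_id, coin,
#'   code); the default 3:1:1 reflects preferential attention to the
#'   diagnostic item.
#' @param payoff_bias Unnormalized bias over the four payoff rows (own,
#'   other, difference, sum) within the attended option.
#' @param id_meanlog,id_sdlog Log-normal duration parameters of identity
#'   fixations (ms).
#' @param seed Optional integer seed for reproducibility.
#' @param return_fixations If `TRUE`, attach a list column `plan` holding
#'   each trial's AOI-level fixation plan (AOI key and duration), usable
#'   as ground truth for [generate_gaze()].
#'
#' @return A data.frame with one row per trial: design columns, `choice`
#'   (`"A"` = selfish, `"B"` = prosocial), `choice_prosocial`, `rt_ms`,
#'   fixation/effort/attention metrics, and `censored`.
#' @export
simulate_cohort <- function(participants, trials, params = addm_params(),
                            p_attend_group = 0.95,
                            identity_bias = c(3, 1, 1),
                            payoff_bias = c(payoff_own = 0.40,
                                            payoff_other = 0.25,
                                            difference = 0.20,
                                            sum = 0.15),
                            id_meanlog = log(250), id_sdlog = 0.3,
                            seed = NULL, return_fixations = FALSE) {
  stopifnot(all(c("participant", "svo_angle") %in% names(participants)))
  need <- c("participant", "trial", "context", "beta", "own_selfish",
            "other_selfish", "own_prosocial", "other_prosocial",
            "prosocial_side")
  stopifnot(all(need %in% names(trials)))
  if (!is.null(seed)) set.seed(seed)

  id_p <- identity_bias / sum(identity_bias)
  pay_p <- payoff_bias / sum(payoff_bias)
  pay_rows <- c("payoff_own", "payoff_other", "difference", "sum")
  id_cells <- c("group_id", "coin", "code")
  svo <- stats::setNames(participants$svo_angle,
                         as.character(participants$participant))
  n <- nrow(trials)
  plans <- if (return_fixations) vector("list", n) else NULL
  num <- function() numeric(n)
  choice <- character(n); choice_pro <- integer(n)
  rt_ms <- num(); n_fix <- integer(n); n_insp <- integer(n)
  d_own <- num(); d_oth <- num(); d_grp <- num(); d_coin <- num()
  d_code <- num(); censored <- logical(n)
  svo_i <- as.numeric(svo[as.character(trials$participant)])
  pro_left_v <- trials$prosocial_side == "left"

  for (i in seq_len(n)) {
    pref <- angle_to_weights(svo_i[i])
    ctx <- if (trials$context[i] == "ingroup") group_context("ingroup")
           else group_context("outgroup", trials$beta[i])
    u_pro <- utility(c(trials$own_prosocial[i], trials$other_prosocial[i]),
                     pref, ctx)
    u_sel <- utility(c(trials$own_selfish[i], trials$other_selfish[i]),
                     pref, ctx)
    u_left <- if (pro_left_v[i]) u_pro else u_sel
    u_right <- if (pro_left_v[i]) u_sel else u_pro

    sim <- simulate_addm_trial(u_left, u_right, params)
    chose_pro <- (sim$choice == "left") == pro_left_v[i]

    # identity-box inspection at trial start
    id_aoi <- character(0); id_dur <- numeric(0)
    if (stats::runif(1) < p_attend_group) {
      n_id <- sample(2:4, 1L)
      id_aoi <- sample(id_cells, n_id, replace = TRUE, prob = id_p)
      id_dur <- stats::rlnorm(n_id, id_meanlog, id_sdlog)
    }

    # option fixations resolved to a concrete payoff cell of that option
    side <- ifelse(sim$fixations$option == "left", "left", "right")
    cell <- sample(pay_rows, length(side), replace = TRUE, prob = pay_p)
    aoi <- c(id_aoi, paste(cell, side, sep = "_"))
    cat_all <- c(id_aoi, cell)
    dur <- c(id_dur, sim$fixations$duration)

    choice[i] <- if (chose_pro) "B" else "A"
    choice_pro[i] <- as.integer(chose_pro)
    rt_ms[i] <- sim$rt + sum(id_dur)
    n_fix[i] <- length(dur)
    n_insp[i] <- length(unique(aoi))
    d_own[i] <- sum(dur[cat_all == "payoff_own"])
    d_oth[i] <- sum(dur[cat_all == "payoff_other"])
    d_grp[i] <- sum(dur[cat_all == "group_id"])
    d_coin[i] <- sum(dur[cat_all == "coin"])
    d_code[i] <- sum(dur[cat_all == "code"])
    censored[i] <- sim$censored
    if (return_fixations)
      plans[[i]] <- data.frame(aoi = aoi, duration = dur)
  }
  pay <- d_own + d_oth
  d_id <- d_grp + d_coin + d_code
  out <- data.frame(
    participant = trials$participant, trial = trials$trial,
    context = trials$context, beta = trials$beta,
    svo_angle = svo_i,
    own_selfish = trials$own_selfish,
    other_selfish = trials$other_selfish,
    own_prosocial = trials$own_prosocial,
    other_prosocial = trials$other_prosocial,
    prosocial_side = trials$prosocial_side,
    choice = choice, choice_prosocial = choice_pro,
    rt_ms = rt_ms, n_fixations = n_fix, n_inspected = n_insp,
    prop_inspected = n_insp / 15,
    dwell_own = d_own, dwell_other = d_oth,
    attention_own = ifelse(pay > 0, 100 * d_own / pay, NA_real_),
    dwell_group = d_grp, dwell_coin = d_coin, dwell_code = d_code,
    share_group = ifelse(d_id > 0, d_grp / d_id, NA_real_),
    share_coin = ifelse(d_id > 0, d_coin / d_id, NA_real_),
    share_code = ifelse(d_id > 0, d_code / d_id, NA_real_),
    prop_fix_on_info = 1,
    group_info_attended = d_grp > 0,
    censored = censored)
  rownames(out) <- NULL
  if (return_fixations) attr(out, "plans") <- plans
  out
}
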