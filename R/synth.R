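#' Specification of a synthetic intergroup allocation experiment
#'
#' Bundles the design constants of the emulated study: two within-subject
#' group contexts with 28 target and 12 filler trials each, own payoffs
#' between 2.40 and 10 EUR (target mean 7.18, SD 2.04), others' payoffs
#' between 0.10 and 7.80 EUR (target mean 3.03, SD 2.22), a 1280 x 1024
#' screen sampled at 120 Hz, and a mixture distribution of SVO angles.
#'
#' @param n_participants Number of participants.
#' @param beta_out Outgroup discount used by the generative utility model.
#' @param n_target,n_filler Trials per group context.
#' @param own_mean,own_sd,own_range Target moments and range of own
#'   payoffs (EUR).
#' @param other_mean,other_sd,other_range Same for the receiver's payoffs.
#' @param svo_mix SVO-angle mixture: a list with `weights`, `means`, `sds`
#'   (degrees). The default mixes a prosocial mode at 45 degrees (equal
#'   weighting of own and others' payoffs) with an individualist mode at
#'   6.3 degrees (weights 0.9/0.1), 60/40 - the two archetypal decision
#'   makers of the utility model.
#' @param sample_rate Gaze sampling rate, Hz.
#' @param screen `c(width, height)` in pixels.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(n_participants = 55, beta_out = 0.5,
                            n_target = 28, n_filler = 12,
                            own_mean = 7.18, own_sd = 2.04,
                            own_range = c(2.40, 10),
                            other_mean = 3.03, other_sd = 2.22,
                            other_range = c(0.10, 7.80),
                            svo_mix = list(weights = c(0.6, 0.4),
                                           means = c(45, 6.3),
                                           sds = c(5, 5)),
                            sample_rate = 120,
                            screen = c(1280, 1024)) {
  stopifnot(n_participants > 0, n_target > 0, n_filler >= 0,
            beta_out > 0, beta_out < 1,
            own_range[1] < own_range[2], other_range[1] < other_range[2])
  structure(list(n_participants = n_participants, beta_out = beta_out,
                 n_target = n_target, n_filler = n_filler,
                 own_mean = own_mean, own_sd = own_sd,
                 own_range = own_range, other_mean = other_mean,
                 other_sd = other_sd, other_range = other_range,
                 svo_mix = svo_mix, sample_rate = sample_rate,
                 screen = screen),
            class = "experiment_spec")
}

#' Payoff law matching target moments on a bounded range
#'
#' The payoff distribution is a Beta rescaled to `[lo, hi]` with its two
#' shape parameters solved in closed form from the requested mean and SD.
#' The bounded Beta family covers the full moment region a bounded
#' unimodal law can express, including the strongly skewed combinations
#' of the allocation task's payoff statistics, which lie outside the
#' stable range of a moment-matched truncated normal.
#'
#' @param mean,sd Target moments on the payoff scale.
#' @param lo,hi Range bounds.
#' @return A list with `shape1`, `shape2`, `lo`, `hi`.
#' @export
match_payoff_law <- function(mean, sd, lo, hi) {
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (m <= 0 || m >= 1 || v >= m * (1 - m))
    stop("moments infeasible for the range", call. = FALSE)
  c0 <- m * (1 - m) / v - 1
  list(shape1 = m * c0, shape2 = (1 - m) * c0, lo = lo, hi = hi)
}

# inverse-CDF sampler with optional per-draw sub-range truncation
rpayoff <- function(n, law, lo = law$lo, hi = law$hi) {
  plo <- stats::pbeta(pmax(0, (lo - law$lo) / (law$hi - law$lo)),
                      law$shape1, law$shape2)
  phi <- stats::pbeta(pmin(1, (hi - law$lo) / (law$hi - law$lo)),
                      law$shape1, law$shape2)
  law$lo + (law$hi - law$lo) *
    stats::qbeta(stats::runif(n, plo, phi), law$shape1, law$shape2)
}

#' Generate participants with ground-truth preferences
#'
#' SVO angles are drawn from the spec's mixture (resampled into the open
#' interval (-16, 61) degrees so weights stay in the empirically typical
#' region) and manipulation-check flags are all clear by default.
#'
#' @param spec An [experiment_spec()].
#' @param seed Optional integer seed.
#' @return A data.frame: `participant`, `svo_angle`, `svo_type`,
#'   `layout_cell`, and all-FALSE exclusion flags.
#' @export
generate_participants <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mix <- spec$svo_mix
  n <- spec$n_participants
  draw <- function(m) {
    comp <- sample(seq_along(mix$weights), m, replace = TRUE,
                   prob = mix$weights)
    stats::rnorm(m, mix$means[comp], mix$sds[comp])
  }
  ang <- draw(n)
  bad <- ang <= -16 | ang >= 61
  while (any(bad)) {
    ang[bad] <- draw(sum(bad))
    bad <- ang <= -16 | ang >= 61
  }
  cells <- layout_cells()
  data.frame(participant = sprintf("p%03d", seq_len(n)),
             svo_angle = ang,
             svo_type = svo_classify(ang),
             layout_cell = cells[(seq_len(n) - 1L) %% length(cells) + 1L],
             wrong_outgroup = FALSE, outgroup_preferred = FALSE,
             demand_failed = FALSE, missing_gaze = FALSE)
}

#' Generate the trial table of a synthetic experiment
#'
#' Per participant and group context, `n_target` target and `n_filler`
#' filler allocation trials are generated in randomized order. A trial is
#' parameterized by a payoff midpoint and a within-trial contrast, the way
#' decomposed dictator games are typically constructed: the two options'
#' own payoffs are `m +/- cost/2` where the prosocial cost is uniform on
#' `cost_range`, and the receiver payoffs are `mo -/+ benefit/2` with the
#' benefit uniform on `benefit_range`, so the prosocial option always
#' costs the dictator money and always benefits the receiver. Midpoints
#' are drawn from bounded payoff laws calibrated (see
#' [match_payoff_law()]) so that the payoffs pooled over both options
#' reproduce the target moments and ranges. The dictator earns more than the receiver in both
#' options, and the payoff sums differ between options (their difference,
#' `benefit - cost`, is the efficiency control of the choice model). The
#' prosocial option's screen side is random per trial. Fillers follow the
#' same payoff law and are flagged.
#'
#' @param spec An [experiment_spec()].
#' @param seed Optional integer seed.
#' @param cost_range Range (EUR) of the dictator's cost of choosing
#'   prosocially.
#' @param benefit_range Range (EUR) of the receiver's benefit from the
#'   prosocial choice.
#' @return A data.frame with one row per trial: `participant`, `trial`
#'   (presentation order), `context`, `beta`, `trial_type`,
#'   `own_selfish`, `other_selfish`, `own_prosocial`, `other_prosocial`,
#'   `prosocial_side`.
#' @export
generate_trials <- function(spec, seed = NULL,
                            cost_range = c(0.3, 0.9),
                            benefit_range = c(0.6, 1.2)) {
  if (!is.null(seed)) set.seed(seed)
  # pooled variance = midpoint variance + E[contrast^2] / 4
  exp_sq <- function(r) mean(r)^2 + diff(r)^2 / 12
  own_mid_sd <- sqrt(max(spec$own_sd^2 - exp_sq(cost_range) / 4, 0.01))
  oth_mid_sd <- sqrt(max(spec$other_sd^2 - exp_sq(benefit_range) / 4, 0.01))
  # calibrate the own-payoff midpoint law so that, after the per-trial
  # clipping to [lo + cost/2, hi - cost/2], the pooled mean still hits
  # the target: fixed-point correction of the law's target mean
  clipped_mean <- function(law, lo, hi) {
    p <- pmax(0, (lo - law$lo) / (law$hi - law$lo))
    q <- pmin(1, (hi - law$lo) / (law$hi - law$lo))
    a <- law$shape1; b <- law$shape2
    num <- stats::pbeta(q, a + 1, b) - stats::pbeta(p, a + 1, b)
    den <- stats::pbeta(q, a, b) - stats::pbeta(p, a, b)
    mean(law$lo + (law$hi - law$lo) * (a / (a + b)) * num / den)
  }
  cost_grid <- seq(cost_range[1], cost_range[2], length.out = 21)
  target <- spec$own_mean
  for (it in 1:25) {
    own_law <- match_payoff_law(target, own_mid_sd,
                                spec$own_range[1] + mean(cost_range) / 2,
                                spec$own_range[2] - mean(cost_range) / 2)
    got <- clipped_mean(own_law, spec$own_range[1] + cost_grid / 2,
                        spec$own_range[2] - cost_grid / 2)
    if (abs(got - spec$own_mean) < 1e-6) break
    target <- target + (spec$own_mean - got)
  }
  oth_law <- match_payoff_law(spec$other_mean, oth_mid_sd,
                              spec$other_range[1] + mean(benefit_range) / 2,
                              spec$other_range[2] - mean(benefit_range) / 2)
  per_ctx <- spec$n_target + spec$n_filler
  n_per <- 2L * per_ctx

  one_participant <- function(pid) {
    m <- n_per
    own1 <- numeric(m); own2 <- numeric(m)
    oth_s <- numeric(m); oth_p <- numeric(m)
    todo <- seq_len(m)
    while (length(todo) > 0) {
      k <- length(todo)
      cost <- stats::runif(k, cost_range[1], cost_range[2])
      benefit <- stats::runif(k, benefit_range[1], benefit_range[2])
      mid <- rpayoff(k, own_law, spec$own_range[1] + cost / 2,
                     spec$own_range[2] - cost / 2)
      # receiver midpoint: stay on the receiver scale and below both owns
      hi <- pmin(spec$other_range[2] - benefit / 2,
                 mid - cost / 2 - benefit / 2 - 0.05)
      lo <- spec$other_range[1] + benefit / 2
      feas <- hi > lo
      mo <- rep(NA_real_, k)
      mo[feas] <- rpayoff(sum(feas), oth_law, lo[feas], hi[feas])
      os <- round(mid + cost / 2, 2); op <- round(mid - cost / 2, 2)
      rs <- round(mo - benefit / 2, 2); rp <- round(mo + benefit / 2, 2)
      ok <- feas & !is.na(mo) & os > op & rp > rs & rp < op & rs < os &
        rs >= spec$other_range[1] & os <= spec$own_range[2] &
        abs((os + rs) - (op + rp)) > 0.005     # sums must differ
      own1[todo[ok]] <- os[ok]; own2[todo[ok]] <- op[ok]
      oth_s[todo[ok]] <- rs[ok]; oth_p[todo[ok]] <- rp[ok]
      todo <- todo[!ok]
    }
    ctx <- rep(c("ingroup", "outgroup"), each = per_ctx)
    type <- rep(rep(c("target", "filler"),
                    c(spec$n_target, spec$n_filler)), 2L)
    ord <- sample.int(m)
    data.frame(participant = pid,
               trial = ord,
               context = ctx,
               beta = ifelse(ctx == "ingroup", 1, spec$beta_out),
               trial_type = type,
               own_selfish = own1, other_selfish = oth_s,
               own_prosocial = own2, other_prosocial = oth_p,
               prosocial_side = sample(c("left", "right"), m,
                                       replace = TRUE))
  }
  ids <- sprintf("p%03d", seq_len(spec$n_participants))
  out <- do.call(rbind, lapply(ids, one_participant))
  out <- out[order(out$participant, out$trial), ]
  rownames(out) <- NULL
  out
}

#' Counterbalancing cells of the screen layout
#'
#' The identity box and the payoff block each occupy one of three vertical
#' positions (top, middle, bottom), giving nine cells.
#'
#' @return A character vector of cell names, e.g. `"id_top.pay_middle"`.
#' @export
layout_cells <- function() {
  g <- expand.grid(id = c("top", "middle", "bottom"),
                   pay = c("top", "middle", "bottom"))
  paste0("id_", g$id, ".pay_", g$pay)
}

#' Generate the AOI layout for a counterbalancing cell
#'
#' Builds the 15-AOI screen: eight 100 x 100 payoff cells (own, other,
#' difference and sum rows for the left and right option), four 100 x 190
#' row labels on the left, and three 100 x 100 identity items (group
#' membership, coin toss, personal code) in a right-hand column. The
#' vertical position of the payoff block and of the identity column is set
#' by the counterbalancing cell. The layout is a schematic emulation of
#' the task screen, not a pixel-accurate reconstruction.
#'
#' @param cell One of [layout_cells()].
#' @param screen `c(width, height)` in pixels.
#' @return An [aoi_layout()].
#' @export
generate_layout <- function(cell = layout_cells()[1],
                            screen = c(1280, 1024)) {
  cell <- match.arg(cell, layout_cells())
  parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
  id_pos <- sub("id_", "", parts[1])
  pay_pos <- sub("pay_", "", parts[2])
  yp <- switch(pay_pos, top = 20, middle = 130, bottom = 260)
  yi <- switch(id_pos, top = 30, middle = 352, bottom = 674)

  rows <- c("own", "other", "difference", "sum")
  row_cat <- c("payoff_own", "payoff_other", "difference", "sum")
  name <- character(0); category <- character(0)
  x0 <- numeric(0); y0 <- numeric(0); w <- numeric(0); h <- numeric(0)
  for (k in seq_along(rows)) {
    name <- c(name, paste0("label_", rows[k]))
    category <- c(category, "row_label")
    x0 <- c(x0, 60); y0 <- c(y0, yp + 190 * (k - 1))
    w <- c(w, 100); h <- c(h, 190)
    for (side in c("left", "right")) {
      name <- c(name, paste(row_cat[k], side, sep = "_"))
      category <- c(category, row_cat[k])
      x0 <- c(x0, if (side == "left") 400 else 800)
      y0 <- c(y0, yp + 190 * (k - 1) + 45)
      w <- c(w, 100); h <- c(h, 100)
    }
  }
  for (j in seq_along(c("group_id", "coin", "code"))) {
    nm <- c("group_id", "coin", "code")[j]
    name <- c(name, nm); category <- c(category, nm)
    x0 <- c(x0, 1050); y0 <- c(y0, yi + 110 * (j - 1))
    w <- c(w, 100); h <- c(h, 100)
  }
  aoi_layout(name, category, x0, y0, w, h, screen = screen)
}

#' Generate a raw gaze stream from a planted fixation plan
#'
#' The inverse of the preprocessing stage: for each planned fixation the
#' AOI centre is emitted at the sampling rate with isotropic Gaussian
#' positional jitter, truncated to +/- 7 px per axis so that the summed
#' x/y dispersion of a planted fixation can never exceed the 30 px
#' detection tolerance; between fixations two linearly interpolated
#' saccade samples are inserted, fast enough never to form a spurious
#' fixation. Consecutive plan entries on the same AOI are merged first
#' (the detector could not distinguish them).
#'
#' @param plan A data.frame with columns `aoi` (a name in `layout`) and
#'   `duration` (ms).
#' @param layout An [aoi_layout()].
#' @param sigma_px Jitter SD in pixels (before truncation).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @param t0 Timestamp of the first sample, ms.
#' @return A data.frame of samples `t`, `x`, `y`, `valid` with attribute
#'   `"truth"` holding the merged plan with planted centroids.
#' @export
generate_gaze <- function(plan, layout, sigma_px = 3, sample_rate = 120,
                          seed = NULL, t0 = 0) {
  stopifnot(inherits(layout, "aoi_layout"),
            all(plan$aoi %in% layout$name))
  if (!is.null(seed)) set.seed(seed)
  # merge consecutive same-AOI entries
  keep <- c(TRUE, plan$aoi[-1] != plan$aoi[-nrow(plan)])
  grp <- cumsum(keep)
  plan <- data.frame(aoi = plan$aoi[keep],
                     duration = as.numeric(tapply(plan$duration, grp, sum)))
  dt <- 1000 / sample_rate
  cx <- layout$x0[match(plan$aoi, layout$name)] +
    layout$w[match(plan$aoi, layout$name)] / 2
  cy <- layout$y0[match(plan$aoi, layout$name)] +
    layout$h[match(plan$aoi, layout$name)] / 2
  jitter <- function(n) {
    z <- stats::rnorm(n, 0, sigma_px)
    pmin(7, pmax(-7, z))
  }
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nrow(plan))) {
    n <- max(1L, round(plan$duration[i] / dt))
    xs <- c(xs, cx[i] + jitter(n))
    ys <- c(ys, cy[i] + jitter(n))
    if (i < nrow(plan)) {
      xs <- c(xs, cx[i] + (cx[i + 1] - cx[i]) * c(1, 2) / 3)
      ys <- c(ys, cy[i] + (cy[i + 1] - cy[i]) * c(1, 2) / 3)
    }
  }
  out <- data.frame(t = t0 + (seq_along(xs) - 1L) * dt,
                    x = xs, y = ys, valid = TRUE)
  attr(out, "truth") <- data.frame(plan, x = cx, y = cy)
  out
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper drawing participants, the trial table, and the
#' simulated choice/gaze-metric dataset in one reproducible step.
#'
#' @param spec An [experiment_spec()].
#' @param params An [addm_params()].
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of `(spec, params, seed)`.
#' @param ... Passed to [simulate_cohort()].
#' @return A list with `participants`, `trials`, `metrics` (the simulated
#'   cohort dataset) and `spec`.
#' @export
generate_experiment <- function(spec = experiment_spec(),
                                params = addm_params(), seed = 1, ...) {
  set.seed(seed)
  participants <- generate_participants(spec)
  trials <- generate_trials(spec)
  metrics <- simulate_cohort(participants, trials, params, ...)
  list(participants = participants, trials = trials, metrics = metrics,
       spec = spec)
}
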