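# Brute-force I-DT oracle: recomputes every window's dispersion from
# scratch (no running min/max), greedy left-to-right maximal windows.
idt_oracle <- function(samples, tol = 30, min_dur = 50) {
  s <- samples
  if ("valid" %in% names(s)) s <- s[s$valid %in% TRUE, ]
  s <- s[is.finite(s$x) & is.finite(s$y), ]
  n <- nrow(s)
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      x = numeric(0), y = numeric(0),
                      n_samples = integer(0))
  if (n == 0L) return(empty)
  dt_nom <- if (n > 1L) median(diff(s$t)) else min_dur
  disp <- function(i, j)
    (max(s$x[i:j]) - min(s$x[i:j])) + (max(s$y[i:j]) - min(s$y[i:j]))
  res <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && disp(i, j + 1L) <= tol + 1e-9) j <- j + 1L
    dur <- s$t[j] - s$t[i] + dt_nom
    if (dur >= min_dur - 1e-9) {
      res[[length(res) + 1L]] <- data.frame(
        onset = s$t[i], duration = dur,
        x = mean(s$x[i:j]), y = mean(s$y[i:j]),
        n_samples = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(res) == 0L) return(empty)
  do.call(rbind, res)
}

# random gaze streams mixing tight clusters and saccade-like jumps
random_gaze_case <- function(n_max = 50) {
  n <- sample(1:n_max, 1)
  regular <- runif(1) < 0.5
  t <- if (regular) (0:(n - 1)) * 1000 / 120
       else sort(runif(n, 0, n * 12))
  if (n > 1 && any(diff(t) <= 0)) t <- t + seq(0, 1e-3, length.out = n)
  # piecewise cluster centers with occasional jumps
  k <- sample(1:4, 1)
  centers <- matrix(runif(2 * k, 0, 1000), ncol = 2)
  idx <- sort(sample(1:k, n, replace = TRUE))
  spread <- sample(c(2, 8, 25), 1)
  data.frame(t = t,
             x = centers[idx, 1] + rnorm(n, 0, spread),
             y = centers[idx, 2] + rnorm(n, 0, spread))
}

# closed-form two-boundary first-passage probability of hitting the
# upper boundary for a drift-diffusion starting at 0
ddm_upper_prob <- function(delta_u, p) {
  1 / (1 + exp(-2 * p$boundary * p$d * delta_u / p$sigma^2))
}

# small simulated cohort for analysis tests
make_cohort <- function(n_participants = 20, seed = 1,
                        params = addm_params(), ...) {
  set.seed(seed)
  sp <- experiment_spec(n_participants = n_participants)
  parts <- generate_participants(sp)
  tr <- generate_trials(sp)
  tr <- tr[tr$trial_type == "target", ]
  met <- simulate_cohort(parts, tr, params, ...)
  derive_regressors(met)
}
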