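#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Groups consecutive gaze samples into fixations using greedy
#' left-to-right maximal windows: starting from a sample, the window grows
#' while the dispersion - the sum of the ranges of the member samples'
#' x and y coordinates - stays at or below `dispersion_tol` pixels. When
#' the window can grow no further, it is emitted as a fixation if it lasts
#' at least `min_duration` ms, and detection restarts at the next sample;
#' otherwise detection restarts one sample later. Because adding a sample
#' can only increase the dispersion, each emitted window is the maximal
#' dispersion-admissible window at its start.
#'
#' A window's duration counts each sample as one frame of viewing time:
#' `t_last - t_first + dt`, where `dt` is the nominal inter-sample
#' interval (the median of the timestamp differences of the trial). At a
#' 120 Hz sampling rate the 50 ms minimum therefore requires six samples;
#' the comparison is inclusive (a span of exactly 50 ms passes).
#'
#' @param samples A data.frame with numeric columns `t` (ms, strictly
#'   increasing), `x`, `y` (pixels), and optionally a logical `valid`
#'   column; invalid samples and samples with missing coordinates are
#'   dropped before detection.
#' @param dispersion_tol Maximum summed x-range + y-range, in pixels.
#' @param min_duration Minimum fixation duration, in ms (inclusive).
#'
#' @return A data.frame with one row per fixation: `onset` (ms), `duration`
#'   (ms), `x`, `y` (centroid = mean of member samples), `n_samples`.
#' @examples
#' s <- data.frame(t = (0:11) * 1000 / 120, x = 100, y = 100)
#' detect_fixations(s)
#' @export
detect_fixations <- function(samples, dispersion_tol = 30,
                             min_duration = 50) {
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y") %in% names(samples)))
  if ("valid" %in% names(samples)) samples <- samples[samples$valid %in% TRUE, ]
  samples <- samples[is.finite(samples$x) & is.finite(samples$y), ]
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      x = numeric(0), y = numeric(0),
                      n_samples = integer(0))
  n <- nrow(samples)
  if (n == 0L) return(empty)
  t <- samples$t; x <- samples$x; y <- samples$y
  if (n > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing within a trial",
         call. = FALSE)
  dt_nom <- if (n > 1L) stats::median(diff(t)) else min_duration
  eps <- 1e-9

  out <- vector("list", 0L)
  i <- 1L
  while (i <= n) {
    xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
    j <- i
    while (j < n) {
      nx_min <- min(xmin, x[j + 1L]); nx_max <- max(xmax, x[j + 1L])
      ny_min <- min(ymin, y[j + 1L]); ny_max <- max(ymax, y[j + 1L])
      if ((nx_max - nx_min) + (ny_max - ny_min) > dispersion_tol + eps) break
      xmin <- nx_min; xmax <- nx_max; ymin <- ny_min; ymax <- ny_max
      j <- j + 1L
    }
    dur <- t[j] - t[i] + dt_nom
    if (dur >= min_duration - eps) {
      idx <- i:j
      out[[length(out) + 1L]] <- data.frame(
        onset = t[i], duration = dur,
        x = mean(x[idx]), y = mean(y[idx]),
        n_samples = length(idx))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Average binocular gaze into a single stream
#'
#' The recording is binocular; detection runs on one stream. Per timestamp
#' the two eyes' coordinates are averaged; when only one eye is valid its
#' coordinates are used alone, and a sample is invalid when both eyes are.
#'
#' @param samples A data.frame with columns `t`, `x_left`, `y_left`,
#'   `x_right`, `y_right` and optional logicals `valid_left`, `valid_right`
#'   (missing coordinates also mark an eye invalid).
#' @return A data.frame with columns `t`, `x`, `y`, `valid`.
#' @export
average_eyes <- function(samples) {
  stopifnot(all(c("t", "x_left", "y_left", "x_right", "y_right") %in%
                  names(samples)))
  vl <- if ("valid_left" %in% names(samples)) samples$valid_left %in% TRUE
        else rep(TRUE, nrow(samples))
  vr <- if ("valid_right" %in% names(samples)) samples$valid_right %in% TRUE
        else rep(TRUE, nrow(samples))
  vl <- vl & is.finite(samples$x_left) & is.finite(samples$y_left)
  vr <- vr & is.finite(samples$x_right) & is.finite(samples$y_right)
  x <- ifelse(vl & vr, (samples$x_left + samples$x_right) / 2,
              ifelse(vl, samples$x_left,
                     ifelse(vr, samples$x_right, NA_real_)))
  y <- ifelse(vl & vr, (samples$y_left + samples$y_right) / 2,
              ifelse(vl, samples$y_left,
                     ifelse(vr, samples$y_right, NA_real_)))
  data.frame(t = samples$t, x = x, y = y, valid = vl | vr)
}

#' Read a raw gaze stream from a delimited file
#'
#' Expects columns `participant`, `trial`, `t`, `x`, `y` and optionally
#' `valid`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of gaze samples.
#' @export
read_gaze_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("participant", "trial", "t", "x", "y")
  if (!all(need %in% names(x)))
    stop("gaze CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}
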