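#' Touch series container
#'
#' Bundles raw or preprocessed touchscreen samples: time-stamped (x, y)
#' positions in pixels together with a touching flag. The source acquisition
#' rate is 60 Hz; [preprocess_touch_series()] resamples to 500 Hz. The default
#' pixel-to-physical conversion is 33.6 px per cm.
#'
#' @param t numeric vector of sample times (s), strictly increasing.
#' @param x,y numeric vectors of screen position (px).
#' @param touching logical vector, `TRUE` while the finger is on the screen.
#' @param fs nominal sampling rate (Hz).
#' @param px_per_cm pixel pitch of the touchscreen (px/cm).
#' @return An object of class `touch_series` (a data frame with columns
#'   `t`, `x`, `y`, `touching` and attributes `fs`, `px_per_cm`).
#' @export
touch_series <- function(t, x, y, touching = rep(TRUE, length(t)),
                         fs = 60, px_per_cm = 33.6) {
  stopifnot(length(t) == length(x), length(t) == length(y),
            length(t) == length(touching))
  if (any(diff(t) <= 0)) stop("touch_series: `t` must be strictly increasing")
  out <- data.frame(t = t, x = x, y = y, touching = as.logical(touching))
  attr(out, "fs") <- fs
  attr(out, "px_per_cm") <- px_per_cm
  class(out) <- c("touch_series", "data.frame")
  out
}

#' Zero-phase low-pass filter
#'
#' Order-4 Butterworth applied forwards and backwards (zero phase), so
#' filtering does not shift stroke onsets. Inputs shorter than the filter's
#' edge-transient support are returned unchanged.
#'
#' @param x numeric signal.
#' @param cutoff_hz cutoff frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param order filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, cutoff_hz, fs, order = 4) {
  n <- length(x)
  if (n <= 3 * (order + 1)) return(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # reflective padding keeps edge transients out of the data window
  npad <- min(n - 1, 3 * fs %/% max(1, cutoff_hz))
  xp <- c(2 * x[1] - rev(x[seq_len(npad) + 1]),
          x,
          2 * x[n] - rev(x[n - seq_len(npad)]))
  y <- signal::filtfilt(bf, xp)
  y[npad + seq_len(n)]
}

#' Upsample and filter a raw touch series
#'
#' Resamples 60 Hz touchscreen samples onto a uniform 500 Hz grid (linear
#' interpolation) and low-pass filters position at 15 Hz to keep only
#' drawing-related movement. Touching flags are carried through by
#' nearest-neighbour interpolation.
#'
#' @param raw a [touch_series()] at the source rate.
#' @param fs_out output sampling rate (Hz), default 500.
#' @param cutoff_hz low-pass cutoff (Hz), default 15.
#' @return A `touch_series` at `fs_out`.
#' @export
preprocess_touch_series <- function(raw, fs_out = 500, cutoff_hz = 15) {
  stopifnot(inherits(raw, "touch_series"))
  if (nrow(raw) < 4) stop("preprocess_touch_series: need at least 4 samples")
  tg <- seq(raw$t[1], raw$t[nrow(raw)], by = 1 / fs_out)
  xg <- approx(raw$t, raw$x, xout = tg, rule = 2)$y
  yg <- approx(raw$t, raw$y, xout = tg, rule = 2)$y
  tch <- approx(raw$t, as.numeric(raw$touching), xout = tg,
                method = "constant", f = 0, rule = 2)$y > 0.5
  xg <- lowpass_zero_phase(xg, cutoff_hz, fs_out)
  yg <- lowpass_zero_phase(yg, cutoff_hz, fs_out)
  touch_series(tg, xg, yg, tch, fs = fs_out,
               px_per_cm = attr(raw, "px_per_cm"))
}

new_stroke <- function(t, x, y, trial_id = NA_integer_,
                       stroke_index = NA_integer_, fs = 500) {
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "onset_t") <- t[1]
  attr(out, "offset_t") <- t[length(t)]
  attr(out, "trial_id") <- trial_id
  attr(out, "stroke_index") <- stroke_index
  attr(out, "fs") <- fs
  class(out) <- c("stroke", "data.frame")
  out
}

#' Segment a touch series into strokes
#'
#' One stroke per maximal run of `touching == TRUE`; onset is the time of
#' first touch and offset the time of last touch of the run, at the series'
#' resolution. Strokes are returned ordered by onset.
#'
#' @param series a preprocessed [touch_series()].
#' @param trial_id optional trial identifier stored on each stroke.
#' @return A list of `stroke` objects (empty if never touching).
#' @export
segment_strokes <- function(series, trial_id = NA_integer_) {
  stopifnot(inherits(series, "touch_series"))
  r <- rle(series$touching)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    idx <- starts[i]:ends[i]
    out[[k]] <- new_stroke(series$t[idx], series$x[idx], series$y[idx],
                           trial_id = trial_id, stroke_index = k,
                           fs = attr(series, "fs"))
  }
  out
}

#' Five-point stencil derivative
#'
#' Finite-difference derivative with the five-point stencil
#' f'\[n\] = (f\[n-2\] - 8 f\[n-1\] + 8 f\[n+1\] - f\[n+2\]) / (12 h) at
#' interior points (exact for polynomials up to degree 4). The first and last
#' two points use one-sided second-order differences.
#'
#' @param f numeric series sampled on a uniform grid.
#' @param h sampling period (s).
#' @return Numeric derivative series, same length as `f`.
#' @export
differentiate_five_point <- function(f, h) {
  n <- length(f)
  if (n < 5) stop("differentiate_five_point: need at least 5 samples")
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (f[i - 2] - 8 * f[i - 1] + 8 * f[i + 1] - f[i + 2]) / (12 * h)
  d[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * h)
  d[2] <- (-3 * f[2] + 4 * f[3] - f[4]) / (2 * h)
  d[n - 1] <- (3 * f[n - 1] - 4 * f[n - 2] + f[n - 3]) / (2 * h)
  d[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * h)
  d
}

#' Instantaneous stroke velocity and speed
#'
#' Velocity is computed by low-pass filtering position at 12.5 Hz,
#' downsampling to 25 Hz, differentiating with the five-point stencil, and
#' upsampling back to the stroke's native rate with a cubic spline. Speed is
#' the per-sample Euclidean norm of velocity. Strokes too short for the 25 Hz
#' grid are differentiated at the largest decimation that retains five points.
#'
#' @param stroke a `stroke` from [segment_strokes()].
#' @return The stroke with added columns `vx`, `vy`, `speed`.
#' @export
stroke_velocity <- function(stroke, fs_mid = 25, cutoff_hz = 12.5) {
  stopifnot(inherits(stroke, "stroke"))
  fs <- attr(stroke, "fs")
  n <- nrow(stroke)
  xf <- lowpass_zero_phase(stroke$x, cutoff_hz, fs)
  yf <- lowpass_zero_phase(stroke$y, cutoff_hz, fs)
  dec <- max(1L, min(as.integer(round(fs / fs_mid)), n %/% 5L))
  idx <- seq(1L, n, by = dec)
  if (length(idx) < 5L) stop("stroke_velocity: stroke too short")
  h <- dec / fs
  vx <- differentiate_five_point(xf[idx], h)
  vy <- differentiate_five_point(yf[idx], h)
  stroke$vx <- spline(stroke$t[idx], vx, xout = stroke$t)$y
  stroke$vy <- spline(stroke$t[idx], vy, xout = stroke$t)$y
  stroke$speed <- sqrt(stroke$vx^2 + stroke$vy^2)
  stroke
}

#' Read/write strokes in long-format CSV
#'
#' The interchange format is one row per sample with columns
#' `trial_id, t_s, x_px, y_px, touching_flag`.
#'
#' @param series a `touch_series`; `trial_id` its trial label.
#' @param path file path.
#' @name stroke_csv
#' @export
write_touch_csv <- function(series, path, trial_id = 1L) {
  df <- data.frame(trial_id = trial_id, t_s = series$t, x_px = series$x,
                   y_px = series$y, touching_flag = as.integer(series$touching))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname stroke_csv
#' @param fs sampling rate of the stored samples (Hz).
#' @return `read_touch_csv` returns a named list of `touch_series`, one per
#'   trial.
#' @export
read_touch_csv <- function(path, fs = 60, px_per_cm = 33.6) {
  df <- read.csv(path)
  lapply(split(df, df$trial_id), function(d) {
    touch_series(d$t_s, d$x_px, d$y_px, d$touching_flag > 0,
                 fs = fs, px_per_cm = px_per_cm)
  })
}
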