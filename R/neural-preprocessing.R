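#' Convert spike times to smoothed firing rates
#'
#' Gaussian-kernel rate estimation on a sliding 10 ms grid: each spike
#' contributes a 25 ms-sd Gaussian bump, truncated at +/- 4 sd and
#' renormalized within the trial window (edge correction), so the rate
#' integrates to the spike count.
#'
#' @param spike_times list with one numeric vector of sorted spike times (s)
#'   per trial (empty trains allowed).
#' @param window c(start, end) of the trial window (s).
#' @param bin grid step (s), default 0.01.
#' @param kernel_sd Gaussian kernel sd (s), default 0.025.
#' @return Matrix of rates (Hz), trials x bins, with bin centres in
#'   attribute `time`.
#' @export
spikes_to_rates <- function(spike_times, window, bin = 0.01,
                            kernel_sd = 0.025) {
  tc <- seq(window[1] + bin / 2, window[2] - bin / 2 + 1e-12, by = bin)
  R <- matrix(0, length(spike_times), length(tc))
  for (k in seq_along(spike_times)) {
    sp <- spike_times[[k]]
    sp <- sp[sp >= window[1] - 4 * kernel_sd & sp <= window[2] + 4 * kernel_sd]
    if (is.unsorted(sp)) stop("spikes_to_rates: spike times must be sorted")
    if (!length(sp)) next
    r <- numeric(length(tc))
    for (s in sp) {
      mass <- stats::pnorm(window[2], s, kernel_sd) -
        stats::pnorm(window[1], s, kernel_sd)
      if (mass <= 0) next
      w <- dnorm(tc, s, kernel_sd)
      w[abs(tc - s) > 4 * kernel_sd] <- 0
      r <- r + w / mass
    }
    R[k, ] <- r
  }
  attr(R, "time") <- tc
  R
}

#' Screen units for rate stability
#'
#' Applies the three exclusion rules to each unit: (i) low rate — the 80th
#' percentile of firing rates across all trials and bins below 1 Hz;
#' (ii) drift — `m / u > 0.2`, where m is the OLS slope of the per-trial
#' mean square-root rate against trial start time in hours and u the mean
#' square-root rate; (iii) fluctuation — with the session split into
#' disjoint contiguous 50-trial bins, `(s_max - s_min) / s_mean > 1.15` on
#' the across-trial sd of sqrt rates per bin, or
#' `(u_max - u_min) / u_mean > 0.65` on the per-bin means. Fluctuation rules
#' require >= 100 trials and are otherwise skipped with a flag. Screening of
#' one unit never depends on the others.
#'
#' @param rates list with one trials x bins rate matrix per unit, or a
#'   K x N x T array.
#' @param trial_start_h trial start times (hours into the session).
#' @return A data frame (`screening_report`): per-unit statistics, exclusion
#'   flags and overall `pass`.
#' @export
screen_units <- function(rates, trial_start_h) {
  if (is.array(rates) && length(dim(rates)) == 3)
    rates <- lapply(seq_len(dim(rates)[2]), function(n) rates[, n, ])
  out <- lapply(seq_along(rates), function(n)
    .screen_one(rates[[n]], trial_start_h, n))
  rep <- do.call(rbind, out)
  class(rep) <- c("screening_report", "data.frame")
  rep
}

.screen_one <- function(R, trial_start_h, unit_id) {
  stopifnot(nrow(R) == length(trial_start_h))
  low_rate <- unname(quantile(R, 0.8, type = 7)) < 1
  sq_mean <- rowMeans(sqrt(pmax(R, 0)))
  fit <- lm.fit(cbind(1, trial_start_h), sq_mean)
  m <- unname(coef(fit)[2])
  u <- mean(sq_mean)
  drift <- is.finite(m / u) && m / u > 0.2
  K <- nrow(R)
  if (K >= 100) {
    nb <- K %/% 50
    grp <- rep(seq_len(nb), each = 50)
    sm <- sq_mean[seq_len(nb * 50)]
    s_b <- tapply(sm, grp, sd)
    u_b <- tapply(sm, grp, mean)
    s_stats <- c(max(s_b), min(s_b), mean(s_b))
    u_stats <- c(max(u_b), min(u_b), mean(u_b))
    fluct_s <- s_stats[3] > 0 && (s_stats[1] - s_stats[2]) / s_stats[3] > 1.15
    fluct_u <- u_stats[3] > 0 && (u_stats[1] - u_stats[2]) / u_stats[3] > 0.65
    skipped <- FALSE
  } else {
    s_stats <- u_stats <- rep(NA_real_, 3)
    fluct_s <- fluct_u <- FALSE
    skipped <- TRUE
  }
  data.frame(unit = unit_id, m = m, u = u,
             s_max = s_stats[1], s_min = s_stats[2], s_mean = s_stats[3],
             u_max = u_stats[1], u_min = u_stats[2], u_mean = u_stats[3],
             flag_low_rate = low_rate, flag_drift = drift,
             flag_fluct_s = fluct_s, flag_fluct_u = fluct_u,
             fluct_skipped = skipped,
             pass = !(low_rate || drift || fluct_s || fluct_u))
}

#' Soft z-score normalization of firing rates
#'
#' Rates are square-root transformed (variance stabilization) and then
#' z-scored per unit in a soft manner,
#' `x_norm = (sqrt(x) - mu) / (sigma + C)`, where mu and sigma are the
#' unit's mean and sd across trials and bins and `C = min(m) + 3` Hz (m the
#' vector of unit mean rates) keeps higher-firing units contributing
#' relatively more and prevents blow-up for near-constant units.
#'
#' @param rates K x N x T array of firing rates (Hz).
#' @param params optional previously fitted parameters (list `mu`, `sigma`,
#'   `C`) to re-apply.
#' @return List with `normalized` (K x N x T) and `params`.
#' @export
normalize_rates <- function(rates, params = NULL) {
  stopifnot(length(dim(rates)) == 3)
  sq <- sqrt(pmax(rates, 0))
  if (is.null(params)) {
    mu <- apply(sq, 2, mean)
    sigma <- apply(sq, 2, sd)
    C <- min(apply(rates, 2, mean)) + 3
    params <- list(mu = mu, sigma = sigma, C = C)
  }
  out <- sweep(sq, 2, params$mu)
  out <- sweep(out, 2, params$sigma + params$C, "/")
  list(normalized = out, params = params)
}

#' Invert the soft z-score
#'
#' @param normalized K x N x T normalized array.
#' @param params the parameters returned by [normalize_rates()].
#' @return The original rate array (Hz).
#' @export
denormalize_rates <- function(normalized, params) {
  sq <- sweep(normalized, 2, params$sigma + params$C, "*")
  sq <- sweep(sq, 2, params$mu, "+")
  sq^2
}

#' Linearly time-warp trials to a common template
#'
#' Builds a median trial from per-trial anchor events (for example fixation
#' touch, image onset, go cue, finger raise, stroke onset/offset, done
#' press, reward): each inter-anchor segment of each trial is linearly
#' rescaled to the median segment duration, and rates are resampled at the
#' warped times — values are unchanged, only their timing. A short Gaussian
#' smoothing (2.5 ms sd) removes discontinuities at anchor joints. Trials
#' with missing or disordered anchors are dropped and reported.
#'
#' @param rates K x N x T array on the grid `time`.
#' @param time bin centres (s).
#' @param anchors K x A matrix of anchor times per trial (columns in event
#'   order).
#' @param joint_sd smoothing sd at anchor joints (s), default 0.0025.
#' @return List: `warped` (K' x N x T' array), `template_time`,
#'   `template_anchors`, `warp_maps` (per trial, template time -> trial
#'   time), `dropped` (trial indices).
#' @export
timewarp_to_template <- function(rates, time, anchors, joint_sd = 0.0025) {
  stopifnot(length(dim(rates)) == 3, dim(rates)[1] == nrow(anchors))
  ok <- apply(anchors, 1, function(a) all(is.finite(a)) && all(diff(a) > 0))
  dropped <- which(!ok)
  anchors_ok <- anchors[ok, , drop = FALSE]
  med_dur <- apply(apply(anchors_ok, 1, diff), 1, median)
  t_anchor <- c(median(anchors_ok[, 1]), median(anchors_ok[, 1]) +
                  cumsum(med_dur))
  dt <- median(diff(time))
  template_time <- seq(t_anchor[1], t_anchor[length(t_anchor)], by = dt)
  Kp <- sum(ok); N <- dim(rates)[2]
  warped <- array(NA_real_, dim = c(Kp, N, length(template_time)))
  warp_maps <- vector("list", Kp)
  kk <- 0
  for (k in which(ok)) {
    kk <- kk + 1
    a <- anchors[k, ]
    # piecewise-linear map: template time -> trial time (anchors to anchors)
    trial_t <- approx(t_anchor, a, xout = template_time, rule = 2)$y
    warp_maps[[kk]] <- cbind(template = template_time, trial = trial_t)
    for (n in seq_len(N)) {
      v <- approx(time, rates[k, n, ], xout = trial_t, rule = 2)$y
      warped[kk, n, ] <- .gauss_smooth(v, dt, joint_sd)
    }
  }
  list(warped = warped, template_time = template_time,
       template_anchors = t_anchor, warp_maps = warp_maps, dropped = dropped)
}

.gauss_smooth <- function(v, dt, sd) {
  if (sd <= 0 || sd < dt / 10) return(v)
  half <- max(1L, ceiling(4 * sd / dt))
  kern <- dnorm(seq(-half, half) * dt, 0, sd)
  kern <- kern / sum(kern)
  n <- length(v)
  vp <- c(rep(v[1], half), v, rep(v[n], half))
  as.numeric(stats::filter(vp, kern, sides = 2))[half + seq_len(n)]
}
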