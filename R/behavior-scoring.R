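#' Raw performance factors for a trial
#'
#' Computes the unscaled scoring factors from the final drawing and the
#' target image. Image-similarity factors: `overlap`, the (feature-weighted)
#' fraction of image points touched within `touch_margin` px by at least one
#' drawn point, and `hausdorff`, the negated image distance (larger is
#' better, so all raw factors share orientation before rescaling).
#' Efficiency: negatively proportional to the excess of drawn ink over image
#' ink. For practised characters only, two task-specific factors are added:
#' similarity of stroke count to shape count, and spatial alignment of drawn
#' strokes to image shapes.
#'
#' Characteristic image features (corners and end points, found as turning
#' maxima along the image polyline) receive `feature_weight` x weight in the
#' overlap factor.
#'
#' @param strokes list of `stroke`s (the drawing).
#' @param image (n x 2) ordered image point set (px).
#' @param task_type `"single_shape"`, `"character_practised"` or
#'   `"character_novel"` (task-specific factors apply only to practised
#'   characters).
#' @param image_shapes for characters, list of per-shape point sets.
#' @param touch_margin touch tolerance (px, default 20).
#' @param feature_weight weight multiplier for characteristic features.
#' @return Named numeric vector of raw factor values (larger = better).
#' @export
compute_raw_factors <- function(strokes, image, task_type = "single_shape",
                                image_shapes = NULL, touch_margin = 20,
                                feature_weight = 2) {
  if (length(strokes) == 0) stop("compute_raw_factors: empty drawing")
  drawn <- do.call(rbind, lapply(strokes, function(s) cbind(s$x, s$y)))
  image <- as.matrix(image)
  if (nrow(image) == 0) stop("compute_raw_factors: empty image")
  w <- .feature_weights(image, feature_weight)
  touched <- min_dist_to_set(image, drawn) <= touch_margin
  overlap <- sum(w[touched]) / sum(w)
  hausdorff <- -image_distance(drawn, image)
  ink_drawn <- sum(vapply(strokes, function(s)
    sum(sqrt(diff(s$x)^2 + diff(s$y)^2)), numeric(1)))
  ink_image <- if (is.null(image_shapes)) .path_length(image) else
    sum(vapply(image_shapes, .path_length, numeric(1)))
  efficiency <- -max(0, ink_drawn - ink_image) / ink_image
  out <- c(overlap = overlap, hausdorff = hausdorff,
           efficiency = efficiency)
  if (identical(task_type, "character_practised") && !is.null(image_shapes)) {
    n_sh <- length(image_shapes)
    out["stroke_count"] <- -abs(length(strokes) - n_sh) / n_sh
    out["shape_alignment"] <- -mean(vapply(strokes, function(s) {
      min(vapply(image_shapes, function(sh)
        image_distance(cbind(s$x, s$y), sh), numeric(1)))
    }, numeric(1)))
  }
  out
}

.path_length <- function(P) sum(sqrt(rowSums(diff(as.matrix(P))^2)))

.feature_weights <- function(image, feature_weight) {
  n <- nrow(image)
  w <- rep(1, n)
  if (n >= 5) {
    d1 <- diff(image)
    ang <- atan2(d1[, 2], d1[, 1])
    turn <- abs(diff(ang))
    turn <- pmin(turn, 2 * pi - turn)
    corners <- which(turn > pi / 3) + 1L
    w[unique(c(1L, n, corners))] <- feature_weight
  } else w[c(1L, n)] <- feature_weight
  w
}

#' Adaptive rescaling bounds
#'
#' Per-factor bounds used to rescale raw factor values to \[0, 1\]: the
#' lower bound is the 1st percentile and the upper bound the 53rd percentile
#' of the raw values from the most recent `window` trials, so the dynamic
#' range of feedback tracks the dynamic range of recent performance.
#'
#' @param window history length (default 50 trials).
#' @param min_history minimum history before bounds stabilize (default 5).
#' @return An `adaptive_bounds` object (empty history).
#' @export
adaptive_bounds <- function(window = 50, min_history = 5) {
  structure(list(history = list(), window = window,
                 min_history = min_history),
            class = "adaptive_bounds")
}

#' Rescale raw factors and update bounds
#'
#' Each raw value is linearly rescaled between its factor's current bounds
#' and clamped to \[0, 1\]; the bounds are then updated with the new raw
#' value. While the history is shorter than `min_history`, bounds are
#' computed from the history including the current value. Degenerate bounds
#' (constant history) are widened symmetrically by an epsilon so the
#' rescaled value is 0.5.
#'
#' @param raw named numeric vector from [compute_raw_factors()].
#' @param bounds an [adaptive_bounds()] object.
#' @return List with `factors` (rescaled, in \[0, 1\]), `bounds` (updated)
#'   and `limits` (the lower/upper bounds used).
#' @export
update_and_rescale <- function(raw, bounds) {
  stopifnot(inherits(bounds, "adaptive_bounds"))
  f <- numeric(length(raw))
  names(f) <- names(raw)
  limits <- matrix(NA_real_, length(raw), 2,
                   dimnames = list(names(raw), c("lower", "upper")))
  for (nm in names(raw)) {
    hist <- bounds$history[[nm]]
    use <- if (length(hist) >= bounds$min_history) hist else c(hist, raw[[nm]])
    use <- tail(use, bounds$window)
    lo <- unname(quantile(use, 0.01, type = 7))
    hi <- unname(quantile(use, 0.53, type = 7))
    if (hi - lo < 1e-9) {
      eps <- max(1e-9, abs(lo) * 1e-9)
      lo <- lo - eps / 2
      hi <- hi + eps / 2
    }
    limits[nm, ] <- c(lo, hi)
    f[nm] <- min(1, max(0, (raw[[nm]] - lo) / (hi - lo)))
    bounds$history[[nm]] <- c(tail(hist, bounds$window - 1), raw[[nm]])
  }
  list(factors = f, bounds = bounds, limits = limits)
}

#' Aggregate factors into the scalar trial score
#'
#' The final score uses the worst factor after weighting:
#' `s_scal = min_i (1 - w_i (1 - f_i))`, so a weight of 0 makes a factor
#' irrelevant and a weight of 1 lets it cap the score alone. The categorical
#' score bins the scalar: great (> 0.82), good (0.65, 0.82\], OK
#' (0.15, 0.65\], fail (<= 0.15).
#'
#' @param factors rescaled factor values in \[0, 1\].
#' @param weights factor weights in \[0, 1\]; default 1 for image-similarity
#'   factors (`overlap`, `hausdorff`) and 0.5 otherwise.
#' @return List with `s_scal` and `category`.
#' @export
aggregate_score <- function(factors, weights = NULL) {
  stopifnot(length(factors) >= 1)
  if (is.null(weights)) {
    weights <- ifelse(names(factors) %in% c("overlap", "hausdorff"), 1, 0.5)
    if (is.null(names(factors))) weights <- rep(1, length(factors))
  }
  stopifnot(all(factors >= 0 & factors <= 1),
            all(weights >= 0 & weights <= 1))
  s <- min(1 - weights * (1 - factors))
  category <- if (s > 0.82) "great" else if (s > 0.65) "good" else
    if (s > 0.15) "OK" else "fail"
  list(s_scal = s, category = category)
}

#' Trial feedback from the scalar score
#'
#' Maps the scalar and categorical scores to the four feedback modalities:
#' screen colour (linear red-to-green interpolation), sound code, delay
#' before reward (linear 5 s + U(0, 2.5) jitter at score 0 down to 0 s at
#' score 1, multiplied by 0.65 unless fail), and reward — the solenoid open
#' duration `C * m * a * s_scal` with category multiplier m = 1.3 / 1.0 /
#' 0.8 / 0 (great / good / OK / fail) and random bonus
#' `a ~ 0.75 + 0.5 U(0, 1)`.
#'
#' @param s_scal scalar score in \[0, 1\].
#' @param category categorical score from [aggregate_score()].
#' @param C reward constant (s), in \[0.15, 0.6\].
#' @param a optional fixed value for the random multiplier (for
#'   reproducibility); sampled if `NULL`.
#' @param seed RNG seed (optional).
#' @return A list: `s_scal`, `category`, `reward_s`, `delay_s`, `colour`
#'   (RGB), `sound`, `m`, `a`.
#' @export
feedback <- function(s_scal, category, C = 0.3, a = NULL, seed = NULL) {
  stopifnot(C >= 0.15, C <= 0.6, s_scal >= 0, s_scal <= 1)
  with_seed(seed, {
    m <- switch(category, great = 1.3, good = 1.0, OK = 0.8, fail = 0)
    if (is.null(a)) a <- 0.75 + 0.5 * runif(1)
    reward <- C * m * a * s_scal
    delay <- (1 - s_scal) * (5 + runif(1, 0, 2.5))
    if (category != "fail") delay <- delay * 0.65
    colour <- (1 - s_scal) * c(1, 0.2, 0) + s_scal * c(0.2, 1, 0.2)
    sound <- switch(category, great = "three_pulses_1300Hz",
                    good = "pulse_1000Hz", OK = "none", fail = "pulse_120Hz")
    list(s_scal = s_scal, category = category, reward_s = reward,
         delay_s = delay, colour = colour, sound = sound, m = m, a = a)
  })
}

#' Score a trial end to end
#'
#' Convenience wrapper: raw factors -> adaptive rescaling -> aggregation ->
#' feedback, returning the updated bounds alongside the outcome (one call
#' per trial keeps the 50-trial history rolling).
#'
#' @inheritParams compute_raw_factors
#' @inheritParams feedback
#' @param bounds an [adaptive_bounds()] object carried across trials.
#' @param weights factor weights (see [aggregate_score()]).
#' @return List with `result` (the [feedback()] list plus `factors`) and
#'   `bounds` (updated).
#' @export
score_trial <- function(strokes, image, bounds, task_type = "single_shape",
                        image_shapes = NULL, weights = NULL, C = 0.3,
                        seed = NULL) {
  raw <- compute_raw_factors(strokes, image, task_type, image_shapes)
  up <- update_and_rescale(raw, bounds)
  agg <- aggregate_score(up$factors, weights)
  fb <- feedback(agg$s_scal, agg$category, C = C, seed = seed)
  fb$factors <- up$factors
  list(result = fb, bounds = up$bounds)
}
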