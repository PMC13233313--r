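.as_trajectory <- function(x, n_points = 70) {
  if (inherits(x, "trajectory_vector")) x else normalize_stroke(x, n_points)
}

#' Fit primitive templates from single-shape trials
#'
#' For each primitive, the template is the pointwise mean of the trial
#' trajectory vectors, and the match threshold `D_max` is the 97.5th
#' percentile of the trajectory distances from the source trials to the
#' template — an estimate of trial-by-trial variation under unambiguous
#' (single-shape) conditions. If all source trials are identical the
#' threshold degenerates to ~0; it is then floored at 5% of the 97.5th
#' percentile of cross-primitive template distances and flagged.
#'
#' @param trials_by_primitive named list; each element a list (>= 5) of
#'   trials for one primitive (`stroke`s or `trajectory_vector`s).
#' @param percentile threshold percentile (default 0.975).
#' @return An object of class `primitive_templates`: list with `mu`
#'   (velocity templates), `mu_pos` (mean resampled positions), `d_max`,
#'   `n_source_trials`, `degenerate`.
#' @export
fit_primitive_templates <- function(trials_by_primitive, percentile = 0.975) {
  stopifnot(length(trials_by_primitive) >= 1,
            !is.null(names(trials_by_primitive)))
  ns <- vapply(trials_by_primitive, length, integer(1))
  if (any(ns < 5)) stop("fit_primitive_templates: need >= 5 trials per ",
                        "primitive (", paste(names(ns)[ns < 5], collapse = ", "),
                        ")")
  tvs <- lapply(trials_by_primitive, function(tr) lapply(tr, .as_trajectory))
  mu <- lapply(tvs, function(tr) Reduce(`+`, lapply(tr, unclass)) / length(tr))
  mu_pos <- lapply(tvs, function(tr)
    Reduce(`+`, lapply(tr, attr, "positions")) / length(tr))
  d_max <- mapply(function(tr, m) {
    d <- vapply(tr, function(v) trajectory_distance(v, m), numeric(1))
    unname(quantile(d, percentile, type = 7))
  }, tvs, mu)
  degenerate <- d_max < 1e-12
  if (any(degenerate)) {
    if (length(mu) >= 2) {
      cross <- trajectory_distance_matrix(mu)
      floor_val <- 0.05 * quantile(cross[upper.tri(cross)], percentile,
                                   type = 7)
    } else floor_val <- 1e-3
    d_max[degenerate] <- pmax(d_max[degenerate], floor_val)
    warning("fit_primitive_templates: degenerate spread for ",
            paste(names(d_max)[degenerate], collapse = ", "),
            "; threshold floored")
  }
  structure(list(mu = mu, mu_pos = mu_pos, d_max = d_max,
                 n_source_trials = ns, degenerate = degenerate),
            class = "primitive_templates")
}

#' Classify a stroke against a primitive template set
#'
#' Assigns the best-matching primitive `p* = argmin_p d(s, mu_p)` (ties break
#' to the lowest primitive index) and scores the assignment quality `high`
#' if the distance is below that primitive's threshold, else `low` (failure
#' to match any primitive). Classification inherits the trajectory metric's
#' invariance to stroke translation and scaling.
#'
#' @param stroke a `stroke` or `trajectory_vector`.
#' @param templates a [fit_primitive_templates()] object.
#' @return A one-row data frame: `p_star`, `distance`, `quality`.
#' @export
classify_stroke <- function(stroke, templates) {
  v <- .as_trajectory(stroke)
  d <- vapply(templates$mu, function(m) trajectory_distance(v, m), numeric(1))
  i <- which.min(d)  # which.min returns the first (lowest-index) minimum
  data.frame(p_star = names(templates$mu)[i], distance = d[i],
             quality = if (d[i] < templates$d_max[i]) "high" else "low",
             stringsAsFactors = FALSE)
}

#' @rdname classify_stroke
#' @param strokes list of strokes.
#' @return `classify_strokes` returns one row per stroke with a `stroke_id`
#'   column.
#' @export
classify_strokes <- function(strokes, templates) {
  out <- do.call(rbind, lapply(strokes, classify_stroke,
                               templates = templates))
  out$stroke_id <- seq_along(strokes)
  out[, c("stroke_id", "p_star", "distance", "quality")]
}

#' Signed curvature of a planar trajectory
#'
#' The inverse of the radius of curvature,
#' kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^(3/2), computed from velocity
#' and acceleration obtained with the five-point stencil. Samples with zero
#' speed are masked (`NA`).
#'
#' @param xy a `stroke` or an (n x 2) position matrix.
#' @param h sampling period; defaults to the stroke's period (or 1 for bare
#'   matrices).
#' @return Numeric vector of signed curvature per sample (units 1/length).
#' @export
curvature <- function(xy, h = NULL) {
  if (inherits(xy, "stroke")) {
    if (is.null(h)) h <- 1 / attr(xy, "fs")
    x <- xy$x; y <- xy$y
  } else {
    if (is.null(h)) h <- 1
    x <- xy[, 1]; y <- xy[, 2]
  }
  vx <- differentiate_five_point(x, h)
  vy <- differentiate_five_point(y, h)
  ax <- differentiate_five_point(vx, h)
  ay <- differentiate_five_point(vy, h)
  sp2 <- vx^2 + vy^2
  k <- (vx * ay - vy * ax) / sp2^1.5
  k[sp2 < 1e-24] <- NA_real_
  k
}

#' Does a polyline properly cross itself?
#'
#' Segment pairs closer than `adj_window` indices apart are ignored
#' (numerical grazing of neighbours).
#'
#' @param P polyline as an (n x 2) matrix.
#' @param adj_window adjacency window (default 2).
#' @return Logical.
#' @export
self_intersects <- function(P, adj_window = 2) {
  n <- nrow(P) - 1L
  if (n < 3) return(FALSE)
  for (i in seq_len(n - 1)) {
    js <- seq.int(i + adj_window + 1L, n)
    js <- js[js <= n]
    if (!length(js)) next
    if (count_crossings(P[c(i, i + 1L), , drop = FALSE],
                        P[min(js):(n + 1L), , drop = FALSE]) > 0)
      return(TRUE)
  }
  FALSE
}

# Blend the first half of curve A (by distance travelled) with the second
# half of curve B: offset-align, then cross-fade with a logistic weight over
# the 10% of arc length around the junction.
.blend_halves <- function(A, B, n = 100, blend_frac = 0.1) {
  Ad <- resample_polyline(A, n)
  Bd <- resample_polyline(B, n)
  half <- n %/% 2
  A1 <- Ad[1:half, , drop = FALSE]
  B2 <- Bd[(half + 1):n, , drop = FALSE]
  B2 <- sweep(B2, 2, A1[half, ] - B2[1, ], "+")
  s <- seq(0, 1, length.out = n)
  tanA <- A1[half, ] - A1[half - 1, ]
  tanB <- B2[2, ] - B2[1, ]
  ds <- 1 / (n - 1)
  posA <- function(si) {
    if (si <= 0.5) .point_at_fraction(A1, si / 0.5)
    else A1[half, ] + tanA / sqrt(sum(tanA^2)) * (si - 0.5) * 0.5
  }
  posB <- function(si) {
    if (si >= 0.5) .point_at_fraction(B2, (si - 0.5) / 0.5)
    else B2[1, ] - tanB / sqrt(sum(tanB^2)) * (0.5 - si) * 0.5
  }
  w <- stats::plogis((s - 0.5) / (blend_frac / 8))
  out <- t(vapply(seq_len(n), function(i)
    (1 - w[i]) * posA(s[i]) + w[i] * posB(s[i]), numeric(2)))
  out
}

#' Generate a remixed-primitive control set
#'
#' Builds simulated primitives that resemble the actual primitives in their
#' subparts but not their whole trajectories: each candidate joins the first
#' half of one primitive (by distance travelled) to the second half of
#' another, offset-aligned and sigmoid-blended at the junction. Candidates
#' are rejected if self-intersecting or if |curvature| anywhere on the inner
#' 80% of the (render-scale) stroke exceeds `max_kappa`. Accepted sets must
#' additionally satisfy: each donor half used at most twice, and every
#' remixed-remixed and remixed-actual trajectory distance at least the
#' minimum actual-actual distance.
#'
#' @param templates a [fit_primitive_templates()] object (the actual
#'   primitives; >= 2).
#' @param n_remixed number of remixed primitives to sample.
#' @param seed RNG seed.
#' @param max_kappa curvature bound (1/px at render scale; default 0.8).
#' @param render_size scale (bounding-box diagonal, px) at which the
#'   curvature bound is applied.
#' @param max_attempts sampling budget.
#' @return An object of class `remixed_set`: list of remixed primitives
#'   (each with `first_donor`, `second_donor`, `curve`, `tv`), with the
#'   distance floor in attribute `min_actual_dist`.
#' @export
generate_remixed_set <- function(templates, n_remixed, seed = 1,
                                 max_kappa = 0.8, render_size = 134,
                                 max_attempts = 500) {
  prims <- names(templates$mu)
  if (length(prims) < 2) stop("generate_remixed_set: need >= 2 primitives")
  act_D <- trajectory_distance_matrix(templates$mu)
  floor_d <- min(act_D[upper.tri(act_D)])
  pool <- expand.grid(first = prims, second = prims,
                      stringsAsFactors = FALSE)
  pool <- pool[pool$first != pool$second, ]
  with_seed(seed, {
    ord <- sample(nrow(pool))
    accepted <- list()
    use_first <- setNames(integer(length(prims)), prims)
    use_second <- setNames(integer(length(prims)), prims)
    att <- 0
    for (r in ord) {
      if (length(accepted) >= n_remixed) break
      att <- att + 1
      if (att > max_attempts) break
      a <- pool$first[r]; b <- pool$second[r]
      if (use_first[a] >= 2 || use_second[b] >= 2) next
      curve <- .blend_halves(templates$mu_pos[[a]], templates$mu_pos[[b]])
      if (self_intersects(curve)) next
      kap <- curvature(curve * render_size /
                         sqrt(diff(range(curve[, 1]))^2 +
                                diff(range(curve[, 2]))^2))
      inner <- seq(ceiling(0.1 * length(kap)), floor(0.9 * length(kap)))
      if (any(abs(kap[inner]) > max_kappa, na.rm = TRUE)) next
      tv <- normalize_stroke(curve)
      d_act <- vapply(templates$mu, function(m) trajectory_distance(tv, m),
                      numeric(1))
      if (any(d_act < floor_d)) next
      d_rem <- vapply(accepted, function(x) trajectory_distance(tv, x$tv),
                      numeric(1))
      if (length(d_rem) && any(d_rem < floor_d)) next
      accepted[[length(accepted) + 1]] <-
        list(first_donor = a, second_donor = b, curve = curve, tv = tv)
      use_first[a] <- use_first[a] + 1
      use_second[b] <- use_second[b] + 1
    }
    if (length(accepted) < n_remixed)
      stop("generate_remixed_set: constraints unsatisfiable for n_remixed = ",
           n_remixed, " (accepted ", length(accepted), ")")
    structure(accepted, min_actual_dist = floor_d, class = "remixed_set")
  })
}

#' Turn a remixed set into a classifiable template set
#'
#' Remixed primitives were never drawn, so no empirical threshold exists;
#' thresholds are inherited from the pool of actual-primitive thresholds in
#' the most lenient way: the largest actual threshold goes to the
#' worst-matching remixed primitive (largest mean trajectory distance to the
#' supplied strokes), the second largest to the second worst, and so on.
#'
#' @param remixed a [generate_remixed_set()] object.
#' @param templates the actual-primitive templates supplying the thresholds.
#' @param strokes character strokes (list) used to rank remixed primitives
#'   by match quality.
#' @return A `primitive_templates` object for the remixed set.
#' @export
remixed_templates <- function(remixed, templates, strokes) {
  tvs <- lapply(strokes, .as_trajectory)
  mean_d <- vapply(remixed, function(rp)
    mean(vapply(tvs, function(v) trajectory_distance(v, rp$tv), numeric(1))),
    numeric(1))
  thr <- sort(templates$d_max, decreasing = TRUE)
  thr <- rep_len(thr, length(remixed))
  d_max <- numeric(length(remixed))
  d_max[order(mean_d, decreasing = TRUE)] <- thr[seq_along(remixed)]
  mu <- lapply(remixed, function(rp) unclass(rp$tv))
  names(mu) <- sprintf("remix%02d", seq_along(remixed))
  structure(list(mu = mu,
                 mu_pos = lapply(remixed, function(rp)
                   attr(rp$tv, "positions")),
                 d_max = setNames(d_max, names(mu)),
                 n_source_trials = setNames(rep(0L, length(mu)), names(mu)),
                 degenerate = setNames(rep(FALSE, length(mu)), names(mu))),
            class = "primitive_templates")
}

#' Primitive-reuse analysis of character strokes
#'
#' Classifies character strokes against several template sets (own, foreign,
#' remixed, ...) and reports the fraction of high-quality matches per set
#' with bootstrap confidence intervals (percentile method, resampling
#' characters), plus the per-primitive match frequency distribution for each
#' set.
#'
#' @param strokes list of character strokes.
#' @param template_sets named list of `primitive_templates`.
#' @param character_ids character id per stroke (bootstrap resampling unit);
#'   defaults to one character per stroke.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return List with `match_fraction` (data frame: set, fraction, ci_lo,
#'   ci_hi), `classifications` (per set) and `frequencies` (per set, counts
#'   of high-quality matches by primitive).
#' @export
reuse_analysis <- function(strokes, template_sets,
                           character_ids = seq_along(strokes),
                           n_boot = 1000, seed = 1) {
  tvs <- lapply(strokes, .as_trajectory)
  cls <- lapply(template_sets, function(tm) classify_strokes(tvs, tm))
  chars <- unique(character_ids)
  frac <- lapply(names(template_sets), function(nm) {
    hi <- cls[[nm]]$quality == "high"
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      pick <- sample(chars, replace = TRUE)
      idx <- unlist(lapply(pick, function(ch) which(character_ids == ch)))
      mean(hi[idx])
    }, numeric(1)))
    data.frame(set = nm, fraction = mean(hi),
               ci_lo = unname(quantile(boot, 0.025)),
               ci_hi = unname(quantile(boot, 0.975)))
  })
  freqs <- lapply(cls, function(cl)
    table(factor(cl$p_star[cl$quality == "high"],
                 levels = unique(cl$p_star))))
  list(match_fraction = do.call(rbind, frac), classifications = cls,
       frequencies = freqs)
}

#' Pairwise kinematic decoding of primitives
#'
#' Quantifies single-trial kinematic separability: each stroke is normalized
#' in time (linear interpolation to `n_time` points) and space (unit
#' bounding-box diagonal, aspect preserved), the concatenated (x, y)
#' coordinates are reduced to `n_pcs` principal components, and every pair
#' of primitives is decoded with a linear max-margin classifier under
#' 10-fold cross-validation.
#'
#' @param strokes list of `stroke`s.
#' @param labels primitive label per stroke.
#' @param n_time time-normalization length (default 50).
#' @param n_pcs retained principal components (default 8).
#' @param folds cross-validation folds (default 10).
#' @param cost SVM regularization parameter (default 0.1).
#' @param min_trials classes with fewer trials are skipped with a warning.
#' @return Symmetric matrix of pairwise decoding accuracies (`NA` diagonal).
#' @export
pairwise_kinematic_decoding <- function(strokes, labels, n_time = 50,
                                        n_pcs = 8, folds = 10, cost = 0.1,
                                        min_trials = 10) {
  stopifnot(length(strokes) == length(labels))
  labels <- as.character(labels)
  counts <- table(labels)
  skip <- names(counts)[counts < min_trials]
  if (length(skip)) {
    warning("pairwise_kinematic_decoding: skipping classes with < ",
            min_trials, " trials: ", paste(skip, collapse = ", "))
    keep <- !(labels %in% skip)
    strokes <- strokes[keep]; labels <- labels[keep]
  }
  classes <- unique(labels)
  if (length(classes) < 2)
    stop("pairwise_kinematic_decoding: need >= 2 primitives")
  X <- t(vapply(strokes, function(s) {
    ti <- seq(s$t[1], s$t[nrow(s)], length.out = n_time)
    x <- approx(s$t, s$x, xout = ti)$y
    y <- approx(s$t, s$y, xout = ti)$y
    dl <- sqrt(diff(range(x))^2 + diff(range(y))^2)
    c(x - mean(x), y - mean(y)) / dl
  }, numeric(2 * n_time)))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  Z <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  acc <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(classes, classes))
  for (i in seq_along(classes)[-length(classes)]) {
    for (j in (i + 1):length(classes)) {
      sel <- labels %in% classes[c(i, j)]
      fit <- e1071::svm(Z[sel, , drop = FALSE], factor(labels[sel]),
                        kernel = "linear", cost = cost, scale = FALSE,
                        cross = folds)
      acc[i, j] <- acc[j, i] <- fit$tot.accuracy / 100
    }
  }
  acc
}
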