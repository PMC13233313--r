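#' Normalize a stroke to a trajectory vector
#'
#' Converts a stroke into the fixed-length velocity representation used by the
#' trajectory distance: the stroke is rescaled (preserving aspect ratio) so
#' its bounding-box diagonal has unit length, resampled to `n_points` points
#' equally spaced in cumulative arc length (removing timing information), and
#' differentiated with the five-point stencil (unit step) to give a velocity
#' series. The representation is therefore invariant to translation, uniform
#' scaling and monotone time reparameterization.
#'
#' @param stroke a `stroke` object, or any two-column matrix/data frame of
#'   (x, y) positions tracing the path.
#' @param n_points number of resampled points (default 70).
#' @return A `trajectory_vector`: an `n_points` x 2 velocity matrix with the
#'   resampled unit-scale positions stored in attribute `positions`.
#' @export
normalize_stroke <- function(stroke, n_points = 70) {
  P <- if (is.data.frame(stroke)) cbind(stroke$x, stroke$y) else
    as.matrix(stroke)[, 1:2, drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(P))) > 0)
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 2) stop("normalize_stroke: degenerate stroke (zero extent)")
  if (sqrt(diff(range(P[, 1]))^2 + diff(range(P[, 2]))^2) <= 0)
    stop("normalize_stroke: degenerate stroke (zero extent)")
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg)) / sum(seg)
  target <- seq(0, 1, length.out = n_points)
  pos <- cbind(approx(s, P[, 1], xout = target, ties = "ordered")$y,
               approx(s, P[, 2], xout = target, ties = "ordered")$y)
  # rescale the resampled positions themselves so the contract is exact;
  # centring makes the stored positions translation-invariant too
  pos <- pos / sqrt(diff(range(pos[, 1]))^2 + diff(range(pos[, 2]))^2)
  pos <- sweep(pos, 2, colMeans(pos))
  h <- 1 / (n_points - 1)  # resampled stroke spans one unit of normalized time
  v <- cbind(differentiate_five_point(pos[, 1], h),
             differentiate_five_point(pos[, 2], h))
  structure(v, positions = pos, class = c("trajectory_vector", class(v)))
}

#' Trajectory distance between two strokes
#'
#' Regularized dynamic-time-warping dissimilarity between two normalized
#' velocity series. The local cost is the Euclidean distance between velocity
#' samples plus a warping penalty `lambda * |i - j|`, with
#' `lambda = lambda_coeff * <|v|>` where the mean absolute velocity is taken
#' over both inputs so the penalty matches the velocity magnitude. The best
#' monotone path cost from (1, 1) to (N, N) (steps right/up/diagonal) is
#' divided by N and squashed to \[0, 1) via `1 - 1/(D + 1)`.
#'
#' @param v1,v2 `trajectory_vector`s (or velocity matrices) of equal length.
#' @param lambda_coeff regularization multiplier on mean speed
#'   (default 0.045).
#' @param rescale if `FALSE`, return the raw per-point DTW cost instead of
#'   the \[0, 1) rescaled distance.
#' @return Scalar trajectory distance in \[0, 1).
#' @export
trajectory_distance <- function(v1, v2, lambda_coeff = 0.045, rescale = TRUE) {
  v1 <- unclass(v1); v2 <- unclass(v2)
  if (nrow(v1) != nrow(v2))
    stop("trajectory_distance: velocity series must have equal length")
  lambda <- lambda_coeff * mean(c(sqrt(rowSums(v1^2)), sqrt(rowSums(v2^2))))
  d_dtw <- dtw_path_cost(v1, v2, lambda) / nrow(v1)
  if (!rescale) return(d_dtw)
  1 - 1 / (d_dtw + 1)
}

#' Pairwise trajectory-distance matrix
#'
#' @param vs list of `trajectory_vector`s.
#' @param ... passed to [trajectory_distance()].
#' @return Symmetric matrix of pairwise distances with zero diagonal.
#' @export
trajectory_distance_matrix <- function(vs, ...) {
  n <- length(vs)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- trajectory_distance(vs[[i]], vs[[j]], ...)
  dimnames(D) <- list(names(vs), names(vs))
  D
}

#' Modified Hausdorff image distance
#'
#' Distance between two images represented as 2-D point sets. Each set is
#' centred on its own centre of mass; the directed distance from A to B is
#' the mean over points of A of the distance to the nearest point of B, and
#' the image distance is the average of the two directed distances. Taking
#' means instead of maxima makes the metric robust to outlier points.
#'
#' @param A,B numeric matrices (n x 2) of point coordinates (px).
#' @return Scalar distance (px); zero iff the centred sets coincide.
#' @export
image_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("image_distance: empty point set")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  (mean(min_dist_to_set(A, B)) + mean(min_dist_to_set(B, A))) / 2
}

.pair_distance <- function(x, y, metric, ...) {
  switch(metric,
         trajectory = trajectory_distance(x, y, ...),
         image = image_distance(x, y),
         euclidean = sqrt(sum((as.numeric(x) - as.numeric(y))^2)),
         stop("unknown metric: ", metric))
}

#' Primitive alignment score
#'
#' Relative similarity of a trial datum to two reference primitive trial
#' sets: `a = d1 / (d1 + d2)`, where `d1` and `d2` are the mean distances
#' from the datum to the P1 and P2 reference trials. A score near 0 means
#' P1-like, near 1 means P2-like. The same score applies to drawings
#' (trajectory metric), images (image metric) and neural population vectors
#' (Euclidean metric).
#'
#' @param datum one trial's data (a `trajectory_vector`, point set, or
#'   numeric vector depending on `metric`).
#' @param ref_p1,ref_p2 non-empty lists of reference trials for the two
#'   primitives.
#' @param metric one of `"trajectory"`, `"image"`, `"euclidean"`.
#' @param ... passed to the underlying distance.
#' @return A list with elements `a`, `d1`, `d2`, `metric`, `degenerate`
#'   (`TRUE` when `d1 + d2 == 0`, in which case `a = 0.5`).
#' @export
primitive_alignment <- function(datum, ref_p1, ref_p2,
                                metric = c("trajectory", "image", "euclidean"),
                                ...) {
  metric <- match.arg(metric)
  if (!is.list(ref_p1)) ref_p1 <- list(ref_p1)
  if (!is.list(ref_p2)) ref_p2 <- list(ref_p2)
  stopifnot(length(ref_p1) > 0, length(ref_p2) > 0)
  d1 <- mean(vapply(ref_p1, function(r) .pair_distance(datum, r, metric, ...),
                    numeric(1)))
  d2 <- mean(vapply(ref_p2, function(r) .pair_distance(datum, r, metric, ...),
                    numeric(1)))
  if (d1 + d2 == 0) {
    return(list(a = 0.5, d1 = d1, d2 = d2, metric = metric, degenerate = TRUE))
  }
  list(a = d1 / (d1 + d2), d1 = d1, d2 = d2, metric = metric,
       degenerate = FALSE)
}

#' Locate the category boundary of a morph set
#'
#' The boundary is the morph level exhibiting discrete trial-by-trial
#' switching between the two primitives: among levels with at least two
#' trials whose alignment scores are bimodal (scores both below `lo` and
#' above `hi` present), the level whose mean alignment is closest to 0.5 is
#' returned; ties break toward the level with the larger minority class.
#'
#' Because drawing-based alignments never reach 0 and 1 (trial-by-trial
#' variation puts a floor under both reference distances), the cutoffs are
#' applied on the endpoint-normalized scale: scores are linearly mapped so
#' the mean alignment of the first morph level (P1 end) is 0 and of the last
#' level (P2 end) is 1. Set `normalize = FALSE` to apply `lo`/`hi` to the
#' raw scores.
#'
#' @param alignments data frame with columns `morph_level` and `a`
#'   (single-trial alignment scores).
#' @param lo,hi bimodality cutoffs (defaults 0.35 and 0.65).
#' @param normalize rescale scores to the practised end points first.
#' @return The boundary morph level, or `NA` if no level qualifies (for
#'   example under a tracing policy).
#' @export
find_category_boundary <- function(alignments, lo = 0.35, hi = 0.65,
                                   normalize = TRUE) {
  lv <- split(alignments$a, alignments$morph_level)
  lv <- lv[vapply(lv, length, integer(1)) >= 2]
  if (length(lv) < 3)
    stop("find_category_boundary: need >= 3 morph levels with >= 2 trials")
  if (normalize) {
    qa <- mean(lv[[1]])
    qb <- mean(lv[[length(lv)]])
    if (qb != qa) lv <- lapply(lv, function(a) (a - qa) / (qb - qa))
  }
  bimodal <- vapply(lv, function(a) any(a < lo) && any(a > hi), logical(1))
  if (!any(bimodal)) return(NA)
  cand <- lv[bimodal]
  dist05 <- vapply(cand, function(a) abs(mean(a) - 0.5), numeric(1))
  best <- which(dist05 == min(dist05))
  if (length(best) > 1) {
    minority <- vapply(cand[best], function(a)
      min(sum(a < 0.5), sum(a >= 0.5)), numeric(1))
    best <- best[which.max(minority)]
  } else best <- best[1]
  lev <- names(cand)[best]
  # restore numeric type when levels are numeric
  if (!is.na(suppressWarnings(as.numeric(lev)))) as.numeric(lev) else lev
}

#' Hallmark tests for categorical structure
#'
#' Tests the two behavioural/neural hallmarks of categorical structure across
#' morph sets: (i) sigmoidal nonlinearity — drawing-based alignment below the
#' image-based alignment at U1 and above it at U2; and (ii) trial-by-trial
#' switching — alignment of A2 trials (boundary trials drawn as primitive 2)
#' above A1 trials. Effects are compared across morph sets with two-sided
#' Wilcoxon signed-rank tests; the reported `W` is the smaller signed-rank
#' sum, so a uniformly positive effect across sets gives `W = 0`.
#'
#' @param set_summary data frame with one row per morph set and columns
#'   `drawing_U1`, `drawing_U2`, `image_U1`, `image_U2` (mean alignments) and
#'   optionally `drawing_A1`, `drawing_A2` (sets lacking a boundary morph may
#'   carry `NA` there and are excluded from the switching test).
#' @return A list with per-set effect sizes (`nonlinearity_effect`,
#'   `switching_effect`), per-set hallmark indicators, signed-rank statistics
#'   and p values, and a `low_power` flag when fewer than 5 sets enter a test.
#' @export
categorical_structure_test <- function(set_summary) {
  need <- c("drawing_U1", "drawing_U2", "image_U1", "image_U2")
  stopifnot(all(need %in% names(set_summary)))
  nl <- ((set_summary$image_U1 - set_summary$drawing_U1) +
           (set_summary$drawing_U2 - set_summary$image_U2)) / 2
  hall_nl <- (set_summary$drawing_U1 < set_summary$image_U1) &
    (set_summary$drawing_U2 > set_summary$image_U2)
  res <- list(nonlinearity_effect = nl,
              hallmark_nonlinearity = hall_nl,
              nonlinearity = .signed_rank(nl))
  if (all(c("drawing_A1", "drawing_A2") %in% names(set_summary))) {
    sw <- set_summary$drawing_A2 - set_summary$drawing_A1
    ok <- !is.na(sw)
    res$switching_effect <- sw
    res$hallmark_switching <- sw > 0
    res$switching <- .signed_rank(sw[ok])
  }
  res$n_sets <- nrow(set_summary)
  res$low_power <- nrow(set_summary) < 5
  res
}

.signed_rank <- function(x) {
  x <- x[!is.na(x) & x != 0]
  if (length(x) < 1) return(list(W = NA_real_, p = NA_real_, n = 0L))
  wt <- suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE))
  v <- unname(wt$statistic)
  n <- length(x)
  list(W = min(v, n * (n + 1) / 2 - v), p = wt$p.value, n = n)
}

#' Write a labelled square distance matrix to CSV
#'
#' @param D square matrix with dimnames.
#' @param path file path.
#' @export
write_distance_csv <- function(D, path) {
  write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}
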