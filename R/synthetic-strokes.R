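#' Simulate one noisy stroke of a primitive
#'
#' Emulates a trial's touchscreen trace of a primitive: the canonical curve
#' is scaled and translated, traversed at (nominally) constant speed over a
#' lognormally jittered duration, sampled at the touchscreen rate, and
#' perturbed by low-pass-filtered Gaussian positional jitter. With zero noise
#' the samples lie exactly on the transformed canonical curve.
#'
#' @param prim a [primitive_spec()].
#' @param location 2-D centre offset (px).
#' @param size bounding-box diagonal of the drawn shape (px); must be > 0.
#' @param noise list with `pos_sd` (px, sd of smooth positional jitter) and
#'   `dur_cv` (sd of log duration scaling).
#' @param seed RNG seed (optional).
#' @param fs sampling rate (Hz), 60 by default.
#' @param base_duration nominal stroke duration (s).
#' @param t0 time of stroke onset (s).
#' @return A `stroke` object (columns `t`, `x`, `y`) sampled at `fs`.
#' @export
sample_stroke <- function(prim, location = c(0, 0), size = 134,
                          noise = list(pos_sd = 2, dur_cv = 0.15),
                          seed = NULL, fs = 60, base_duration = 0.7, t0 = 0) {
  if (size <= 0) stop("sample_stroke: size must be positive")
  pos_sd <- if (is.null(noise$pos_sd)) 0 else noise$pos_sd
  dur_cv <- if (is.null(noise$dur_cv)) 0 else noise$dur_cv
  with_seed(seed, {
    dur <- base_duration * exp(rnorm(1, 0, dur_cv))
    n <- max(6L, as.integer(round(dur * fs)) + 1L)
    t <- t0 + (seq_len(n) - 1) / fs
    P <- resample_polyline(prim$canonical_curve, n) * size
    P <- sweep(P, 2, location, "+")
    if (pos_sd > 0) {
      for (k in 1:2) {
        j <- lowpass_zero_phase(rnorm(n), 5, fs)
        s <- sd(j)
        if (s > 0) P[, k] <- P[, k] + j * (pos_sd / s)
      }
    }
    new_stroke(t, P[, 1], P[, 2], fs = fs)
  })
}

#' Assemble strokes into a raw touch series
#'
#' Concatenates strokes with non-touching gap samples between them (the
#' finger travelling between stroke end and next stroke start), producing the
#' raw 60 Hz series that [preprocess_touch_series()] and [segment_strokes()]
#' consume.
#'
#' @param strokes list of `stroke` objects.
#' @param gap inter-stroke air time (s).
#' @param fs sampling rate (Hz).
#' @param lead,trail non-touching padding before the first / after the last
#'   stroke (s).
#' @return A [touch_series()].
#' @export
strokes_to_touch_series <- function(strokes, gap = 0.25, fs = 60,
                                    lead = 0.2, trail = 0.2) {
  stopifnot(length(strokes) >= 1)
  t <- numeric(0); x <- numeric(0); y <- numeric(0); tch <- logical(0)
  cur <- 0
  first <- strokes[[1]]
  n_lead <- max(1L, round(lead * fs))
  t <- c(t, cur + (seq_len(n_lead) - 1) / fs)
  x <- c(x, rep(first$x[1], n_lead)); y <- c(y, rep(first$y[1], n_lead))
  tch <- c(tch, rep(FALSE, n_lead))
  cur <- cur + n_lead / fs
  for (i in seq_along(strokes)) {
    s <- strokes[[i]]
    ns <- nrow(s)
    t <- c(t, cur + (seq_len(ns) - 1) / fs)
    x <- c(x, s$x); y <- c(y, s$y)
    tch <- c(tch, rep(TRUE, ns))
    cur <- cur + ns / fs
    if (i < length(strokes)) {
      ng <- max(1L, round(gap * fs))
      nxt <- strokes[[i + 1]]
      t <- c(t, cur + (seq_len(ng) - 1) / fs)
      x <- c(x, seq(s$x[ns], nxt$x[1], length.out = ng))
      y <- c(y, seq(s$y[ns], nxt$y[1], length.out = ng))
      tch <- c(tch, rep(FALSE, ng))
      cur <- cur + ng / fs
    }
  }
  nt <- max(1L, round(trail * fs))
  last <- strokes[[length(strokes)]]
  t <- c(t, cur + (seq_len(nt) - 1) / fs)
  x <- c(x, rep(last$x[nrow(last)], nt)); y <- c(y, rep(last$y[nrow(last)], nt))
  tch <- c(tch, rep(FALSE, nt))
  touch_series(t, x, y, tch, fs = fs)
}

#' Simulate drawing behaviour over a morph set
#'
#' Emulates the two hypothesized drawing policies for morphed images. The
#' categorical policy draws the primitive whose side of the category boundary
#' the morph falls on, with a stochastic 50/50 mixture exactly at the
#' boundary morph (discrete trial-by-trial switching). The tracing policy
#' draws the interpolated shape itself, so drawing variation follows image
#' variation continuously.
#'
#' @param morph_set a [make_morph_set()] object.
#' @param policy `"categorical"` or `"tracing"`.
#' @param boundary_fraction category boundary in (0, 1); the closest morph
#'   fraction becomes the boundary (A) morph.
#' @param n_trials trials per morph level.
#' @param noise stroke noise parameters (see [sample_stroke()]).
#' @param seed RNG seed.
#' @return List with `trials` (data frame: `trial_id`, `morph_fraction`,
#'   `condition`, `drawn_primitive`) and `strokes` (list of `stroke`s).
#' @export
simulate_drawing_policy <- function(morph_set,
                                    policy = c("categorical", "tracing"),
                                    boundary_fraction = 0.5, n_trials = 10,
                                    noise = list(pos_sd = 2, dur_cv = 0.1),
                                    seed = 1) {
  policy <- match.arg(policy)
  stopifnot(boundary_fraction > 0, boundary_fraction < 1)
  fr <- morph_set$fractions
  cond <- morph_condition_labels(fr, boundary_fraction)
  with_seed(seed, {
    rows <- list(); strokes <- list(); id <- 0L
    for (k in seq_along(fr)) {
      for (tr in seq_len(n_trials)) {
        id <- id + 1L
        if (policy == "tracing") {
          spec <- morph_set$specs[[k]]
          drawn <- if (fr[k] <= 0.5) "P1" else "P2"
        } else {
          use_a <- if (cond[k] == "A") runif(1) < 0.5 else fr[k] < boundary_fraction
          spec <- if (use_a) morph_set$prim_a else morph_set$prim_b
          drawn <- if (use_a) "P1" else "P2"
        }
        strokes[[id]] <- sample_stroke(spec, location = morph_set$location,
                                       size = morph_set$size, noise = noise)
        rows[[id]] <- data.frame(trial_id = id, morph_fraction = fr[k],
                                 condition = cond[k], drawn_primitive = drawn)
      }
    }
    list(trials = do.call(rbind, rows), strokes = strokes,
         policy = policy, morph_set = morph_set)
  })
}

#' Count proper crossings between two polylines
#'
#' Shared endpoints and tangent contacts are not counted.
#'
#' @param P,Q polylines as (n x 2) matrices.
#' @return Integer crossing count.
#' @export
count_crossings <- function(P, Q) {
  np <- nrow(P) - 1L; nq <- nrow(Q) - 1L
  i <- rep(seq_len(np), each = nq); j <- rep(seq_len(nq), times = np)
  p1x <- P[i, 1]; p1y <- P[i, 2]; p2x <- P[i + 1, 1]; p2y <- P[i + 1, 2]
  q1x <- Q[j, 1]; q1y <- Q[j, 2]; q2x <- Q[j + 1, 1]; q2y <- Q[j + 1, 2]
  d1 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
  d2 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
  d3 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
  d4 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
  sum(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Sample a multi-shape character
#'
#' Generates a character image by chaining `n_shapes` primitives with
#' `n_shapes - 1` relations, each relation placing an attachment point of
#' shape i+1 onto an attachment point of shape i (attachment points are
#' arc-length fractions along each curve). Candidates are rejection-sampled
#' until the crossing filter passes: no pair of distinct shape curves may
#' properly cross more than `max_cross` times.
#'
#' @param library list of [primitive_spec()]s to sample shapes from.
#' @param n_shapes number of component shapes (2-6).
#' @param seed RNG seed.
#' @param size per-shape bounding-box diagonal (px).
#' @param max_cross maximum allowed crossings per shape pair (default 1,
#'   which also accommodates the by-construction contact at the attachment).
#' @param max_attempts rejection-sampling budget.
#' @return A `character_spec`: list with `n_shapes`, `shapes`, `relations`
#'   (data frame of attachment fractions), `curves` (placed per-shape
#'   curves), `image` (merged point set) and `ground_truth_segmentation`
#'   (shape index per image point).
#' @export
sample_character <- function(library, n_shapes, seed = 1, size = 100,
                             max_cross = 1, max_attempts = 2000) {
  stopifnot(n_shapes >= 2, n_shapes <= 6)
  with_seed(seed, {
    for (att in seq_len(max_attempts)) {
      idx <- sample(length(library), n_shapes, replace = TRUE)
      shapes <- library[idx]
      rel <- data.frame(on_prev = runif(n_shapes - 1),
                        on_next = runif(n_shapes - 1))
      curves <- vector("list", n_shapes)
      curves[[1]] <- resample_polyline(shapes[[1]]$canonical_curve, 50) * size
      ok <- TRUE
      for (i in 2:n_shapes) {
        cur <- resample_polyline(shapes[[i]]$canonical_curve, 50) * size
        anchor_prev <- .point_at_fraction(curves[[i - 1]], rel$on_prev[i - 1])
        anchor_cur <- .point_at_fraction(cur, rel$on_next[i - 1])
        curves[[i]] <- sweep(cur, 2, anchor_prev - anchor_cur, "+")
      }
      for (a in 1:(n_shapes - 1)) {
        for (b in (a + 1):n_shapes) {
          if (count_crossings(curves[[a]], curves[[b]]) > max_cross) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        image <- do.call(rbind, curves)
        seg <- rep(seq_len(n_shapes), each = nrow(curves[[1]]))
        return(structure(list(n_shapes = n_shapes, shapes = shapes,
                              shape_ids = names(library)[idx],
                              relations = rel, curves = curves,
                              image = image,
                              ground_truth_segmentation = seg, size = size),
                         class = "character_spec"))
      }
    }
    stop("sample_character: crossing filter not satisfied in ",
         max_attempts, " attempts")
  })
}

.point_at_fraction <- function(P, f) {
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg)) / sum(seg)
  c(approx(s, P[, 1], xout = f, ties = "ordered")$y,
    approx(s, P[, 2], xout = f, ties = "ordered")$y)
}

#' Replay a character's strokes from ground truth
#'
#' Draws each component shape of a character as one noisy stroke at its
#' placed location and size, in shape order — the ground-truth multi-stroke
#' drawing of the character.
#'
#' @param char a `character_spec`.
#' @param noise,seed stroke noise parameters (see [sample_stroke()]).
#' @return List of `stroke`s, one per component shape, with the source
#'   primitive ids in attribute `source_primitives`.
#' @export
character_strokes <- function(char, noise = list(pos_sd = 2, dur_cv = 0.1),
                              seed = 1) {
  with_seed(seed, {
    out <- lapply(seq_len(char$n_shapes), function(i) {
      P <- char$curves[[i]]
      ctr <- colMeans(P)
      diag_len <- sqrt(diff(range(P[, 1]))^2 + diff(range(P[, 2]))^2)
      sample_stroke(char$shapes[[i]], location = ctr, size = diag_len,
                    noise = noise)
    })
    attr(out, "source_primitives") <- char$shape_ids
    out
  })
}
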