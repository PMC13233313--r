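# Seed hygiene: generators restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Primitive specification
#'
#' A stroke primitive is a canonical planar curve defined by a small set of
#' named control parameters: initial heading `theta0` (rad), total turning
#' `turn` (rad), and a sinusoidal curvature modulation (`amp`, `phase`,
#' `freq`). The curve is traced by integrating the heading over arc length,
#' then centred and rescaled to unit bounding-box diagonal. Because the curve
#' is a deterministic function of its parameters, morphing between two
#' primitives is literal linear interpolation of control parameters.
#'
#' @param primitive_id label for the primitive.
#' @param control_params named numeric vector with entries `theta0`, `turn`,
#'   `amp`, `phase`, `freq`.
#' @param n_points number of points on the canonical curve (>= 10).
#' @return An object of class `primitive_spec` with fields `primitive_id`,
#'   `control_params` and `canonical_curve` (an `n_points` x 2 matrix).
#' @export
primitive_spec <- function(primitive_id, control_params, n_points = 100) {
  need <- c("theta0", "turn", "amp", "phase", "freq")
  stopifnot(all(need %in% names(control_params)), n_points >= 10)
  curve <- primitive_curve(control_params, n_points)
  structure(list(primitive_id = primitive_id,
                 control_params = control_params[need],
                 canonical_curve = curve),
            class = "primitive_spec")
}

#' Canonical curve from control parameters
#'
#' @param params named control parameters (see [primitive_spec()]).
#' @param n_points number of curve points.
#' @return Matrix of (x, y) positions, centred, unit bounding-box diagonal,
#'   with consecutive points distinct.
#' @export
primitive_curve <- function(params, n_points = 100) {
  s <- seq(0, 1, length.out = n_points)
  theta <- params[["theta0"]] + params[["turn"]] * s +
    params[["amp"]] * sin(2 * pi * params[["freq"]] * s + params[["phase"]])
  ds <- 1 / (n_points - 1)
  x <- cumsum(c(0, cos(head(theta, -1)) * ds))
  y <- cumsum(c(0, sin(head(theta, -1)) * ds))
  P <- cbind(x = x, y = y)
  diag_len <- sqrt(diff(range(P[, 1]))^2 + diff(range(P[, 2]))^2)
  if (diag_len <= 0) stop("primitive_curve: degenerate parameters")
  P <- P / diag_len
  sweep(P, 2, colMeans(P))
}

.sample_control_params <- function() {
  c(theta0 = runif(1, 0, 2 * pi),
    turn = runif(1, -2.2 * pi, 2.2 * pi),
    amp = runif(1, 0, 1.8),
    phase = runif(1, 0, 2 * pi),
    freq = runif(1, 0.8, 2))
}

#' Generate a library of distinct stroke primitives
#'
#' Samples control parameters at random and keeps a candidate only if its
#' trajectory distance to every already accepted primitive exceeds
#' `distinct_floor`, emulating a subject's repertoire of idiosyncratic,
#' mutually distinct one-stroke primitives.
#'
#' @param n_primitives number of primitives (>= 2).
#' @param seed RNG seed; the same call yields an identical library.
#' @param distinct_floor minimum pairwise trajectory distance.
#' @param max_attempts attempts per slot before giving up.
#' @return List of [primitive_spec()] objects named `prim01`, `prim02`, ...
#' @export
make_primitive_library <- function(n_primitives, seed = 1,
                                   distinct_floor = 0.25,
                                   max_attempts = 200) {
  stopifnot(n_primitives >= 2)
  with_seed(seed, {
    lib <- list()
    vecs <- list()
    for (i in seq_len(n_primitives)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- primitive_spec(sprintf("prim%02d", i), .sample_control_params())
        v <- normalize_stroke(p$canonical_curve)
        if (all(vapply(vecs, function(u) trajectory_distance(u, v),
                       numeric(1)) > distinct_floor)) {
          lib[[i]] <- p
          vecs[[i]] <- v
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("make_primitive_library: distinctness floor unreachable ",
                    "after ", max_attempts, " attempts")
    }
    names(lib) <- vapply(lib, `[[`, character(1), "primitive_id")
    lib
  })
}

#' Render a primitive as an image point set
#'
#' @param prim a [primitive_spec()].
#' @param location 2-D offset of the shape centre (px).
#' @param size bounding-box diagonal of the rendered shape (px); the default
#'   (134 px at 33.6 px/cm) corresponds to the ~4 cm shapes used on screen.
#' @param n_points number of rendered points.
#' @return Matrix of (x, y) image points (px).
#' @export
primitive_image <- function(prim, location = c(0, 0), size = 134,
                            n_points = 100) {
  P <- resample_polyline(prim$canonical_curve, n_points)
  sweep(P * size, 2, location, "+")
}

#' Resample a polyline by arc length
#'
#' @param P polyline as an (n x 2) matrix.
#' @param n number of output points, equally spaced in cumulative arc
#'   length.
#' @return An (n x 2) matrix.
#' @export
resample_polyline <- function(P, n) {
  P <- as.matrix(P)
  keep <- c(TRUE, rowSums(abs(diff(P))) > 0)
  P <- P[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg)) / sum(seg)
  target <- seq(0, 1, length.out = n)
  cbind(approx(s, P[, 1], xout = target, ties = "ordered")$y,
        approx(s, P[, 2], xout = target, ties = "ordered")$y)
}

#' Construct a morph set between two primitives
#'
#' Builds the stimulus family used to probe categorical structure: the two
#' practised end-point shapes plus `n_morphs` interior images obtained by
#' linear interpolation of the control parameters. Fractions 0 and 1
#' reproduce the practised shapes exactly.
#'
#' @param prim_a,prim_b [primitive_spec()]s sharing a control-parameter
#'   schema.
#' @param n_morphs number of interior morphs (default 5, so 7 images total).
#' @param size,location rendering parameters (see [primitive_image()]).
#' @return An object of class `morph_set`: list with `prim_a`, `prim_b`,
#'   `fractions`, `images` (point sets per fraction) and `specs`
#'   (interpolated `primitive_spec`s per fraction).
#' @export
make_morph_set <- function(prim_a, prim_b, n_morphs = 5, size = 134,
                           location = c(0, 0)) {
  if (!identical(names(prim_a$control_params), names(prim_b$control_params)))
    stop("make_morph_set: incompatible control-parameter schemas")
  fr <- seq(0, 1, length.out = n_morphs + 2)
  specs <- lapply(fr, function(f) {
    cp <- (1 - f) * prim_a$control_params + f * prim_b$control_params
    primitive_spec(sprintf("morph_%.3f", f), cp)
  })
  specs[[1]] <- prim_a
  specs[[length(specs)]] <- prim_b
  images <- lapply(specs, primitive_image, location = location, size = size)
  structure(list(prim_a = prim_a, prim_b = prim_b, fractions = fr,
                 images = images, specs = specs, size = size,
                 location = location),
            class = "morph_set")
}

#' Sample a morphable primitive pair
#'
#' Morph sets interpolate between two related practised shapes, so the two
#' end points must be behaviourally distinct primitives yet close enough in
#' parameter space that the image-based alignment varies linearly with morph
#' fraction (a property of the real stimulus sets, verified at design time).
#' This sampler draws a base primitive and a partner at a moderate control-
#' parameter offset, rejecting pairs whose trajectory distance is below
#' `min_dist` or whose image-alignment linearity falls below `min_r2`.
#'
#' @param seed RNG seed.
#' @param param_step typical offset per control parameter.
#' @param min_dist minimum trajectory distance between the end points.
#' @param min_r2 minimum R^2 of image alignment vs morph fraction.
#' @param max_attempts sampling budget.
#' @return List with `prim_a`, `prim_b`, `distance` and `image_r2`.
#' @export
make_morph_pair <- function(seed = 1,
                            param_step = c(theta0 = 0.4, turn = 1.2,
                                           amp = 0.5, phase = 0.4,
                                           freq = 0.25),
                            min_dist = 0.3, min_r2 = 0.99,
                            max_attempts = 100) {
  with_seed(seed, {
    for (att in seq_len(max_attempts)) {
      base <- .sample_control_params()
      delta <- param_step * sample(c(-1, 1), 5, replace = TRUE) *
        runif(5, 0.7, 1.3)
      A <- primitive_spec("prim_a", base)
      B <- primitive_spec("prim_b", base + delta)
      d <- trajectory_distance(normalize_stroke(A$canonical_curve),
                               normalize_stroke(B$canonical_curve))
      if (d < min_dist) next
      ms <- make_morph_set(A, B, n_morphs = 5)
      a_img <- vapply(seq_along(ms$fractions), function(k)
        primitive_alignment(ms$images[[k]], ms$images[1],
                            ms$images[length(ms$images)],
                            metric = "image")$a, numeric(1))
      r2 <- summary(lm(a_img ~ ms$fractions))$r.squared
      if (r2 >= min_r2)
        return(list(prim_a = A, prim_b = B, distance = d, image_r2 = r2))
    }
    stop("make_morph_pair: no acceptable pair in ", max_attempts,
         " attempts")
  })
}

#' Morph trial-condition labels
#'
#' Labels each morph fraction as practised (P1/P2), unambiguous (U1/U2) or
#' ambiguous (A, the category-boundary morph).
#'
#' @param fractions morph fractions in \[0, 1\].
#' @param boundary_fraction the boundary morph fraction (or `NA` for none).
#' @return Character vector of condition labels.
#' @export
morph_condition_labels <- function(fractions, boundary_fraction = 0.5) {
  lab <- ifelse(fractions == 0, "P1", ifelse(fractions == 1, "P2", NA))
  mid <- is.na(lab)
  if (!is.na(boundary_fraction)) {
    b <- fractions[which.min(abs(fractions - boundary_fraction))]
    lab[mid] <- ifelse(fractions[mid] == b, "A",
                       ifelse(fractions[mid] < b, "U1", "U2"))
  } else {
    lab[mid] <- ifelse(fractions[mid] < 0.5, "U1", "U2")
  }
  lab
}
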