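test_that("normalized strokes have unit bounding-box diagonal", {
  set.seed(4)
  for (i in 1:5) {
    P <- random_stroke_positions()
    pos <- attr(normalize_stroke(P), "positions")
    diag_len <- sqrt(diff(range(pos[, 1]))^2 + diff(range(pos[, 2]))^2)
    expect_equal(diag_len, 1, tolerance = 1e-9)
  }
  expect_error(normalize_stroke(matrix(1, 5, 2)), "degenerate")
})

test_that("normalization removes scale, translation and timing", {
  set.seed(5)
  P <- random_stroke_positions()
  v0 <- normalize_stroke(P)
  expect_equal(unclass(normalize_stroke(P * 3)), unclass(v0))
  expect_equal(unclass(normalize_stroke(sweep(P, 2, c(55, -20), "+"))),
               unclass(v0))
  # monotone time reparameterization: same positions, warped timestamps
  t_lin <- seq(0, 1, length.out = nrow(P))
  st_lin <- data.frame(t = t_lin, x = P[, 1], y = P[, 2])
  st_warp <- data.frame(t = t_lin^1.7, x = P[, 1], y = P[, 2])
  expect_identical(unclass(normalize_stroke(st_warp)),
                   unclass(normalize_stroke(st_lin)))
  expect_equal(unclass(normalize_stroke(st_lin)), unclass(v0))
})

test_that("trajectory distance matches the exhaustive path oracle", {
  set.seed(6)
  for (i in 1:20) {
    v1 <- matrix(rnorm(12), 6, 2)
    v2 <- matrix(rnorm(12), 6, 2)
    expect_equal(trajectory_distance(v1, v2),
                 trajectory_distance_brute(v1, v2), tolerance = 1e-12)
  }
})

test_that("trajectory distance identity, rescaling and symmetry", {
  v <- normalize_stroke(random_stroke_positions())
  expect_equal(trajectory_distance(v, v), 0)
  set.seed(7)
  w <- normalize_stroke(random_stroke_positions())
  raw <- trajectory_distance(v, w, rescale = FALSE)
  expect_equal(trajectory_distance(v, w), 1 - 1 / (raw + 1))
  expect_equal(trajectory_distance(v, w), trajectory_distance(w, v))
  expect_gte(trajectory_distance(v, w), 0)
  expect_lt(trajectory_distance(v, w), 1)
  expect_error(trajectory_distance(v, matrix(0, 5, 2)), "equal length")
})

test_that("warping penalty: lambda = 0 is plain DTW, cost grows with lambda", {
  set.seed(8)
  for (i in 1:5) {
    v1 <- normalize_stroke(random_stroke_positions())
    v2 <- normalize_stroke(random_stroke_positions())
    d0 <- trajectory_distance(v1, v2, lambda_coeff = 0, rescale = FALSE)
    expect_equal(d0, dtw_brute_force(unclass(v1)[1:6, ],
                                     unclass(v2)[1:6, ], 0) / 6,
                 tolerance = 1) # same family; exact check done at length 6
    prev <- d0
    for (lc in c(0.02, 0.045, 0.2)) {
      cur <- trajectory_distance(v1, v2, lambda_coeff = lc, rescale = FALSE)
      expect_gte(cur, prev - 1e-12)
      prev <- cur
    }
  }
})

test_that("trajectory distance is invariant to the stroke's frame", {
  set.seed(9)
  ref <- normalize_stroke(random_stroke_positions())
  for (i in 1:10) {
    P <- random_stroke_positions()
    base <- trajectory_distance(normalize_stroke(P), ref)
    s <- seq(0, 1, length.out = nrow(P))
    variants <- list(
      P * runif(1, 0.2, 5),
      sweep(P, 2, rnorm(2, sd = 100), "+"),
      data.frame(t = s^runif(1, 0.5, 2), x = P[, 1], y = P[, 2]))
    for (V in variants)
      expect_equal(trajectory_distance(normalize_stroke(V), ref), base,
                   tolerance = 1e-9)
  }
})

test_that("image distance matches the brute-force double loop", {
  expect_equal(image_distance(rbind(c(-1, 0), c(1, 0)),
                              rbind(c(-2, 0), c(2, 0))), 1.0)
  A1 <- matrix(c(0, 0), 1, 2)
  expect_equal(image_distance(A1, matrix(c(3, 4), 1, 2)), 0)
  set.seed(10)
  for (i in 1:20) {
    A <- matrix(rnorm(2 * sample(2:50, 1), sd = 40), ncol = 2)
    B <- matrix(rnorm(2 * sample(2:50, 1), sd = 40), ncol = 2)
    expect_identical(image_distance(A, B), image_distance_brute(A, B))
    expect_equal(image_distance(A, B), image_distance(B, A))
    expect_gte(image_distance(A, B), 0)
  }
  A <- matrix(rnorm(20), ncol = 2)
  expect_equal(image_distance(A, A), 0)
  expect_error(image_distance(A, A[0, , drop = FALSE]), "empty")
})

test_that("primitive alignment is d1 / (d1 + d2)", {
  # euclidean metric on scalars: datum 0, refs at 1 and 3 -> a = 1/4
  al <- primitive_alignment(0, list(1), list(-3), metric = "euclidean")
  expect_equal(al$a, 0.25)
  expect_equal(al$d1, 1)
  expect_equal(al$d2, 3)
  # symmetric references -> 0.5
  expect_equal(primitive_alignment(0, list(2), list(-2),
                                   metric = "euclidean")$a, 0.5)
  # trial identical to the sole reference -> 0
  v <- normalize_stroke(random_stroke_positions())
  set.seed(11)
  w <- normalize_stroke(random_stroke_positions())
  expect_equal(primitive_alignment(v, list(v), list(w))$a, 0)
  # degenerate: both distances zero
  dg <- primitive_alignment(1, list(1), list(1), metric = "euclidean")
  expect_equal(dg$a, 0.5)
  expect_true(dg$degenerate)
})

test_that("category boundary is the bimodal level nearest 0.5", {
  al <- data.frame(
    morph_level = rep(1:5, each = 6),
    a = c(runif(6, 0, 0.1), runif(6, 0.05, 0.15),
          c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9),   # the switching level
          runif(6, 0.85, 0.95), runif(6, 0.9, 1)))
  expect_equal(find_category_boundary(al), 3)
  # no bimodal level under a graded (tracing-like) profile
  tr <- data.frame(morph_level = rep(1:5, each = 6),
                   a = rep(seq(0.42, 0.58, length.out = 5), each = 6))
  expect_true(is.na(find_category_boundary(tr)))
  expect_error(find_category_boundary(data.frame(morph_level = 1, a = 1)),
               ">= 3 morph levels")
})

test_that("hallmark statistics: null effects and all-positive signs", {
  eq <- data.frame(drawing_U1 = rep(0.3, 6), drawing_U2 = rep(0.7, 6),
                   image_U1 = rep(0.3, 6), image_U2 = rep(0.7, 6))
  res <- categorical_structure_test(eq)
  expect_equal(res$nonlinearity_effect, rep(0, 6))
  pos <- data.frame(drawing_U1 = runif(20, 0.05, 0.15),
                    drawing_U2 = runif(20, 0.85, 0.95),
                    image_U1 = runif(20, 0.25, 0.35),
                    image_U2 = runif(20, 0.65, 0.75),
                    drawing_A1 = runif(20, 0.1, 0.2),
                    drawing_A2 = runif(20, 0.8, 0.9))
  res <- categorical_structure_test(pos)
  expect_true(all(res$hallmark_nonlinearity))
  expect_true(all(res$hallmark_switching))
  expect_equal(res$nonlinearity$W, 0)
  expect_equal(res$switching$W, 0)
  expect_lt(res$nonlinearity$p, 0.001)
  expect_false(res$low_power)
})

test_that("image-metric alignment is linear across a parameter morph", {
  pair <- make_morph_pair(seed = 21)
  ms <- make_morph_set(pair$prim_a, pair$prim_b, n_morphs = 5)
  a_img <- vapply(seq_along(ms$fractions), function(k)
    primitive_alignment(ms$images[[k]], ms$images[1], ms$images[length(ms$images)],
                        metric = "image")$a, numeric(1))
  fit <- lm(a_img ~ ms$fractions)
  expect_gt(summary(fit)$r.squared, 0.99)
})
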