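# A small tensor with planar signal: two primitives at two locations.
planar_tensor <- function(seed = 20, n_units = 24, n_trials = 8,
                          primitive_gain = 1.5, location_gain = 1.5,
                          noise_sd = 0.4, primitive_by_location = FALSE) {
  cond <- condition_grid(c("p1", "p2"), locations = 1:2)
  simulate_population(population_design(
    cond, n_units = n_units, n_trials_per_condition = n_trials,
    primitive_gain = primitive_gain, location_gain = location_gain,
    primitive_by_location = primitive_by_location,
    noise = list(type = "gaussian", sd = noise_sd), seed = seed))
}

test_that("condition PCA recovers planar signal and keeps splits disjoint", {
  cond <- condition_grid(c("p1", "p2", "p3"), locations = 1)
  des <- population_design(cond, n_units = 20, n_trials_per_condition = 8,
                           primitive_gain = 2, location_gain = 0,
                           noise = list(type = "gaussian", sd = 0.1),
                           seed = 21)
  pt <- simulate_population(des)
  cp <- fit_condition_pca(pt, "primitive", window = c(0.05, 0.6),
                          n_splits = 4, seed = 2)
  for (sp in cp$splits) {
    expect_length(intersect(sp$train_idx, sp$test_idx), 0)
    expect_equal(crossprod(sp$rotation), diag(ncol(sp$rotation)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # three condition means with a shared ramp live in a low-dim subspace:
  # the leading 2 PCs should explain almost all condition-mean variance
  sp <- cp$splits[[1]]
  lab <- sp$test_conditions$primitive
  cm <- do.call(rbind, lapply(split(seq_along(lab), lab), function(ix)
    apply(sp$proj[ix, , , drop = FALSE], 2, mean)))
  v_tot <- sum(apply(cm, 2, var))
  expect_gt(sum(apply(cm[, 1:2], 2, var)) / v_tot, 0.99)
  # determinism given the seed
  cp2 <- fit_condition_pca(pt, "primitive", window = c(0.05, 0.6),
                           n_splits = 4, seed = 2)
  expect_identical(cp$splits[[1]]$proj, cp2$splits[[1]]$proj)
  expect_error(fit_condition_pca(subset_tensor(pt, trials = c(1, 9, 17)),
                                 "primitive"), ">= 2 trials")
})

test_that("neural distance debiases same-distribution condition pairs", {
  set.seed(22)
  dstars <- vapply(1:50, function(i) {
    proj <- array(rnorm(40 * 3 * 4), dim = c(40, 3, 4))
    labels <- rep(c("A", "B"), each = 20)
    neural_distance(proj, labels, "A", "B")
  }, numeric(1))
  se <- sd(dstars) / sqrt(length(dstars))
  expect_lt(abs(mean(dstars)), 3 * se)
  # identical trial sets give exactly zero
  proj <- array(rnorm(12 * 3 * 2), dim = c(12, 3, 2))
  nd <- neural_distance_matrix(proj, rep(c("A", "B"), each = 6))
  expect_equal(nd$dstar["A", "A"], 0)
  expect_equal(nd$dstar, t(nd$dstar))
})

test_that("point-mass conditions give the closed form delta / d_max", {
  # two point-mass conditions separated by delta, external d_max
  delta <- 3; d_max <- 10
  proj <- array(0, dim = c(8, 2, 1))
  proj[5:8, 1, 1] <- delta
  labels <- rep(c("A", "B"), each = 4)
  d <- neural_distance(proj, labels, "A", "B", d_max = d_max)
  expect_equal(d, delta / d_max, tolerance = 1e-9)
  expect_error(neural_distance_matrix(array(0, dim = c(8, 2, 1)), labels),
               "degenerate")
})

test_that("encoding strength recovers simulated gains", {
  pt <- planar_tensor(seed = 23, primitive_gain = 1.5, location_gain = 0,
                      n_trials = 10)
  ea <- encoding_analysis(pt, "primitive", "location", n_splits = 4,
                          seed = 3)
  expect_gt(ea$var1_encoding, 0.2)
  expect_lt(abs(ea$var2_encoding), 0.1)
  expect_gt(ea$var1_encoding, ea$var2_encoding + 0.15)
  # permuting primitive labels destroys primitive encoding
  ptp <- pt
  set.seed(99)
  ptp$conditions$primitive <- sample(ptp$conditions$primitive)
  eap <- encoding_analysis(ptp, "primitive", "location", n_splits = 4,
                           seed = 3)
  expect_lt(eap$var1_encoding, ea$var1_encoding / 3)
})

test_that("encoding strength is monotone in primitive gain", {
  gains <- c(0, 0.75, 2)
  enc <- vapply(gains, function(g) {
    pt <- planar_tensor(seed = 24, primitive_gain = g, location_gain = 0.5,
                        n_trials = 8)
    encoding_analysis(pt, "primitive", "location", n_splits = 3,
                      seed = 4)$var1_encoding
  }, numeric(1))
  expect_equal(order(enc), seq_along(gains))
})

test_that("region comparison recovers an injected offset", {
  set.seed(25)
  n_pairs <- 120
  base <- data.frame(pair_id = sprintf("c%03d", 1:n_pairs),
                     dstar = runif(n_pairs, 0, 0.5))
  lift <- base
  lift$dstar <- lift$dstar + 0.1 + rnorm(n_pairs, 0, 0.01)
  same <- base
  tabs <- list(A = list(primitive = base), B = list(primitive = lift),
               C = list(primitive = same))
  res <- compare_regions(tabs)
  tAB <- subset(res$tests, region_a == "A" & region_b == "B")
  expect_equal(tAB$beta, 0.1, tolerance = 0.05)
  expect_true(tAB$significant)
  tAC <- subset(res$tests, region_a == "A" & region_b == "C")
  expect_equal(tAC$beta, 0, tolerance = 1e-9)
  expect_false(tAC$significant)
  expect_equal(res$beaten["B", "primitive"], 2L)
  expect_equal(res$n_tests, 3)
})

test_that("8 regions x 2 variables yields 56 Bonferroni-corrected tests", {
  set.seed(26)
  mk <- function() list(primitive = data.frame(pair_id = paste0("p", 1:10),
                                               dstar = runif(10)),
                        location = data.frame(pair_id = paste0("l", 1:10),
                                              dstar = runif(10)))
  tabs <- setNames(replicate(8, mk(), simplify = FALSE),
                   c("M1", "PMd", "PMv", "SMA", "preSMA", "dlPFC", "vlPFC",
                     "FP"))
  res <- compare_regions(tabs)
  expect_equal(res$n_tests, 56)
  expect_equal(nrow(res$tests), 56)
  expect_true(all(res$tests$p_bonferroni >= res$tests$p))
})

test_that("decoder accuracy is rescaled so chance maps to zero", {
  pt <- planar_tensor(seed = 27, primitive_gain = 2, location_gain = 0,
                      n_trials = 10, noise_sd = 0.3)
  dec <- cross_condition_decode(pt$rates, pt$conditions, pt$time,
                                train_condition = 1)
  expect_equal(dec$chance, 0.5)
  expect_equal(dec$rescaled, (dec$raw - dec$chance) / (1 - dec$chance))
  expect_gt(dec$rescaled, 0.8)
  expect_error(cross_condition_decode(
    pt$rates, transform(pt$conditions,
                        primitive = ifelse(seq_len(nrow(pt$conditions)) < 5,
                                           "px", primitive)),
    pt$time, train_condition = 1), "every class")
})

test_that("generalization separates invariant from conjunctive codes", {
  inv <- planar_tensor(seed = 28, primitive_gain = 2, location_gain = 0,
                       n_trials = 10, noise_sd = 0.4)
  d_inv <- cross_condition_decode(inv$rates, inv$conditions, inv$time,
                                  train_condition = 1)
  spec <- planar_tensor(seed = 28, primitive_gain = 2, location_gain = 0,
                        n_trials = 10, noise_sd = 0.4,
                        primitive_by_location = TRUE)
  d_spec <- cross_condition_decode(spec$rates, spec$conditions, spec$time,
                                   train_condition = 1)
  expect_gt(d_inv$rescaled, 0.8)
  expect_lt(d_spec$rescaled, 0.2)
  expect_gt(d_spec$within_rescaled, 0.8)  # the code is decodable in place
})

test_that("neural alignment reflects categorical vs linear morph codes", {
  cond <- condition_grid(c("pa", "pb"),
                         morph_fractions = seq(0, 1, length.out = 7))
  cond <- cond[(cond$primitive == "pa") == (cond$morph_fraction <= 0.5) |
                 cond$morph_fraction %in% c(0, 1), ]
  cond <- unique(transform(cond, primitive = NA))
  cond$primitive <- ifelse(cond$morph_fraction == 0, "pa",
                           ifelse(cond$morph_fraction == 1, "pb", NA))
  mk <- function(categorical, seed) simulate_population(population_design(
    cond, n_units = 30, n_trials_per_condition = 10,
    time_base = seq(0.55, 1.0, by = 0.05), primitive_gain = 2,
    location_gain = 0, categorical_flag = categorical,
    noise = list(type = "gaussian", sd = 0.5), seed = seed))
  ptc <- mk(TRUE, 29)
  al <- neural_primitive_alignment(ptc$rates, ptc$conditions, ptc$time,
                                   window = c(0.6, 1.0))
  expect_true(all(al$a >= 0 & al$a <= 1))
  byc <- tapply(al$a, al$condition, mean)
  expect_lt(byc[["P1"]], 0.4)
  expect_gt(byc[["P2"]], 0.6)
  expect_gt(byc[["A2"]], byc[["A1"]])
  # categorical code: U1 sits with P1, U2 with P2 (sigmoidal profile)
  expect_lt(byc[["U1"]], 0.4)
  expect_gt(byc[["U2"]], 0.6)
  ptl <- mk(FALSE, 30)
  all_ <- neural_primitive_alignment(ptl$rates, ptl$conditions, ptl$time,
                                     window = c(0.6, 1.0))
  bym <- tapply(all_$a, all_$morph_fraction, mean)
  fr <- as.numeric(names(bym))
  expect_gt(summary(lm(as.numeric(bym) ~ fr))$r.squared, 0.9)
})

test_that("pairwise primitive decoding generalizes for separable codes", {
  cond <- condition_grid(c("p1", "p2", "p3"), locations = 1:2)
  pt <- simulate_population(population_design(
    cond, n_units = 24, n_trials_per_condition = 6, primitive_gain = 2,
    location_gain = 0.5, noise = list(type = "gaussian", sd = 0.3),
    seed = 31, regions = c("PMv", "M1")))
  acc <- pairwise_primitive_decoding(pt, n_pcs = 20)
  expect_true(all(is.na(diag(acc))))
  expect_equal(acc, t(acc))
  expect_true(all(acc[upper.tri(acc)] > 0.9))
  byreg <- pairwise_primitive_decoding(pt, n_pcs = 10,
                                       regions = c("PMv", "M1"),
                                       n_subsample = 2)
  expect_named(byreg, c("PMv", "M1"))
})

test_that("initial-reach correction recovers an additive offset", {
  cond <- rbind(
    transform(condition_grid(c("p1", "p2"), task_types = "single_shape"),
              first = TRUE),
    transform(condition_grid(c("p1", "p2"), task_types = "character"),
              first = TRUE),
    transform(condition_grid(c("p1", "p2"), task_types = "character"),
              first = FALSE))
  des <- population_design(cond[, !(names(cond) %in% "first")],
                           n_units = 10, n_trials_per_condition = 12,
                           primitive_gain = 1, task_gain = 0.5,
                           noise = list(type = "gaussian", sd = 0.2),
                           seed = 32)
  pt <- simulate_population(des)
  pt$conditions$first_stroke <- rep(cond$first,
                                    each = des$n_trials_per_condition)
  r_true <- 1.7
  first <- which(pt$conditions$first_stroke)
  pt_off <- pt
  for (k in first) pt_off$rates[k, , ] <- pt_off$rates[k, , ] + r_true
  res <- correct_initial_reach(pt_off)
  expect_equal(mean(res$beta_f), r_true, tolerance = 0.1)
  # non-first-stroke activity is untouched
  nf <- which(!pt$conditions$first_stroke)
  expect_identical(res$tensor$rates[nf, , ], pt_off$rates[nf, , ])
  # corrected first-stroke means agree with non-first means
  expect_equal(mean(res$tensor$rates[first, , ]),
               mean(pt_off$rates[nf, , ]), tolerance = 0.1)
  # with no reach effect the correction is a near no-op
  res0 <- correct_initial_reach(pt)
  expect_lt(max(abs(res0$tensor$rates - pt$rates)), 0.2)
  pt_bad <- pt
  pt_bad$conditions$first_stroke <- TRUE
  expect_error(correct_initial_reach(pt_bad), "non-first")
})

test_that("FVAF is 1 for exact linear data and recovers the injected lag", {
  set.seed(33)
  dt <- 0.05
  E <- matrix(rnorm(20), 10, 2)
  prims <- rep(c("a", "b", "c", "d"), each = 5)
  velocity <- lapply(seq_along(prims), function(i) {
    t <- seq(0, 2, by = dt)
    cbind(sin(2 * pi * t / 2 + i), cos(2 * pi * t / 1.3 + 0.3 * i))
  })
  neural_exact <- lapply(velocity, function(v) v %*% t(E))
  fv <- fvaf_kinematics(neural_exact, velocity, prims, dt)
  expect_gt(fv$fvaf_by_lag[["0.00"]], 1 - 1e-9)
  # zero predictor with b = 0 gives FVAF exactly 0 by the formula
  ss_err <- sum(unlist(neural_exact)^2)
  expect_equal(1 - ss_err / ss_err, 0)
  # inject a -0.1 s lag: neural at t encodes velocity at t + 0.1
  k <- round(0.1 / dt)
  neural_lag <- lapply(velocity, function(v) {
    Ti <- nrow(v)
    f <- matrix(0, Ti, 10)
    f[1:(Ti - k), ] <- v[(1 + k):Ti, ] %*% t(E)
    f[(Ti - k + 1):Ti, ] <- f[Ti - k, ]
    f + matrix(rnorm(Ti * 10, 0, 0.05), Ti, 10)
  })
  fvl <- fvaf_kinematics(neural_lag, velocity, prims, dt)
  expect_equal(fvl$peak_lag, -0.1, tolerance = 1e-9)
  expect_error(fvaf_kinematics(neural_exact[1:10], velocity[1:10],
                               prims[1:10], dt), ">= 3 primitives")
})

test_that("fixation decoding excludes far fixations and tracks planning", {
  cond <- condition_grid(c("p1", "p2", "p3"))
  des <- population_design(cond, n_units = 20, n_trials_per_condition = 10,
                           primitive_gain = 2, location_gain = 0,
                           noise = list(type = "gaussian", sd = 0.3),
                           seed = 34)
  pt <- simulate_population(des)
  shapes <- list(p1 = cbind(100, 100), p2 = cbind(300, 100),
                 p3 = cbind(200, 300))
  fixations <- data.frame(x = c(100, 300, 200, 600),
                          y = c(110, 90, 290, 600),
                          planned_primitive = c("p2", "p1", "p3", "p1"))
  # fixation-aligned activity that encodes the *planned* primitive:
  # reuse planning-epoch activity patterns from trials of that primitive
  late <- dim(pt$rates)[3]
  act <- t(vapply(fixations$planned_primitive, function(p)
    colMeans(pt$rates[pt$conditions$primitive == p, , late]),
    numeric(dim(pt$rates)[2])))
  res <- fixation_decoding(pt, window = c(0.3, 0.6), fixations, shapes, act)
  expect_equal(res$n_excluded, 1)
  expect_equal(nrow(res$scores), 3)
  expect_true(all(res$probs >= 0 & res$probs <= 1))
  expect_gt(mean(res$scores$p_planned), mean(res$scores$p_fixated))
})
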