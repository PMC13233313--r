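test_that("primitive libraries are distinct and seed-deterministic", {
  lib <- make_primitive_library(3, seed = 5)
  lib2 <- make_primitive_library(3, seed = 5)
  expect_identical(lib, lib2)
  vs <- lapply(lib, function(p) normalize_stroke(p$canonical_curve))
  D <- trajectory_distance_matrix(vs)
  expect_true(all(D[upper.tri(D)] > 0.25))
  for (p in lib) {
    expect_gte(nrow(p$canonical_curve), 10)
    expect_true(all(rowSums(abs(diff(p$canonical_curve))) > 0))
  }
  # a subject-sized repertoire of 11 primitives is reachable
  lib11 <- make_primitive_library(11, seed = 7)
  expect_length(lib11, 11)
})

test_that("zero-noise strokes lie exactly on the transformed curve", {
  prim <- small_library()[[1]]
  s <- sample_stroke(prim, location = c(40, -30), size = 120,
                     noise = list(pos_sd = 0, dur_cv = 0), seed = 1)
  curve <- sweep(prim$canonical_curve * 120, 2, c(40, -30), "+")
  # exact point-on-polyline check: distance to the nearest curve segment
  seg_dist <- function(p, A, B) {
    ab <- B - A
    tt <- pmin(1, pmax(0, ((p[1] - A[, 1]) * ab[, 1] +
                             (p[2] - A[, 2]) * ab[, 2]) /
                        (ab[, 1]^2 + ab[, 2]^2)))
    min(sqrt((A[, 1] + tt * ab[, 1] - p[1])^2 +
               (A[, 2] + tt * ab[, 2] - p[2])^2))
  }
  A <- curve[-nrow(curve), , drop = FALSE]
  B <- curve[-1, , drop = FALSE]
  dev <- vapply(seq_len(nrow(s)), function(i)
    seg_dist(c(s$x[i], s$y[i]), A, B), numeric(1))
  expect_lt(max(dev), 1e-9)
  expect_error(sample_stroke(prim, size = 0), "size")
})

test_that("noisy repetitions stay below the match threshold", {
  prim <- small_library()[[2]]
  s1 <- normalize_stroke(sample_stroke(prim, seed = 1))
  s2 <- normalize_stroke(sample_stroke(prim, seed = 2))
  d <- trajectory_distance(s1, s2)
  expect_gt(d, 0)
  expect_lt(d, 0.3)
  # size variation up to the experimental 2.5x ratio leaves the metric alone
  big <- normalize_stroke(sample_stroke(prim, size = 250,
                                        noise = list(pos_sd = 0, dur_cv = 0)))
  small <- normalize_stroke(sample_stroke(prim, size = 100,
                                          noise = list(pos_sd = 0,
                                                       dur_cv = 0)))
  expect_lt(trajectory_distance(big, small), 0.05)
})

test_that("morph sets interpolate parameters with exact end points", {
  lib <- small_library()
  ms <- make_morph_set(lib[[1]], lib[[2]], n_morphs = 5)
  expect_length(ms$images, 7)  # 2 practised + 5 morphs
  expect_identical(ms$images[[1]],
                   primitive_image(lib[[1]]))
  expect_identical(ms$images[[7]], primitive_image(lib[[2]]))
  mid <- ms$specs[[4]]$control_params
  expect_equal(mid, (lib[[1]]$control_params + lib[[2]]$control_params) / 2)
  bad <- lib[[3]]
  bad$control_params <- c(foo = 1)
  expect_error(make_morph_set(lib[[1]], bad), "schema")
})

test_that("categorical policy switches at the boundary; tracing does not", {
  pair <- make_morph_pair(seed = 31)
  ms <- make_morph_set(pair$prim_a, pair$prim_b, n_morphs = 5)
  sim <- simulate_drawing_policy(ms, "categorical", boundary_fraction = 0.5,
                                 n_trials = 8, seed = 2)
  bnd <- ms$fractions[which.min(abs(ms$fractions - 0.5))]
  at_b <- sim$trials$morph_fraction == bnd
  expect_setequal(unique(sim$trials$drawn_primitive[at_b]), c("P1", "P2"))
  expect_true(all(sim$trials$drawn_primitive[sim$trials$morph_fraction < bnd]
                  == "P1"))
  tr <- simulate_drawing_policy(ms, "tracing", n_trials = 4, seed = 3)
  # tracing drawings follow the image: drawing alignment ~ image alignment
  refs1 <- which(tr$trials$condition == "P1")
  refs2 <- which(tr$trials$condition == "P2")
  tvs <- lapply(tr$strokes, normalize_stroke)
  lv <- sort(unique(tr$trials$morph_fraction))
  a_draw <- vapply(lv, function(f) {
    ix <- which(tr$trials$morph_fraction == f)
    mean(vapply(ix, function(k)
      primitive_alignment(tvs[[k]], tvs[setdiff(refs1, k)],
                          tvs[setdiff(refs2, k)])$a, numeric(1)))
  }, numeric(1))
  a_img <- vapply(seq_along(lv), function(k)
    primitive_alignment(ms$images[[k]], ms$images[1], ms$images[7],
                        metric = "image")$a, numeric(1))
  expect_gt(cor(a_draw, a_img), 0.95)
  expect_lt(max(abs(a_draw - a_img)), 0.35)
})

test_that("characters respect relations and the crossing filter", {
  lib <- small_library()
  ch2 <- sample_character(lib, 2, seed = 3)
  expect_equal(nrow(ch2$relations), 1)
  ch <- sample_character(lib, 4, seed = 9)
  expect_equal(nrow(ch$relations), 3)
  expect_length(ch$ground_truth_segmentation, nrow(ch$image))
  for (a in 1:(ch$n_shapes - 1)) for (b in (a + 1):ch$n_shapes)
    expect_lte(count_crossings(ch$curves[[a]], ch$curves[[b]]), 1)
  # consecutive shapes touch exactly at the sampled attachment points
  for (i in 1:(ch$n_shapes - 1)) {
    a_prev <- actionsym:::.point_at_fraction(ch$curves[[i]],
                                             ch$relations$on_prev[i])
    a_next <- actionsym:::.point_at_fraction(ch$curves[[i + 1]],
                                             ch$relations$on_next[i])
    expect_equal(a_prev, a_next, tolerance = 1e-9)
  }
})

test_that("ground-truth character strokes classify back to their sources", {
  lib <- small_library()
  tmpl <- small_templates()
  hits <- 0; total <- 0
  for (sd in 1:3) {
    ch <- sample_character(lib, 3, seed = 40 + sd)
    strokes <- character_strokes(ch, seed = 50 + sd)
    cls <- classify_strokes(strokes, tmpl)
    hits <- hits + sum(cls$p_star == attr(strokes, "source_primitives"))
    total <- total + nrow(cls)
  }
  expect_gte(hits / total, 0.95)
})

test_that("population tensors are deterministic and schema-valid", {
  cond <- condition_grid(c("p1", "p2"), locations = 1:2)
  des <- population_design(cond, n_units = 20, n_trials_per_condition = 4,
                           seed = 4)
  pt <- simulate_population(des)
  expect_identical(pt, simulate_population(des))
  expect_silent(validate_population_tensor(pt))
  expect_equal(dim(pt$rates)[1], nrow(cond) * 4)
  # poisson noise gives non-negative rates
  des_p <- population_design(cond, n_units = 10, n_trials_per_condition = 3,
                             noise = list(type = "poisson"), seed = 5)
  expect_true(all(simulate_population(des_p)$rates >= 0))
})

test_that("zero gains produce no encoding of any variable", {
  cond <- condition_grid(c("p1", "p2"), locations = 1:2)
  des <- population_design(cond, n_units = 30, n_trials_per_condition = 10,
                           primitive_gain = 0, location_gain = 0, seed = 6)
  pt <- simulate_population(des)
  ea <- encoding_analysis(pt, "primitive", "location",
                          window = c(0.05, 0.6), n_splits = 4, seed = 1)
  expect_lt(abs(ea$var1_encoding), 0.1)
  expect_lt(abs(ea$var2_encoding), 0.1)
})

test_that("YAML config drives the generators", {
  cfg <- list(primitives = list(n = 3, seed = 2),
              morphs = list(prim_a = "prim01", prim_b = "prim02",
                            n_morphs = 4),
              population = list(primitives = list("prim01", "prim02"),
                                locations = list(1, 2), n_units = 8,
                                n_trials_per_condition = 3, seed = 9))
  out <- simulate_from_config(cfg)
  expect_length(out$library, 3)
  expect_length(out$morph_set$images, 6)
  expect_s3_class(out$tensor, "population_tensor")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  out2 <- simulate_from_config(path)
  expect_identical(out2$tensor$rates, out$tensor$rates)
})

test_that("population tensors round-trip through text serialization", {
  cond <- condition_grid("p1", locations = 1)
  des <- population_design(cond, n_units = 4, n_trials_per_condition = 3,
                           seed = 8)
  pt <- simulate_population(des)
  dir <- withr::local_tempdir()
  write_population_tensor(pt, dir)
  back <- read_population_tensor(dir)
  expect_equal(back$rates, pt$rates, tolerance = 1e-12)
  expect_equal(back$time, pt$time)
  expect_equal(back$conditions$primitive, as.character(pt$conditions$primitive))
})
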