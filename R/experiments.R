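#' Condition table for a morph-set recording session
#'
#' One condition per morph image: the end points carry the practised
#' primitive labels, interior morphs carry `NA` primitive and their morph
#' fraction.
#'
#' @param prims labels of the two practised primitives.
#' @param fractions morph fractions including 0 and 1 (default 7 levels).
#' @return Condition data frame for [population_design()].
#' @export
morph_condition_grid <- function(prims = c("pa", "pb"),
                                 fractions = seq(0, 1, length.out = 7)) {
  data.frame(primitive = ifelse(fractions == 0, prims[1],
                                ifelse(fractions == 1, prims[2], NA)),
             location = 1, size = 1, task_type = "single_shape",
             morph_fraction = fractions, stringsAsFactors = FALSE)
}

#' Simulated behavioural morph experiment
#'
#' Generates one morph set (a morphable primitive pair plus interpolated
#' images), simulates drawing behaviour under the given policy, scores every
#' trial's drawing-based and the set's image-based primitive alignment,
#' locates the category boundary from the trial-by-trial alignment scores,
#' and summarizes the set for the categorical-structure hallmark tests.
#'
#' @param seed RNG seed for the whole experiment.
#' @param policy `"categorical"` or `"tracing"`.
#' @param n_trials trials per morph level.
#' @param noise stroke noise (see [sample_stroke()]).
#' @return List: `summary` (one row for [categorical_structure_test()]),
#'   `boundary` (detected boundary fraction or `NA`), `alignments`
#'   (per-trial drawing alignment), `image_alignment` (per level), `trials`.
#' @export
run_morph_behaviour <- function(seed, policy = "categorical", n_trials = 8,
                                noise = list(pos_sd = 2, dur_cv = 0.1)) {
  pair <- make_morph_pair(seed = seed)
  ms <- make_morph_set(pair$prim_a, pair$prim_b, n_morphs = 5)
  sim <- simulate_drawing_policy(ms, policy, boundary_fraction = 0.5,
                                 n_trials = n_trials, noise = noise,
                                 seed = seed + 1000)
  tvs <- lapply(sim$strokes, normalize_stroke)
  p1 <- which(sim$trials$condition == "P1")
  p2 <- which(sim$trials$condition == "P2")
  a <- vapply(seq_along(tvs), function(k)
    primitive_alignment(tvs[[k]], tvs[setdiff(p1, k)],
                        tvs[setdiff(p2, k)])$a, numeric(1))
  al <- data.frame(morph_level = sim$trials$morph_fraction, a = a)
  boundary <- find_category_boundary(al)
  # trial conditions follow the *detected* boundary (A excluded if none)
  cond <- morph_condition_labels(sim$trials$morph_fraction,
                                 if (is.na(boundary)) NA else boundary)
  a_img <- vapply(seq_along(ms$fractions), function(k)
    primitive_alignment(ms$images[[k]], ms$images[1],
                        ms$images[length(ms$images)],
                        metric = "image")$a, numeric(1))
  drawing <- data.frame(condition = cond,
                        drawn_primitive = sim$trials$drawn_primitive,
                        a = a, stringsAsFactors = FALSE)
  image <- data.frame(condition = morph_condition_labels(ms$fractions,
                                                         boundary),
                      a = a_img, stringsAsFactors = FALSE)
  list(summary = alignment_set_summary(drawing, image),
       boundary = boundary, alignments = al,
       image_alignment = data.frame(fraction = ms$fractions, a = a_img),
       trials = sim$trials)
}

#' Simulated neural morph experiment
#'
#' Simulates a population tensor for one morph session (categorical or
#' linear morph readout), projects test trials with cross-validated
#' condition PCA over the unique images, computes per-trial neural primitive
#' alignment late in the planning epoch, and pairs it with the image-based
#' alignment of a matched morph set.
#'
#' @param seed RNG seed.
#' @param categorical categorical (`TRUE`) or linear (`FALSE`) readout.
#' @param n_units,n_trials simulation size.
#' @param noise_sd Gaussian rate noise (normalized units).
#' @return List: `summary` (one row for [categorical_structure_test()]),
#'   `alignments` (per test trial), `image_alignment`.
#' @export
run_morph_neural <- function(seed, categorical = TRUE, n_units = 30,
                             n_trials = 10, noise_sd = 0.5) {
  cond <- morph_condition_grid()
  des <- population_design(cond, n_units = n_units,
                           n_trials_per_condition = n_trials,
                           time_base = seq(0.325, 0.975, by = 0.05),
                           primitive_gain = 2, location_gain = 0,
                           categorical_flag = categorical,
                           noise = list(type = "gaussian", sd = noise_sd),
                           seed = seed)
  pt <- simulate_population(des)
  cp <- fit_condition_pca(pt, "morph_fraction", window = c(0.3, 1.0),
                          n_splits = 4, bin = 0.15, slide = 0.05,
                          seed = seed + 1)
  als <- lapply(cp$splits, function(sp)
    neural_primitive_alignment(sp$proj, sp$test_conditions, cp$time,
                               window = c(0.6, 1.0)))
  al <- do.call(rbind, als)
  pair <- make_morph_pair(seed = seed)
  ms <- make_morph_set(pair$prim_a, pair$prim_b, n_morphs = 5)
  a_img <- vapply(seq_along(ms$fractions), function(k)
    primitive_alignment(ms$images[[k]], ms$images[1],
                        ms$images[length(ms$images)],
                        metric = "image")$a, numeric(1))
  image <- data.frame(condition = morph_condition_labels(ms$fractions, 0.5),
                      a = a_img, stringsAsFactors = FALSE)
  list(summary = alignment_set_summary(al, image), alignments = al,
       image_alignment = data.frame(fraction = ms$fractions, a = a_img))
}

#' Simulated primitive-reuse run
#'
#' One simulated comparison of character strokes against the subject's own
#' primitive set, a disjoint foreign set, and a remixed control set: strokes
#' are drawn from the own library at sub-threshold noise and classified
#' against all three template sets.
#'
#' @param seed RNG seed.
#' @param own,foreign fitted `primitive_templates` for the two subjects.
#' @param remixed a [generate_remixed_set()] for the own set.
#' @param n_strokes strokes per run.
#' @return List: `fractions` (named high-quality match fractions),
#'   `recovery` (fraction of strokes recovering their source primitive),
#'   `classifications`.
#' @export
run_reuse_run <- function(seed, own, foreign, remixed, own_library,
                          n_strokes = 50) {
  with_seed(seed, {
    src <- sample(names(own_library), n_strokes, replace = TRUE)
    strokes <- lapply(seq_len(n_strokes), function(i)
      sample_stroke(own_library[[src[i]]], seed = seed * 10000 + i))
    tvs <- lapply(strokes, normalize_stroke)
    rem_tmpl <- remixed_templates(remixed, own, tvs)
    sets <- list(own = own, foreign = foreign, remixed = rem_tmpl)
    cls <- lapply(sets, function(tm) classify_strokes(tvs, tm))
    fractions <- vapply(cls, function(cl) mean(cl$quality == "high"),
                       numeric(1))
    list(fractions = fractions,
         recovery = mean(cls$own$p_star == src),
         classifications = cls)
  })
}
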