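#' Re-bin a population tensor in time
#'
#' Sliding-window average of rates (window `width`, step `slide`),
#' optionally restricted to an analysis window.
#'
#' @param pt a `population_tensor`.
#' @param width,slide bin width and slide (s).
#' @param window optional c(start, end) analysis window (s) applied to the
#'   new bin centres.
#' @return The re-binned `population_tensor`.
#' @export
rebin_tensor <- function(pt, width, slide, window = NULL) {
  t0 <- pt$time
  starts <- seq(t0[1], t0[length(t0)] - width + 1e-9, by = slide)
  if (!length(starts)) starts <- t0[1]
  centres <- starts + width / 2
  idx <- lapply(starts, function(s) which(t0 >= s - 1e-9 & t0 < s + width - 1e-9))
  keep <- lengths(idx) > 0
  starts <- starts[keep]; centres <- centres[keep]; idx <- idx[keep]
  dm <- dim(pt$rates)
  out <- array(0, dim = c(dm[1], dm[2], length(idx)))
  for (b in seq_along(idx)) {
    sl <- pt$rates[, , idx[[b]], drop = FALSE]
    out[, , b] <- if (length(idx[[b]]) == 1) sl[, , 1] else
      apply(sl, c(1, 2), mean)
  }
  pt$rates <- out
  pt$time <- centres
  pt$bin_width <- width
  if (!is.null(window)) {
    sel <- pt$time >= window[1] & pt$time <= window[2]
    pt$rates <- pt$rates[, , sel, drop = FALSE]
    pt$time <- pt$time[sel]
  }
  pt
}

#' Condition-averaged, cross-validated PCA
#'
#' Fits a linear subspace on trial-averaged (condition-mean) activity to
#' minimize the influence of trial-by-trial noise, in a cross-validated
#' manner: trials are stratified into train/test halves, PCA is fitted on
#' the train split's condition-mean N x (C*T) matrix, and only test trials
#' are projected and carried downstream. Eight randomized splits are drawn
#' and downstream results are averaged over splits.
#'
#' @param pt a `population_tensor` (normalized rates).
#' @param condition_key character vector of condition-table columns whose
#'   conjunction defines the averaging conditions.
#' @param window analysis window (s).
#' @param n_components retained components (default 8).
#' @param n_splits randomized train/test splits (default 8).
#' @param bin,slide temporal re-binning before fitting (s).
#' @param seed RNG seed.
#' @return A `condition_pca`: list with `splits` (each holding `rotation`,
#'   `center`, `train_idx`, `test_idx`, `proj` (K_test x D x T array) and
#'   `test_conditions`), plus `time` and the call parameters.
#' @export
fit_condition_pca <- function(pt, condition_key, window = NULL,
                              n_components = 8, n_splits = 8, bin = 0.15,
                              slide = 0.02, seed = 1) {
  validate_population_tensor(pt)
  ptb <- rebin_tensor(pt, bin, slide, window)
  lab <- interaction(ptb$conditions[, condition_key, drop = FALSE],
                     drop = TRUE, sep = "||")
  if (any(table(lab) < 2))
    stop("fit_condition_pca: every condition needs >= 2 trials")
  K <- dim(ptb$rates)[1]; N <- dim(ptb$rates)[2]; T <- dim(ptb$rates)[3]
  n_components <- min(n_components, N)
  splits <- with_seed(seed, lapply(seq_len(n_splits), function(s) {
    train <- unlist(lapply(split(seq_len(K), lab), function(ix)
      sample(ix, ceiling(length(ix) / 2))))
    test <- setdiff(seq_len(K), train)
    Xc <- do.call(cbind, lapply(split(train, droplevels(lab[train])),
                                function(ix) {
      sl <- ptb$rates[ix, , , drop = FALSE]
      matrix(apply(sl, c(2, 3), mean), N, T)
    }))
    pc <- prcomp(t(Xc), center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
    ctr <- pc$center
    proj <- array(0, dim = c(length(test), n_components, T))
    for (tt in seq_len(T)) {
      M <- matrix(ptb$rates[test, , tt], length(test), N)
      proj[, , tt] <- sweep(M, 2, ctr) %*% rot
    }
    list(rotation = rot, center = ctr, train_idx = train, test_idx = test,
         proj = proj,
         test_conditions = ptb$conditions[test, , drop = FALSE])
  }))
  structure(list(splits = splits, time = ptb$time,
                 condition_key = condition_key,
                 n_components = n_components),
            class = "condition_pca")
}

.bin_dist_mats <- function(proj) {
  K <- dim(proj)[1]; D <- dim(proj)[2]; T <- dim(proj)[3]
  lapply(seq_len(T), function(tt)
    as.matrix(dist(matrix(proj[, , tt], K, D))))
}

#' Debiased, normalized neural distance
#'
#' For two trial sets A and B, the neural distance is the mean pairwise
#' Euclidean distance between all across-condition trial pairs — per time
#' bin, normalized by `d_max(t)`, the 98th percentile of distances between
#' all pairs of different trials across all conditions, then averaged over
#' bins — minus the average within-condition distance,
#' `D* = D_AB - (D_AA + D_BB) / 2`. The subtraction debiases the metric: two
#' sets sampled from the same distribution have expected `D*` of zero, and
#' small negatives are retained. Within-condition means use distinct trial
#' pairs only, so `D*` of a condition with itself is exactly 0.
#'
#' @param proj K x D x T array of projected single-trial activity.
#' @param labels condition label per trial (each level needs >= 2 trials).
#' @param d_max optional externally supplied bound (scalar or per-bin);
#'   computed from the data when `NULL`.
#' @return List with `dstar` (symmetric condition matrix, zero diagonal),
#'   `within`, `across`, `d_max`, and the per-trial mean normalized distance
#'   matrix `trial_matrix`.
#' @export
neural_distance_matrix <- function(proj, labels, d_max = NULL) {
  labels <- factor(labels)
  stopifnot(dim(proj)[1] == length(labels))
  if (any(table(labels) < 2))
    stop("neural_distance_matrix: every condition needs >= 2 trials")
  mats <- .bin_dist_mats(proj)
  if (is.null(d_max)) {
    d_max <- vapply(mats, function(M) quantile(M[upper.tri(M)], 0.98,
                                               type = 7, names = FALSE),
                    numeric(1))
  } else d_max <- rep_len(d_max, length(mats))
  if (any(d_max <= 0))
    stop("neural_distance_matrix: degenerate data (d_max = 0)")
  Dn <- Reduce(`+`, Map(function(M, dm) M / dm, mats, as.list(d_max))) /
    length(mats)
  lev <- levels(labels)
  nl <- length(lev)
  within <- setNames(vapply(lev, function(a) {
    ix <- which(labels == a)
    M <- Dn[ix, ix, drop = FALSE]
    mean(M[upper.tri(M)])
  }, numeric(1)), lev)
  across <- matrix(0, nl, nl, dimnames = list(lev, lev))
  dstar <- across
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    if (i == j) next
    ia <- which(labels == lev[i]); ib <- which(labels == lev[j])
    across[i, j] <- mean(Dn[ia, ib])
  }
  for (i in seq_len(nl - 1)) for (j in (i + 1):nl) {
    dstar[i, j] <- dstar[j, i] <-
      across[i, j] - (within[i] + within[j]) / 2
  }
  list(dstar = dstar, within = within, across = across, d_max = d_max,
       trial_matrix = Dn, labels = labels)
}

#' @rdname neural_distance_matrix
#' @param cond_a,cond_b the two condition labels to compare.
#' @return `neural_distance` returns the scalar `D*` for one condition pair.
#' @export
neural_distance <- function(proj, labels, cond_a, cond_b, d_max = NULL) {
  nd <- neural_distance_matrix(proj, labels, d_max = d_max)
  nd$dstar[as.character(cond_a), as.character(cond_b)]
}

#' Encoding strength of a variable
#'
#' The mean neural distance across all condition pairs that differ in the
#' target variable but share every control variable (for example, different
#' primitives at the same location measures primitive encoding).
#'
#' @param dstar condition-pair `D*` matrix from [neural_distance_matrix()].
#' @param level_table data frame mapping matrix levels (column `level`) to
#'   variable values.
#' @param variable target variable column name.
#' @param controls character vector of control column names.
#' @return List with `strength` (scalar) and `pairs` (per-pair data frame,
#'   used by [compare_regions()]).
#' @export
encoding_strength <- function(dstar, level_table, variable, controls) {
  lev <- rownames(dstar)
  stopifnot(all(lev %in% level_table$level))
  tab <- level_table[match(lev, level_table$level), , drop = FALSE]
  rows <- list()
  for (i in seq_len(length(lev) - 1)) for (j in (i + 1):length(lev)) {
    differ <- tab[[variable]][i] != tab[[variable]][j]
    same_ctrl <- all(vapply(controls, function(cv)
      identical(tab[[cv]][i], tab[[cv]][j]), logical(1)))
    if (differ && same_ctrl) {
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = paste(lev[i], lev[j], sep = " vs "),
        dstar = dstar[i, j])
    }
  }
  if (!length(rows)) stop("encoding_strength: no qualifying condition pair")
  pairs <- do.call(rbind, rows)
  list(strength = mean(pairs$dstar), pairs = pairs)
}

#' Two-variable encoding analysis of a population tensor
#'
#' The full pipeline behind the encoding summaries: cross-validated
#' condition PCA on the conjunction of the two variables, debiased neural
#' distances between all conjunctive conditions on the test split, and
#' encoding strength of each variable controlling for the other — averaged
#' over the randomized splits.
#'
#' @param pt a `population_tensor`.
#' @param var1,var2 condition-table columns (e.g. `"primitive"`,
#'   `"location"`).
#' @param window analysis window (s).
#' @param ... passed to [fit_condition_pca()].
#' @return List with `var1_encoding`, `var2_encoding` (split-averaged
#'   scalars), `pair_tables` (per variable, split-averaged per-pair `D*`,
#'   for region comparison) and `dstar` (split-averaged matrix).
#' @export
encoding_analysis <- function(pt, var1 = "primitive", var2 = "location",
                              window = c(0.05, 0.6), ...) {
  cpca <- fit_condition_pca(pt, condition_key = c(var1, var2),
                            window = window, ...)
  res <- lapply(cpca$splits, function(sp) {
    lab <- interaction(sp$test_conditions[, c(var1, var2)], drop = TRUE,
                       sep = "||")
    nd <- neural_distance_matrix(sp$proj, lab)
    lev <- rownames(nd$dstar)
    parts <- strsplit(lev, "||", fixed = TRUE)
    tab <- data.frame(level = lev,
                      v1 = vapply(parts, `[`, character(1), 1),
                      v2 = vapply(parts, `[`, character(1), 2),
                      stringsAsFactors = FALSE)
    e1 <- encoding_strength(nd$dstar, tab, "v1", "v2")
    e2 <- encoding_strength(nd$dstar, tab, "v2", "v1")
    list(e1 = e1, e2 = e2, dstar = nd$dstar)
  })
  avg_pairs <- function(which_e) {
    ps <- lapply(res, function(r) r[[which_e]]$pairs)
    ids <- ps[[1]]$pair_id
    data.frame(pair_id = ids,
               dstar = rowMeans(vapply(ps, function(p)
                 p$dstar[match(ids, p$pair_id)], numeric(length(ids)))))
  }
  list(var1_encoding = mean(vapply(res, function(r) r$e1$strength,
                                   numeric(1))),
       var2_encoding = mean(vapply(res, function(r) r$e2$strength,
                                   numeric(1))),
       pair_tables = list(var1 = avg_pairs("e1"), var2 = avg_pairs("e2")),
       dstar = Reduce(`+`, lapply(res, `[[`, "dstar")) / length(res))
}

#' Compare brain regions in encoding strength
#'
#' For each region pair and each variable, fits the least-squares model
#' `dstar ~ region + condition_pair` on the combined per-pair neural
#' distances of the two regions and tests the region coefficient (two-sided
#' t-test), Bonferroni-corrected over all variables x region pairs. Each
#' region is then summarized by its "beaten counts": for each variable, the
#' number of other regions it significantly exceeds.
#'
#' @param region_tables named list (one element per region) of lists with
#'   one per-variable data frame (`pair_id`, `dstar`) each, as produced by
#'   [encoding_analysis()]`$pair_tables`.
#' @param alpha significance level after correction (default 0.05).
#' @return List with `tests` (per region pair x variable: beta, p,
#'   p_bonferroni, significant) and `beaten` (per region x variable counts).
#' @export
compare_regions <- function(region_tables, alpha = 0.05) {
  regions <- names(region_tables)
  stopifnot(length(regions) >= 2)
  variables <- names(region_tables[[1]])
  pairs <- combn(regions, 2, simplify = FALSE)
  n_tests <- length(variables) * length(pairs)
  rows <- list()
  for (v in variables) {
    for (pr in pairs) {
      d1 <- region_tables[[pr[1]]][[v]]
      d2 <- region_tables[[pr[2]]][[v]]
      dat <- rbind(cbind(d1, region = 0), cbind(d2, region = 1))
      dat$pair_id <- factor(dat$pair_id)
      fit <- if (nlevels(dat$pair_id) > 1)
        lm(dstar ~ region + pair_id, data = dat)
      else lm(dstar ~ region, data = dat)
      sm <- suppressWarnings(summary(fit))$coefficients
      if (!"region" %in% rownames(sm))
        stop("compare_regions: rank-deficient design for ",
             pr[1], " vs ", pr[2])
      beta <- sm["region", "Estimate"]
      p <- sm["region", "Pr(>|t|)"]
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, region_a = pr[1], region_b = pr[2], beta = beta,
        p = p, p_bonferroni = min(1, p * n_tests))
    }
  }
  tests <- do.call(rbind, rows)
  tests$significant <- tests$p_bonferroni < alpha
  beaten <- matrix(0L, length(regions), length(variables),
                   dimnames = list(regions, variables))
  for (r in seq_len(nrow(tests))) {
    tr <- tests[r, ]
    if (!tr$significant) next
    winner <- if (tr$beta > 0) tr$region_b else tr$region_a
    beaten[winner, tr$variable] <- beaten[winner, tr$variable] + 1L
  }
  list(tests = tests, beaten = beaten, n_tests = n_tests)
}

.ovr_fit <- function(X, y, cost = 0.1) {
  classes <- sort(unique(as.character(y)))
  fits <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
  })
  list(fits = fits, classes = classes)
}

.ovr_predict <- function(model, X) {
  dec <- vapply(model$fits, function(f) {
    dv <- attr(predict(f, X, decision.values = TRUE), "decision.values")
    d <- dv[, 1]
    if (grepl("^neg", colnames(dv)[1])) -d else d
  }, numeric(nrow(X)))
  dec <- matrix(dec, nrow = nrow(X))
  # highest decision value wins; which.max takes the first index on ties
  model$classes[apply(dec, 1, which.max)]
}

#' Cross-condition decoder generalization
#'
#' Trains a linear max-margin one-versus-rest classifier on the trials of
#' one condition (for example one location) and tests it on held-out
#' conditions, per time bin; accuracies are averaged over the analysis
#' window and linearly rescaled so chance (1/number of classes) maps to 0
#' and perfect accuracy to 1. Within-condition (cross-validated) decoding is
#' reported alongside.
#'
#' @param x K x D x T activity array (projected or unit space).
#' @param conditions K-row condition table.
#' @param time bin centres (s).
#' @param label_key column holding the decoded classes.
#' @param condition_key column holding the generalization conditions.
#' @param train_condition value of `condition_key` used for training.
#' @param test_conditions values tested (default: all others).
#' @param window analysis window (s).
#' @param cost SVM regularization (default 0.1).
#' @param within_folds folds for within-condition decoding (default 5).
#' @param seed RNG seed for the within-condition folds.
#' @return List: `rescaled`, `raw`, `per_bin`, `within_rescaled`,
#'   `within_raw`, `chance`, `classes`.
#' @export
cross_condition_decode <- function(x, conditions, time,
                                   label_key = "primitive",
                                   condition_key = "location",
                                   train_condition,
                                   test_conditions = NULL,
                                   window = c(0.05, 0.6), cost = 0.1,
                                   within_folds = 5, seed = 1) {
  y <- as.character(conditions[[label_key]])
  cond <- conditions[[condition_key]]
  if (is.null(test_conditions))
    test_conditions <- setdiff(unique(cond), train_condition)
  tr <- which(cond == train_condition)
  te <- which(cond %in% test_conditions)
  classes <- sort(unique(y[c(tr, te)]))
  if (!all(classes %in% y[tr]) || !all(classes %in% y[te]))
    stop("cross_condition_decode: every class must appear in train and test")
  bins <- which(time >= window[1] & time <= window[2])
  if (!length(bins)) stop("cross_condition_decode: empty analysis window")
  acc <- vapply(bins, function(tt) {
    Xtr <- matrix(x[tr, , tt], length(tr), dim(x)[2])
    Xte <- matrix(x[te, , tt], length(te), dim(x)[2])
    mod <- .ovr_fit(Xtr, y[tr], cost)
    mean(.ovr_predict(mod, Xte) == y[te])
  }, numeric(1))
  chance <- 1 / length(classes)
  raw <- mean(acc)
  within <- with_seed(seed, {
    folds <- sample(rep_len(seq_len(within_folds), length(tr)))
    wacc <- vapply(bins, function(tt) {
      X <- matrix(x[tr, , tt], length(tr), dim(x)[2])
      mean(vapply(seq_len(within_folds), function(fd) {
        hold <- folds == fd
        if (!all(classes %in% y[tr][!hold])) return(NA_real_)
        mod <- .ovr_fit(X[!hold, , drop = FALSE], y[tr][!hold], cost)
        mean(.ovr_predict(mod, X[hold, , drop = FALSE]) == y[tr][hold])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    mean(wacc)
  })
  list(rescaled = (raw - chance) / (1 - chance), raw = raw,
       per_bin = setNames(acc, time[bins]),
       within_rescaled = (within - chance) / (1 - chance),
       within_raw = within, chance = chance, classes = classes)
}

#' Neural primitive alignment over a morph set
#'
#' Scores each trial's time-averaged population activity (Euclidean metric)
#' with the primitive alignment a = d1 / (d1 + d2) against the practised
#' P1 and P2 trials; reference distances exclude the trial itself. The
#' output feeds [categorical_structure_test()] via
#' [alignment_set_summary()].
#'
#' @param proj K x D x T projected activity.
#' @param conditions K-row condition table (needs `trial_condition`,
#'   `morph_fraction`, `drawn_primitive`).
#' @param time bin centres (s).
#' @param window time-averaging window (s), default 0.6-1.0 s (late
#'   planning, where boundary-trial separation is greatest).
#' @return Data frame: trial, morph_fraction, condition, drawn_primitive, a.
#' @export
neural_primitive_alignment <- function(proj, conditions, time,
                                       window = c(0.6, 1.0)) {
  bins <- which(time >= window[1] & time <= window[2])
  if (!length(bins)) stop("neural_primitive_alignment: empty window")
  K <- dim(proj)[1]
  V <- t(vapply(seq_len(K), function(k)
    rowMeans(matrix(proj[k, , bins], dim(proj)[2], length(bins))),
    numeric(dim(proj)[2])))
  tc <- conditions$trial_condition
  p1 <- which(tc == "P1"); p2 <- which(tc == "P2")
  if (!length(p1) || !length(p2))
    stop("neural_primitive_alignment: P1/P2 reference trials required")
  a <- vapply(seq_len(K), function(k) {
    r1 <- setdiff(p1, k); r2 <- setdiff(p2, k)
    d1 <- mean(sqrt(colSums((t(V[r1, , drop = FALSE]) - V[k, ])^2)))
    d2 <- mean(sqrt(colSums((t(V[r2, , drop = FALSE]) - V[k, ])^2)))
    if (d1 + d2 == 0) 0.5 else d1 / (d1 + d2)
  }, numeric(1))
  data.frame(trial = seq_len(K), morph_fraction = conditions$morph_fraction,
             condition = tc, drawn_primitive = conditions$drawn_primitive,
             a = a, stringsAsFactors = FALSE)
}

#' Summarize per-trial alignments into one morph-set row
#'
#' Produces the one-row-per-morph-set input to
#' [categorical_structure_test()]: mean drawing (or neural) alignment per
#' trial condition, with boundary (A) trials split into A1/A2 by the drawn
#' primitive, paired with the image-metric alignments of the same
#' conditions.
#'
#' Image alignments are linearly rescaled so that the practised end points
#' (P1, P2) match the drawing scores; drawing-based alignments never reach 0
#' and 1 exactly because of trial-by-trial variation, and the rescaling
#' makes the U1/U2 drawing-versus-image comparison unbiased.
#'
#' @param drawing data frame with columns `condition`, `a` and (for
#'   boundary splitting) `drawn_primitive`.
#' @param image data frame with columns `condition`, `a` (image-metric
#'   alignment per morph level).
#' @return One-row data frame with `drawing_*` and `image_*` columns
#'   (`image_U1`, `image_U2` rescaled as above).
#' @export
alignment_set_summary <- function(drawing, image) {
  dr <- drawing
  if (!is.null(dr$drawn_primitive)) {
    amb <- dr$condition == "A"
    dr$condition[amb] <- ifelse(dr$drawn_primitive[amb] %in% c("P1", "prim_a"),
                                "A1", "A2")
    amb2 <- dr$condition %in% c("A1", "A2") &
      !(dr$drawn_primitive %in% c("P1", "prim_a", "P2", "prim_b"))
    # labels already A1/A2 (neural tensors) are kept as-is
    dr$condition[amb2] <- dr$condition[amb2]
  }
  dm <- tapply(dr$a, dr$condition, mean)
  im <- tapply(image$a, image$condition, mean)
  gv <- function(x, nm) if (nm %in% names(x)) unname(x[nm]) else NA_real_
  img_u1 <- gv(im, "U1"); img_u2 <- gv(im, "U2")
  ends <- c(gv(dm, "P1"), gv(dm, "P2"), gv(im, "P1"), gv(im, "P2"))
  if (all(is.finite(ends)) && ends[4] != ends[3]) {
    sc <- function(x) ends[1] + (x - ends[3]) / (ends[4] - ends[3]) *
      (ends[2] - ends[1])
    img_u1 <- sc(img_u1); img_u2 <- sc(img_u2)
  }
  data.frame(drawing_P1 = gv(dm, "P1"), drawing_U1 = gv(dm, "U1"),
             drawing_A1 = gv(dm, "A1"), drawing_A2 = gv(dm, "A2"),
             drawing_U2 = gv(dm, "U2"), drawing_P2 = gv(dm, "P2"),
             image_U1 = img_u1, image_U2 = img_u2)
}

#' Pairwise primitive decoding from trial vectors
#'
#' Represents each trial as the concatenation of its units' time series
#' (0.2 s bins, 0.1 s slide), reduces to the top `n_pcs` principal
#' components, and decodes every pair of primitives with a linear classifier
#' trained at one generalization condition (location or size) and tested at
#' the others, averaging over train conditions. When `regions` is given,
#' each region's unit count is matched to the smallest by random
#' subsampling without replacement, averaged over `n_subsample` repeats.
#'
#' @param pt a `population_tensor`.
#' @param window analysis window (s).
#' @param condition_key generalization variable (default `"location"`).
#' @param n_pcs retained components (default 50).
#' @param bin,slide trial-vector binning (s).
#' @param cost SVM regularization.
#' @param regions optional region labels to compare.
#' @param n_subsample subsampling repeats (default 10).
#' @param min_units regions below this unit count are excluded.
#' @param seed RNG seed.
#' @return A primitive x primitive accuracy matrix, or a named list of them
#'   (one per region).
#' @export
pairwise_primitive_decoding <- function(pt, window = c(0.05, 0.6),
                                        condition_key = "location",
                                        n_pcs = 50, bin = 0.2, slide = 0.1,
                                        cost = 0.1, regions = NULL,
                                        n_subsample = 10, min_units = 5,
                                        seed = 1) {
  validate_population_tensor(pt)
  if (is.null(regions)) return(.ppd_one(pt, window, condition_key, n_pcs,
                                        bin, slide, cost))
  counts <- table(pt$unit_region)[regions]
  keep <- names(counts)[!is.na(counts) & counts >= min_units]
  if (length(keep) < length(regions))
    warning("pairwise_primitive_decoding: excluding regions below ",
            min_units, " units")
  n_match <- min(counts[keep])
  with_seed(seed, {
    out <- lapply(keep, function(rg) {
      ix <- which(pt$unit_region == rg)
      reps <- lapply(seq_len(n_subsample), function(r)
        .ppd_one(subset_tensor(pt, units = sample(ix, n_match)),
                 window, condition_key, n_pcs, bin, slide, cost))
      Reduce(`+`, reps) / length(reps)
    })
    setNames(out, keep)
  })
}

.ppd_one <- function(pt, window, condition_key, n_pcs, bin, slide, cost) {
  ptb <- rebin_tensor(pt, bin, slide, window)
  dm <- dim(ptb$rates)
  D <- matrix(ptb$rates, dm[1], dm[2] * dm[3])
  pc <- prcomp(D, center = TRUE, scale. = FALSE)
  Z <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  y <- as.character(ptb$conditions$primitive)
  g <- ptb$conditions[[condition_key]]
  prims <- sort(unique(y))
  if (length(prims) < 2 || length(unique(g)) < 2)
    stop("pairwise_primitive_decoding: need >= 2 primitives and >= 2 ",
         condition_key, " conditions")
  acc <- matrix(NA_real_, length(prims), length(prims),
                dimnames = list(prims, prims))
  for (i in seq_len(length(prims) - 1)) for (j in (i + 1):length(prims)) {
    sel <- y %in% prims[c(i, j)]
    accs <- vapply(unique(g), function(gc) {
      tr <- sel & g == gc; te <- sel & g != gc
      if (length(unique(y[tr])) < 2 || !any(te)) return(NA_real_)
      fit <- e1071::svm(Z[tr, , drop = FALSE], factor(y[tr]),
                        kernel = "linear", cost = cost, scale = FALSE)
      mean(as.character(predict(fit, Z[te, , drop = FALSE])) == y[te])
    }, numeric(1))
    acc[i, j] <- acc[j, i] <- mean(accs, na.rm = TRUE)
  }
  acc
}

#' Correct neural activity for the initial reach
#'
#' Single-shape strokes (and the first stroke of a character) include the
#' initial reaching movement from the hold button; later character strokes
#' do not. To compare them, the mean effect of the initial reach is
#' estimated per unit and time bin with the least-squares model
#' `y ~ first_stroke + task_type + primitive` and the first-stroke
#' coefficient is subtracted from first-stroke trials only; other trials
#' are untouched.
#'
#' @param pt a `population_tensor` whose conditions include first and
#'   non-first strokes.
#' @return List with `tensor` (corrected) and `beta_f` (N x T matrix of
#'   reach effects).
#' @export
correct_initial_reach <- function(pt) {
  validate_population_tensor(pt)
  cond <- pt$conditions
  xf <- as.numeric(cond$first_stroke)
  if (all(xf == 1) || all(xf == 0))
    stop("correct_initial_reach: need both first and non-first strokes")
  X <- cbind(intercept = 1, Xf = xf)
  if (length(unique(cond$task_type)) > 1)
    X <- cbind(X, Xt = as.numeric(factor(cond$task_type)) - 1)
  prim <- factor(cond$primitive)
  if (nlevels(prim) > 1)
    X <- cbind(X, stats::model.matrix(~prim)[, -1, drop = FALSE])
  qx <- qr(X)
  dm <- dim(pt$rates)
  Y <- matrix(pt$rates, dm[1], dm[2] * dm[3])
  B <- qr.coef(qx, Y)
  beta_f <- matrix(B["Xf", ], dm[2], dm[3])
  corr <- pt$rates
  first <- which(xf == 1)
  for (k in first) corr[k, , ] <- corr[k, , ] - beta_f
  pt$rates <- corr
  list(tensor = pt, beta_f = beta_f)
}

#' Linear kinematic encoding model scored by FVAF
#'
#' Fits `f_t = E v_t + b` mapping 2-D finger velocity to activity in the
#' top neural components, training on all primitives but one and scoring
#' the held-out primitive with the fraction of variance accounted for,
#' `FVAF = 1 - SS_err / SS_tot` (uncentred total sum of squares; predictions
#' include the intercept). The fit is repeated over a grid of neural-
#' behaviour lags (negative = neural leads) by shifting the pairing of
#' neural and velocity samples; the scalar summary averages lags in
#' `summary_window`.
#'
#' @param neural list per trial of T_i x D matrices (top neural components).
#' @param velocity list per trial of T_i x 2 velocity matrices.
#' @param primitive primitive label per trial (>= 3 levels).
#' @param dt sample period of the series (s).
#' @param lags lag grid (s), default -0.3 to 0.3 in 0.05 steps.
#' @param summary_window lags averaged into the scalar summary (s).
#' @return List: `fvaf_by_lag`, `summary`, `peak_lag`, `lags`.
#' @export
fvaf_kinematics <- function(neural, velocity, primitive, dt,
                            lags = seq(-0.3, 0.3, by = 0.05),
                            summary_window = c(-0.15, -0.05)) {
  stopifnot(length(neural) == length(velocity),
            length(neural) == length(primitive))
  prims <- unique(as.character(primitive))
  if (length(prims) < 3)
    stop("fvaf_kinematics: need >= 3 primitives for held-out scheme")
  if (all(vapply(velocity, function(v) all(v == 0), logical(1))))
    stop("fvaf_kinematics: degenerate velocity (all zero)")
  fvaf_lag <- vapply(lags, function(L) {
    k <- as.integer(round(L / dt))
    F_all <- list(); V_all <- list(); lab <- character(0)
    for (i in seq_along(neural)) {
      Ti <- nrow(neural[[i]])
      f_idx <- seq.int(max(1, 1 + k), min(Ti, Ti + k))
      if (length(f_idx) < 2) next
      F_all[[length(F_all) + 1]] <- neural[[i]][f_idx, , drop = FALSE]
      V_all[[length(V_all) + 1]] <- velocity[[i]][f_idx - k, , drop = FALSE]
      lab <- c(lab, rep(as.character(primitive[i]), length(f_idx)))
    }
    F <- do.call(rbind, F_all); V <- do.call(rbind, V_all)
    mean(vapply(prims, function(hp) {
      tr <- lab != hp; te <- lab == hp
      B <- qr.coef(qr(cbind(V[tr, , drop = FALSE], 1)), F[tr, , drop = FALSE])
      pred <- cbind(V[te, , drop = FALSE], 1) %*% B
      resid <- pred - F[te, , drop = FALSE]
      1 - sum(resid^2) / sum(F[te, , drop = FALSE]^2)
    }, numeric(1)))
  }, numeric(1))
  names(fvaf_lag) <- sprintf("%.2f", lags)
  in_sum <- lags >= summary_window[1] - 1e-9 & lags <= summary_window[2] + 1e-9
  list(fvaf_by_lag = fvaf_lag, summary = mean(fvaf_lag[in_sum]),
       peak_lag = lags[which.max(fvaf_lag)], lags = lags)
}

#' Fixation-aligned primitive decoding
#'
#' Trains a one-versus-rest logistic decoder of the planned primitive on
#' planning-epoch snippets (0.3 s bins, 0.1 s slide) from single-shape
#' trials, then scores fixation-aligned population activity with one
#' probability per primitive. Each fixation is assigned the primitive of
#' the nearest image shape; fixations farther than `exclude_px` from every
#' shape are excluded (count reported).
#'
#' @param train_pt single-shape `population_tensor` from the same session.
#' @param window planning-epoch training window (s).
#' @param fixations data frame with `x`, `y` (px) and `planned_primitive`.
#' @param shapes named list (primitive -> point set) of displayed shapes.
#' @param fixation_activity n_fix x N activity matrix aligned to fixations.
#' @param exclude_px exclusion radius (px, default 70).
#' @param bin,slide training snippet binning (s).
#' @return List: `scores` (per kept fixation: fixated and planned primitive
#'   and their probabilities), `probs` (full matrix), `n_excluded`.
#' @export
fixation_decoding <- function(train_pt, window, fixations, shapes,
                              fixation_activity, exclude_px = 70,
                              bin = 0.3, slide = 0.1) {
  validate_population_tensor(train_pt)
  ptb <- rebin_tensor(train_pt, bin, slide, window)
  dm <- dim(ptb$rates)
  X <- do.call(rbind, lapply(seq_len(dm[3]), function(tt)
    matrix(ptb$rates[, , tt], dm[1], dm[2])))
  y <- rep(as.character(ptb$conditions$primitive), times = dm[3])
  prims <- sort(unique(y))
  coefs <- lapply(prims, function(cl) {
    fit <- suppressWarnings(glm.fit(cbind(1, X), as.numeric(y == cl),
                                    family = binomial()))
    coef(fit)
  })
  dmin <- vapply(shapes, function(sh)
    min_dist_to_set(as.matrix(fixations[, c("x", "y")]), as.matrix(sh)),
    numeric(nrow(fixations)))
  dmin <- matrix(dmin, nrow = nrow(fixations))
  nearest <- apply(dmin, 1, which.min)
  best <- dmin[cbind(seq_len(nrow(fixations)), nearest)]
  keep <- best <= exclude_px
  probs <- vapply(coefs, function(b) {
    eta <- cbind(1, fixation_activity[keep, , drop = FALSE]) %*% b
    as.numeric(stats::plogis(eta))
  }, numeric(sum(keep)))
  probs <- matrix(probs, nrow = sum(keep), dimnames = list(NULL, prims))
  fixated <- names(shapes)[nearest[keep]]
  planned <- as.character(fixations$planned_primitive[keep])
  scores <- data.frame(fixation = which(keep), fixated_primitive = fixated,
                       planned_primitive = planned,
                       p_fixated = probs[cbind(seq_len(sum(keep)),
                                               match(fixated, prims))],
                       p_planned = probs[cbind(seq_len(sum(keep)),
                                               match(planned, prims))],
                       stringsAsFactors = FALSE)
  list(scores = scores, probs = probs, n_excluded = sum(!keep))
}
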