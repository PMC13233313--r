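#' Condition table for a simulated population
#'
#' @param primitives,locations,sizes,task_types,morph_fractions condition
#'   factor levels; the grid is their full crossing.
#' @return Data frame with one row per condition.
#' @export
condition_grid <- function(primitives, locations = 1, sizes = 1,
                           task_types = "single_shape",
                           morph_fractions = NA_real_) {
  expand.grid(primitive = primitives, location = locations, size = sizes,
              task_type = task_types, morph_fraction = morph_fractions,
              stringsAsFactors = FALSE)
}

#' Design for a simulated population tensor
#'
#' Describes how unit firing rates are generated: each unit has random
#' tuning weights for primitive, location, size and task type, scaled by the
#' corresponding gains; a shared ramping temporal profile carries the signal;
#' and Gaussian (on rates) or Poisson (on counts) noise is added. For morph
#' designs, `categorical_flag = TRUE` routes each morph trial through the
#' boundary rule (the drawn primitive's tuning is used, switching
#' stochastically at the boundary), whereas `FALSE` mixes the two end-point
#' tunings linearly in the morph fraction. `primitive_by_location = TRUE`
#' draws primitive tuning independently per location (a location-specific,
#' non-invariant code).
#'
#' @param conditions data frame from [condition_grid()].
#' @param n_units,n_trials_per_condition dimensions of the simulation.
#' @param time_base bin centres (s), strictly increasing.
#' @param bin_width bin width (s).
#' @param baseline baseline rate (Hz).
#' @param primitive_gain,location_gain,size_gain,task_gain non-negative
#'   tuning gains (Hz per unit tuning weight).
#' @param categorical_flag categorical vs linear morph readout.
#' @param primitive_by_location location-specific primitive tuning.
#' @param boundary_fraction category boundary for morph trials.
#' @param noise list: `type` (`"gaussian"` or `"poisson"`) and `sd`
#'   (Gaussian rate sd, Hz).
#' @param regions region label(s) recycled over units.
#' @param seed RNG seed.
#' @return An object of class `population_design`.
#' @export
population_design <- function(conditions, n_units = 60,
                              n_trials_per_condition = 8,
                              time_base = seq(0.025, 0.575, by = 0.05),
                              bin_width = 0.05, baseline = 10,
                              primitive_gain = 1, location_gain = 1,
                              size_gain = 0, task_gain = 0,
                              categorical_flag = TRUE,
                              primitive_by_location = FALSE,
                              boundary_fraction = 0.5,
                              noise = list(type = "gaussian", sd = 1),
                              regions = "PMv", seed = 1) {
  gains <- c(primitive_gain, location_gain, size_gain, task_gain)
  if (any(gains < 0)) stop("population_design: gains must be >= 0")
  if (any(diff(time_base) <= 0))
    stop("population_design: time bins must be strictly increasing")
  structure(list(conditions = conditions, n_units = n_units,
                 n_trials_per_condition = n_trials_per_condition,
                 time_base = time_base, bin_width = bin_width,
                 baseline = baseline, primitive_gain = primitive_gain,
                 location_gain = location_gain, size_gain = size_gain,
                 task_gain = task_gain, categorical_flag = categorical_flag,
                 primitive_by_location = primitive_by_location,
                 boundary_fraction = boundary_fraction, noise = noise,
                 regions = regions, seed = seed),
            class = "population_design")
}

#' Simulate a population tensor
#'
#' Generates trials x units x time-bins firing rates with the tuning
#' structure specified by the design (see [population_design()]). The rate
#' of unit n on a trial of condition c is
#' `baseline + g(t) * (primitive_gain * w_prim + location_gain * w_loc + ...)`
#' plus noise, where `g(t)` is a ramping profile after stimulus onset and
#' the `w` are fixed standard-normal tuning weights per unit and level.
#'
#' @param design a [population_design()].
#' @return A `population_tensor`: list with `rates` (K x N x T array),
#'   `conditions` (K-row label table with `primitive`, `location`, `size`,
#'   `task_type`, `morph_fraction`, `drawn_primitive`, `trial_condition`,
#'   `first_stroke`, `stroke_index`), `time`, `bin_width`, `unit_region`.
#' @export
simulate_population <- function(design) {
  stopifnot(inherits(design, "population_design"))
  d <- design
  with_seed(d$seed, {
    cond <- d$conditions
    prims <- unique(cond$primitive[!is.na(cond$primitive)])
    is_morph <- any(!is.na(cond$morph_fraction))
    if (is_morph && length(prims) != 2)
      stop("simulate_population: morph designs need exactly 2 primitives")
    locs <- unique(cond$location)
    szs <- unique(cond$size)
    tks <- unique(cond$task_type)
    N <- d$n_units; T <- length(d$time_base)
    w_prim <- if (d$primitive_by_location) {
      array(rnorm(N * length(prims) * length(locs)),
            dim = c(N, length(prims), length(locs)),
            dimnames = list(NULL, prims, as.character(locs)))
    } else {
      matrix(rnorm(N * length(prims)), N, length(prims),
             dimnames = list(NULL, prims))
    }
    w_loc <- matrix(rnorm(N * length(locs)), N, length(locs),
                    dimnames = list(NULL, as.character(locs)))
    w_size <- matrix(rnorm(N * length(szs)), N, length(szs),
                     dimnames = list(NULL, as.character(szs)))
    w_task <- matrix(rnorm(N * length(tks)), N, length(tks),
                     dimnames = list(NULL, tks))
    g <- pmin(1, pmax(0, (d$time_base - min(d$time_base)) / 0.2 + 0.2))
    K <- nrow(cond) * d$n_trials_per_condition
    rates <- array(0, dim = c(K, N, T))
    labels <- cond[rep(seq_len(nrow(cond)), each = d$n_trials_per_condition), ,
                   drop = FALSE]
    rownames(labels) <- NULL
    labels$drawn_primitive <- as.character(labels$primitive)
    for (k in seq_len(K)) {
      row <- labels[k, ]
      f <- row$morph_fraction
      if (is_morph && !is.na(f)) {
        if (d$categorical_flag) {
          use_a <- if (f == d$boundary_fraction) runif(1) < 0.5 else
            f < d$boundary_fraction
          pr <- if (use_a) prims[1] else prims[2]
          labels$drawn_primitive[k] <- pr
          wp <- .prim_weights(w_prim, pr, row$location, d)
        } else {
          labels$drawn_primitive[k] <- if (f <= 0.5) prims[1] else prims[2]
          wp <- (1 - f) * .prim_weights(w_prim, prims[1], row$location, d) +
            f * .prim_weights(w_prim, prims[2], row$location, d)
        }
      } else {
        wp <- .prim_weights(w_prim, as.character(row$primitive),
                            row$location, d)
      }
      tun <- d$primitive_gain * wp +
        d$location_gain * w_loc[, as.character(row$location)] +
        d$size_gain * w_size[, as.character(row$size)] +
        d$task_gain * w_task[, as.character(row$task_type)]
      mu <- d$baseline + outer(tun, g)
      if (identical(d$noise$type, "poisson")) {
        lam <- pmax(mu, 0) * d$bin_width
        rates[k, , ] <- matrix(rpois(N * T, lam), N, T) / d$bin_width
      } else {
        rates[k, , ] <- mu + matrix(rnorm(N * T, 0, d$noise$sd), N, T)
      }
    }
    if (is_morph) {
      labels$trial_condition <- morph_condition_labels(labels$morph_fraction,
                                                       d$boundary_fraction)
      bnd <- labels$trial_condition == "A"
      labels$trial_condition[bnd] <-
        ifelse(labels$drawn_primitive[bnd] == prims[1], "A1", "A2")
    } else {
      labels$trial_condition <- NA_character_
    }
    labels$first_stroke <- TRUE
    labels$stroke_index <- 1L
    pt <- structure(list(rates = rates, conditions = labels,
                         time = d$time_base, bin_width = d$bin_width,
                         unit_region = rep_len(d$regions, N)),
                    class = "population_tensor")
    validate_population_tensor(pt)
    pt
  })
}

.prim_weights <- function(w_prim, prim, location, d) {
  if (d$primitive_by_location) w_prim[, prim, as.character(location)]
  else w_prim[, prim]
}

#' Validate the population-tensor schema
#'
#' Checks the label schema that every population-analysis operation assumes:
#' a K x N x T rate array, a K-row condition table with the required columns,
#' a strictly increasing time base matching T, and one region label per unit.
#'
#' @param pt a `population_tensor`.
#' @return `pt`, invisibly; errors if the schema is violated.
#' @export
validate_population_tensor <- function(pt) {
  stopifnot(inherits(pt, "population_tensor"))
  dm <- dim(pt$rates)
  if (length(dm) != 3) stop("rates must be a K x N x T array")
  if (nrow(pt$conditions) != dm[1])
    stop("condition table rows must match trial count")
  need <- c("primitive", "location", "size", "task_type", "morph_fraction",
            "drawn_primitive", "trial_condition", "first_stroke",
            "stroke_index")
  miss <- setdiff(need, names(pt$conditions))
  if (length(miss)) stop("condition table missing: ",
                         paste(miss, collapse = ", "))
  if (length(pt$time) != dm[3]) stop("time base must match T")
  if (any(diff(pt$time) <= 0)) stop("time base must be strictly increasing")
  if (length(pt$unit_region) != dm[2]) stop("one region label per unit")
  invisible(pt)
}

#' Subset a population tensor by trials or units
#'
#' @param pt a `population_tensor`.
#' @param trials,units index vectors (logical or integer).
#' @return The subset `population_tensor`.
#' @export
subset_tensor <- function(pt, trials = NULL, units = NULL) {
  if (!is.null(trials)) {
    pt$rates <- pt$rates[trials, , , drop = FALSE]
    pt$conditions <- pt$conditions[trials, , drop = FALSE]
    rownames(pt$conditions) <- NULL
  }
  if (!is.null(units)) {
    pt$rates <- pt$rates[, units, , drop = FALSE]
    pt$unit_region <- pt$unit_region[units]
  }
  pt
}

#' Serialize a population tensor to plain text
#'
#' Writes `rates.csv` (long format: trial, unit, bin, rate), `conditions.csv`
#' and `meta.json` (time base, bin width, unit regions) into `dir`, and reads
#' them back. Real recordings exported in this schema are interchangeable
#' with simulated tensors downstream.
#'
#' @param pt a `population_tensor`.
#' @param dir directory path.
#' @name tensor_io
#' @export
write_population_tensor <- function(pt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(pt$rates)
  long <- data.frame(trial = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
                     unit = rep(rep(seq_len(dm[2]), each = dm[1]),
                                times = dm[3]),
                     bin = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
                     rate = as.vector(pt$rates))
  write.csv(long, file.path(dir, "rates.csv"), row.names = FALSE)
  write.csv(pt$conditions, file.path(dir, "conditions.csv"), row.names = FALSE)
  jsonlite::write_json(list(time = pt$time, bin_width = pt$bin_width,
                            unit_region = pt$unit_region, dim = dm),
                       file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' @rdname tensor_io
#' @export
read_population_tensor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  long <- read.csv(file.path(dir, "rates.csv"))
  dm <- meta$dim
  rates <- array(0, dim = dm)
  rates[cbind(long$trial, long$unit, long$bin)] <- long$rate
  conditions <- read.csv(file.path(dir, "conditions.csv"),
                         stringsAsFactors = FALSE)
  conditions$trial_condition <- as.character(conditions$trial_condition)
  conditions$drawn_primitive <- as.character(conditions$drawn_primitive)
  pt <- structure(list(rates = rates, conditions = conditions,
                       time = meta$time, bin_width = meta$bin_width,
                       unit_region = meta$unit_region),
                  class = "population_tensor")
  validate_population_tensor(pt)
  pt
}
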