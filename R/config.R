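#' Run the synthetic-data generators from a YAML config
#'
#' The config may contain blocks `primitives`, `morphs`, `characters` and
#' `population`, each with its own seed. Example:
#'
#' ```yaml
#' primitives: {n: 6, seed: 1}
#' morphs: {prim_a: prim01, prim_b: prim02, n_morphs: 5}
#' characters: {n: 3, n_shapes: 3, seed: 2}
#' population:
#'   primitives: [prim01, prim02]
#'   locations: [1, 2]
#'   n_units: 40
#'   n_trials_per_condition: 8
#'   primitive_gain: 1
#'   location_gain: 1
#'   seed: 3
#' ```
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return A list with whichever of `library`, `morph_set`, `characters`
#'   and `tensor` the config requested.
#' @export
simulate_from_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out <- list()
  if (!is.null(cfg$primitives)) {
    p <- cfg$primitives
    out$library <- make_primitive_library(p$n, seed = p$seed %||% 1)
  }
  if (!is.null(cfg$morphs)) {
    m <- cfg$morphs
    lib <- out$library
    if (is.null(lib)) stop("simulate_from_config: morphs need primitives")
    out$morph_set <- make_morph_set(lib[[m$prim_a]], lib[[m$prim_b]],
                                    n_morphs = m$n_morphs %||% 5)
  }
  if (!is.null(cfg$characters)) {
    ch <- cfg$characters
    if (is.null(out$library))
      stop("simulate_from_config: characters need primitives")
    out$characters <- lapply(seq_len(ch$n %||% 1), function(i)
      sample_character(out$library, ch$n_shapes %||% 3,
                       seed = (ch$seed %||% 1) + i))
  }
  if (!is.null(cfg$population)) {
    p <- cfg$population
    cond <- condition_grid(primitives = unlist(p$primitives),
                           locations = unlist(p$locations %||% 1),
                           sizes = unlist(p$sizes %||% 1),
                           task_types = unlist(p$task_types %||%
                                                 "single_shape"))
    keep <- setdiff(names(p), c("primitives", "locations", "sizes",
                                "task_types"))
    des <- do.call(population_design, c(list(conditions = cond), p[keep]))
    out$tensor <- simulate_population(des)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
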