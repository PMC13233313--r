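# Expensive fixtures are built once per test run and shared across files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_library <- function() fixture("small_library", function()
  make_primitive_library(4, seed = 11))

# Templates fitted from noisy single-shape trials of the small library.
small_templates <- function() fixture("small_templates", function() {
  lib <- small_library()
  trials <- lapply(lib, function(p)
    lapply(1:20, function(i) sample_stroke(p, seed = 100 + i)))
  fit_primitive_templates(trials)
})

# A subject-sized repertoire; remixed-set constraints need the smaller
# between-primitive distance floor that comes with more primitives.
rich_templates <- function() fixture("rich_templates", function() {
  lib <- make_primitive_library(8, seed = 11)
  trials <- lapply(lib, function(p)
    lapply(1:12, function(i) sample_stroke(p, seed = 100 + i)))
  fit_primitive_templates(trials)
})
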