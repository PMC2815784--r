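# Shared, lazily computed fixtures.  The Monte Carlo runs are the expensive
# part of the suite; they are simulated once and reused across test files.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .test_cache)
  }
  get(name, envir = .test_cache, inherits = FALSE)
}

# rat phantom, full physics, acceptance-grade statistics
rat_grid <- function() cached("rat_grid", simulate_single_microbeam(
  rat_phantom(), microbeam_spec(50, 2), source_spectrum(),
  transport_config(n_histories = 4e6, seed = 1)))

rat_metrics <- function() cached("rat_metrics",
  rat_study(grid = rat_grid())$metrics)

# human phantom, one grid per beam height (= field height)
human_grid <- function(field_mm) cached(paste0("human_grid_", field_mm),
  simulate_single_microbeam(
    human_phantom(), microbeam_spec(50, field_mm), source_spectrum(),
    transport_config(n_histories = 4e6, seed = 1)))

human_metrics <- function(field_mm, spacing_um = 200) cached(
  paste0("human_metrics_", field_mm, "_", spacing_um),
  human_study(field_width_mm = field_mm, spacing_um = spacing_um,
              grid = human_grid(field_mm))$metrics)

# small, fast rat grid for behavioural (non-acceptance) tests
small_grid <- function() cached("small_grid", simulate_single_microbeam(
  rat_phantom(), microbeam_spec(50, 2), source_spectrum(),
  transport_config(n_histories = 2e5, seed = 11)))
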