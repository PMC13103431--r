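# Shared fixtures, built lazily and cached for the session.

fixture_env <- new.env(parent = emptyenv())

ref_protocol <- function() {
  if (is.null(fixture_env$protocol)) fixture_env$protocol <- reference_protocol()
  fixture_env$protocol
}

# Small four-population training sets (fast unit-test scale).
small_training_sets <- function(n_cells = 90, seed = 11) {
  key <- paste0("sets_", n_cells, "_", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- lapply(
      reference_population_specs(seed = seed, n_cells = n_cells),
      simulate_population, protocol = ref_protocol()
    )
  }
  fixture_env[[key]]
}

small_model <- function(n_cells = 90, seed = 11) {
  key <- paste0("model_", n_cells, "_", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- train_npq_model(small_training_sets(n_cells, seed),
                                          seed = seed)
  }
  fixture_env[[key]]
}

# Full-size reference training run (used by the acceptance checks).
reference_model <- function(seed = 1) {
  key <- paste0("refmodel_", seed)
  if (is.null(fixture_env[[key]])) {
    sets <- lapply(reference_population_specs(seed = seed),
                   simulate_population, protocol = ref_protocol())
    fixture_env[[paste0("refsets_", seed)]] <- sets
    fixture_env[[key]] <- train_npq_model(sets, seed = seed)
  }
  fixture_env[[key]]
}

reference_sets <- function(seed = 1) {
  reference_model(seed)
  fixture_env[[paste0("refsets_", seed)]]
}
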