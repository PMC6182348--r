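# Shared fixtures. Simulated table sets are cached so several test
# files can reuse one fit-sized dataset without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

cached_tables <- function(preset = "female_like", seed = 1, ...) {
  key <- paste(preset, seed, ..., sep = "/")
  if (is.null(.fixture_cache[[key]])) {
    gt <- make_ground_truth(preset, seed = seed, ...)
    .fixture_cache[[key]] <- simulate_life_tables(gt)
  }
  .fixture_cache[[key]]
}

cached_fit <- function(model, preset = "female_like", seed = 1) {
  key <- paste("fit", model, preset, seed, sep = "/")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- fit_mortality_model(
      cached_tables(preset, seed), model
    )
  }
  .fixture_cache[[key]]
}

# A tiny deterministic three-group grid used in hand-computed examples.
tiny_grid <- function() age_grid(c(0, 1, 5), c(1, 4, 5))

# Noiseless life tables carrying exact probabilities q (matrix ages x years).
exact_tables <- function(q, grid, years, E = 1e5, sex = "test") {
  lapply(seq_along(years), function(j) {
    build_life_table(q[, j], grid, year = years[j], sex = sex,
                     E = rep(E, length(grid)), d_obs = E * q[, j],
                     close_last = FALSE)
  })
}
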