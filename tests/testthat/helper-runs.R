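# Lazily computed, cached end-to-end runs shared by the heavier tests so the
# 10,000-person population is generated and rendered once per session.

.run_cache <- new.env(parent = emptyenv())

cached_population <- function(n = 10000, seed = 101) {
  key <- paste0("pop_", n, "_", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- generate_population(population_params(n = n),
                                             seed = seed)
  }
  .run_cache[[key]]
}

cached_render <- function(dialect, n = 10000, seed = 101,
                          render_seed = 202) {
  key <- paste0("render_", dialect, "_", n, "_", seed, "_", render_seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- render_dialect(cached_population(n, seed), dialect,
                                        fixture_codelists(),
                                        fixture_mapping(),
                                        seed = render_seed)
  }
  .run_cache[[key]]
}

cached_cohort <- function(dialect, disease, n = 10000, seed = 101,
                          render_seed = 202) {
  key <- paste0("cohort_", dialect, "_", disease, "_", n, "_", seed, "_",
                render_seed)
  if (is.null(.run_cache[[key]])) {
    r <- cached_render(dialect, n, seed, render_seed)
    cls <- fixture_codelists()
    spec <- cohort_spec(disease)
    .run_cache[[key]] <- list(
      cohort = apply_cohort_criteria(r$bundle, spec, cls[[disease]],
                                     codelists = cls),
      manifest = r$manifest, spec = spec)
  }
  .run_cache[[key]]
}
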