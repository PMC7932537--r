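# Shared simulated experiment at the generator's default scale, built once
# per test run (used by the end-to-end and acceptance tests).

.fixture_env <- new.env(parent = emptyenv())

default_experiment <- function() {
  if (is.null(.fixture_env$sim)) {
    naive <- simulate_naive_library(seed = 101)
    land <- make_landscape(seed = 102)
    sel <- simulate_selection(naive, land, selection_config(seed = 103),
                              protease_label = "simMMP")
    an <- selectome_analysis(sel, naive)
    .fixture_env$sim <- list(naive = naive, landscape = land,
                             selection = sel, analysis = an)
  }
  .fixture_env$sim
}

# Smaller companion experiment for generator-behavior tests.
small_experiment <- function(landscape, seed = 301, n_distinct = 2e5,
                             depth = 6e5, sel_depth = 6e4, ...) {
  naive <- simulate_naive_library(n_distinct, depth, seed = seed)
  sel <- simulate_selection(naive, landscape,
                            selection_config(sequencing_depth = sel_depth,
                                             seed = seed + 1L, ...))
  list(naive = naive, selection = sel)
}
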