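# Shared fixtures.  The default-geometry swallow simulations are the
# expensive objects; they are computed once per test run and memoised.
.sim_cache <- new.env(parent = emptyenv())

default_model <- function(cell_size = 0.2, wire = FALSE) {
  build_domain(domain_spec(cell_size = cell_size),
               appliance_spec(wire_present = wire))
}

cached_sim <- function(key = "gingival_02", cell_size = 0.2,
                       direction = "gingival", wire = FALSE) {
  if (is.null(.sim_cache[[key]])) {
    model <- default_model(cell_size = cell_size, wire = wire)
    .sim_cache[[key]] <- simulate_swallow(model, swallow_cycle(direction))
  }
  .sim_cache[[key]]
}

# small appliance-free channel geometry for solver validation
channel_model <- function(cell_size = 0.1, depth = 1.4) {
  build_domain(domain_spec(length_md = 0.8, length_og = 0.8, depth = depth,
                           cell_size = cell_size))
}

# compact bracket geometry for quick solver runs
small_bracket_model <- function(cell_size = 0.4) {
  build_domain(domain_spec(cell_size = cell_size), appliance_spec())
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
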