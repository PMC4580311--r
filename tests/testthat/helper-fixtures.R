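# Shared fixtures: shipped model (loaded once) and small labeling setups.

shipped_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- load_network(xump_model_path())
  .fixture_env$model
}
.fixture_env <- new.env(parent = emptyenv())

scramble_setup <- function(tracer = 0.2) {
  list(net = toy_scramble_network(),
       lab = tracer_mixture("S_e", tracer),
       fr = fragment_map(list(A = list(A = 1:2), B = list(B = 1:2))))
}

# steady-state flux vector for the full model, methanol/glycerol condition
full_model_fluxes <- function(net) {
  basis <- parameterize_free_fluxes(net, list(
    fixed = c(GLYC_up = 1.64, MEOH_up = 0.81, GLC_up = 0, T_HCHO = 0.4),
    include_biomass = TRUE,
    lower = c(BIOMASS = 0.1), upper = c(BIOMASS = 0.1)))
  stats::setNames(basis$v0 + as.numeric(basis$N %*% basis$theta_feasible),
                  basis$reactions)
}

expect_mdv_valid <- function(ms, tol = 1e-9) {
  for (f in names(ms$mdvs)) {
    expect_true(all(ms$mdvs[[f]] >= -tol))
    expect_equal(sum(ms$mdvs[[f]]), 1, tolerance = tol)
  }
}
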