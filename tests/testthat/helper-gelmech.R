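# Shared fixtures. Reference parameter sets used across tests; a small cache
# so the heavier simulations are run once per test session.

params_swelling <- function() # cell-free swelling reference case
  gel_params(chi = 0.75, eta_s = 0.25, xi = 0.5, R = 0.5)

params_traction <- function(tau0 = 1, D = 0.01) # cell-seeded reference case
  gel_params(chi = 0.75, tau0 = tau0, eta_s = 0.25, xi = 0.5, R = 0.5, D = D)

# coarse settings for property tests where resolution is not the point
coarse_settings <- function(t_end, dX = 0.01, ...)
  gel_settings(dX = dX, t_end = t_end, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fun) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fun()
  .run_cache[[key]]
}

# registry scenario at full stated resolution (dX = 0.002, dT = 5e-4)
cached_scenario <- function(name, t_end = NULL, series_every = 200) {
  key <- paste0(name, "_", t_end %||% "default")
  cached_run(key, function() {
    cfg <- scenario_registry(name)
    s <- cfg$settings
    if (!is.null(t_end)) s$t_end <- t_end
    s$series_every <- series_every
    run_scenario(cfg, settings = s)
  })
}

expect_2dp <- function(actual, printed) {
  expect_equal(round(actual, 2), printed, tolerance = 1e-12)
}
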