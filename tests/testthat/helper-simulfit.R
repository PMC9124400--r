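# Shared fixtures.  Everything is generated in code; the canonical growth
# example uses the generator defaults (six curves, K = 10, nu = 0.5,
# sigma = 0.01, measurement SD 0.1).

richards_pars <- c(K = 10, n0 = 0.01, nu = 0.5, r = 0.2)

richards_closed_form <- function(t, K, n0, nu, r) {
  K * (1 - (1 - (K / n0)^nu) * exp(-r * nu * t))^(-1 / nu)
}

make_growth_curves <- function(seed, ...) {
  suppressMessages(simulate_growth_curves(seed = seed, ...))
}

# simultaneous fits of the three sharing arrangements over fixed seeds,
# computed once per test run
.fit_cache <- new.env(parent = emptyenv())

growth_fits_over_seeds <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.fit_cache[[key]])) {
    return(.fit_cache[[key]])
  }
  res <- lapply(seeds, function(s) {
    curves <- make_growth_curves(s)
    list(
      detached = simulfit(growth_example_topology(curves, "detached")),
      shared = simulfit(growth_example_topology(curves, "shared")),
      independent = simulfit(growth_example_topology(curves, "independent"))
    )
  })
  .fit_cache[[key]] <- res
  res
}
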