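# shared fixtures, built once per test run

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(extent_m = c(500, 500), n_routes = 10,
                        route_length = 12, seed = 99)
      trees <- generate_landscape(cfg)
      sim <- suppressWarnings(suppressMessages(simulate_routes(trees, cfg)))
      disks <- suppressMessages(
        availability_disks(trees, sim$routes, bbmm_params(delta = 3)))
      dtab <- dir_table(trees, sim$routes, disks, max_lag = 4)
      cache <<- list(cfg = cfg, trees = trees, routes = sim$routes,
                     truth = sim$truth, disks = disks, dir = dtab)
    }
    cache
  }
})

# four-tree toy landscape on a line, DI known exactly
toy_trees <- function() {
  data.frame(tree_id = 1:4,
             x = c(0, 10, 20, 30), y = rep(0, 4),
             di = c(0.2, 0.4, 0.6, 0.8),
             species = factor(c("NPUM", "NANT", "NBET", "OTHER"),
                              levels = c("NPUM", "NANT", "NBET", "OTHER")),
             dbh = rep(40, 4), height = rep(15, 4),
             decay_stage = 1:4)
}

# a hand-built 4-step route over the toy landscape
toy_routes <- function() {
  data.frame(route_id = 1, woodpecker_id = 1, step = 1:4, tree_id = 1:4,
             arrival_min = c(0, 10, 20, 30),
             departure_min = c(8, 18, 28, 38),
             behavior = c("F", "F", "O", "F"),
             family_size = 4, censored = c(FALSE, FALSE, FALSE, TRUE))
}

reduced_mcmc <- function(chains = 2, iterations = 1200, burnin = 400,
                         thin = 2) {
  mcmc_config(chains = chains, iterations = iterations, burnin = burnin,
              thin = thin)
}
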