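test_that("the Cox linear predictor is the additive log relative hazard", {
  rec <- data.frame(dir = 1, dis = 0, dbh = 0, ht = 0,
                    species = factor("NPUM", levels = levels(toy_trees()$species)))
  expect_equal(cox_linear_predictor(rec), 0)
  expect_equal(cox_linear_predictor(rec, betas = c(dir = -2.47)), -2.47)
  # additivity over disjoint covariate profiles
  r1 <- data.frame(dir = 1.5, dis = 0, dbh = 0, ht = 0)
  r2 <- data.frame(dir = 0, dis = 30, dbh = 0, ht = 0)
  r12 <- data.frame(dir = 1.5, dis = 30, dbh = 0, ht = 0)
  b <- c(dir = -2, dis = -0.02, dbh = 0, ht = 0)
  expect_equal(cox_linear_predictor(r12, b),
               cox_linear_predictor(r1, b) + cox_linear_predictor(r2, b))
})

test_that("hazard ratios transform coefficients as printed", {
  expect_equal(round(hazard_ratio(-2.47), 2), 0.08)
  expect_equal(round(hazard_ratio(-2.33), 2), 0.10)
  # exp(0.81) = 2.2479: the printed 2.24 was taken from the unrounded
  # posterior mean, so agreement is asserted at the printed precision
  expect_equal(hazard_ratio(0.81), 2.24, tolerance = 0.01 / 2.24)
  expect_equal(hazard_ratio(0), 1)
  # exact reciprocal symmetry
  expect_equal(hazard_ratio(1.3) * hazard_ratio(-1.3), 1)
  expect_equal(hr_interpretation(c(2.24, 0.08, 1)),
               c("leaves earlier", "stays longer", "neutral"))
})

test_that("survival from a constant step baseline matches the closed form", {
  grid <- seq(0.5, 50, by = 0.5)
  h <- rep(0.1 * 0.5, length(grid))           # constant hazard 0.1/min
  s <- treeforage:::survival_from_baseline(grid, grid, h, lp = 0)
  expect_equal(s, exp(-0.1 * grid), tolerance = 1e-10)
  # S(0) = 1 and non-increasing for any profile
  s2 <- treeforage:::survival_from_baseline(c(0, grid), grid, h, lp = 0.7)
  expect_equal(s2[1], 1)
  expect_true(all(diff(s2) <= 0))
  # proportional hazards: log-survival ratio is constant in time
  sa <- treeforage:::survival_from_baseline(grid, grid, h, lp = 0.5)
  sb <- treeforage:::survival_from_baseline(grid, grid, h, lp = -0.3)
  expect_equal(log(sa) / log(sb), rep(exp(0.5) / exp(-0.3), length(grid)),
               tolerance = 1e-10)
})

test_that("the gamma-process Cox sampler recovers coefficients", {
  rec <- simulate_residence_records(400, betas = c(dir = -2.5, dis = 0,
                                                   dbh = 0, ht = 0),
                                    species_hazard = c(NPUM = 0, NANT = 0,
                                                       NBET = 0, OTHER = 0),
                                    baseline_rate = 0.2, seed = 14)
  fit <- fit_cox_gamma(rec, covariates = "dir",
                       config = cox_config(mcmc = reduced_mcmc(2, 2500, 800)),
                       seed = 2)
  b <- fit$natural[fit$natural$parameter == "dir", ]
  expect_equal(b$mean, -2.5, tolerance = 0.5)
  expect_gt(b$bci_upper, -2.5 - 1)
  expect_lt(b$bci_lower, -2.5 + 1)
  expect_true(fit$converged)
  # the posterior-mean cumulative baseline tracks the true exponential law
  # (Nelson-Aalen oracle on the same data, at the covariate means)
  lp0 <- mean(-2.5 * rec$dir)
  H_true <- 0.2 * exp(lp0) * fit$grid
  mid <- fit$grid <= quantile(rec$time, 0.8)
  expect_equal(fit$H0[mid], H_true[mid], tolerance = 0.25)
})

test_that("null-effect fits cover zero and censoring is honoured", {
  rec <- simulate_residence_records(250, betas = c(dir = 0, dis = 0,
                                                   dbh = 0, ht = 0),
                                    species_hazard = c(NPUM = 0, NANT = 0,
                                                       NBET = 0, OTHER = 0),
                                    baseline_rate = 0.15,
                                    censor_time = 20, seed = 15)
  expect_lt(mean(rec$event), 1)  # some censored records exist
  fit <- fit_cox_gamma(rec, covariates = c("dir", "dbh"),
                       config = cox_config(mcmc = reduced_mcmc(2, 2000, 700)),
                       seed = 5)
  for (i in seq_len(nrow(fit$natural))) {
    expect_lt(fit$natural$bci_lower[i], 0)
    expect_gt(fit$natural$bci_upper[i], 0)
  }
  expect_equal(fit$n_events, sum(rec$event))
})

test_that("a huge confidence parameter collapses the baseline to the prior", {
  rec <- simulate_residence_records(60, betas = c(dir = 0, dis = 0, dbh = 0,
                                                  ht = 0),
                                    species_hazard = c(NPUM = 0, NANT = 0,
                                                       NBET = 0, OTHER = 0),
                                    baseline_rate = 0.3, seed = 16)
  lam <- 0.5   # deliberately wrong prior rate
  fit <- fit_cox_gamma(rec, covariates = "dir",
                       config = cox_config(c = 1e6, lambda_star = lam,
                                           mcmc = reduced_mcmc(2, 1200, 400)),
                       seed = 7)
  expect_equal(fit$H0, lam * fit$grid, tolerance = 0.02)
})

test_that("remaining probability respects profiles and refuses unknown species", {
  w <- small_world()
  rec <- residence_records(w$dir, w$routes, w$trees, scale = "route")
  fit <- fit_cox_gamma(rec, covariates = c("dir", "dis", "dbh", "species"),
                       config = cox_config(mcmc = reduced_mcmc(2, 1500, 500)),
                       seed = 8)
  tt <- seq(0, 30, by = 1)
  base_prof <- list(dir = 1, dis = 15, dbh = 40, species = "NPUM")
  s1 <- remaining_probability(fit, base_prof, tt)
  expect_equal(s1$surv[1], 1)
  expect_true(all(diff(s1$surv) <= 0))
  # lower DIR with a negative coefficient -> uniformly lower survival
  b_dir <- fit$natural$mean[fit$natural$parameter == "dir"]
  lo <- remaining_probability(fit, modifyList(base_prof, list(dir = 0.6)), tt)
  if (b_dir < 0) expect_true(all(lo$surv[-1] <= s1$surv[-1]))
  expect_error(remaining_probability(fit, list(species = "XYZ"), tt),
               "species")
})

test_that("candidate-set selection ranks the generating covariates first", {
  rec <- simulate_residence_records(350, betas = c(dir = 0, dis = -0.05,
                                                   dbh = -0.05, ht = 0),
                                    species_hazard = c(NPUM = 0, NANT = 0,
                                                       NBET = 0, OTHER = 0),
                                    baseline_rate = 2, seed = 17)
  res <- candidate_set_selection(
    rec,
    candidates = list("dis+dbh" = c("dis", "dbh"), "dir" = "dir"),
    config = cox_config(mcmc = reduced_mcmc(2, 1500, 500)), seed = 9)
  expect_equal(res$ranking$model[1], "dis+dbh")
  expect_equal(sum(res$ranking$weight), 1)
  # single candidate gets weight one
  one <- candidate_set_selection(rec, candidates = list(m = "dis"),
                                 config = cox_config(
                                   mcmc = reduced_mcmc(2, 800, 300)),
                                 seed = 10)
  expect_equal(one$ranking$weight, 1)
})
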