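#' State probabilities of the three-state tree-use model
#'
#' For a tree at foraging period t with availability `a`, previous-period use
#' `f_prev`, selection probability `W` and foraging-mode probability `v`:
#' \deqn{Pr(U) = (1-a) + [(1-f)(1-W) + f] a}
#' \deqn{Pr(F) = v (1-f) W a}
#' \deqn{Pr(O) = (1-v)(1-f) W a}
#' The three probabilities sum to one for any inputs in \[0, 1\]. An
#' unavailable tree (`a = 0`) or a tree used in the previous period
#' (`f_prev = 1`) is unused with probability one.
#'
#' @param a,f_prev,W,v numeric in `[0, 1]` (vectorised).
#' @return matrix with columns `U`, `F`, `O`.
#' @examples
#' state_probabilities(1, 0, 0.8, 0.9)  # (0.20, 0.72, 0.08)
#' @export
state_probabilities <- function(a, f_prev, W, v) {
  args <- cbind(a = a, f_prev = f_prev, W = W, v = v)
  if (any(args < 0 | args > 1)) stop("all inputs must lie in [0, 1]",
                                     call. = FALSE)
  a <- args[, "a"]; f <- args[, "f_prev"]; W <- args[, "W"]; v <- args[, "v"]
  U <- (1 - a) + ((1 - f) * (1 - W) + f) * a
  Fp <- v * (1 - f) * W * a
  O <- (1 - v) * (1 - f) * W * a
  cbind(U = U, F = Fp, O = O)
}

#' Tree selection probability from the logit model
#'
#' `logit(W) = beta0 + beta1 * DIR + species_effect + gamma + rho * N_r
#'             [+ eta * dir_route * n_r]`.
#' The interaction term enters only when `eta` is non-zero.
#'
#' @param dir Decay Index Ratio at the configured scale.
#' @param beta0,beta1 intercept and DIR slope.
#' @param species_effect,gamma additive species and individual effects.
#' @param rho,N_r family-size slope and family size.
#' @param eta,n_r interaction slope with route length, and route length.
#' @return selection probability W.
#' @examples
#' selection_probability(2, 0, 0.96)  # 1 / (1 + exp(-1.92))
#' @export
selection_probability <- function(dir, beta0, beta1, species_effect = 0,
                                  gamma = 0, rho = 0, N_r = 0,
                                  eta = 0, n_r = 0) {
  plogis(beta0 + beta1 * dir + species_effect + gamma + rho * N_r +
           eta * dir * n_r)
}

#' MCMC settings
#'
#' Defaults mirror the reference analysis: 3 chains of 20,000 iterations,
#' 10,000 burn-in, thinning by 3. Reduce for tests and simulation studies.
#'
#' @param chains number of chains (>= 1).
#' @param iterations total iterations per chain.
#' @param burnin iterations discarded (< iterations).
#' @param thin thinning interval.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iterations = 20000, burnin = 10000,
                        thin = 3) {
  if (chains < 1) stop("need at least one chain", call. = FALSE)
  if (burnin >= iterations) stop("burnin must be < iterations", call. = FALSE)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' Build tree-use observations from DIR records
#'
#' One row per available tree per period: state `y` (`U`/`F`/`O`),
#' availability `a` (1 by construction), previous-period use `f_prev`, the
#' DIR covariate at the requested scale, and route covariates.
#'
#' @param dir_tab output of [dir_table()].
#' @param routes routes table (for family size, route length, woodpecker).
#' @param trees tree table (for species).
#' @param scale `"local"`, `"route"`, `"lag1"` .. `"lag4"`, or
#'   `"resid0"` .. `"resid4"` for the standardized residual series.
#' @return data.frame with `route_id`, `period`, `tree_id`, `y`, `a`,
#'   `f_prev`, `dir`, `dir_route`, `species`, `N_r`, `n_r`,
#'   `woodpecker_id`. Rows whose DIR at the requested scale is missing are
#'   dropped.
#' @export
selection_observations <- function(dir_tab, routes, trees,
                                   scale = "local") {
  col <- if (scale %in% c("local", "route")) {
    c(local = "dir_local", route = "dir_route")[[scale]]
  } else if (grepl("^lag[1-4]$", scale)) {
    paste0("dir_", scale)
  } else if (grepl("^resid[0-4]$", scale)) {
    paste0("resid_", sub("resid", "lag", scale))
  } else stop("unknown scale: ", scale, call. = FALSE)
  if (!col %in% names(dir_tab)) stop("column ", col, " not in dir_tab",
                                     call. = FALSE)
  ok <- !is.na(dir_tab[[col]])
  d <- dir_tab[ok, ]
  # previous-period used tree per route
  key_prev <- paste(d$route_id, d$period - 1, d$tree_id)
  used_key <- paste(routes$route_id, routes$step, routes$tree_id)
  f_prev <- as.integer(key_prev %in% used_key)
  rmeta <- routes[!duplicated(routes$route_id), ]
  n_r <- as.integer(table(routes$route_id))[match(d$route_id,
                                                  sort(unique(routes$route_id)))]
  i <- match(d$route_id, rmeta$route_id)
  out <- data.frame(
    route_id = d$route_id, period = d$period, tree_id = d$tree_id,
    y = ifelse(d$used == 1, d$behavior, "U"),
    a = 1L, f_prev = f_prev,
    dir = d[[col]], dir_route = d$dir_route,
    species = trees$species[match(d$tree_id, trees$tree_id)],
    N_r = rmeta$family_size[i], n_r = n_r,
    woodpecker_id = rmeta$woodpecker_id[i])
  out
}

#' Simulate observations from the three-state model itself
#'
#' Draws data from the model's own generative law (each available tree used
#' independently with probability `W = plogis(beta0 + beta1 * dir + gamma)`,
#' foraging with probability `v` given use): the oracle for parameter
#' recovery and coverage studies of [fit_selection_model()]. DIR values are
#' lognormal around 1.
#'
#' @param n_routes,n_periods study dimensions.
#' @param beta0,beta1 true logit coefficients on the driving covariate.
#' @param v true foraging-mode probability.
#' @param avail_range range of available trees per period.
#' @param dir_sdlog lognormal SD of the DIR values.
#' @param cor_route correlation (on the log scale) between the driving
#'   `dir` covariate and the competing `dir_route` covariate; 1 makes them
#'   identical, values near the reported 0.67-0.84 range give a realistic
#'   competing scale for model-identification studies.
#' @param n_woodpeckers,sd_gamma individuals and their intercept SD.
#' @param seed integer seed.
#' @return data.frame shaped like [selection_observations()] output; `dir`
#'   is the covariate that drives selection, `dir_route` the competing one.
#' @export
simulate_selection_observations <- function(n_routes = 40, n_periods = 20,
                                            beta0 = -2.5, beta1 = 1.2,
                                            v = 0.94, avail_range = 7:16,
                                            dir_sdlog = 0.25, cor_route = 1,
                                            n_woodpeckers = 1, sd_gamma = 0,
                                            seed = 1L) {
  set.seed(seed)
  gam <- rnorm(n_woodpeckers, 0, sd_gamma)
  rows <- vector("list", n_routes)
  for (r in seq_len(n_routes)) {
    wp <- ((r - 1L) %% n_woodpeckers) + 1L
    fam <- sample(3:5, 1)
    per <- lapply(seq_len(n_periods), function(t) {
      m <- sample(avail_range, 1)
      z1 <- rnorm(m, 0, dir_sdlog)
      dir <- exp(z1)
      dir_route <- if (cor_route == 1) dir else
        exp(cor_route * z1 +
              sqrt(1 - cor_route^2) * rnorm(m, 0, dir_sdlog))
      W <- plogis(beta0 + beta1 * dir + gam[wp])
      used <- rbinom(m, 1, W)
      y <- ifelse(used == 1, ifelse(runif(m) < v, "F", "O"), "U")
      data.frame(route_id = r, period = t,
                 tree_id = seq_len(m), y = y, a = 1L, f_prev = 0L,
                 dir = dir, dir_route = dir_route,
                 species = factor("NPUM", levels = SPECIES_LEVELS),
                 N_r = fam, n_r = n_periods, woodpecker_id = wp)
    })
    rows[[r]] <- do.call(rbind, per)
  }
  do.call(rbind, rows)
}

# build the fixed-effects design matrix; returns list(X, indicator, center,
# scale, names)
build_selection_design <- function(obs, fixed, standardize, indicators) {
  n <- nrow(obs)
  X <- matrix(1, n, 1)
  nm <- "(Intercept)"
  ind <- FALSE
  center <- 0; scl <- 1
  for (f in fixed) {
    if (f == "species") {
      spf <- factor(obs$species, levels = SPECIES_LEVELS)
      mm <- stats::model.matrix(~ spf)[, -1, drop = FALSE]
      colnames(mm) <- paste0("sp", sub("spf", "", colnames(mm)))
      X <- cbind(X, mm)
      nm <- c(nm, colnames(mm))
      ind <- c(ind, rep(isTRUE(indicators), ncol(mm)))
      center <- c(center, rep(0, ncol(mm)))
      scl <- c(scl, rep(1, ncol(mm)))
    } else if (f == "interaction") {
      v <- obs$dir_route * obs$n_r
      cc <- if (standardize) mean(v) else 0
      ss <- if (standardize && sd(v) > 0) sd(v) else 1
      X <- cbind(X, (v - cc) / ss)
      nm <- c(nm, "eta_dir_route_x_n_r")
      ind <- c(ind, isTRUE(indicators))
      center <- c(center, cc); scl <- c(scl, ss)
    } else {
      v <- obs[[f]]
      if (is.null(v)) stop("covariate column not found: ", f, call. = FALSE)
      cc <- if (standardize) mean(v) else 0
      ss <- if (standardize && sd(v) > 0) sd(v) else 1
      X <- cbind(X, (v - cc) / ss)
      nm <- c(nm, f)
      ind <- c(ind, isTRUE(indicators))
      center <- c(center, cc); scl <- c(scl, ss)
    }
  }
  colnames(X) <- nm
  list(X = X, indicator = ind, center = center, scale = scl, names = nm)
}

#' Fit the three-state Bayesian tree-selection model
#'
#' Metropolis-within-Gibbs sampling of the categorical likelihood
#' `y ~ cat(Pr(U), Pr(F), Pr(O))` (see [state_probabilities()]) with the
#' selection logit of [selection_probability()]. Priors: Normal(0, 10^2) on
#' regression coefficients, half-Normal(0, 10) on the random-intercept SD,
#' Uniform(0, 1) on the foraging-mode probability `v` (conjugate Beta
#' update), and Bernoulli(0.5) Kuo-Mallick indicators when
#' `indicators = TRUE`. Rows with `f_prev = 1` carry no likelihood
#' information (their state is unused with probability one) and are dropped
#' with a message.
#'
#' @param obs observations from [selection_observations()] or
#'   [simulate_selection_observations()] (needs `y`, `f_prev`, covariate
#'   columns, optionally `woodpecker_id`).
#' @param fixed character vector of fixed effects: covariate column names
#'   (e.g. `"dir"`), `"species"`, and/or `"interaction"`
#'   (`dir_route x n_r`).
#' @param random_woodpecker include Gaussian per-woodpecker intercepts.
#' @param indicators attach inclusion indicators to all fixed effects
#'   except the intercept.
#' @param standardize center/scale numeric covariates before fitting
#'   (summaries are reported on both scales).
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed (per-chain sub-seeds are derived from it).
#' @return object of class `selection_fit`: posterior `summary` (mean, SD,
#'   95% BCI, PSRF per parameter), `natural` (covariates back-transformed
#'   to their original scale), inclusion probabilities `P`, `v_mean`,
#'   `dic`/`pd`/`deviance`, `converged` (all PSRF <= 1.1), `n_obs`, and the
#'   per-chain `draws`.
#' @export
fit_selection_model <- function(obs, fixed = "dir",
                                random_woodpecker = TRUE,
                                indicators = FALSE, standardize = TRUE,
                                mcmc = mcmc_config(), seed = 1L) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  y <- as.character(obs$y)
  if (!all(y %in% c("U", "F", "O")))
    stop("y must be in {U, F, O}", call. = FALSE)
  n_total <- nrow(obs)
  if (!is.null(obs$f_prev) && any(obs$f_prev == 1)) {
    drop <- obs$f_prev == 1
    if (any(y[drop] != "U"))
      stop("invalid data: a tree used at t-1 cannot be used at t",
           call. = FALSE)
    message(sum(drop), " row(s) with f_prev = 1 dropped (no information)")
    obs <- obs[!drop, ]
    y <- y[!drop]
  }
  if (!any(y != "U") || !any(y == "U"))
    stop("observations must include both used and unused trees",
         call. = FALSE)
  used <- as.integer(y != "U")
  nF <- sum(y == "F"); nO <- sum(y == "O")

  des <- build_selection_design(obs, fixed, standardize, indicators)
  p <- ncol(des$X)

  if (random_woodpecker && !is.null(obs$woodpecker_id) &&
      length(unique(obs$woodpecker_id)) > 1) {
    gf <- factor(obs$woodpecker_id)
    group <- as.integer(gf) - 1L
    n_groups <- nlevels(gf)
    gnames <- paste0("gamma[", levels(gf), "]")
  } else {
    group <- integer(nrow(obs))
    n_groups <- 0L
    gnames <- character(0)
  }

  par_names <- c(des$names, gnames, "sd_gamma", "v")
  chains <- vector("list", mcmc$chains)
  ind_chains <- vector("list", mcmc$chains)
  dev_chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(route_seed(seed, 7000L + ch))
    res <- selection_mcmc_cpp(used, des$X, des$indicator, group, n_groups,
                              nF, nO, mcmc$iterations, mcmc$burnin,
                              mcmc$thin, 10.0, 10.0)
    eff <- res$draws
    # effective coefficients: indicator * beta
    for (j in which(des$indicator))
      eff[, j] <- eff[, j] * res$indicators[, j]
    colnames(eff) <- par_names
    chains[[ch]] <- eff
    ind_chains[[ch]] <- res$indicators
    dev_chains[[ch]] <- res$deviance
  }
  keep_cols <- if (n_groups > 0) seq_len(p + n_groups + 2) else c(seq_len(p),
                                                                  p + 2)
  summ <- summarize_chains(lapply(chains, function(m)
    m[, keep_cols, drop = FALSE]))

  all_eff <- do.call(rbind, chains)
  eff_mean <- colMeans(all_eff)[seq_len(p)]
  gamma_mean <- if (n_groups > 0) colMeans(all_eff)[p + seq_len(n_groups)]
                else numeric(0)
  v_mean <- mean(all_eff[, p + n_groups + 2])

  # plug-in deviance at the posterior mean
  lp_hat <- as.numeric(des$X %*% eff_mean)
  if (n_groups > 0) lp_hat <- lp_hat + gamma_mean[group + 1L]
  dev_hat <- -2 * (selection_loglik_cpp(lp_hat, used) +
                     nF * log(v_mean) + nO * log(1 - v_mean))
  dev_all <- unlist(dev_chains)
  dic <- compute_dic(dev_all, dev_hat)

  P <- NULL
  if (any(des$indicator)) {
    ind_all <- do.call(rbind, ind_chains)
    P <- setNames(colMeans(ind_all)[des$indicator],
                  des$names[des$indicator])
  }

  # natural-scale coefficients for standardized covariates
  natural <- NULL
  if (standardize) {
    nat <- all_eff[, seq_len(p), drop = FALSE]
    for (j in seq_len(p)[-1]) nat[, j] <- nat[, j] / des$scale[j]
    nat[, 1] <- nat[, 1] -
      as.numeric(nat[, -1, drop = FALSE] %*% des$center[-1])
    natural <- data.frame(parameter = des$names,
                          mean = colMeans(nat),
                          sd = apply(nat, 2, sd),
                          bci_lower = apply(nat, 2, quantile, 0.025),
                          bci_upper = apply(nat, 2, quantile, 0.975),
                          row.names = NULL)
  }

  out <- list(summary = summ, natural = natural, P = P, v_mean = v_mean,
              dic = dic$dic, pd = dic$pd, mean_deviance = dic$mean_deviance,
              deviance_draws = dev_all,
              deviance_summary = c(mean = mean(dev_all), sd = sd(dev_all),
                                   quantile(dev_all, c(0.025, 0.975))),
              converged = all(summ$psrf <= 1.1, na.rm = TRUE),
              n_obs = n_total, n_used = nF + nO, fixed = fixed,
              transform = list(center = des$center, scale = des$scale,
                               names = des$names),
              draws = chains, seed = seed)
  class(out) <- "selection_fit"
  out
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("Three-state tree-selection model fit\n")
  cat(sprintf("  n = %d observations (%d used), DIC = %.1f (pD = %.1f)\n",
              x$n_obs, x$n_used, x$dic, x$pd))
  if (!x$converged) cat("  WARNING: PSRF > 1.1 for some parameters\n")
  print(x$summary, digits = 3)
  if (!is.null(x$P)) {
    cat("  inclusion probabilities:\n")
    print(round(x$P, 3))
  }
  invisible(x)
}

#' Staged DIR model selection across lags
#'
#' Reproduces the staged procedure: (1) screen the `dir_route x n_r`
#' interaction and retain it only if its 95% BCI excludes zero; (2) for each
#' lag, fit the candidate set {DIR_lag (uncorrected), DIR_route,
#' DIR_route + residualized DIR_lag, null} on the observations where that
#' lag is defined; (3) rank each block by DIC (blocks have different N and
#' are ranked internally only).
#'
#' @param dir_tab,routes,trees as in [selection_observations()].
#' @param lags integer lags to assess (0 = local scale).
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed.
#' @param random_woodpecker passed through to [fit_selection_model()].
#' @return list with `interaction` (screen fit summary and decision) and
#'   `blocks`: per lag, the four fits and their [rank_models()] table.
#' @export
staged_selection <- function(dir_tab, routes, trees, lags = 0:4,
                             mcmc = mcmc_config(), seed = 1L,
                             random_woodpecker = TRUE) {
  obs_route <- selection_observations(dir_tab, routes, trees, "route")
  screen <- fit_selection_model(obs_route, fixed = c("dir", "interaction"),
                                random_woodpecker = random_woodpecker,
                                mcmc = mcmc, seed = seed)
  eta <- screen$summary[screen$summary$parameter == "eta_dir_route_x_n_r", ]
  keep_eta <- nrow(eta) == 1 && (eta$bci_lower > 0 || eta$bci_upper < 0)
  extra <- if (keep_eta) "interaction" else character(0)

  blocks <- list()
  for (lg in lags) {
    scale_un <- if (lg == 0) "local" else paste0("lag", lg)
    scale_rs <- paste0("resid", lg)
    obs_un <- selection_observations(dir_tab, routes, trees, scale_un)
    obs_rs <- selection_observations(dir_tab, routes, trees, scale_rs)
    fits <- list(
      dir_lag = fit_selection_model(obs_un, fixed = c("dir", extra),
                                    random_woodpecker = random_woodpecker,
                                    mcmc = mcmc, seed = seed),
      dir_route = fit_selection_model(obs_un, fixed = c("dir_route", extra),
                                      random_woodpecker = random_woodpecker,
                                      mcmc = mcmc, seed = seed),
      both = fit_selection_model(obs_rs, fixed = c("dir_route", "dir", extra),
                                 random_woodpecker = random_woodpecker,
                                 mcmc = mcmc, seed = seed),
      null = fit_selection_model(obs_un, fixed = extra,
                                 random_woodpecker = random_woodpecker,
                                 mcmc = mcmc, seed = seed))
    names(fits) <- c(paste0("DIR_lag", lg), "DIR_route",
                     paste0("DIR_route+resid", lg), "null")
    blocks[[paste0("lag", lg)]] <- list(fits = fits,
                                        ranking = rank_models(fits))
  }
  list(interaction = list(fit = screen, retained = keep_eta),
       blocks = blocks)
}
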