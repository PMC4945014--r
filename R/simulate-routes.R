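#' Simulate foraging routes over a tree landscape
#'
#' A forager starts on a uniformly chosen tree and, at each step, enumerates
#' candidate trees within `perceptual_radius_m` of its current tree
#' (excluding trees already used on the route, or only the previous tree when
#' `memory = "consecutive"`). Each candidate's Decay Index Ratio (DIR) is
#' computed against the strategy-specific reference set -- LF: the current
#' candidate set; DF: the candidate set `lag` steps earlier; RF: all
#' candidates encountered so far on the route -- and one tree is selected
#' with probability proportional to
#' `plogis(true_beta0 + true_beta1 * DIR)`. Behaviour on a used tree is
#' foraging (`F`) with probability `v_true`, otherwise other-use (`O`).
#' Residence time follows a proportional-hazards law with rate
#' `baseline_rate * exp(lp)`, where `lp` combines DIR, travel distance, DBH,
#' height, species and family size via the configured coefficients. The final
#' step of each route is flagged censored.
#'
#' Routes that run out of candidates are truncated with a warning; truncated
#' routes shorter than six trees are discarded (with a message).
#'
#' @param trees landscape from [generate_landscape()].
#' @param config a [sim_config()]; randomness flows from `config$seed`, with
#'   deterministic per-route sub-streams (fixed seed implies byte-identical
#'   output).
#' @return list with elements `routes` (data.frame: `route_id`,
#'   `woodpecker_id`, `step`, `tree_id`, `arrival_min`, `departure_min`,
#'   `behavior`, `family_size`, `censored`), `truth` (generator parameters
#'   plus the per-step true DIR values) and `discarded` (number of routes
#'   dropped for being shorter than six trees).
#' @examples
#' cfg <- sim_config(extent_m = c(300, 300), n_routes = 3, seed = 2)
#' sim <- simulate_routes(generate_landscape(cfg), cfg)
#' @export
simulate_routes <- function(trees, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(trees) == 0) stop("landscape is empty", call. = FALSE)
  coords <- cbind(trees$x, trees$y)
  di <- trees$di
  sp_off <- config$species_hazard[as.character(trees$species)]
  rb <- config$residence_betas

  all_routes <- vector("list", config$n_routes)
  all_truth <- vector("list", config$n_routes)
  discarded <- 0L
  kept_id <- 0L

  for (r in seq_len(config$n_routes)) {
    set.seed(route_seed(config$seed, r))
    wp <- ((r - 1L) %% config$n_woodpeckers) + 1L
    fam <- sample(3:5, 1)
    start <- sample.int(nrow(trees), 1)

    used <- integer(config$route_length)
    dir_true <- numeric(config$route_length)
    travel <- numeric(config$route_length)
    used[1] <- start
    cand_sets <- list()   # candidate set enumerated while standing at tree s
    seen <- integer(0)    # distinct candidates encountered so far (RF)

    # the start tree's own DIR is measured against its raw perceptual disk
    d0 <- sqrt(colSums((t(coords) - coords[start, ])^2))
    disk0 <- which(d0 <= config$perceptual_radius_m)
    dir_true[1] <- di[start] / mean(di[disk0])
    travel[1] <- 0
    n_steps <- config$route_length

    for (s in seq_len(config$route_length - 1L)) {
      cur <- used[s]
      d <- sqrt(colSums((t(coords) - coords[cur, ])^2))
      excl <- if (config$memory == "route") used[seq_len(s)] else used[s]
      # quality-expectation search: if no candidate within the perceptual
      # disk meets the strategy's reference quality (DIR >= 1), the forager
      # widens its search before settling -- so a route-informed bird makes
      # longer hops through poor stands while a locally-informed bird, whose
      # reference adapts to the disk, almost never needs to
      cand <- integer(0)
      dirs <- numeric(0)
      accepted <- logical(0)
      for (f in c(1, 2, 4)) {
        cand <- setdiff(which(d <= f * config$perceptual_radius_m), excl)
        if (length(cand) == 0) next
        if (f == 1) {
          cand_sets[[s]] <- cand
          seen <- union(seen, cand)
        }
        # RF: long-term memory of the whole home range, i.e. the landscape
        # mean (the analysis's Eq-4 route reference is its estimable proxy)
        ref_di <- switch(config$strategy,
          LF = di[cand],
          DF = {
            k <- max(1L, s - config$lag)
            if (length(cand_sets) >= k && !is.null(cand_sets[[k]]))
              di[cand_sets[[k]]] else di[cand]
          },
          RF = di)
        dirs <- di[cand] / mean(ref_di)
        # each candidate passes the quality-expectation check independently
        # with probability plogis(beta0 + beta1 * DIR); if the whole set is
        # rejected the forager widens its search
        accepted <- runif(length(cand)) <
          plogis(config$true_beta0 + config$true_beta1 * dirs)
        if (any(accepted)) break
      }
      if (length(cand) == 0) {
        warning(sprintf("route %d truncated at step %d: no candidate tree within %.0f m",
                        r, s, 4 * config$perceptual_radius_m), call. = FALSE)
        n_steps <- s
        break
      }
      if (length(cand_sets) < s || is.null(cand_sets[[s]])) {
        # base disk had no candidate; fall back to the widened set
        cand_sets[[s]] <- cand
        seen <- union(seen, cand)
      }
      pool <- if (any(accepted)) which(accepted) else seq_along(cand)
      w <- plogis(config$true_beta0 + config$true_beta1 * dirs[pool])
      pick <- if (length(pool) == 1) pool else sample(pool, 1, prob = w)
      nxt <- cand[pick]
      used[s + 1L] <- nxt
      dir_true[s + 1L] <- dirs[pick]
      travel[s + 1L] <- d[nxt]
    }
    if (n_steps < 6L) {
      discarded <- discarded + 1L
      message(sprintf("route %d discarded: only %d trees (< 6)", r, n_steps))
      next
    }
    used <- used[seq_len(n_steps)]
    dir_true <- dir_true[seq_len(n_steps)]
    travel <- travel[seq_len(n_steps)]

    behavior <- ifelse(runif(n_steps) < config$v_true, "F", "O")
    lp <- rb[["dir"]] * dir_true + rb[["dis"]] * travel +
      rb[["dbh"]] * trees$dbh[used] + rb[["ht"]] * trees$height[used] +
      sp_off[used] + config$rho_family * (fam - 4)
    rate <- config$baseline_rate * exp(lp)
    res_t <- if (config$residence_dist == "exponential") {
      rexp(n_steps, rate)
    } else {
      # PH Weibull: S(t) = exp(-rate * t^shape)
      rweibull(n_steps, shape = config$weibull_shape,
               scale = rate^(-1 / config$weibull_shape))
    }
    arrival <- numeric(n_steps)
    departure <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      arrival[s] <- if (s == 1) 0 else
        departure[s - 1] + travel[s] / config$travel_speed_m_min
      departure[s] <- arrival[s] + res_t[s]
    }

    kept_id <- kept_id + 1L
    all_routes[[r]] <- data.frame(
      route_id = kept_id, woodpecker_id = wp, step = seq_len(n_steps),
      tree_id = used, arrival_min = arrival, departure_min = departure,
      behavior = behavior, family_size = fam,
      censored = seq_len(n_steps) == n_steps)
    all_truth[[r]] <- data.frame(route_id = kept_id, step = seq_len(n_steps),
                                 tree_id = used, dir_true = dir_true,
                                 travel_m = travel)
  }

  routes <- do.call(rbind, all_routes)
  if (is.null(routes))
    stop("all simulated routes were shorter than six trees", call. = FALSE)
  rownames(routes) <- NULL
  truth <- list(strategy = config$strategy, lag = config$lag,
                beta0 = config$true_beta0, beta1 = config$true_beta1,
                v_true = config$v_true,
                residence_betas = config$residence_betas,
                species_hazard = config$species_hazard,
                baseline_rate = config$baseline_rate,
                steps = do.call(rbind, all_truth))
  list(routes = routes, truth = truth, discarded = discarded)
}

#' Simulate residence-time records directly from the proportional-hazards law
#'
#' Draws standalone records (no landscape or routes) for testing the Cox
#' model: covariates are sampled from realistic marginals (DIR lognormal
#' around 1, travel distance gamma with mean ~28 m, DBH/height lognormal,
#' species multinomial) and times are exponential with rate
#' `baseline_rate * exp(lp)`.
#'
#' @param n number of records.
#' @param betas named vector `c(dir, dis, dbh, ht)`.
#' @param species_hazard named species log-hazard offsets (`NPUM` baseline).
#' @param baseline_rate baseline departure rate (events/min).
#' @param censor_time optional administrative censoring time (minutes).
#' @param seed integer seed.
#' @return data.frame with `time`, `event`, `dir`, `dis`, `dbh`, `ht`,
#'   `species`, `family_size`, plus the true linear predictor `lp_true`.
#' @export
simulate_residence_records <- function(n,
                                       betas = c(dir = -2.47, dis = -0.02,
                                                 dbh = -0.03, ht = -0.01),
                                       species_hazard = c(NPUM = 0, NANT = 0.81,
                                                          NBET = 0.31,
                                                          OTHER = -0.40),
                                       baseline_rate = 11,
                                       censor_time = NULL,
                                       seed = 1L) {
  set.seed(seed)
  dir <- exp(rnorm(n, 0, 0.25))
  dis <- rgamma(n, shape = 4, scale = 7)
  dbh <- rlnorm(n, log(40), 0.3)
  ht <- rlnorm(n, log(15), 0.25)
  species <- factor(sample(SPECIES_LEVELS, n, TRUE,
                           prob = c(0.45, 0.2, 0.3, 0.05)),
                    levels = SPECIES_LEVELS)
  fam <- sample(3:5, n, TRUE)
  lp <- betas[["dir"]] * dir + betas[["dis"]] * dis + betas[["dbh"]] * dbh +
    betas[["ht"]] * ht + species_hazard[as.character(species)]
  tt <- rexp(n, baseline_rate * exp(lp))
  event <- rep(1L, n)
  if (!is.null(censor_time)) {
    event <- as.integer(tt <= censor_time)
    tt <- pmin(tt, censor_time)
  }
  data.frame(time = tt, event = event, dir = dir, dis = dis, dbh = dbh,
             ht = ht, species = species, family_size = fam, lp_true = lp)
}
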