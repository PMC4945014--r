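#' Configuration for the synthetic foraging world
#'
#' Bundles every knob of the synthetic-data generator: landscape geometry and
#' tree density, the spatially autocorrelated decay-index (DI) field, the
#' forager's strategy and selection coefficients, and the proportional-hazards
#' law for residence times. Defaults describe the study system the package
#' emulates: ~100 trees/ha southern-beech stands, routes of sequentially used
#' trees (routes shorter than six trees are discarded), 7-16 trees available
#' per period, and residence times of a few minutes driven by tree quality,
#' size and travel distance.
#'
#' @param extent_m landscape width and height in metres.
#' @param tree_density trees per hectare (default 100, the density at which a
#'   ~100 ha home range holds ~10,000 trees).
#' @param di_field named vector `c(corr_length, mean, sd)`: correlation length
#'   (metres; distance at which the spatial component's correlation drops to
#'   1/e), marginal mean and SD of the decay index. DI values are floored at
#'   0.01.
#' @param di_nugget fraction of the DI variance that is tree-level white
#'   noise (decay differences between neighbouring trees); the remainder is
#'   the spatially structured stand-scale component. The pair correlation at
#'   distance d > 0 is `(1 - di_nugget) * exp(-(d / corr_length)^2)`.
#' @param species_probs probabilities over the four species classes
#'   `NPUM`, `NANT`, `NBET`, `OTHER` (must sum to 1).
#' @param strategy forager strategy: `"LF"` (locally informed: reference set =
#'   current candidates), `"DF"` (delayed: reference set lagged by `lag`
#'   steps) or `"RF"` (route informed: all candidates seen so far).
#' @param lag integer 1-4, the information lag of a DF forager.
#' @param true_beta0,true_beta1 selection-logit intercept and DIR slope: a
#'   candidate is chosen with probability proportional to
#'   `plogis(true_beta0 + true_beta1 * DIR)`.
#' @param perceptual_radius_m radius (m) of the candidate disk the simulated
#'   forager perceives around its current tree.
#' @param v_true probability that a used tree is a foraging (vs other-use)
#'   tree.
#' @param n_routes,route_length number of routes and trees per route
#'   (`route_length >= 6`; shorter truncated routes are discarded).
#' @param residence_betas named vector `c(dir, dis, dbh, ht)` of log-hazard
#'   coefficients for the residence-time law.
#' @param species_hazard named vector of species log-hazard offsets
#'   (baseline `NPUM = 0`).
#' @param rho_family log-hazard effect per family member (applied to
#'   `family_size - 4` so the default rate refers to a typical family).
#' @param baseline_rate baseline departure rate (events/min) at covariate
#'   value zero.
#' @param residence_dist `"exponential"` (constant baseline hazard; default,
#'   closed-form testable) or `"weibull"`.
#' @param weibull_shape shape parameter when `residence_dist = "weibull"`.
#' @param dbh_meanlog,dbh_sdlog,ht_meanlog,ht_sdlog lognormal parameters for
#'   diameter at breast height (cm) and tree height (m).
#' @param travel_speed_m_min flight speed used to convert inter-tree distance
#'   into travel time.
#' @param memory `"route"` (never revisit any tree of the current route;
#'   default) or `"consecutive"` (only the previous tree is excluded).
#' @param n_woodpeckers number of individuals routes are spread over.
#' @param seed integer seed; all randomness of the generator flows from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(extent_m = c(300, 300), n_routes = 4, seed = 7)
#' trees <- generate_landscape(cfg)
#' @export
sim_config <- function(extent_m = c(1000, 1000),
                       tree_density = 100,
                       di_field = c(corr_length = 60, mean = 0.5, sd = 0.15),
                       di_nugget = 0.5,
                       species_probs = c(NPUM = 0.45, NANT = 0.20,
                                         NBET = 0.30, OTHER = 0.05),
                       strategy = c("LF", "DF", "RF"),
                       lag = 1L,
                       true_beta0 = -2.5,
                       true_beta1 = 1.2,
                       perceptual_radius_m = 12,
                       v_true = 0.94,
                       n_routes = 39L,
                       route_length = 12L,
                       residence_betas = c(dir = -2.47, dis = -0.02,
                                           dbh = -0.03, ht = -0.01),
                       species_hazard = c(NPUM = 0, NANT = 0.81,
                                          NBET = 0.31, OTHER = -0.40),
                       rho_family = 0,
                       baseline_rate = 11,
                       residence_dist = c("exponential", "weibull"),
                       weibull_shape = 1,
                       dbh_meanlog = log(40), dbh_sdlog = 0.3,
                       ht_meanlog = log(15), ht_sdlog = 0.25,
                       travel_speed_m_min = 60,
                       memory = c("route", "consecutive"),
                       n_woodpeckers = 14L,
                       seed = 1L) {
  strategy <- match.arg(strategy)
  memory <- match.arg(memory)
  residence_dist <- match.arg(residence_dist)
  if (length(extent_m) != 2 || any(!is.finite(extent_m)) || any(extent_m <= 0))
    stop("extent_m must be two positive numbers (metres)", call. = FALSE)
  if (!is.finite(tree_density) || tree_density <= 0)
    stop("tree_density must be strictly positive", call. = FALSE)
  if (length(di_field) != 3 || di_field[[1]] <= 0 || di_field[[3]] < 0)
    stop("di_field must be c(corr_length > 0, mean, sd >= 0)", call. = FALSE)
  if (di_nugget < 0 || di_nugget > 1)
    stop("di_nugget must be in [0, 1]", call. = FALSE)
  if (length(species_probs) != 4 || abs(sum(species_probs) - 1) > 1e-8 ||
      any(species_probs < 0))
    stop("species_probs must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  if (!lag %in% 1:4) stop("lag must be an integer in 1..4", call. = FALSE)
  if (route_length < 6)
    stop("route_length must be >= 6 (shorter routes are discarded)",
         call. = FALSE)
  if (perceptual_radius_m <= 0)
    stop("perceptual_radius_m must be strictly positive", call. = FALSE)
  if (v_true < 0 || v_true > 1) stop("v_true must be in [0,1]", call. = FALSE)
  if (baseline_rate <= 0) stop("baseline_rate must be > 0", call. = FALSE)
  if (n_routes < 1) stop("n_routes must be >= 1", call. = FALSE)

  cfg <- list(extent_m = as.numeric(extent_m),
              tree_density = tree_density,
              di_field = c(corr_length = as.numeric(di_field[[1]]),
                           mean = as.numeric(di_field[[2]]),
                           sd = as.numeric(di_field[[3]])),
              di_nugget = di_nugget,
              species_probs = species_probs,
              strategy = strategy, lag = as.integer(lag),
              true_beta0 = true_beta0, true_beta1 = true_beta1,
              perceptual_radius_m = perceptual_radius_m,
              v_true = v_true,
              n_routes = as.integer(n_routes),
              route_length = as.integer(route_length),
              residence_betas = residence_betas,
              species_hazard = species_hazard,
              rho_family = rho_family,
              baseline_rate = baseline_rate,
              residence_dist = residence_dist,
              weibull_shape = weibull_shape,
              dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
              ht_meanlog = ht_meanlog, ht_sdlog = ht_sdlog,
              travel_speed_m_min = travel_speed_m_min,
              memory = memory,
              n_woodpeckers = as.integer(n_woodpeckers),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed per route (kept below 2^31)
route_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + i * 9973) %% 2147483647)
}

SPECIES_LEVELS <- c("NPUM", "NANT", "NBET", "OTHER")
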