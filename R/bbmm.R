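#' Brownian-bridge smoothing parameters
#'
#' @param sigma2_m Brownian-motion rate variance (m^2 per minute), or `NULL`
#'   to have [availability_disks()] estimate it from the routes.
#' @param delta location error SD in metres (default 3, the accuracy of a
#'   handheld GPS unit).
#' @param alpha_mode how the bridge fraction alpha is chosen: `"midpoint"`
#'   (alpha = 0.5, the default: tree-to-tree movement is hop-like, with
#'   residence dominating elapsed time, so the elapsed-time fraction is a
#'   poor proxy for spatial progress) or `"timestamps"` (elapsed-time
#'   fraction between arrival fixes).
#' @return object of class `bbmm_params`.
#' @export
bbmm_params <- function(sigma2_m = NULL, delta = 3,
                        alpha_mode = c("midpoint", "timestamps")) {
  alpha_mode <- match.arg(alpha_mode)
  if (!is.null(sigma2_m) && (!is.finite(sigma2_m) || sigma2_m < 0))
    stop("sigma2_m must be >= 0", call. = FALSE)
  if (!is.finite(delta) || delta < 0) stop("delta must be >= 0", call. = FALSE)
  structure(list(sigma2_m = sigma2_m, delta = delta, alpha_mode = alpha_mode),
            class = "bbmm_params")
}

#' Expected location on a Brownian bridge
#'
#' Linear interpolation between the bridge endpoints: the expected position
#' after a fraction `alpha` of the elapsed time is
#' `(1 - alpha) * tr_t + alpha * tr_t2`.
#'
#' @param tr_t,tr_t2 numeric length-2 endpoints (x, y) in metres.
#' @param alpha elapsed-time fraction in `[0, 1]`.
#' @return numeric length-2 expected location.
#' @examples
#' interpolate_expected_location(c(0, 0), c(10, 0), 0.5)  # (5, 0)
#' @export
interpolate_expected_location <- function(tr_t, tr_t2, alpha) {
  stopifnot(length(tr_t) == 2, length(tr_t2) == 2)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]", call. = FALSE)
  (1 - alpha) * tr_t + alpha * tr_t2
}

#' Per-axis variance of the Brownian bridge at fraction alpha
#'
#' `sigma2_t = T * alpha * (1 - alpha) * sigma2_m
#'             + (1 - alpha)^2 * delta^2 + alpha^2 * delta^2`,
#' the conditional variance of a Brownian bridge with observation error
#' `delta` at both endpoints.
#'
#' @param params a [bbmm_params()] (with non-`NULL` `sigma2_m`).
#' @param elapsed_total total elapsed time T of the bridge (minutes, > 0).
#' @param alpha elapsed-time fraction in `[0, 1]`.
#' @return per-axis variance `sigma2_t` in m^2.
#' @examples
#' bridge_variance(bbmm_params(sigma2_m = 0, delta = 3), 10, 0.5)  # 4.5
#' @export
bridge_variance <- function(params, elapsed_total, alpha) {
  stopifnot(inherits(params, "bbmm_params"))
  if (is.null(params$sigma2_m)) stop("sigma2_m is not set", call. = FALSE)
  if (any(elapsed_total <= 0)) stop("elapsed_total must be > 0", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]", call. = FALSE)
  elapsed_total * alpha * (1 - alpha) * params$sigma2_m +
    ((1 - alpha)^2 + alpha^2) * params$delta^2
}

#' Radius of the circular-normal isopleth
#'
#' For an isotropic bivariate normal with per-axis variance `sigma2_t`, the
#' radial distance is Rayleigh, so the radius containing a probability
#' `mass` is `sqrt(-2 * sigma2_t * log(1 - mass))`; at 90% this is
#' `sqrt(2 * sigma2_t * ln 10)`.
#'
#' @param sigma2_t per-axis variance (m^2).
#' @param mass probability mass enclosed (default 0.90).
#' @return radius in metres.
#' @examples
#' isopleth_radius(25)  # ~10.73 m
#' @export
isopleth_radius <- function(sigma2_t, mass = 0.90) {
  if (any(sigma2_t < 0)) stop("sigma2_t must be >= 0", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  sqrt(-2 * sigma2_t * log(1 - mass))
}

# build the (dx, dy, T, alpha) table of bridge triplets from a routes table
triplet_table <- function(routes, trees, alpha_mode = "timestamps") {
  ord <- order(routes$route_id, routes$step)
  routes <- routes[ord, ]
  xy <- trees[match(routes$tree_id, trees$tree_id), c("x", "y")]
  out <- NULL
  for (rid in unique(routes$route_id)) {
    idx <- which(routes$route_id == rid)
    n <- length(idx)
    if (n < 3) next
    for (t in seq_len(n - 2)) {
      i1 <- idx[t]; i2 <- idx[t + 1]; i3 <- idx[t + 2]
      has_time <- all(c("arrival_min", "departure_min") %in% names(routes)) &&
        alpha_mode == "timestamps"
      # each tree location is a BBMM fix at its arrival time
      if (has_time) {
        T_tot <- routes$arrival_min[i3] - routes$arrival_min[i1]
        alpha <- (routes$arrival_min[i2] - routes$arrival_min[i1]) / T_tot
        if (!is.finite(alpha) || T_tot <= 0) { alpha <- 0.5; T_tot <- max(T_tot, 1e-6) }
        alpha <- min(max(alpha, 0), 1)
      } else {
        T_tot <- if ("arrival_min" %in% names(routes))
          max(routes$arrival_min[i3] - routes$arrival_min[i1], 1e-6) else 1
        alpha <- 0.5
      }
      mu <- (1 - alpha) * c(xy$x[i1], xy$y[i1]) + alpha * c(xy$x[i3], xy$y[i3])
      out <- rbind(out, data.frame(
        route_id = rid, period = t + 1L,
        dx = xy$x[i2] - mu[1], dy = xy$y[i2] - mu[2],
        T_total = T_tot, alpha = alpha,
        mu_x = mu[1], mu_y = mu[2]))
    }
  }
  out
}

#' Estimate the Brownian-motion rate variance from observed routes
#'
#' Maximum-likelihood estimate of `sigma2_m`: each intermediate tree of a
#' (t, t+1, t+2) triplet is modelled as bivariate normal around the
#' interpolated expected location with per-axis variance
#' [bridge_variance()]. The likelihood is maximised over all routes pooled
#' (default) or per route, by 1-D bounded optimisation.
#'
#' @param routes routes table (`route_id`, `step`, `tree_id`, and optionally
#'   `arrival_min`/`departure_min` for timestamp-based alpha).
#' @param trees tree table with `tree_id`, `x`, `y`.
#' @param delta location error SD (m).
#' @param alpha_mode see [bbmm_params()].
#' @param per_route if `TRUE`, return one estimate per route.
#' @param upper upper bound of the search interval (m^2/min).
#' @return estimated `sigma2_m` (named vector when `per_route = TRUE`).
#' @export
estimate_sigma2m <- function(routes, trees, delta = 3,
                             alpha_mode = c("midpoint", "timestamps"),
                             per_route = FALSE, upper = 1e4) {
  alpha_mode <- match.arg(alpha_mode)
  tri <- triplet_table(routes, trees, alpha_mode)
  if (is.null(tri) || nrow(tri) < 3)
    stop("need at least 3 triplets to estimate sigma2_m", call. = FALSE)
  negll <- function(s2m, tt) {
    s2 <- tt$T_total * tt$alpha * (1 - tt$alpha) * s2m +
      ((1 - tt$alpha)^2 + tt$alpha^2) * delta^2
    if (any(s2 <= 0)) {
      # only possible when delta = 0 and alpha in {0,1}; such triplets carry
      # no information unless the residual is non-zero
      bad <- s2 <= 0
      if (any(abs(tt$dx[bad]) > 1e-12 | abs(tt$dy[bad]) > 1e-12)) return(Inf)
      tt <- tt[!bad, , drop = FALSE]
      s2 <- s2[!bad]
      if (nrow(tt) == 0) return(0)
    }
    -sum(dnorm(tt$dx, 0, sqrt(s2), log = TRUE) +
           dnorm(tt$dy, 0, sqrt(s2), log = TRUE))
  }
  est_one <- function(tt) {
    if (all(abs(tt$dx) < 1e-9 & abs(tt$dy) < 1e-9) && delta > 0) {
      warning("no bridge dispersion beyond location error; sigma2_m -> 0",
              call. = FALSE)
      return(0)
    }
    opt <- optimize(negll, c(0, upper), tt = tt, tol = 1e-6)
    if (opt$minimum > 0.99 * upper)
      warning("sigma2_m estimate at the search boundary; increase `upper`",
              call. = FALSE)
    # compare against the boundary s2m = 0
    if (negll(0, tt) <= opt$objective) 0 else opt$minimum
  }
  if (per_route) {
    vapply(split(tri, tri$route_id), est_one, numeric(1))
  } else est_one(tri)
}

#' Build BBMM availability disks along routes
#'
#' For each interior period t+1 of a route (periods `2 .. n-1` of an n-step
#' route), fits the circular normal of the Brownian bridge spanning trees
#' t and t+2: center = interpolated expected location, per-axis variance =
#' [bridge_variance()], and availability radius `r90` = the 90% isopleth
#' ([isopleth_radius()]). Every tree within the closed disk (distance
#' `<= r90`) is available (`a = 1`) for that period.
#'
#' @param trees tree table.
#' @param routes routes table.
#' @param params [bbmm_params()]; if `sigma2_m` is `NULL` it is estimated
#'   from `routes` via [estimate_sigma2m()].
#' @param mass isopleth mass (default 0.90).
#' @return data.frame with one row per available tree and columns
#'   `route_id`, `period`, `center_x`, `center_y`, `sigma2_t`, `r90`,
#'   `tree_id`, `a`; empty disks appear as a single row with `tree_id = NA`
#'   and `a = 0`. The fitted `sigma2_m` is attached as attribute
#'   `"sigma2_m"`.
#' @export
availability_disks <- function(trees, routes, params = bbmm_params(),
                               mass = 0.90) {
  stopifnot(inherits(params, "bbmm_params"))
  if (is.null(params$sigma2_m))
    params$sigma2_m <- estimate_sigma2m(routes, trees, delta = params$delta,
                                        alpha_mode = params$alpha_mode)
  tri <- triplet_table(routes, trees, params$alpha_mode)
  if (is.null(tri)) stop("no triplets: routes need >= 3 steps", call. = FALSE)
  s2t <- bridge_variance(params, tri$T_total, tri$alpha)
  r90 <- isopleth_radius(s2t, mass)
  res <- vector("list", nrow(tri))
  n_empty <- 0L
  for (i in seq_len(nrow(tri))) {
    dist <- sqrt((trees$x - tri$mu_x[i])^2 + (trees$y - tri$mu_y[i])^2)
    member <- which(dist <= r90[i])
    if (length(member) == 0) {
      n_empty <- n_empty + 1L
      res[[i]] <- data.frame(route_id = tri$route_id[i], period = tri$period[i],
                             center_x = tri$mu_x[i], center_y = tri$mu_y[i],
                             sigma2_t = s2t[i], r90 = r90[i],
                             tree_id = NA_integer_, a = 0L)
    } else {
      res[[i]] <- data.frame(route_id = tri$route_id[i], period = tri$period[i],
                             center_x = tri$mu_x[i], center_y = tri$mu_y[i],
                             sigma2_t = s2t[i], r90 = r90[i],
                             tree_id = trees$tree_id[member], a = 1L)
    }
  }
  if (n_empty > 0)
    message(n_empty, " disk(s) contained no tree; DIR is undefined there")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "sigma2_m") <- params$sigma2_m
  out
}
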