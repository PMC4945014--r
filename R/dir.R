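#' Expected decay index of a reference set
#'
#' Arithmetic mean of the decay indices of the trees available during a
#' period (or set of periods).
#'
#' @param di_values numeric vector of decay indices (non-empty).
#' @return mean DI.
#' @examples
#' expected_di(c(0.2, 0.4, 0.6))  # 0.4
#' @export
expected_di <- function(di_values) {
  if (length(di_values) == 0)
    stop("availability undefined: empty reference set", call. = FALSE)
  mean(di_values)
}

#' Decay Index Ratio of a tree against a reference set
#'
#' `DIR = DI_i / E(DI)` where `E(DI)` is [expected_di()] of the reference
#' set. The reference set depends on the scale: the current availability
#' disk (local, lag 0), the union of the previous `lag` disks (lagged), or
#' all distinct trees available along the route (route level).
#'
#' @param di_i DI of the focal tree (vectorised).
#' @param reference DI values of the reference set.
#' @return DIR value(s).
#' @examples
#' compute_dir(0.6, c(0.2, 0.4, 0.6))  # 1.5
#' @export
compute_dir <- function(di_i, reference) {
  m <- expected_di(reference)
  if (m == 0) stop("reference mean DI is zero: DIR undefined", call. = FALSE)
  di_i / m
}

#' Standardized residuals of lagged DIR on route-level DIR
#'
#' Ordinary least squares of `dir_lag` on `dir_route` (with intercept);
#' residuals are divided by their sample SD so the output has mean 0 and
#' SD 1. Used to decorrelate lagged DIR covariates from the route-level DIR
#' before fitting joint selection models.
#'
#' @param dir_lag,dir_route paired numeric vectors (length >= 3).
#' @return standardized residual vector.
#' @export
residualize_dir <- function(dir_lag, dir_route) {
  stopifnot(length(dir_lag) == length(dir_route))
  if (length(dir_lag) < 3) stop("need at least 3 points", call. = FALSE)
  if (sd(dir_route) == 0) {
    warning("dir_route is constant; returning centered dir_lag", call. = FALSE)
    r <- dir_lag - mean(dir_lag)
  } else {
    r <- residuals(lm(dir_lag ~ dir_route))
  }
  s <- sd(r)
  if (s < 1e-12) return(rep(0, length(r)))
  as.numeric(r / s)
}

#' Per-tree DIR records at every spatio-temporal scale
#'
#' For each availability disk and each tree in it, computes the Decay Index
#' Ratio at the local scale (reference = current disk), at lags 1..`max_lag`
#' (reference = trees available at the previous `lag` disks) and at the
#' route level (reference = distinct trees available across all the route's
#' disks), plus the standardized residuals of each lagged series on the
#' route-level series.
#'
#' @param trees tree table with `tree_id` and `di`.
#' @param routes routes table (used to flag used trees and their behaviour).
#' @param availability output of [availability_disks()].
#' @param max_lag largest lag (default 4).
#' @param lag_mode `"union"` (reference = distinct trees across disks
#'   t-1 .. t-lag; default) or `"single"` (only the disk at t-lag).
#' @return data.frame with columns `route_id`, `period`, `tree_id`, `used`,
#'   `behavior`, `di`, `dir_local`, `dir_lag1..dir_lagK`, `dir_route`,
#'   `resid_lag0..resid_lagK`. A lagged DIR is `NA` for periods with fewer
#'   than `lag` preceding disks.
#' @export
dir_table <- function(trees, routes, availability, max_lag = 4,
                      lag_mode = c("union", "single")) {
  lag_mode <- match.arg(lag_mode)
  stopifnot(max_lag >= 1)
  av <- availability[!is.na(availability$tree_id), ]
  di_of <- trees$di[match(av$tree_id, trees$tree_id)]
  av$di <- di_of

  used_key <- paste(routes$route_id, routes$step, routes$tree_id)
  beh_lookup <- setNames(as.character(routes$behavior), used_key)

  pieces <- vector("list", 0)
  for (rid in unique(av$route_id)) {
    rav <- av[av$route_id == rid, ]
    periods <- sort(unique(rav$period))
    disk_di <- lapply(periods, function(p) rav$di[rav$period == p])
    disk_id <- lapply(periods, function(p) rav$tree_id[rav$period == p])
    names(disk_di) <- names(disk_id) <- periods
    # route reference: distinct trees over all the route's disks
    route_ids <- unique(unlist(disk_id))
    route_mean <- mean(trees$di[match(route_ids, trees$tree_id)])
    for (k in seq_along(periods)) {
      p <- periods[k]
      ids <- disk_id[[k]]
      di <- disk_di[[k]]
      rec <- data.frame(route_id = rid, period = p, tree_id = ids,
                        di = di,
                        dir_local = compute_dir(di, di),
                        dir_route = di / route_mean)
      for (lg in seq_len(max_lag)) {
        col <- paste0("dir_lag", lg)
        prev <- k - seq_len(lg)      # indices of disks t-1 .. t-lag
        if (any(prev < 1)) { rec[[col]] <- NA_real_; next }
        ref_ids <- if (lag_mode == "union") {
          unique(unlist(disk_id[prev]))
        } else disk_id[[k - lg]]
        ref <- trees$di[match(ref_ids, trees$tree_id)]
        rec[[col]] <- compute_dir(di, ref)
      }
      key <- paste(rid, p, ids)
      beh <- beh_lookup[key]
      rec$used <- as.integer(!is.na(beh))
      rec$behavior <- ifelse(is.na(beh), "", beh)
      pieces[[length(pieces) + 1]] <- rec
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  # standardized residuals of each lag series (incl. lag 0) on dir_route
  lag_cols <- c("dir_local", paste0("dir_lag", seq_len(max_lag)))
  for (j in seq_along(lag_cols)) {
    rc <- paste0("resid_lag", j - 1)
    v <- out[[lag_cols[j]]]
    ok <- !is.na(v)
    out[[rc]] <- NA_real_
    if (sum(ok) >= 3) out[[rc]][ok] <- residualize_dir(v[ok], out$dir_route[ok])
  }
  cols <- c("route_id", "period", "tree_id", "used", "behavior", "di",
            "dir_local", paste0("dir_lag", seq_len(max_lag)), "dir_route",
            paste0("resid_lag", 0:max_lag))
  out[, cols]
}
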