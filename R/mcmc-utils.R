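#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Between/within-chain variance ratio `sqrt(1 + (B/n) / W)`, where `W` is
#' the mean within-chain variance and `B/n` the variance of the chain means.
#' Identical chains give exactly 1; well-mixed chains give values near 1;
#' chains stuck in different regions give values well above 1.1.
#'
#' @param chains matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least two chains.
#' @return the PSRF (scalar).
#' @export
psrf <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1) stop("chains must have equal lengths", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  W <- mean(apply(chains, 2, var))
  Bn <- var(colMeans(chains))
  if (W == 0) return(if (Bn == 0) 1 else Inf)
  sqrt(1 + Bn / W)
}

#' Deviance information criterion
#'
#' `pD = mean(deviance) - deviance(posterior mean)`;
#' `DIC = mean(deviance) + pD`.
#'
#' @param deviance_draws vector of deviance values over posterior draws
#'   (>= 2 draws).
#' @param deviance_at_posterior_mean deviance evaluated at the
#'   posterior-mean parameters (plug-in).
#' @return list with `dic`, `pd`, `mean_deviance`.
#' @export
compute_dic <- function(deviance_draws, deviance_at_posterior_mean) {
  if (length(deviance_draws) < 2) stop("need >= 2 draws", call. = FALSE)
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_posterior_mean
  list(dic = dbar + pd, pd = pd, mean_deviance = dbar)
}

#' Posterior inclusion probability of a Kuo-Mallick indicator
#'
#' @param indicator_draws 0/1 draws of the inclusion indicator.
#' @return posterior mean (the inclusion probability P).
#' @export
inclusion_probability <- function(indicator_draws) {
  if (!all(indicator_draws %in% c(0, 1)))
    stop("indicator draws must be 0/1", call. = FALSE)
  mean(indicator_draws)
}

#' DIC model weights
#'
#' `w_m = exp(-dDIC_m / 2) / sum(exp(-dDIC / 2))`.
#'
#' @param dic vector of DIC values.
#' @return normalized weights.
#' @export
dic_weights <- function(dic) {
  d <- dic - min(dic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank candidate models by DIC
#'
#' @param fits named list of fits; each must carry `$dic` and `$n_obs`
#'   (as produced by [fit_selection_model()] or [fit_cox_gamma()]).
#' @param weights include DIC weights column.
#' @return data.frame sorted by DIC with `model`, `dic`, `pd`, `delta_dic`,
#'   `supported` (`delta_dic < 2`), and optionally `weight`.
#' @export
rank_models <- function(fits, weights = FALSE) {
  if (length(fits) < 1) stop("need at least one fit", call. = FALSE)
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1)
    stop("fits were made on differing observation counts; rank within ",
         "blocks of equal N only", call. = FALSE)
  dic <- vapply(fits, function(f) f$dic, numeric(1))
  pd <- vapply(fits, function(f) if (is.null(f$pd)) NA_real_ else f$pd,
               numeric(1))
  ord <- order(dic)
  out <- data.frame(model = names(fits)[ord], dic = dic[ord], pd = pd[ord],
                    delta_dic = dic[ord] - min(dic))
  out$supported <- out$delta_dic < 2
  if (weights) out$weight <- dic_weights(out$dic)
  rownames(out) <- NULL
  out
}

# per-parameter posterior summary across chains
# draws_by_chain: list of matrices (kept x p) with identical colnames
summarize_chains <- function(draws_by_chain) {
  all <- do.call(rbind, draws_by_chain)
  p <- ncol(all)
  rhat <- vapply(seq_len(p), function(j)
    psrf(lapply(draws_by_chain, function(m) m[, j])), numeric(1))
  data.frame(parameter = colnames(all),
             mean = colMeans(all),
             sd = apply(all, 2, sd),
             bci_lower = apply(all, 2, quantile, 0.025),
             bci_upper = apply(all, 2, quantile, 0.975),
             psrf = rhat,
             row.names = NULL)
}
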