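#' Ordinal validation of the senescence index against decay stage
#'
#' Proportional-odds (cumulative logit) regression of the observed ordinal
#' decay stage on the tree-level senescence index (PSRI):
#' `logit P(Y <= k) = theta_k - b * PSRI`, fit by maximum likelihood. A
#' positive slope `b` means PSRI increases with decay stage. Used to justify
#' treating the (scaled) PSRI as a decay index.
#'
#' Backed by `MASS::polr`; a constant predictor degenerates to the
#' intercept-only model, whose ML thresholds are the logits of the cumulative
#' category frequencies (computed in closed form).
#'
#' @param decay_stage ordinal stage (integer or ordered factor), >= 2
#'   observed categories.
#' @param psri numeric senescence index per tree.
#' @return object of class `ordinal_fit`: list with `slope`, `se`, `z`,
#'   `thresholds` (strictly increasing cutpoints), `loglik`, `n`.
#' @export
fit_ordinal_psri <- function(decay_stage, psri) {
  stopifnot(length(decay_stage) == length(psri))
  y <- factor(decay_stage, ordered = TRUE)
  if (nlevels(y) < 2) stop("need >= 2 observed categories", call. = FALSE)
  if (length(y) < nlevels(y)) stop("need n >= number of categories",
                                   call. = FALSE)
  if (sd(psri) == 0) {
    # intercept-only ML: thresholds are logits of cumulative frequencies
    p <- cumsum(table(y) / length(y))
    th <- qlogis(p[-length(p)])
    ll <- sum(table(y) * log(table(y) / length(y)))
    out <- list(slope = NA_real_, se = NA_real_, z = NA_real_,
                thresholds = as.numeric(th), loglik = as.numeric(ll),
                n = length(y))
    class(out) <- "ordinal_fit"
    return(out)
  }
  d <- data.frame(y = y, x = as.numeric(psri))
  fit <- tryCatch(
    MASS::polr(y ~ x, data = d, Hess = TRUE),
    error = function(e) {
      warning("polr failed (possible separation); refitting with scaled x: ",
              conditionMessage(e), call. = FALSE)
      MASS::polr(y ~ I(scale(x)), data = d, Hess = TRUE)
    })
  b <- unname(coef(fit)[1])
  se <- sqrt(diag(vcov(fit)))[1]
  out <- list(slope = b, se = unname(se), z = unname(b / se),
              thresholds = as.numeric(fit$zeta),
              loglik = as.numeric(logLik(fit)), n = length(y))
  class(out) <- "ordinal_fit"
  out
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Proportional-odds fit (decay stage ~ PSRI)\n")
  cat(sprintf("  n = %d, logLik = %.2f\n", x$n, x$loglik))
  if (is.na(x$slope)) {
    cat("  constant predictor: intercept-only model\n")
  } else {
    cat(sprintf("  slope = %.3f (SE %.3f, z = %.2f)\n", x$slope, x$se, x$z))
  }
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = ", "),
      "\n")
  invisible(x)
}
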