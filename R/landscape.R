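#' Simulate a Gaussian random field at point locations
#'
#' White noise on a padded torus grid is smoothed with a Gaussian kernel by
#' FFT and bilinearly interpolated at the requested coordinates. The resulting
#' field has (approximately) unit marginal variance and Gaussian correlation
#' `exp(-(d / corr_length)^2)`, i.e. `corr_length` is the distance at which
#' correlation falls to 1/e.
#'
#' Uses the current RNG state; seed outside for reproducibility.
#'
#' @param x,y coordinates (metres) at which the field is evaluated.
#' @param extent landscape width/height in metres, `c(w, h)`.
#' @param corr_length correlation length in metres (> 0).
#' @return numeric vector of field values (approximately N(0, 1) marginals).
#' @examples
#' set.seed(1)
#' z <- simulate_gaussian_field(runif(50, 0, 100), runif(50, 0, 100),
#'                              c(100, 100), corr_length = 20)
#' @export
simulate_gaussian_field <- function(x, y, extent, corr_length) {
  stopifnot(corr_length > 0, length(extent) == 2, all(extent > 0))
  sk <- corr_length / 2              # kernel SD; kernel*kernel => corr exp(-(d/L)^2)
  pad <- 3 * corr_length
  Lx <- extent[1] + pad
  Ly <- extent[2] + pad
  h <- corr_length / 3               # grid spacing: 3 nodes per corr length
  nx <- min(512L, max(16L, as.integer(ceiling(Lx / h))))
  ny <- min(512L, max(16L, as.integer(ceiling(Ly / h))))
  hx <- Lx / nx
  hy <- Ly / ny
  # Gaussian kernel on the torus
  dx <- (0:(nx - 1)) * hx
  dx <- pmin(dx, Lx - dx)
  dy <- (0:(ny - 1)) * hy
  dy <- pmin(dy, Ly - dy)
  K <- exp(-outer(dx^2, dy^2, "+") / (2 * sk^2))
  K <- K / sqrt(sum(K^2))            # unit-variance smoother
  Z <- matrix(rnorm(nx * ny), nx, ny)
  S <- Re(fft(fft(Z) * fft(K), inverse = TRUE)) / (nx * ny)
  # bilinear interpolation at the points
  fx <- pmin(pmax(x / hx, 0), nx - 1.000001)
  fy <- pmin(pmax(y / hy, 0), ny - 1.000001)
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0;   wy <- fy - j0
  idx <- function(i, j) S[cbind(i + 1L, j + 1L)]
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  (1 - wx) * (1 - wy) * idx(i0, j0) + wx * (1 - wy) * idx(i1, j0) +
    (1 - wx) * wy * idx(i0, j1) + wx * wy * idx(i1, j1)
}

#' Generate a synthetic tree landscape
#'
#' Trees form a homogeneous Poisson point pattern at the configured density.
#' Decay indices (DI) are a Gaussian random field with the configured
#' correlation length, rescaled to the marginal mean/SD and floored at 0.01;
#' species are multinomial; DBH and height are lognormal. An ordinal
#' `decay_stage` (1-4) is derived from the DI with observation noise, for use
#' with [fit_ordinal_psri()].
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` with columns `tree_id`, `x`, `y`, `di`, `species`,
#'   `dbh`, `height`, `decay_stage`.
#' @examples
#' trees <- generate_landscape(sim_config(extent_m = c(200, 200), seed = 1))
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(route_seed(config$seed, 0L))
  area_ha <- prod(config$extent_m) / 1e4
  n <- rpois(1, config$tree_density * area_ha)
  if (n == 0) stop("landscape is empty: increase extent or density",
                   call. = FALSE)
  x <- runif(n, 0, config$extent_m[1])
  y <- runif(n, 0, config$extent_m[2])
  fld <- config$di_field
  nug <- if (is.null(config$di_nugget)) 0 else config$di_nugget
  z <- if (fld["sd"] > 0) {
    zs <- if (nug < 1) {
      simulate_gaussian_field(x, y, config$extent_m, fld[["corr_length"]])
    } else rep(0, n)
    sqrt(1 - nug) * zs + sqrt(nug) * rnorm(n)
  } else rep(0, n)
  di <- pmax(fld[["mean"]] + fld[["sd"]] * z, 0.01)
  species <- factor(sample(SPECIES_LEVELS, n, replace = TRUE,
                           prob = config$species_probs),
                    levels = SPECIES_LEVELS)
  dbh <- rlnorm(n, config$dbh_meanlog, config$dbh_sdlog)
  height <- rlnorm(n, config$ht_meanlog, config$ht_sdlog)
  # ordinal stage: noisy discretisation of DI into 4 decay classes
  noisy <- di + rnorm(n, 0, 0.5 * max(fld[["sd"]], 0.01))
  br <- quantile(noisy, c(0.4, 0.7, 0.9))
  decay_stage <- as.integer(cut(noisy, c(-Inf, br, Inf), labels = FALSE))
  data.frame(tree_id = seq_len(n), x = x, y = y, di = di,
             species = species, dbh = dbh, height = height,
             decay_stage = decay_stage)
}
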