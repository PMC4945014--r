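test_that("expected-location interpolation is the linear map", {
  expect_equal(interpolate_expected_location(c(0, 0), c(10, 0), 0.5), c(5, 0))
  expect_equal(interpolate_expected_location(c(0, 0), c(10, 20), 0.25),
               c(2.5, 5.0))
  expect_equal(interpolate_expected_location(c(1, 2), c(7, -3), 1), c(7, -3))
  expect_equal(interpolate_expected_location(c(3, 3), c(3, 3), 0.7), c(3, 3))
  expect_error(interpolate_expected_location(c(0, 0), c(1, 1), 1.2), "alpha")
})

test_that("bridge variance follows the BBMM formula", {
  expect_equal(bridge_variance(bbmm_params(sigma2_m = 0, delta = 3), 10, 0.5),
               4.5)
  expect_equal(bridge_variance(bbmm_params(sigma2_m = 8, delta = 0), 10, 0.5),
               20)
  # endpoint with no observation error
  expect_equal(bridge_variance(bbmm_params(sigma2_m = 5, delta = 0), 10, 0),
               0)
  # general formula at an asymmetric alpha
  p <- bbmm_params(sigma2_m = 4, delta = 2)
  expect_equal(bridge_variance(p, 12, 0.25),
               12 * 0.25 * 0.75 * 4 + (0.75^2 + 0.25^2) * 4)
  expect_error(bridge_variance(p, -1, 0.5), "elapsed")
})

test_that("the 90% isopleth radius is the Rayleigh quantile", {
  expect_equal(isopleth_radius(25), sqrt(2 * 25 * log(10)))
  expect_equal(isopleth_radius(0), 0)
  # Monte-Carlo oracle: fraction of circular-normal draws inside r90
  set.seed(4)
  s2 <- 25
  r90 <- isopleth_radius(s2)
  d <- sqrt(rnorm(1e5, 0, sqrt(s2))^2 + rnorm(1e5, 0, sqrt(s2))^2)
  expect_equal(mean(d <= r90), 0.90, tolerance = 0.01)
})

test_that("sigma2_m is recovered from Brownian triplets", {
  # simulation-recovery oracle: one long route of pure Brownian motion with
  # known rate; arrival times define the bridges; delta = 0
  set.seed(11)
  s2m_true <- 10
  n <- 202
  dt <- runif(n - 1, 2, 8)
  tt <- c(0, cumsum(dt))
  xy <- apply(rbind(c(0, 0),
                    matrix(rnorm(2 * (n - 1), 0,
                                 sqrt(s2m_true * rep(dt, each = 2))),
                           ncol = 2, byrow = TRUE)), 2, cumsum)
  trees <- data.frame(tree_id = seq_len(n), x = xy[, 1], y = xy[, 2])
  routes <- data.frame(route_id = 1, step = seq_len(n), tree_id = seq_len(n),
                       arrival_min = tt, departure_min = tt)
  est <- estimate_sigma2m(routes, trees, delta = 0,
                          alpha_mode = "timestamps")
  expect_lt(abs(est - s2m_true) / s2m_true, 0.15)
})

test_that("sigma2_m estimation is degenerate-safe and scale-equivariant", {
  # intermediate points exactly at the interpolated means -> estimate 0
  n <- 11
  trees <- data.frame(tree_id = 1:n, x = seq(0, 100, length.out = n), y = 0)
  routes <- data.frame(route_id = 1, step = 1:n, tree_id = 1:n,
                       arrival_min = seq(0, 50, length.out = n),
                       departure_min = seq(0, 50, length.out = n))
  expect_warning(est0 <- estimate_sigma2m(routes, trees, delta = 3),
                 "sigma2_m")
  expect_equal(est0, 0)
  # scaling all coordinates by k scales the estimate by k^2 (delta = 0)
  set.seed(3)
  n <- 52
  dt <- rep(4, n - 1)
  xy <- apply(rbind(c(0, 0),
                    matrix(rnorm(2 * (n - 1), 0, sqrt(6 * 4)),
                           ncol = 2)), 2, cumsum)
  tr1 <- data.frame(tree_id = 1:n, x = xy[, 1], y = xy[, 2])
  rt <- data.frame(route_id = 1, step = 1:n, tree_id = 1:n,
                   arrival_min = c(0, cumsum(dt)),
                   departure_min = c(0, cumsum(dt)))
  k <- 3
  tr2 <- transform(tr1, x = k * x, y = k * y)
  e1 <- estimate_sigma2m(rt, tr1, delta = 0, alpha_mode = "timestamps")
  e2 <- estimate_sigma2m(rt, tr2, delta = 0, alpha_mode = "timestamps")
  expect_equal(e2 / e1, k^2, tolerance = 1e-3)
})

test_that("availability disks exist for interior periods with correct membership", {
  trees <- toy_trees()
  routes <- toy_routes()
  disks <- availability_disks(trees, routes,
                              bbmm_params(sigma2_m = 25, delta = 3))
  # 4-step route -> disks at periods 2 and 3 only
  expect_setequal(unique(disks$period), c(2, 3))
  # membership: every listed tree lies within r90 of the center (closed disk)
  d <- sqrt((trees$x[match(disks$tree_id, trees$tree_id)] - disks$center_x)^2 +
              (trees$y[match(disks$tree_id, trees$tree_id)] - disks$center_y)^2)
  expect_true(all(d <= disks$r90 + 1e-12))
  expect_true(all(disks$a == 1))
  # r90 consistent with sigma2_t
  expect_equal(disks$r90, sqrt(2 * disks$sigma2_t * log(10)))
  # complement check: trees not listed are farther than r90
  for (p in c(2, 3)) {
    dd <- disks[disks$period == p, ]
    outs <- setdiff(trees$tree_id, dd$tree_id)
    if (length(outs)) {
      dout <- sqrt((trees$x[outs] - dd$center_x[1])^2 +
                     (trees$y[outs] - dd$center_y[1])^2)
      expect_true(all(dout > dd$r90[1]))
    }
  }
})

test_that("a vanishing bridge variance collapses the disk to the center", {
  trees <- toy_trees()
  routes <- toy_routes()
  disks <- availability_disks(trees, routes,
                              bbmm_params(sigma2_m = 1e-12, delta = 0))
  # center of period 2 is the midpoint of trees 1 and 3 = (10, 0) = tree 2
  d2 <- disks[disks$period == 2, ]
  expect_equal(d2$center_x, 10)
  expect_identical(d2$tree_id, 2L)
})

test_that("empty disks are reported, not dropped", {
  trees <- data.frame(tree_id = 1:3, x = c(0, 150, 200), y = 0)
  routes <- data.frame(route_id = 1, step = 1:3, tree_id = 1:3,
                       arrival_min = c(0, 10, 20),
                       departure_min = c(1, 11, 21))
  expect_message(
    disks <- availability_disks(trees, routes,
                                bbmm_params(sigma2_m = 0.01, delta = 0.1)),
    "no tree")
  expect_true(is.na(disks$tree_id[disks$period == 2]))
  expect_identical(disks$a[disks$period == 2], 0L)
})
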