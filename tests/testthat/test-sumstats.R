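test_that("uncorrected K equals the brute-force pair-count oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    side <- sample(c(30, 50, 80), 1)
    w <- plot_window(side, side)
    p <- point_pattern(runif(n, 0, side), runif(n, 0, side), w)
    r <- seq(0, side / 4, 0.5)
    K <- ripley_K(p, r, correction = "none")$values
    expect_lt(max(abs(K - brute_K(p$x, p$y, r, side^2))), 1e-10)
  }
})

test_that("two points 1 m apart in a 10 x 10 window give the closed form", {
  p <- point_pattern(c(4, 5), c(5, 5), plot_window(10, 10))
  K <- ripley_K(p, c(0, 0.5, 1), correction = "none")
  expect_equal(K$values, c(0, 0, 100))  # |W|/(n(n-1)) * 2 = 100
  expect_error(ripley_K(point_pattern(1, 1, plot_window(10, 10))),
               "fewer than 2")
})

test_that("K is monotone non-decreasing for every correction", {
  set.seed(4)
  w <- plot_window(60, 40)
  p <- point_pattern(runif(150, 0, 60), runif(150, 0, 40), w)
  for (corr in c("none", "isotropic", "translation")) {
    K <- ripley_K(p, seq(0, 10, 0.25), correction = corr)$values
    expect_true(all(diff(K) >= -1e-12), info = corr)
    expect_true(all(K >= 0), info = corr)
  }
})

test_that("pair correlation behaves on known patterns", {
  # hard-core pattern: no pairs below the spacing, g(1) ~ 0
  w <- plot_window(100, 100)
  hc <- hardcore_pattern(w, spacing = 5, seed = 2)
  g <- pair_correlation(hc, seq(0, 10, 0.5), bandwidth = 0.75)
  expect_lt(g$values[g$r == 1], 1e-10)
  # Thomas clustering: g(2) > 1
  set.seed(5)
  tp <- simulate_thomas(thomas_params(5e-4, 5, 10), plot_window(200, 200))
  gt <- pair_correlation(tp, seq(0, 10, 0.5))
  expect_gt(gt$values[gt$r == 2], 1)
  expect_error(pair_correlation(hc, bandwidth = -1), "bandwidth")
})

test_that("inhomogeneous pcf reduces exactly to the homogeneous one", {
  set.seed(6)
  w <- plot_window(100, 100)
  p <- point_pattern(runif(120, 0, 100), runif(120, 0, 100), w)
  lam <- raster_surface(matrix(120 / 1e4, 20, 20), 5)
  r <- seq(0, 20, 0.5)
  g0 <- pair_correlation(p, r, bandwidth = 1.5)
  g1 <- pair_correlation_inhom(p, lam, r, bandwidth = 1.5)
  expect_lt(max(abs(g0$values - g1$values), na.rm = TRUE), 1e-10)
  expect_true(is.na(g1$values[1]))  # undefined at r = 0

  # same reduction for the inhomogeneous K
  K0 <- ripley_K(p, r)
  K1 <- ripley_K_inhom(p, lam, r)
  expect_lt(max(abs(K0$values - K1$values)), 1e-10)

  # zero intensity at a data point is reported with the point
  bad <- raster_surface(matrix(c(0, rep(1, 399)), 20, 20), 5)
  expect_error(pair_correlation_inhom(point_pattern(c(1, 50), c(1, 50), w),
                                      bad, r),
               "point 1")
})

test_that("rank envelopes classify the obvious cases", {
  r <- seq(0, 10, 1)
  mkcurve <- function(v) summary_curve(r, v, "K")
  set.seed(9)
  sims <- lapply(1:199, function(i) mkcurve(pi * r^2 + rnorm(11, 0, 5)))
  med <- apply(sapply(sims, function(s) s$values), 1, median)

  e1 <- envelope(mkcurve(med), sims, level = 0.95)
  expect_false(e1$significant)

  mx <- apply(sapply(sims, function(s) s$values), 1, max)
  e2 <- envelope(mkcurve(mx + 1), sims, level = 0.95)
  expect_true(e2$significant)
  expect_true(all(e2$exceeds_above))
  expect_true(all(e1$lower$values <= e1$upper$values))

  # 199 sims at 95%: bounds are the 5th-lowest and 5th-highest values
  vals5 <- sapply(sims, function(s) s$values[5])
  expect_equal(e1$upper$values[5], sort(vals5, decreasing = TRUE)[5])
  expect_equal(e1$lower$values[5], sort(vals5)[5])

  expect_error(envelope(summary_curve(r + 1, med, "K"), sims), "mismatched")
})

test_that("Loosmore GoF matches its rank-based definition", {
  r <- seq(0, 10, 1)
  set.seed(10)
  sims <- lapply(1:99, function(i)
    summary_curve(r, r + rnorm(11, 0, 0.5), "K"))
  simbar <- rowMeans(sapply(sims, function(s) s$values))

  # observed equal to the simulation mean: u ~ 0, p ~ 1
  g1 <- gof_loosmore(summary_curve(r, simbar, "K"), sims)
  expect_lt(g1$u_obs, min(g1$u_sims))
  expect_equal(g1$p_value, 1)

  # observed wildly off: p attains its floor 1 / (n_sim + 1)
  g2 <- gof_loosmore(summary_curve(r, r + 50, "K"), sims)
  expect_equal(g2$p_value, 1 / 100)
  expect_equal(g2$p_value, (1 + sum(g2$u_sims >= g2$u_obs)) /
                 (length(g2$u_sims) + 1))
  expect_error(gof_loosmore(summary_curve(r, simbar, "K"), sims,
                            range = c(0, 99)),
               "outside")
})
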