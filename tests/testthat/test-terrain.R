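make_posts <- function(f, nx = 10, ny = 8, cell = 20) {
  outer((0:ny) * cell, (0:nx) * cell,
        function(y, x) f(y, x) + 0 * (x + y))  # force vectorized result
}

test_that("quadrat topography on analytic planes", {
  # horizontal plane: everything flat
  topo <- quadrat_topography(make_posts(function(y, x) 42))
  expect_equal(topo$mean_elev, rep(42, nrow(topo)))
  expect_equal(topo$slope, rep(0, nrow(topo)))
  expect_equal(topo$convexity, rep(0, nrow(topo)))

  # tilted plane z = 0.1 x: slope = atan(0.1) everywhere, interior convexity 0
  topo <- quadrat_topography(make_posts(function(y, x) 0.1 * x))
  expect_equal(topo$slope, rep(atan(0.1) * 180 / pi, nrow(topo)),
               tolerance = 1e-10)
  conv <- attr(topo, "convexity")
  expect_equal(max(abs(conv[2:(nrow(conv) - 1), 2:(ncol(conv) - 1)])), 0,
               tolerance = 1e-10)
})

test_that("a Gaussian hill has positive apex and negative foot convexity", {
  hill <- function(y, x) 50 * exp(-((x - 100)^2 + (y - 80)^2) / (2 * 40^2))
  topo <- quadrat_topography(make_posts(hill))
  conv <- attr(topo, "convexity")
  elev <- attr(topo, "elev")
  apex <- which(elev == max(elev), arr.ind = TRUE)[1, ]
  expect_gt(conv[apex[1], apex[2]], 0)
  # foot of the hill (beyond the inflection ring) is convex: negative
  expect_lt(conv[4, 2], 0)
  expect_lt(min(conv), 0)
})

test_that("habitat classification follows the convexity and elevation rules", {
  mk_topo <- function(conv, elev) {
    t <- data.frame(qx = 1, qy = 1)
    attr(t, "elev") <- matrix(elev, 1, 1)
    attr(t, "convexity") <- matrix(conv, 1, 1)
    attr(t, "cell_size") <- 20
    t
  }
  lab <- function(conv, elev, mask = NULL)
    classify_habitats(mk_topo(conv, elev), mask)$labels[1, 1]
  expect_equal(lab(-2.5, 430), "low_valley")
  expect_equal(lab(-2.0, 500), "high_slope")   # boundary belongs to slope
  expect_equal(lab(1.99, 430), "low_slope")
  expect_equal(lab(2.0, 430), "low_ridge")     # boundary belongs to ridge
  expect_equal(lab(-3, 450), "high_valley")    # 450 m is the high stratum
  expect_equal(lab(3, 600, matrix(TRUE, 1, 1)), "disturbed")
})

test_that("habitat classification is total, idempotent and counts add up", {
  terr <- make_terrain(seed = 5)
  topo <- quadrat_topography(terr$posts)
  hab1 <- classify_habitats(topo)
  hab2 <- classify_habitats(topo)
  expect_identical(hab1$labels, hab2$labels)
  expect_true(all(hab1$labels %in% habitat_levels()))
  expect_equal(sum(table(hab1$labels)), length(topo$mean_elev))
})

test_that("Matheron semivariogram matches hand-computed cases", {
  # constant field: zero everywhere
  set.seed(1)
  x <- runif(40, 0, 100); y <- runif(40, 0, 100)
  emp <- empirical_semivariogram(x, y, rep(3, 40), seq(0, 150, 25))
  expect_equal(emp$gamma[emp$npairs > 0], rep(0, sum(emp$npairs > 0)))

  # two samples, values 0 and 2 at distance 10: gamma = 0.5 * (2 - 0)^2 = 2
  emp2 <- suppressWarnings(
    empirical_semivariogram(c(0, 10), c(0, 0), c(0, 2), c(5, 15)))
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$npairs, 1)

  # white noise: flat semivariogram near the field variance
  set.seed(42)
  n <- 400
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  z <- rnorm(n, 0, 2)
  emp3 <- empirical_semivariogram(x, y, z, seq(0, 100, 20))
  # each bin mean should be near var(z) = 4 within 3 SE (Monte Carlo oracle)
  se <- 3 * sqrt(2 * 16 / emp3$npairs)  # var of 0.5*(N(0,2)-N(0,2))^2 ~ 2*sigma^4
  expect_true(all(abs(emp3$gamma - var(z)) < se + 0.5))
})

test_that("ordinary kriging honours its invariants", {
  set.seed(7)
  w <- plot_window(100, 100)
  x <- runif(50, 0, 100); y <- runif(50, 0, 100)
  vg <- list(nugget = 0, psill = 1, range = 30)

  # constant samples: surface identically that constant (weights sum to 1)
  s <- krige_block(x, y, rep(2.5, 50), vg, w, cell_size = 10)
  expect_equal(range(s$values), c(2.5, 2.5), tolerance = 1e-8)

  # kriging weights sum to 1 for arbitrary target cells
  for (cx in c(15, 55, 95))
    expect_equal(sum(stagepp:::krige_weights_cell(x, y, vg, cx, 45)), 1,
                 tolerance = 1e-8)

  # nugget 0, lone isolated sample: block prediction ~ sample value
  s2 <- krige_block(50, 50, 7, list(nugget = 0, psill = 1, range = 30), w,
                    cell_size = 10)
  expect_equal(surface_value_at(s2, 50, 50), 7, tolerance = 1e-6)

  # leave-one-out on a smooth field beats the field sd
  f <- function(x, y) sin(x / 25) + cos(y / 20)
  z <- f(x, y)
  vg2 <- fit_variogram(empirical_semivariogram(x, y, z, seq(0, 80, 10)))
  err <- vapply(seq_along(z), function(i) {
    s <- krige_block(x[-i], y[-i], z[-i], vg2, w, cell_size = 5)
    surface_value_at(s, x[i], y[i]) - z[i]
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), sd(z))
})

test_that("environmental PCA is orthogonal and conserves variance", {
  env <- tiny_env(30, 30, k = 5)
  S <- sapply(env$scores, function(s) as.vector(s$values))
  cors <- cor(S)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  expect_equal(sum(env$sdev^2), 5, tolerance = 1e-8)
  expect_equal(sum(env$explained), 1, tolerance = 1e-12)

  # duplicated variable: first component loads equally on the twins
  base <- tiny_env(20, 20, k = 1)$scores[[1]]
  set.seed(8)
  other <- raster_surface(matrix(rnorm(400), 20, 20), 5)
  env2 <- pca_environment(list(a = base, b = base, c = other))
  l <- env2$loadings[, 1]
  expect_equal(unname(abs(l["a"])), unname(abs(l["b"])), tolerance = 1e-8)

  # constant variable dropped with a warning
  cst <- raster_surface(matrix(1, 20, 20), 5)
  expect_warning(env3 <- pca_environment(list(a = base, k = cst, c = other)),
                 "constant")
  expect_equal(length(env3$scores), 2)
})

test_that("seven independent fields share variance about equally", {
  set.seed(11)
  surfs <- lapply(1:7, function(i)
    raster_surface(matrix(rnorm(1600), 40, 40), 5, name = paste0("n", i)))
  names(surfs) <- paste0("n", 1:7)
  env <- pca_environment(surfs)
  expect_true(all(env$explained > 0.09 & env$explained < 0.20))
})
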