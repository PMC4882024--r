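test_that("Matern covariance special cases and shape", {
  mp <- matern_params(1.3, 10, 0.5)
  expect_equal(matern_cov(0, mp), 1.3)
  # nu = 0.5 equals the exponential closed form (sqrt(2*0.5) = 1)
  r <- seq(0, 60, 0.25)
  expect_lt(max(abs(matern_cov(r, mp) - 1.3 * exp(-r / 10))), 1e-12)
  # strictly decreasing over (0, 5 phi] for several smoothness values
  for (nu in c(0.25, 0.5, 1, 2)) {
    v <- matern_cov(seq(0.01, 50, 0.1), matern_params(2, 10, nu))
    expect_true(all(diff(v) < 0), info = paste("nu =", nu))
  }
  expect_error(matern_params(1, -1, 0.5), "positive")
})

test_that("Gaussian field simulation has the right marginal moments", {
  w <- plot_window(400, 400)
  set.seed(41)
  vals <- unlist(lapply(1:8, function(i)
    as.vector(simulate_gaussian_field(w, 5, matern_params(1.5, 10, 0.5))$values)))
  expect_lt(abs(mean(vals)), 0.1)
  expect_lt(abs(var(vals) / 1.5 - 1), 0.12)
})

test_that("log-Gaussian Cox simulations match the pcf closed form", {
  # for a log-Gaussian Cox process g(r) = exp(C(r)); check at r = phi
  w <- plot_window(250, 250)
  mp <- matern_params(1, 10, 0.5)
  loglin <- structure(list(
    mu = log(500 / window_area(w)),
    beta = numeric(0),
    terms = data.frame(comp = integer(0), degree = integer(0)),
    intensity = raster_surface(matrix(500 / window_area(w), 50, 50), 5),
    loglik = NA, aic = NA, n = 500, env_cell_size = 5),
    class = "loglinear_model")
  model <- cox_model(loglin, mp)
  set.seed(42)
  g10 <- replicate(120, {
    p <- simulate_cox(model)
    if (n_points(p) < 30) return(NA_real_)
    pair_correlation(p, c(0, 5, 10, 15), bandwidth = 2.5)$values[3]
  })
  expect_lt(abs(mean(g10, na.rm = TRUE) / exp(matern_cov(10, mp)) - 1), 0.10)

  # mean count matches exp(mu) |W| under the unit-mean field convention
  set.seed(43)
  counts <- replicate(150, n_points(simulate_cox(model)))
  # Cox counts are overdispersed; compare on 3 SE of the realized counts
  expect_lt(abs(mean(counts) - 500), 3 * sd(counts) / sqrt(150))
})

test_that("without a residual the Cox model is exactly the HPP", {
  env <- tiny_env(30, 30, k = 2)
  set.seed(44)
  lam <- raster_surface(exp(0.6 * env$scores[[1]]$values), 5)
  lam$values <- lam$values * 300 / (sum(lam$values) * 25)
  p <- simulate_ipp(lam)
  m <- fit_loglinear(p, env, data.frame(comp = 1, degree = 1))
  p1 <- simulate_cox(cox_model(m, NULL), seed = 123)
  p2 <- simulate_ipp(m$intensity, seed = 123)
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)
})

test_that("two-step fit: step 1 is the composite-likelihood fit", {
  env <- tiny_env(40, 40, k = 2)
  set.seed(45)
  lam <- raster_surface(exp(1.0 * env$scores[[1]]$values), 5)
  lam$values <- lam$values * 600 / (sum(lam$values) * 25)
  base <- fit_loglinear(simulate_ipp(lam), env,
                        data.frame(comp = 1, degree = 1))
  cm <- cox_model(base, matern_params(0.8, 8, 0.5))
  set.seed(46)
  pc <- simulate_cox(cm)
  terms <- data.frame(comp = 1, degree = 1)
  two <- fit_cox_twostep(pc, env, terms = terms, r_max = 60)
  ref <- fit_loglinear(pc, env, terms)
  expect_equal(two$loglin$beta, ref$beta, tolerance = 1e-12)
  expect_equal(two$loglin$mu, ref$mu, tolerance = 1e-12)
  # recovered trend and clustering parameters are in range
  expect_lt(abs(two$loglin$beta[["PC1"]] - 1.0), 0.45)
  expect_gt(two$matern$variance, 0.15)
})

test_that("variance decomposition honours its identities", {
  env <- tiny_env(20, 20, k = 2)
  sc <- as.vector(env$scores[[1]]$values)
  mk_loglin <- function(beta, terms) structure(
    list(mu = -5, beta = beta, terms = terms, intensity = NULL,
         loglik = NA, aic = NA, n = 100, env_cell_size = 5),
    class = "loglinear_model")

  # D absent, beta present: PVE = 1
  m1 <- cox_model(mk_loglin(c(PC1 = 0.7), data.frame(comp = 1, degree = 1)))
  d1 <- variance_decomposition(m1, env)
  expect_equal(d1$pve, 1)
  expect_equal(d1$pvd, 0)

  # beta empty, D present: PVE = 0
  m2 <- cox_model(mk_loglin(numeric(0),
                            data.frame(comp = integer(0), degree = integer(0))),
                  matern_params(0.5, 10, 0.5))
  d2 <- variance_decomposition(m2, env)
  expect_equal(d2$pve, 0)
  expect_equal(d2$pvd, 1)

  # V_env equal to the Matern variance by construction: PVE = 0.5
  b <- 0.9
  venv <- var(sc * b)
  m3 <- cox_model(mk_loglin(c(PC1 = b), data.frame(comp = 1, degree = 1)),
                  matern_params(venv, 10, 0.5))
  d3 <- variance_decomposition(m3, env)
  expect_equal(d3$pve, 0.5, tolerance = 1e-12)
  expect_identical(d3$pve + d3$pvd, 1)

  # intercept-only with no D: undefined, flagged
  m4 <- cox_model(mk_loglin(numeric(0),
                            data.frame(comp = integer(0), degree = integer(0))))
  expect_false(variance_decomposition(m4, env)$defined)
})

test_that("model selection keeps D on Cox data and drops it on HPP data", {
  env <- tiny_env(40, 40, k = 2)
  set.seed(47)
  lam <- raster_surface(exp(0.8 * env$scores[[1]]$values), 5)
  lam$values <- lam$values * 500 / (sum(lam$values) * 25)
  base <- fit_loglinear(simulate_ipp(lam), env,
                        data.frame(comp = 1, degree = 1))
  truecox <- cox_model(base, matern_params(1, 8, 0.5))
  # retention power with 39 GoF simulations is ~0.8 on this fixture (the
  # inhomogeneous pcf has a heavy-tailed null under strong intensity
  # contrast); the null-side drop rate is essentially 1
  keep <- replicate(6, {
    p <- simulate_cox(truecox)
    !is.null(select_cox_model(p, env, n_sim = 39)$matern)
  })
  drop <- replicate(6, {
    p <- simulate_ipp(base$intensity)
    is.null(select_cox_model(p, env, n_sim = 39)$matern)
  })
  expect_gte(sum(keep), 4)
  expect_gte(sum(drop), 5)
})

test_that("PVE increments are grouped by syndrome", {
  tab <- data.frame(species = rep(c("A", "B", "C"), each = 3),
                    stage = rep(c("sapling", "juvenile", "adult"), 3),
                    pve = c(0.2, 0.3, 0.5, 0.1, 0.1, 0.1, 0.4, NA, 0.6))
  syn <- c(A = "wind", B = "animal", C = "animal")
  out <- pve_increments(tab, syndromes = syn)
  inc <- out$increments
  expect_equal(inc$delta_pve[inc$species == "A" &
                               inc$pair == "adult-juvenile"], 0.2)
  expect_equal(inc$delta_pve[inc$species == "B"], c(0, 0))
  # C has a missing juvenile PVE: both increments touching it are excluded
  expect_equal(nrow(inc[inc$species == "C", ]), 0)
  expect_equal(sort(unique(inc$syndrome)), c("animal", "wind"))
})
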