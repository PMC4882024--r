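#' Thomas (Poisson cluster) process parameters
#'
#' Parents form a homogeneous Poisson process of intensity `kappa` per m2;
#' each parent receives a Poisson(`mu`) number of offspring displaced by an
#' isotropic Gaussian with standard deviation `sigma` metres. The implied
#' stationary intensity is `kappa * mu`.
#'
#' @param kappa parent intensity per m2 (> 0).
#' @param sigma offspring displacement sd, metres (> 0).
#' @param mu mean offspring per parent (> 0).
#' @return object of class `thomas_params`.
#' @export
thomas_params <- function(kappa, sigma, mu) {
  if (any(c(kappa, sigma, mu) <= 0))
    stop("thomas_params: kappa, sigma, mu must be strictly positive")
  structure(list(kappa = kappa, sigma = sigma, mu = mu),
            class = "thomas_params")
}

#' @export
print.thomas_params <- function(x, ...) {
  cat(sprintf("Thomas process: kappa = %.4g /m2, sigma = %.3g m, mu = %.3g (lambda = %.4g)\n",
              x$kappa, x$sigma, x$mu, x$kappa * x$mu))
  invisible(x)
}

#' Theoretical K function of the Thomas process
#'
#' `K(r) = pi r^2 + (1 - exp(-r^2 / (4 sigma^2))) / kappa`.
#'
#' @param params a [thomas_params()] (`mu` is not needed and may be absent).
#' @param r distances, metres (>= 0).
#' @return numeric vector of K values.
#' @export
thomas_K <- function(params, r) {
  pi * r^2 + (1 - exp(-r^2 / (4 * params$sigma^2))) / params$kappa
}

#' Fit a Thomas process by minimum contrast on K
#'
#' Minimizes `int_0^rmax (Khat(r)^q - K(r; kappa, sigma)^q)^2 dr` with
#' `q = 0.25` (trapezoid rule on a 0.5-m grid) over `(kappa, sigma)`;
#' `mu` is then the observed intensity divided by `kappa`. Several starting
#' values are tried and the deterministic best is kept, so two runs on the
#' same pattern give identical estimates.
#'
#' @param pattern a [point_pattern()] with at least 10 points.
#' @param r_max upper integration limit, metres (default 100, clamped to
#'   0.49 of the shorter window side).
#' @param contrast_exponent the exponent `q`.
#' @param correction edge correction for the empirical K.
#' @return a [thomas_params()] with attributes `contrast` (objective at the
#'   optimum) and `convergence`.
#' @export
fit_thomas <- function(pattern, r_max = 100, contrast_exponent = 0.25,
                       correction = "isotropic") {
  n <- n_points(pattern)
  if (n < 10) stop("fit_thomas: at least 10 points required")
  w <- pattern$window
  r_max <- min(r_max, 0.49 * min(w$x_extent, w$y_extent))
  r <- default_r_grid(r_max)
  Khat <- ripley_K(pattern, r, correction = correction)$values
  lam <- intensity_hat(pattern)
  q <- contrast_exponent
  Kq <- Khat^q
  obj <- function(p) {
    kap <- exp(p[1]); sig <- exp(p[2])
    d2 <- (Kq - (pi * r^2 + (1 - exp(-r^2 / (4 * sig^2))) / kap)^q)^2
    sum((d2[-1] + d2[-length(d2)]) / 2 * diff(r))
  }
  starts <- expand.grid(kappa = lam / c(2, 10, 50), sigma = c(2, 5, 15))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- optim(log(as.numeric(starts[i, ])), obj, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0 && best$value > obj(best$par) * (1 + 1e-6))
    stop("fit_thomas: optimizer failed to converge; best iterate kappa=",
         exp(best$par[1]), " sigma=", exp(best$par[2]))
  kap <- exp(best$par[1]); sig <- exp(best$par[2])
  out <- thomas_params(kap, sig, lam / kap)
  attr(out, "contrast") <- best$value
  attr(out, "convergence") <- best$convergence
  attr(out, "r_max") <- r_max
  out
}

#' Simulate a Thomas process
#'
#' Parents are placed on the window expanded by `4 sigma` on all sides (so
#' that less than 1e-4 of offspring mass is lost from unrepresented
#' parents); offspring outside the window are discarded.
#'
#' @param params a [thomas_params()].
#' @param window a [plot_window()].
#' @param seed optional integer seed.
#' @return a [point_pattern()].
#' @export
simulate_thomas <- function(params, window, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- 4 * params$sigma
  xr <- xrange(window) + c(-ex, ex)
  yr <- yrange(window) + c(-ex, ex)
  A <- diff(xr) * diff(yr)
  n_par <- rpois(1, params$kappa * A)
  if (n_par == 0) return(point_pattern(numeric(0), numeric(0), window))
  px <- runif(n_par, xr[1], xr[2])
  py <- runif(n_par, yr[1], yr[2])
  n_off <- rpois(n_par, params$mu)
  cx <- rep(px, n_off) + rnorm(sum(n_off), 0, params$sigma)
  cy <- rep(py, n_off) + rnorm(sum(n_off), 0, params$sigma)
  keep <- inside_window(window, cx, cy)
  point_pattern(cx[keep], cy[keep], window)
}

simulate_csr <- function(lambda, window, conditional_n = NULL) {
  n <- if (is.null(conditional_n)) rpois(1, lambda * window_area(window))
       else conditional_n
  xr <- xrange(window); yr <- yrange(window)
  point_pattern(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]), window)
}

#' Aggregation screen against complete spatial randomness
#'
#' Tests whether a pattern is significantly *clustered*: a Loosmore
#' goodness-of-fit test of the empirical K against CSR simulations of the
#' same intensity over `range`, combined with a positive mean deviation of
#' `Khat` from the simulation mean. Species must pass this screen in every
#' life stage to enter the pipeline.
#'
#' @param pattern a [point_pattern()].
#' @param n_sim number of CSR simulations (default 199).
#' @param range distance range, metres (default 0-30).
#' @param alpha rejection level (default 0.05).
#' @param seed optional integer seed.
#' @return logical: `TRUE` iff GoF p <= alpha and the mean K deviation over
#'   `range` is positive. Attributes `p_value` and `mean_deviation`.
#' @export
csr_aggregation_screen <- function(pattern, n_sim = 199, range = c(0, 30),
                                   alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_points(pattern)
  if (n < 2) stop("csr_aggregation_screen: at least 2 points required")
  r <- default_r_grid(range[2])
  lam <- intensity_hat(pattern)
  obs <- ripley_K(pattern, r)
  sims <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    p <- simulate_csr(lam, pattern$window)
    while (n_points(p) < 2) p <- simulate_csr(lam, pattern$window)
    sims[[i]] <- ripley_K(p, r)
  }
  gof <- gof_loosmore(obs, sims, range = range)
  simbar <- rowMeans(curves_matrix(sims))
  in_range <- r >= range[1] & r <= range[2]
  mdev <- mean(obs$values[in_range] - simbar[in_range])
  out <- gof$p_value <= alpha && mdev > 0
  attr(out, "p_value") <- gof$p_value
  attr(out, "mean_deviation") <- mdev
  out
}

#' Stem density per habitat
#'
#' Counts points per habitat class of a 20-m [classify_habitats()] map and
#' divides by the habitat area. Habitats with zero area are excluded.
#'
#' @param pattern a [point_pattern()].
#' @param habitat_map a `habitat_map`.
#' @return named numeric vector, stems per hectare, one entry per habitat
#'   present in the map.
#' @export
habitat_density <- function(pattern, habitat_map) {
  qa_ha <- habitat_map$cell_size^2 / 1e4  # quadrat area in hectares
  area <- table(factor(habitat_map$labels, levels = habitat_map$levels)) * qa_ha
  area <- area[area > 0]
  lab <- habitat_at(habitat_map, pattern$x, pattern$y)
  cnt <- table(factor(lab, levels = names(area)))
  as.numeric(cnt) / as.numeric(area) -> dens
  names(dens) <- names(area)
  dens
}

#' Species-habitat association test under a Thomas null
#'
#' Fits a Thomas cluster process to the observed pattern (absorbing
#' environment-independent, dispersal-like aggregation into the null), then
#' simulates `n_sim` realizations and compares the observed per-habitat stem
#' density with the simulated density distribution. A habitat association is
#' `positive` when the observed density lies strictly above the upper bound
#' of the central `level` interval; the bound is rank-based (for 999
#' simulations at 99%: the 6th-largest simulated density). Only positive
#' associations are classified; everything else is `none`.
#'
#' @param pattern a [point_pattern()].
#' @param habitat_map a `habitat_map` covering the window.
#' @param n_sim simulations (default 999).
#' @param level central interval level (default 0.99).
#' @param seed optional integer seed.
#' @param params optional pre-fitted [thomas_params()].
#' @return object of class `association_result`: data.frame `table` with
#'   columns `habitat, observed, lower, upper, classification`, plus
#'   `params`, `n_sim`, `level`, `testable`. If the Thomas fit fails the
#'   species is flagged `testable = FALSE` (not silently skipped).
#' @export
habitat_association_test <- function(pattern, habitat_map, n_sim = 999,
                                     level = 0.99, seed = NULL,
                                     params = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) {
    params <- tryCatch(fit_thomas(pattern), error = function(e) e)
    if (inherits(params, "error"))
      return(structure(list(table = NULL, params = NULL, n_sim = n_sim,
                            level = level, testable = FALSE,
                            message = conditionMessage(params)),
                       class = "association_result"))
  }
  obs <- habitat_density(pattern, habitat_map)
  sims <- matrix(0, n_sim, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_sim))
    sims[i, ] <- habitat_density(simulate_thomas(params, pattern$window),
                                 habitat_map)
  k <- floor((n_sim + 1) * (1 - level) / 2) + 1L  # e.g. 6th-largest of 999
  upper <- apply(sims, 2, function(v) sort(v, decreasing = TRUE)[k])
  lower <- apply(sims, 2, function(v) sort(v)[k])
  cls <- ifelse(obs > upper, "positive", "none")
  structure(list(table = data.frame(habitat = names(obs), observed = obs,
                                    lower = lower, upper = upper,
                                    classification = cls,
                                    row.names = NULL),
                 params = params, n_sim = n_sim, level = level,
                 testable = TRUE),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  if (!x$testable) {
    cat("habitat association: untestable (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf("habitat association test (%d sims, level %.2f):\n",
              x$n_sim, x$level))
  print(x$table, digits = 4)
  invisible(x)
}
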