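# Cox process with log-linear environmental term plus a Matern-covariance
# Gaussian residual on the log-intensity scale, estimated by the two-step
# (composite likelihood, then minimum contrast) approach.

#' Matern covariance parameters
#'
#' @param variance marginal variance of the residual field on the
#'   log-intensity scale (> 0).
#' @param scale distance parameter phi, metres (> 0).
#' @param smoothness Matern smoothness nu (> 0).
#' @return object of class `matern_params`.
#' @export
matern_params <- function(variance, scale, smoothness = 0.5) {
  if (any(c(variance, scale, smoothness) <= 0))
    stop("matern_params: all parameters must be strictly positive")
  structure(list(variance = variance, scale = scale,
                 smoothness = smoothness), class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("Matern: variance = %.4g, scale = %.3g m, smoothness = %.3g\n",
              x$variance, x$scale, x$smoothness))
  invisible(x)
}

#' Matern covariance function
#'
#' `C(r) = s2 * 2^(1-nu)/Gamma(nu) * (r sqrt(2 nu)/phi)^nu * K_nu(r sqrt(2 nu)/phi)`,
#' with `C(0) = s2`. For `nu = 0.5` this equals the exponential covariance
#' `s2 exp(-r sqrt(2)/phi)` (note the sqrt(2 nu) parameterization).
#'
#' @param r distances, metres (>= 0), vectorized.
#' @param params a [matern_params()].
#' @return numeric vector of covariances.
#' @export
matern_cov <- function(r, params) {
  s2 <- params$variance; phi <- params$scale; nu <- params$smoothness
  out <- rep(s2, length(r))
  pos <- r > 0
  if (any(pos)) {
    u <- r[pos] * sqrt(2 * nu) / phi
    out[pos] <- s2 * 2^(1 - nu) / gamma(nu) * u^nu * besselK(u, nu)
  }
  out
}

#' Simulate a stationary Gaussian random field on a grid
#'
#' Circulant-embedding (FFT) simulation of a zero-mean Gaussian field with
#' Matern covariance on the cell centres of a regular grid. If the
#' embedding is not non-negative definite the (small) negative eigenvalues
#' are truncated to zero, with a warning when the truncated mass is
#' substantial; this is the standard approximate fallback.
#'
#' @param window a [plot_window()].
#' @param cell_size grid cell, metres.
#' @param params a [matern_params()].
#' @param seed optional integer seed.
#' @return a [raster_surface()] holding one realization.
#' @export
simulate_gaussian_field <- function(window, cell_size, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nx <- round(window$x_extent / cell_size)
  ny <- round(window$y_extent / cell_size)
  M <- 2^ceiling(log2(2 * nx)); N <- 2^ceiling(log2(2 * ny))
  # torus distances between cell centres on the embedding grid
  dx <- (0:(M - 1)); dx <- pmin(dx, M - dx) * cell_size
  dy <- (0:(N - 1)); dy <- pmin(dy, N - dy) * cell_size
  D <- sqrt(outer(dx^2, dy^2, "+"))
  C <- matrix(matern_cov(as.vector(D), params), M, N)
  ev <- Re(fft(C))
  neg <- ev < 0
  if (any(neg)) {
    if (sum(-ev[neg]) > 1e-3 * sum(ev[!neg]))
      warning("simulate_gaussian_field: circulant embedding not nnd; ",
              "truncating negative spectral mass (approximate simulation)")
    ev[neg] <- 0
  }
  Z <- matrix(stats::rnorm(M * N), M, N) + 1i * matrix(stats::rnorm(M * N), M, N)
  F <- fft(sqrt(ev / (M * N)) * Z)
  vals <- Re(F)[1:nx, 1:ny]  # rows index x on the embedding; transpose below
  raster_surface(t(vals), cell_size, origin = window$origin,
                 name = "gaussian field")
}

#' Cox model container
#'
#' A log-linear environmental intensity model plus an optional Matern
#' residual. With the residual absent the model is exactly the
#' heterogeneous Poisson model.
#'
#' @param loglin a `loglinear_model` from [fit_loglinear()].
#' @param matern a [matern_params()] or `NULL`.
#' @return object of class `cox_model`.
#' @export
cox_model <- function(loglin, matern = NULL) {
  stopifnot(inherits(loglin, "loglinear_model"))
  if (!is.null(matern)) stopifnot(inherits(matern, "matern_params"))
  structure(list(loglin = loglin, matern = matern), class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat("Cox process model\n  ")
  print(x$loglin)
  if (is.null(x$matern)) cat("  no residual field (heterogeneous Poisson)\n")
  else { cat("  residual "); print(x$matern) }
  invisible(x)
}

#' Simulate from a Cox model
#'
#' Draws the Matern residual field `D` on the intensity grid with mean
#' `-variance/2` so that `E[exp(D)] = 1` (the intercept stays comparable
#' across models), multiplies the environmental intensity by `exp(D)`, and
#' thins a homogeneous Poisson pattern. With the residual absent this is
#' exactly [simulate_ipp()] (same seed, same pattern).
#'
#' @param model a [cox_model()].
#' @param seed optional integer seed.
#' @return a [point_pattern()].
#' @export
simulate_cox <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam <- model$loglin$intensity
  if (is.null(model$matern)) return(simulate_ipp(lam))
  w <- surface_window(lam)
  D <- simulate_gaussian_field(w, lam$cell_size, model$matern)
  lam2 <- raster_surface(lam$values *
                           exp(D$values - model$matern$variance / 2),
                         lam$cell_size, origin = lam$origin,
                         name = "cox intensity")
  simulate_ipp(lam2)
}

# theoretical inhomogeneous K of the log-Gaussian Cox model:
# g(s) = exp(C(s)), K(r) = int_0^r 2 pi s g(s) ds  (trapezoid on a fine grid)
cox_theoretical_K <- function(r, params, refine = 4L) {
  rmax <- max(r)
  s <- seq(0, rmax, length.out = refine * length(r))
  gs <- 2 * pi * s * exp(matern_cov(s, params))
  Kfine <- c(0, cumsum((gs[-1] + gs[-length(gs)]) / 2 * diff(s)))
  stats::approx(s, Kfine, xout = r)$y
}

#' Two-step fit of the Cox model
#'
#' Step 1 estimates the intercept and environmental coefficients by the
#' Poisson composite-likelihood estimating equation (the same machinery as
#' [fit_loglinear()], consistent under the Cox model). Step 2 estimates the
#' Matern residual variance and scale by minimum contrast (`q = 0.25`,
#' 0-100 m) between the inhomogeneous K of the data (weighted by the step-1
#' intensity) and the theoretical Cox K; the smoothness `nu` is profiled
#' over a small grid.
#'
#' @inheritParams fit_loglinear
#' @param r_max contrast range upper limit (default 100 m, clamped to the
#'   window).
#' @param contrast_exponent the exponent `q` (default 0.25).
#' @param nu_grid candidate smoothness values.
#' @return a [cox_model()] with attribute `contrast`.
#' @export
fit_cox_twostep <- function(pattern, env, terms = NULL, r_max = 100,
                            contrast_exponent = 0.25,
                            nu_grid = c(0.25, 0.5, 1)) {
  if (n_points(pattern) < 10) stop("fit_cox_twostep: at least 10 points required")
  step1 <- fit_loglinear(pattern, env, terms)
  w <- pattern$window
  r_max <- min(r_max, 0.49 * min(w$x_extent, w$y_extent))
  r <- default_r_grid(r_max)
  Khat <- ripley_K_inhom(pattern, step1$intensity, r)$values
  q <- contrast_exponent
  Kq <- Khat^q
  contrast_of <- function(s2, phi, nu) {
    Kth <- cox_theoretical_K(r, matern_params(s2, phi, nu))
    d2 <- (Kq - Kth^q)^2
    sum((d2[-1] + d2[-length(d2)]) / 2 * diff(r))
  }
  best <- NULL
  for (nu in nu_grid) {
    obj <- function(p) contrast_of(exp(p[1]), exp(p[2]), nu)
    for (start in list(c(log(0.5), log(10)), c(log(1.5), log(30)))) {
      fit <- optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 600, reltol = 1e-9))
      if (is.null(best) || fit$value < best$value) {
        best <- fit; best$nu <- nu
      }
    }
  }
  if (!is.finite(best$value))
    stop("fit_cox_twostep: minimum contrast failed; best iterate ",
         paste(exp(best$par), collapse = ", "))
  mp <- matern_params(exp(best$par[1]), exp(best$par[2]), best$nu)
  out <- cox_model(step1, mp)
  attr(out, "contrast") <- best$value
  out
}

#' Stepwise Cox model selection
#'
#' Selects the environmental terms by AIC-stepwise search on the step-1
#' composite likelihood ([stepwise_select()]), then decides whether the
#' residual clustering term is needed: `n_sim` patterns are simulated from
#' the no-residual (heterogeneous Poisson) model and the residual is
#' retained iff the Loosmore GoF of the observed inhomogeneous pair
#' correlation against those simulations rejects at `alpha`. When retained,
#' the Matern parameters are estimated by [fit_cox_twostep()] and the final
#' model's adequacy is checked by a second GoF against its own simulations.
#'
#' @inheritParams fit_cox_twostep
#' @param n_sim GoF simulations (default 39).
#' @param alpha rejection level (default 0.05).
#' @param gof_range distance range for the GoF tests, metres (default
#'   0-20 m, the neighbourhood band where residual clustering is assessed).
#' @param seed optional integer seed.
#' @param loglin optional pre-selected `loglinear_model`.
#' @return a [cox_model()] with attributes `d_pvalue` (GoF p against the
#'   no-residual model), `adequate` (final GoF pass) and `adequacy_pvalue`.
#' @export
select_cox_model <- function(pattern, env, n_sim = 39, alpha = 0.05,
                             gof_range = c(0, 20), seed = NULL,
                             loglin = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loglin)) loglin <- stepwise_select(pattern, env)
  lam <- loglin$intensity
  r <- default_r_grid(gof_range[2])
  bw <- stoyan_bandwidth(pattern)
  gof_curves <- function(model_sim) {
    sims <- vector("list", n_sim)
    for (i in seq_len(n_sim)) {
      p <- model_sim()
      tries <- 0
      while (n_points(p) < 2 && tries < 100) { p <- model_sim(); tries <- tries + 1 }
      sims[[i]] <- pair_correlation_inhom(p, lam, r, bandwidth = bw)
    }
    sims
  }
  obs <- pair_correlation_inhom(pattern, lam, r, bandwidth = bw)
  grange <- c(max(gof_range[1], min(r[r > 0])), gof_range[2])
  gof0 <- gof_loosmore(obs, gof_curves(function() simulate_ipp(lam)),
                       range = grange)
  if (gof0$p_value > alpha) {
    out <- cox_model(loglin, NULL)
    attr(out, "d_pvalue") <- gof0$p_value
    attr(out, "adequate") <- TRUE
    attr(out, "adequacy_pvalue") <- gof0$p_value
    return(out)
  }
  out <- fit_cox_twostep(pattern, env, terms = loglin$terms)
  gof1 <- gof_loosmore(obs, gof_curves(function() simulate_cox(out)),
                       range = grange)
  attr(out, "d_pvalue") <- gof0$p_value
  attr(out, "adequate") <- gof1$p_value > alpha
  attr(out, "adequacy_pvalue") <- gof1$p_value
  out
}

#' Spatial variance decomposition (PVE / PVD)
#'
#' Decomposes the spatial variance of the log intensity into the part
#' explained by the environmental term and the part carried by the residual
#' field: `V_env` is the variance of `H(u) beta_hat` over grid cells,
#' `V_resid` is the fitted Matern marginal variance (0 when the residual is
#' absent); `PVE = V_env / (V_env + V_resid)` and `PVD = 1 - PVE` exactly.
#'
#' @param model a [cox_model()].
#' @param env the `env_stack` the model was fitted on.
#' @return object of class `decomposition_result` with `pve`, `pvd`,
#'   `v_env`, `v_resid`, `defined`.
#' @export
variance_decomposition <- function(model, env) {
  terms <- model$loglin$terms
  v_env <- if (nrow(terms) == 0) 0 else {
    Xc <- cell_design(env, terms)
    var(as.vector(Xc %*% model$loglin$beta))
  }
  v_res <- if (is.null(model$matern)) 0 else model$matern$variance
  if (v_env + v_res == 0) {
    return(structure(list(pve = NA_real_, pvd = NA_real_, v_env = 0,
                          v_resid = 0, defined = FALSE),
                     class = "decomposition_result"))
  }
  pve <- v_env / (v_env + v_res)
  structure(list(pve = pve, pvd = 1 - pve, v_env = v_env, v_resid = v_res,
                 defined = TRUE),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  if (!x$defined) cat("variance decomposition undefined (no environment, no residual)\n")
  else cat(sprintf("PVE = %.3f, PVD = %.3f (V_env = %.3g, V_resid = %.3g)\n",
                   x$pve, x$pvd, x$v_env, x$v_resid))
  invisible(x)
}

#' Stage-to-stage PVE increments by dispersal syndrome
#'
#' Computes, for each species and each consecutive stage pair, the PVE
#' increment (later stage minus earlier stage), and summarizes the
#' increments per dispersal syndrome. Species missing either stage of a
#' pair are excluded from that increment.
#'
#' @param pve_table data.frame with columns `species`, `stage`, `pve`.
#' @param stages ordered character vector of stage names (early to late).
#' @param syndromes named character vector mapping species code to one of
#'   `"gravity_ballistic"`, `"animal"`, `"wind"`.
#' @return list with `increments` (species, pair, delta_pve, syndrome) and
#'   `by_syndrome` (per syndrome and pair: mean, n).
#' @export
pve_increments <- function(pve_table,
                           stages = c("sapling", "juvenile", "adult"),
                           syndromes) {
  rows <- list()
  for (sp in unique(pve_table$species)) {
    sub <- pve_table[pve_table$species == sp, ]
    for (k in seq_len(length(stages) - 1)) {
      lo <- sub$pve[sub$stage == stages[k]]
      hi <- sub$pve[sub$stage == stages[k + 1]]
      if (length(lo) == 1 && length(hi) == 1 && !is.na(lo) && !is.na(hi)) {
        rows[[length(rows) + 1]] <- data.frame(
          species = sp,
          pair = paste(stages[k + 1], stages[k], sep = "-"),
          delta_pve = hi - lo,
          syndrome = unname(syndromes[sp]))
      }
    }
  }
  inc <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(species = character(0), pair = character(0),
               delta_pve = numeric(0), syndrome = character(0))
  by_syn <- if (nrow(inc) > 0)
    aggregate(delta_pve ~ syndrome + pair, inc,
              function(v) c(mean = mean(v), n = length(v)))
  else NULL
  list(increments = inc, by_syndrome = by_syn)
}
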