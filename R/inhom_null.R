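# Heterogeneous Poisson machinery: log-linear intensity on PCA covariates,
# fitted by the Berman-Turner quadrature device (one dummy point per grid
# cell plus the data points, cell-area weights, weighted Poisson GLM).

# term table: data.frame(comp, degree); design column = score^degree
term_label <- function(terms) {
  if (nrow(terms) == 0) return(character(0))
  ifelse(terms$degree == 1, paste0("PC", terms$comp),
         paste0("I(PC", terms$comp, "^2)"))
}

# cell-level design matrix (ncell x nterms, no intercept)
cell_design <- function(env, terms) {
  ncell <- length(env$scores[[1]]$values)
  if (nrow(terms) == 0) return(matrix(0, ncell, 0))
  X <- matrix(0, ncell, nrow(terms))
  for (k in seq_len(nrow(terms)))
    X[, k] <- as.vector(env$scores[[terms$comp[k]]]$values)^terms$degree[k]
  colnames(X) <- term_label(terms)
  X
}

# Berman-Turner quadrature layout for one pattern on the env grid:
# weights partition each cell's area among its data points plus one dummy
bt_setup <- function(pattern, env) {
  s1 <- env$scores[[1]]
  cellarea <- env$cell_size^2
  ncell <- length(s1$values)
  idx <- cell_index(s1, pattern$x, pattern$y)
  cell_of_point <- (idx$ix - 1L) * nrow(s1$values) + idx$iy
  m_per_cell <- tabulate(cell_of_point, nbins = ncell) + 1L
  w <- c(cellarea / m_per_cell[cell_of_point], cellarea / m_per_cell)
  y <- c(m_per_cell[cell_of_point] / cellarea, rep(0, ncell))
  list(cell_of_point = cell_of_point, w = w, y = y, ncell = ncell,
       cellarea = cellarea)
}

# lean fit on a precomputed cell design; returns coefficients and loglik
bt_fit <- function(bt, Xcell) {
  X <- cbind(1, rbind(Xcell[bt$cell_of_point, , drop = FALSE], Xcell))
  fit <- pois_irls(X, bt$y, bt$w)
  if (isTRUE(fit$singular) || !fit$converged) return(NULL)
  cf <- fit$coefficients
  eta_cell <- as.vector(cbind(1, Xcell) %*% cf)
  loglik <- sum(eta_cell[bt$cell_of_point]) -
    sum(exp(eta_cell)) * bt$cellarea
  list(coefficients = cf, eta_cell = eta_cell, loglik = loglik)
}

#' Fit a log-linear heterogeneous Poisson intensity model
#'
#' Maximizes the Poisson point-process likelihood
#' `sum_i log rho(x_i) - int_W rho(u) du` for
#' `log rho(u) = mu + H(u) beta` by the Berman-Turner device: quadrature
#' points are the data points plus one dummy per grid cell, with weights
#' that partition each cell's area, fitted as a weighted Poisson GLM.
#' Covariates are piecewise constant on the grid, so the intercept score
#' equation makes the fitted intensity integrate exactly to the observed
#' count.
#'
#' @param pattern a [point_pattern()] with at least 10 points (relaxed for
#'   the intercept-only model).
#' @param env an `env_stack` from [pca_environment()].
#' @param terms data.frame with columns `comp` (component index) and
#'   `degree` (1 or 2); `NULL` or zero rows fits the homogeneous model.
#' @return object of class `loglinear_model`: `mu` (intercept),
#'   `beta` (named coefficients), `terms`, `intensity` (fitted
#'   [raster_surface()]), `loglik`, `aic`, `n`, `env_cell_size`.
#' @export
fit_loglinear <- function(pattern, env, terms = NULL) {
  if (is.null(terms)) terms <- data.frame(comp = integer(0), degree = integer(0))
  n <- n_points(pattern)
  if (n < 1) stop("fit_loglinear: empty pattern")
  if (nrow(terms) > 0 && n < 10)
    stop("fit_loglinear: at least 10 points required with covariates")
  s1 <- env$scores[[1]]
  cellarea <- env$cell_size^2
  Xcell <- cell_design(env, terms)
  bt <- bt_setup(pattern, env)
  fit <- bt_fit(bt, Xcell)
  if (is.null(fit))
    stop("fit_loglinear: singular design or IRLS non-convergence")
  cf <- fit$coefficients
  lam_cell <- exp(fit$eta_cell)
  loglik <- fit$loglik
  p <- length(cf)
  structure(list(mu = unname(cf[1]),
                 beta = setNames(cf[-1], term_label(terms)),
                 terms = terms,
                 intensity = raster_surface(matrix(lam_cell, nrow(s1$values)),
                                            env$cell_size, origin = s1$origin,
                                            name = "fitted intensity"),
                 loglik = loglik, aic = -2 * loglik + 2 * p, n = n,
                 env_cell_size = env$cell_size),
            class = "loglinear_model")
}

#' @export
print.loglinear_model <- function(x, ...) {
  cat(sprintf("log-linear intensity model: mu = %.4f, %d covariate term(s), AIC = %.2f\n",
              x$mu, length(x$beta), x$aic))
  if (length(x$beta) > 0) print(round(x$beta, 4))
  invisible(x)
}

# candidate add/drop moves under the marginality principle
stepwise_moves <- function(terms, n_comp, max_degree = 2) {
  has <- function(comp, deg) any(terms$comp == comp & terms$degree == deg)
  add <- list(); drop <- list()
  for (cmp in seq_len(n_comp)) {
    if (!has(cmp, 1)) add <- c(add, list(data.frame(comp = cmp, degree = 1)))
    else {
      if (max_degree >= 2 && !has(cmp, 2))
        add <- c(add, list(data.frame(comp = cmp, degree = 2)))
      if (!has(cmp, 2))
        drop <- c(drop, list(data.frame(comp = cmp, degree = 1)))
    }
    if (has(cmp, 2)) drop <- c(drop, list(data.frame(comp = cmp, degree = 2)))
  }
  list(add = add, drop = drop)
}

#' Stepwise selection of the heterogeneous Poisson model
#'
#' Forward-backward search over linear and quadratic terms of each
#' principal component, starting from the intercept-only model. The
#' marginality principle is enforced: a quadratic term never enters without
#' its linear term, and a linear term is never dropped while its quadratic
#' term remains. Deterministic: the same input always yields the same model.
#'
#' The default criterion is BIC (penalty `log(n)` per parameter, `n` the
#' point count): with up to 14 candidate terms an AIC search admits at
#' least one spurious term in most null replicates, whereas the BIC keeps
#' the intercept-only model on homogeneous data at the expected ~90+ percent
#' rate and keeps the variance decomposition honest on clustered data.
#'
#' @inheritParams fit_loglinear
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param max_degree polynomial cap (default 2).
#' @return the selected `loglinear_model` (possibly intercept-only).
#' @export
stepwise_select <- function(pattern, env, criterion = c("BIC", "AIC"),
                            max_degree = 2) {
  criterion <- match.arg(criterion)
  n_comp <- length(env$scores)
  pen <- if (criterion == "BIC") log(n_points(pattern)) else 2
  # all candidate columns once; candidate models subset columns
  all_terms <- data.frame(comp = rep(seq_len(n_comp), each = max_degree),
                          degree = rep(seq_len(max_degree), n_comp))
  Xall <- cell_design(env, all_terms)
  bt <- bt_setup(pattern, env)
  col_of <- function(tt) (tt$comp - 1L) * max_degree + tt$degree
  score_terms <- function(tt) {
    f <- bt_fit(bt, Xall[, col_of(tt), drop = FALSE])
    if (is.null(f)) Inf else -2 * f$loglik + pen * (nrow(tt) + 1)
  }
  terms <- data.frame(comp = integer(0), degree = integer(0))
  cur_score <- score_terms(terms)
  repeat {
    mv <- stepwise_moves(terms, n_comp, max_degree)
    cand <- c(lapply(mv$add, function(t) rbind(terms, t)),
              lapply(mv$drop, function(t)
                terms[!(terms$comp == t$comp & terms$degree == t$degree), ,
                      drop = FALSE]))
    if (length(cand) == 0) break
    scores <- vapply(cand, score_terms, numeric(1))
    best <- which.min(scores)
    if (scores[best] < cur_score - 1e-8) {
      cur_score <- scores[best]; terms <- cand[[best]]
    } else break
  }
  fit_loglinear(pattern, env, terms)
}

#' Simulate an inhomogeneous Poisson pattern
#'
#' Thins a homogeneous Poisson pattern at the maximum of the (piecewise
#' constant) intensity surface; the expected count equals the integral of
#' the intensity over the window.
#'
#' @param intensity a [raster_surface()] of non-negative intensities, or a
#'   `loglinear_model` (its fitted surface is used).
#' @param seed optional integer seed.
#' @return a [point_pattern()].
#' @export
simulate_ipp <- function(intensity, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(intensity, "loglinear_model")) intensity <- intensity$intensity
  w <- surface_window(intensity)
  lmax <- max(intensity$values)
  if (lmax <= 0) return(point_pattern(numeric(0), numeric(0), w))
  n <- rpois(1, lmax * window_area(w))
  xr <- xrange(w); yr <- yrange(w)
  x <- runif(n, xr[1], xr[2]); y <- runif(n, yr[1], yr[2])
  keep <- runif(n) < surface_value_at(intensity, x, y) / lmax
  point_pattern(x[keep], y[keep], w)
}

#' Dispersal-limitation test under the heterogeneous Poisson null
#'
#' Simulates `n_sim` patterns from the fitted (or supplied) heterogeneous
#' Poisson model and compares the inhomogeneous pair correlation of the
#' observed pattern with the simulated ones, all evaluated against the same
#' fitted intensity surface. The species is flagged dispersal-limited when
#' the observed curve rises above the pointwise envelope anywhere in
#' `scale_range` (one-sided). A Loosmore GoF over the same range is
#' returned alongside.
#'
#' @inheritParams fit_loglinear
#' @param n_sim simulations (default 199).
#' @param level envelope level (default 0.95).
#' @param scale_range metres (default 0-20).
#' @param seed optional integer seed.
#' @param model optional pre-fitted `loglinear_model` (skips stepwise
#'   selection).
#' @return list with `envelope` (an `envelope_result`), `gof`
#'   (a `gof_result`), `significant`, `model`.
#' @export
dispersal_limitation_test <- function(pattern, env, n_sim = 199, level = 0.95,
                                      scale_range = c(0, 20), seed = NULL,
                                      model = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- stepwise_select(pattern, env)
  lam <- model$intensity
  r <- default_r_grid(scale_range[2])
  bw <- stoyan_bandwidth(pattern)
  obs <- pair_correlation_inhom(pattern, lam, r, bandwidth = bw)
  sims <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    p <- simulate_ipp(lam)
    tries <- 0
    while (n_points(p) < 2 && tries < 100) { p <- simulate_ipp(lam); tries <- tries + 1 }
    sims[[i]] <- pair_correlation_inhom(p, lam, r, bandwidth = bw)
  }
  env_res <- envelope(obs, sims, level = level, scale_range = scale_range)
  gof <- gof_loosmore(obs, sims, range = c(max(scale_range[1], min(r[r > 0])),
                                           scale_range[2]))
  list(envelope = env_res, gof = gof, significant = env_res$significant,
       model = model)
}
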