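#' Summary-statistic curve
#'
#' Container for a second-order summary statistic evaluated on a distance
#' grid. The grid is strictly increasing and starts at 0; pair-correlation
#' statistics are undefined at r = 0 and carry `NA` there.
#'
#' @param r distance grid, metres.
#' @param values statistic values.
#' @param statistic one of `"K"`, `"g"`, `"g_inhom"`, `"K_inhom"`.
#' @param correction edge-correction label.
#' @return object of class `summary_curve`.
#' @export
summary_curve <- function(r, values, statistic, correction = "isotropic") {
  stopifnot(length(r) == length(values), !is.unsorted(r, strictly = TRUE))
  structure(list(r = r, values = values, statistic = statistic,
                 correction = correction), class = "summary_curve")
}

#' @export
print.summary_curve <- function(x, ...) {
  cat(sprintf("summary curve %s (%s correction), %d r values in [%g, %g]\n",
              x$statistic, x$correction, length(x$r), min(x$r), max(x$r)))
  invisible(x)
}

default_r_grid <- function(rmax, step = 0.5) seq(0, rmax, by = step)

correction_code <- function(correction) {
  match(match.arg(correction, c("none", "isotropic", "translation")),
        c("none", "isotropic", "translation")) - 1L
}

#' Ripley's K function
#'
#' Edge-corrected empirical K:
#' `Khat(r) = |W| / (n (n - 1)) * sum_{i != j} e_ij 1(d_ij <= r)`, with
#' `e_ij` the chosen edge-correction weight (Ripley isotropic, translation,
#' or none).
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @param r distance grid starting at 0 (default 0.5-m steps to a quarter of
#'   the shorter window side).
#' @param correction `"isotropic"` (default), `"translation"` or `"none"`.
#' @return a [summary_curve()].
#' @export
ripley_K <- function(pattern, r = NULL,
                     correction = c("isotropic", "translation", "none")) {
  correction <- match.arg(correction)
  n <- n_points(pattern)
  if (n < 2) stop("ripley_K: undefined for fewer than 2 points")
  w <- pattern$window
  if (is.null(r)) r <- default_r_grid(min(w$x_extent, w$y_extent) / 4)
  xr <- xrange(w); yr <- yrange(w)
  S <- pair_count_cum(pattern$x, pattern$y, r, xr[1], xr[2], yr[1], yr[2],
                      correction_code(correction))
  K <- window_area(w) * S / (n * (n - 1))
  summary_curve(r, K, "K", correction)
}

stoyan_bandwidth <- function(pattern) 0.15 / sqrt(intensity_hat(pattern))

#' Pair correlation function
#'
#' Kernel-smoothed (Epanechnikov) density of pairwise distances, edge
#' corrected and normalized so that the expectation under complete spatial
#' randomness is 1. Default bandwidth is Stoyan's `0.15 / sqrt(lambda_hat)`.
#' The value at r = 0 is `NA`.
#'
#' @inheritParams ripley_K
#' @param bandwidth kernel half-width, metres (> 0).
#' @return a [summary_curve()].
#' @export
pair_correlation <- function(pattern, r = NULL,
                             correction = c("isotropic", "translation", "none"),
                             bandwidth = NULL) {
  correction <- match.arg(correction)
  n <- n_points(pattern)
  if (n < 2) stop("pair_correlation: undefined for fewer than 2 points")
  if (is.null(bandwidth)) bandwidth <- stoyan_bandwidth(pattern)
  if (bandwidth <= 0) stop("pair_correlation: bandwidth must be > 0")
  w <- pattern$window
  if (is.null(r)) r <- default_r_grid(min(w$x_extent, w$y_extent) / 4)
  xr <- xrange(w); yr <- yrange(w)
  S <- pair_kernel_sum(pattern$x, pattern$y, r, bandwidth,
                       xr[1], xr[2], yr[1], yr[2],
                       correction_code(correction))
  g <- window_area(w) * S / (2 * pi * r * n * (n - 1))
  g[r <= 0] <- NA_real_
  out <- summary_curve(r, g, "g", correction)
  out$bandwidth <- bandwidth
  out
}

#' Inhomogeneous pair correlation function
#'
#' As [pair_correlation()], but each pair contribution is weighted by
#' `1 / (lambda(x_i) lambda(x_j))` with `lambda` a supplied intensity
#' surface. A small-sample factor `n / (n - 1)` is applied so that with a
#' constant intensity `n / |W|` the estimate equals the homogeneous pair
#' correlation exactly.
#'
#' @inheritParams pair_correlation
#' @param intensity a [raster_surface()] of intensities, strictly positive at
#'   every data point.
#' @return a [summary_curve()].
#' @export
pair_correlation_inhom <- function(pattern, intensity, r = NULL,
                                   correction = c("isotropic", "translation",
                                                  "none"),
                                   bandwidth = NULL) {
  correction <- match.arg(correction)
  n <- n_points(pattern)
  if (n < 2) stop("pair_correlation_inhom: undefined for fewer than 2 points")
  if (is.null(bandwidth)) bandwidth <- stoyan_bandwidth(pattern)
  if (bandwidth <= 0) stop("pair_correlation_inhom: bandwidth must be > 0")
  lam <- surface_value_at(intensity, pattern$x, pattern$y)
  if (any(lam <= 0)) {
    i <- which(lam <= 0)[1]
    stop(sprintf("zero or negative intensity at data point %d (x=%g, y=%g)",
                 i, pattern$x[i], pattern$y[i]))
  }
  w <- pattern$window
  if (is.null(r)) r <- default_r_grid(min(w$x_extent, w$y_extent) / 4)
  xr <- xrange(w); yr <- yrange(w)
  S <- pair_kernel_sum(pattern$x, pattern$y, r, bandwidth,
                       xr[1], xr[2], yr[1], yr[2],
                       correction_code(correction), lam)
  g <- (n / (n - 1)) * S / (2 * pi * r * window_area(w))
  g[r <= 0] <- NA_real_
  out <- summary_curve(r, g, "g_inhom", correction)
  out$bandwidth <- bandwidth
  out
}

#' Inhomogeneous K function
#'
#' Intensity-weighted K with the same `n / (n - 1)` convention as
#' [pair_correlation_inhom()], so that a constant intensity reproduces
#' [ripley_K()] exactly. Used by the two-step Cox fit.
#'
#' @inheritParams pair_correlation_inhom
#' @return a [summary_curve()].
#' @export
ripley_K_inhom <- function(pattern, intensity, r = NULL,
                           correction = c("isotropic", "translation", "none")) {
  correction <- match.arg(correction)
  n <- n_points(pattern)
  if (n < 2) stop("ripley_K_inhom: undefined for fewer than 2 points")
  lam <- surface_value_at(intensity, pattern$x, pattern$y)
  if (any(lam <= 0)) stop("ripley_K_inhom: non-positive intensity at a data point")
  w <- pattern$window
  if (is.null(r)) r <- default_r_grid(min(w$x_extent, w$y_extent) / 4)
  xr <- xrange(w); yr <- yrange(w)
  S <- pair_count_cum(pattern$x, pattern$y, r, xr[1], xr[2], yr[1], yr[2],
                      correction_code(correction), lam)
  K <- (n / (n - 1)) * S / window_area(w)
  summary_curve(r, K, "K_inhom", correction)
}

curves_matrix <- function(curves) {
  r <- curves[[1]]$r
  for (cv in curves)
    if (!isTRUE(all.equal(cv$r, r))) stop("curves on mismatched r grids")
  vapply(curves, function(cv) cv$values, numeric(length(r)))
}

#' Pointwise Monte Carlo simulation envelope
#'
#' Rank-based pointwise envelope: with `m` simulated curves at two-sided
#' level `L`, the bounds are the k-th smallest and k-th largest simulated
#' values at each distance, `k = floor((m + 1) (1 - L) / 2)` (for 199
#' simulations at 95%: the 5th-lowest and 5th-highest). Significance is
#' one-sided: the observed curve exceeds the upper bound at any distance
#' inside `scale_range`.
#'
#' @param observed a [summary_curve()].
#' @param simulated list of [summary_curve()]s on the same r grid.
#' @param level two-sided pointwise level, typically 0.95 or 0.99.
#' @param scale_range distances (m) over which exceedance counts as
#'   significant; default the full grid.
#' @return object of class `envelope_result` with elements `observed`,
#'   `lower`, `upper`, `n_sim`, `level`, `scale_range`, `exceeds_above`,
#'   `significant`.
#' @export
envelope <- function(observed, simulated, level = 0.95, scale_range = NULL) {
  M <- curves_matrix(c(list(observed), simulated))
  r <- observed$r
  sims <- M[, -1, drop = FALSE]
  m <- ncol(sims)
  k <- max(1L, floor((m + 1) * (1 - level) / 2))
  lower <- apply(sims, 1, function(v) sort(v)[k])
  upper <- apply(sims, 1, function(v) sort(v, decreasing = TRUE)[k])
  if (is.null(scale_range)) scale_range <- range(r)
  in_range <- r >= scale_range[1] & r <= scale_range[2]
  exceeds <- !is.na(observed$values) & !is.na(upper) &
    observed$values > upper
  structure(list(observed = observed,
                 lower = summary_curve(r, lower, observed$statistic,
                                       observed$correction),
                 upper = summary_curve(r, upper, observed$statistic,
                                       observed$correction),
                 n_sim = m, level = level, scale_range = scale_range,
                 exceeds_above = exceeds,
                 significant = any(exceeds & in_range)),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf("envelope: %d sims, level %.2f, range [%g, %g] m -> %s\n",
              x$n_sim, x$level, x$scale_range[1], x$scale_range[2],
              if (x$significant) "significant above" else "not significant"))
  invisible(x)
}

#' Loosmore-Ford goodness-of-fit test
#'
#' Scale-integrated squared deviation of each curve from the mean of all the
#' other curves: `u_i = sum_r (H_i(r) - Hbar_{-i}(r))^2 dr` over the stated
#' distance range, with a rank p-value
#' `p = (1 + #{u_sim >= u_obs}) / (n_sim + 1)`.
#'
#' @param observed a [summary_curve()].
#' @param simulated list of at least 39 simulated curves on the same grid.
#' @param range distance range (m) of integration; must lie inside the grid.
#' @return object of class `gof_result` with `u_obs`, `u_sims`, `p_value`,
#'   `range`.
#' @export
gof_loosmore <- function(observed, simulated, range = NULL) {
  if (length(simulated) < 39)
    warning("gof_loosmore: fewer than 39 simulations")
  M <- curves_matrix(c(list(observed), simulated))
  r <- observed$r
  if (is.null(range)) range <- base::range(r)
  if (range[1] < min(r) || range[2] > max(r))
    stop("gof_loosmore: range outside the r grid")
  keep <- r >= range[1] & r <= range[2] & stats::complete.cases(M)
  if (!any(keep)) stop("gof_loosmore: no usable r values in range")
  M <- M[keep, , drop = FALSE]
  dr <- diff(r[keep])
  dr <- c(dr, dr[length(dr)])  # weight per grid point
  ntot <- ncol(M)
  tot <- rowSums(M)
  u <- vapply(seq_len(ntot), function(i) {
    hbar <- (tot - M[, i]) / (ntot - 1)
    sum((M[, i] - hbar)^2 * dr)
  }, numeric(1))
  u_obs <- u[1]; u_sims <- u[-1]
  p <- (1 + sum(u_sims >= u_obs)) / (length(u_sims) + 1)
  structure(list(u_obs = u_obs, u_sims = u_sims, p_value = p, range = range),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Loosmore GoF: u = %.4g over [%g, %g] m, p = %.4f (%d sims)\n",
              x$u_obs, x$range[1], x$range[2], x$p_value, length(x$u_sims)))
  invisible(x)
}

#' Export a curve with envelope bounds as delimited text
#'
#' @param env an `envelope_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  df <- data.frame(r = env$observed$r, observed = env$observed$values,
                   lower = env$lower$values, upper = env$upper$values,
                   exceeds_above = env$exceeds_above)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
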