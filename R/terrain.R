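#' Quadrat topography from corner-post elevations
#'
#' Computes the three standard quadrat-level topographic variables from a
#' survey of elevation posts on the 20-m quadrat corners, following the
#' forest-dynamics-plot convention:
#' * mean elevation: mean of the quadrat's four corner posts;
#' * slope: mean tilt angle (degrees) of the four planes through each triple
#'   of corners;
#' * convexity: quadrat mean elevation minus the mean elevation of the eight
#'   neighbouring quadrats. For edge quadrats the convention is centre-point
#'   elevation minus the quadrat's own corner mean; with bilinear
#'   interpolation from corner posts these coincide, so edge quadrats get
#'   convexity 0.
#'
#' @param posts numeric matrix of corner elevations, `(ny+1) x (nx+1)`, with
#'   `posts[i, j]` the post at `x = (j-1) * cell`, `y = (i-1) * cell`.
#' @param cell_size quadrat side, metres (default 20).
#' @return `data.frame` with one row per quadrat: `qx, qy` (1-based column /
#'   row indices), `x0, y0` (lower-left corner), `mean_elev`, `convexity`,
#'   `slope`. Matrices are attached as attributes `elev`, `convexity`,
#'   `slope` (`ny x nx`).
#' @export
quadrat_topography <- function(posts, cell_size = 20) {
  posts <- as.matrix(posts)
  nyp <- nrow(posts); nxp <- ncol(posts)
  if (nyp < 2 || nxp < 2) stop("quadrat_topography: post grid too small")
  ny <- nyp - 1L; nx <- nxp - 1L
  z00 <- posts[1:ny, 1:nx]          # (x, y)
  z10 <- posts[1:ny, 2:(nx + 1)]    # (x+1, y)
  z01 <- posts[2:(ny + 1), 1:nx]    # (x, y+1)
  z11 <- posts[2:(ny + 1), 2:(nx + 1)]
  elev <- (z00 + z10 + z01 + z11) / 4

  # slope: mean tilt of the four corner-triple planes
  L <- cell_size
  tilt <- function(gx, gy) atan(sqrt(gx^2 + gy^2)) * 180 / pi
  s1 <- tilt((z10 - z00) / L, (z01 - z00) / L)  # omit z11
  s2 <- tilt((z11 - z01) / L, (z01 - z00) / L)  # omit z10
  s3 <- tilt((z10 - z00) / L, (z11 - z10) / L)  # omit z01
  s4 <- tilt((z11 - z01) / L, (z11 - z10) / L)  # omit z00
  slope <- (s1 + s2 + s3 + s4) / 4

  # convexity: focal mean elevation minus 8-neighbour mean (interior only)
  conv <- matrix(0, ny, nx)
  if (ny >= 3 && nx >= 3) {
    for (i in 2:(ny - 1)) for (j in 2:(nx - 1)) {
      nb <- elev[(i - 1):(i + 1), (j - 1):(j + 1)]
      conv[i, j] <- elev[i, j] - (sum(nb) - elev[i, j]) / 8
    }
  }

  out <- data.frame(qx = rep(seq_len(nx), each = ny),
                    qy = rep(seq_len(ny), times = nx),
                    x0 = rep((seq_len(nx) - 1) * cell_size, each = ny),
                    y0 = rep((seq_len(ny) - 1) * cell_size, times = nx),
                    mean_elev = as.vector(elev),
                    convexity = as.vector(conv),
                    slope = as.vector(slope))
  attr(out, "elev") <- elev
  attr(out, "convexity") <- conv
  attr(out, "slope") <- slope
  attr(out, "cell_size") <- cell_size
  out
}

#' Seven-class habitat classification of 20-m quadrats
#'
#' Classifies each quadrat by convexity into valley (`convexity < breaks[1]`),
#' slope (`breaks[1] <= convexity < breaks[2]`) or ridge
#' (`convexity >= breaks[2]`), then splits each by elevation into low
#' (`< elevation_break`) and high (`>= elevation_break`). Quadrats in the
#' disturbed mask override all rules. The classification is total: every
#' quadrat receives exactly one of the seven labels.
#'
#' @param topo output of [quadrat_topography()].
#' @param disturbed_mask logical `ny x nx` matrix (or NULL) marking
#'   historically disturbed quadrats.
#' @param convexity_breaks numeric length-2, metres; default `c(-2, 2)`.
#' @param elevation_break metres above sea level; default 450.
#' @return object of class `habitat_map`: list with `labels` (character
#'   `ny x nx` matrix), `cell_size`, `levels`.
#' @export
classify_habitats <- function(topo, disturbed_mask = NULL,
                              convexity_breaks = c(-2, 2),
                              elevation_break = 450) {
  elev <- attr(topo, "elev"); conv <- attr(topo, "convexity")
  cs <- attr(topo, "cell_size")
  ny <- nrow(elev); nx <- ncol(elev)
  base <- matrix("slope", ny, nx)
  base[conv < convexity_breaks[1]] <- "valley"
  base[conv >= convexity_breaks[2]] <- "ridge"
  strat <- ifelse(elev >= elevation_break, "high", "low")
  lab <- matrix(paste(strat, base, sep = "_"), ny, nx)
  if (!is.null(disturbed_mask)) {
    stopifnot(identical(dim(disturbed_mask), dim(lab)))
    lab[disturbed_mask] <- "disturbed"
  }
  structure(list(labels = lab, cell_size = cs,
                 levels = habitat_levels()),
            class = "habitat_map")
}

#' @rdname classify_habitats
#' @export
habitat_levels <- function() {
  c("disturbed", "high_valley", "low_valley", "high_ridge", "low_ridge",
    "high_slope", "low_slope")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("habitat map:", ncol(x$labels), "x", nrow(x$labels), "quadrats of",
      x$cell_size, "m\n")
  print(table(factor(x$labels, levels = x$levels)))
  invisible(x)
}

#' @rdname classify_habitats
#' @param map a `habitat_map`
#' @param x,y point coordinates
#' @export
habitat_at <- function(map, x, y) {
  ix <- floor(x / map$cell_size) + 1L
  iy <- floor(y / map$cell_size) + 1L
  ix <- pmin(pmax(ix, 1L), ncol(map$labels))
  iy <- pmin(pmax(iy, 1L), nrow(map$labels))
  map$labels[cbind(iy, ix)]
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Half the mean squared difference of sample values over point pairs whose
#' separation falls in each lag bin.
#'
#' @param x,y sample coordinates, metres.
#' @param z sample values.
#' @param lag_breaks increasing bin boundaries, metres.
#' @return `data.frame` with `lag` (bin midpoint), `gamma`, `npairs`; empty
#'   bins are reported with `npairs = 0` and `gamma = NA`.
#' @export
empirical_semivariogram <- function(x, y, z, lag_breaks = seq(0, 200, by = 10)) {
  n <- length(z)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 30) warning("semivariogram from fewer than 30 samples")
  d <- as.vector(stats::dist(cbind(x, y)))
  dz2 <- as.vector(stats::dist(z))^2
  bin <- cut(d, lag_breaks, include.lowest = FALSE)
  gamma <- tapply(dz2, bin, function(v) mean(v) / 2)
  np <- tapply(dz2, bin, length)
  np[is.na(np)] <- 0
  mid <- (lag_breaks[-1] + lag_breaks[-length(lag_breaks)]) / 2
  data.frame(lag = mid, gamma = as.numeric(gamma), npairs = as.numeric(np))
}

#' Fit an exponential variogram model by weighted least squares
#'
#' Model `gamma(h) = nugget + psill * (1 - exp(-h / range))`; `range` is the
#' exponential decay distance (effective range about 3x). Weights are the
#' per-bin pair counts; empty bins are excluded.
#'
#' @param emp output of [empirical_semivariogram()].
#' @return list with `nugget`, `psill`, `range`, `converged`.
#' @export
fit_variogram <- function(emp) {
  ok <- emp$npairs > 0 & is.finite(emp$gamma)
  h <- emp$lag[ok]; g <- emp$gamma[ok]; w <- emp$npairs[ok]
  if (length(h) < 3) stop("fit_variogram: fewer than 3 usable lag bins")
  s0 <- max(g); r0 <- max(h) / 3
  obj <- function(p) {
    nug <- exp(p[1]); ps <- exp(p[2]); rg <- exp(p[3])
    sum(w * (nug + ps * (1 - exp(-h / rg)) - g)^2)
  }
  fit <- optim(log(c(s0 * 0.1 + 1e-8, s0 + 1e-8, r0)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  p <- exp(fit$par)
  # keep the system well conditioned: positive sill, range within the
  # observable lag span
  list(nugget = p[1], psill = max(p[2], 1e-10),
       range = min(max(p[3], min(h) / 2), 3 * max(h)),
       converged = fit$convergence == 0)
}

exp_cov <- function(h, vg) vg$psill * exp(-h / vg$range)

#' Ordinary block kriging onto a regular grid
#'
#' Predicts block means on a square-cell grid from scattered samples by
#' ordinary kriging under an exponential variogram, each block approximated
#' by the average of a 2 x 2 sub-point layout. Kriging weights solve the
#' ordinary-kriging system (they sum to 1 for every cell); with zero nugget
#' the predictor interpolates the samples exactly.
#'
#' @param x,y,z sample coordinates and values.
#' @param vg fitted variogram, see [fit_variogram()].
#' @param window a [plot_window()].
#' @param cell_size prediction cell, metres (default 5).
#' @param name label for the output surface.
#' @return a [raster_surface()] of block predictions.
#' @export
krige_block <- function(x, y, z, vg, window, cell_size = 5, name = "kriged") {
  stopifnot(vg$psill > 0)
  n <- length(z)
  D <- as.matrix(stats::dist(cbind(x, y)))
  # ordinary-kriging weights are invariant to scaling the covariance, so the
  # system is solved on the correlation scale for conditioning; the relative
  # nugget (plus a tiny ridge for coincident samples) sits on the diagonal
  rel_nugget <- vg$nugget / vg$psill + 1e-6
  A <- rbind(cbind(exp_cov(D, vg) / vg$psill + diag(rel_nugget, n), 1),
             c(rep(1, n), 0))
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  nx <- round(window$x_extent / cell_size)
  ny <- round(window$y_extent / cell_size)
  cx <- window$origin[1] + (seq_len(nx) - 0.5) * cell_size
  cy <- window$origin[2] + (seq_len(ny) - 0.5) * cell_size
  gx <- rep(cx, each = ny); gy <- rep(cy, times = nx)
  if (is.null(Ainv)) {
    warning("krige_block: singular kriging system; nearest-sample fallback")
    vals <- numeric(nx * ny)
    for (k in seq_along(vals)) {
      d2 <- (x - gx[k])^2 + (y - gy[k])^2
      vals[k] <- z[which.min(d2)]
    }
  } else {
    # prediction = (z, 0)' A^{-1} rhs(cell); precompute the row vector once
    v <- as.vector(crossprod(c(z, 0), Ainv))
    vals <- krige_grid(x, y, v, gx, gy, cell_size / 4, vg$range)
  }
  raster_surface(matrix(vals, nrow = ny, ncol = nx), cell_size,
                 origin = window$origin, name = name)
}

# internal: kriging weights for one target cell (used by tests to verify the
# weights-sum-to-1 invariant)
krige_weights_cell <- function(x, y, vg, cx, cy, cell_size = 5) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  rel_nugget <- vg$nugget / vg$psill + 1e-6
  A <- rbind(cbind(exp_cov(D, vg) / vg$psill + diag(rel_nugget, n), 1),
             c(rep(1, n), 0))
  off <- cell_size / 4
  sub <- cbind(c(-off, off, -off, off), c(-off, -off, off, off))
  c0 <- numeric(n)
  for (q in 1:4)
    c0 <- c0 + exp_cov(sqrt((x - cx - sub[q, 1])^2 +
                            (y - cy - sub[q, 2])^2), vg) / (4 * vg$psill)
  solve(A, c(c0, 1))[1:n]
}

#' Principal components of an environmental surface stack
#'
#' Standardizes each surface to zero mean and unit variance over grid cells,
#' then rotates to orthogonal components ordered by explained variance.
#' Constant surfaces are dropped with a warning before rotation. Component
#' score fields are pairwise uncorrelated and total standardized variance is
#' conserved.
#'
#' @param surfaces named list of aligned [raster_surface()] objects
#'   (conventionally elevation, convexity, slope, total C, total N, total P,
#'   pH at 5-m resolution).
#' @return object of class `env_stack`: list with `scores` (list of component
#'   [raster_surface()]s named `PC1..PCk`), `loadings`, `sdev`,
#'   `explained` (variance shares), `center`, `scale`, `input_names`,
#'   `cell_size`, `window`.
#' @export
pca_environment <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  cs <- surfaces[[1]]$cell_size
  dm <- dim(surfaces[[1]]$values)
  for (s in surfaces)
    if (!identical(dim(s$values), dm) || s$cell_size != cs)
      stop("pca_environment: surfaces not aligned on the same grid")
  X <- sapply(surfaces, function(s) as.vector(s$values))
  if (is.null(colnames(X)) || any(colnames(X) == ""))
    colnames(X) <- if (!is.null(names(surfaces))) names(surfaces) else
      paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("pca_environment: dropping constant variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  scores <- lapply(seq_len(ncol(pc$x)), function(k)
    raster_surface(matrix(pc$x[, k], nrow = dm[1], ncol = dm[2]),
                   cs, origin = surfaces[[1]]$origin,
                   name = paste0("PC", k)))
  names(scores) <- paste0("PC", seq_along(scores))
  structure(list(scores = scores, loadings = pc$rotation, sdev = pc$sdev,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center, scale = pc$scale,
                 input_names = colnames(X), cell_size = cs,
                 window = surface_window(surfaces[[1]])),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("environment stack: %d components on %g-m grid\n",
              length(x$scores), x$cell_size))
  cat("explained variance shares:",
      paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  invisible(x)
}
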