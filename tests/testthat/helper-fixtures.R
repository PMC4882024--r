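# Shared fixtures, all built in code.

# small analytic environment stack: k standardized component-like surfaces
# on an nx x ny grid of 5-m cells (window nx*5 x ny*5 m)
tiny_env <- function(nx = 40, ny = 40, k = 3, cell = 5, seed = 99) {
  set.seed(seed)
  xs <- (seq_len(nx) - 0.5) * cell
  ys <- (seq_len(ny) - 0.5) * cell
  fns <- list(
    function(y, x) sin(x / 40) + 0.3 * cos(y / 25),
    function(y, x) cos((x + y) / 60),
    function(y, x) (x - mean(xs)) * (y - mean(ys)) / (max(xs) * max(ys)),
    function(y, x) sin(y / 30),
    function(y, x) cos(x / 55) - sin(y / 45)
  )
  surfs <- lapply(seq_len(k), function(i) {
    base <- outer(ys, xs, fns[[((i - 1) %% length(fns)) + 1]])
    raster_surface(base + matrix(rnorm(nx * ny, 0, 0.15), ny, nx), cell,
                   name = paste0("v", i))
  })
  names(surfs) <- paste0("v", seq_len(k))
  pca_environment(surfs)
}

# simple 2 x 2-habitat map splitting a square window into quadrants
quadrant_habitat_map <- function(side_quadrats = 10, cell = 20) {
  half <- side_quadrats / 2
  lab <- matrix("low_slope", side_quadrats, side_quadrats)
  lab[1:half, 1:half] <- "low_valley"
  lab[1:half, (half + 1):side_quadrats] <- "low_ridge"
  lab[(half + 1):side_quadrats, 1:half] <- "high_valley"
  structure(list(labels = lab, cell_size = cell, levels = habitat_levels()),
            class = "habitat_map")
}

# hard-core pattern: Matern II dependent thinning (uniform marks, a point
# survives iff no point with a smaller mark lies within the spacing). This
# process is purely inhibitory, g(r) <= 1 at every distance -- unlike a
# jittered lattice (pcf peaks at lattice distances) or sequential packing
# (contact peak at the spacing), which would legitimately be flagged as
# clustered at some scale.
hardcore_pattern <- function(window, spacing = 5, seed = 1) {
  set.seed(seed)
  A <- window_area(window)
  n0 <- rpois(1, 3 / (pi * spacing^2) * A)
  xr <- stagepp:::xrange(window); yr <- stagepp:::yrange(window)
  x <- runif(n0, xr[1], xr[2] - 1e-9)
  y <- runif(n0, yr[1], yr[2] - 1e-9)
  mark <- runif(n0)
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  keep <- vapply(seq_len(n0), function(i) {
    close <- d2[i, ] < spacing^2
    close[i] <- FALSE
    !any(mark[close] < mark[i])
  }, logical(1))
  point_pattern(x[keep], y[keep], window)
}

# brute-force K oracle (no correction), independent of the package kernels
brute_K <- function(x, y, r, area) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  vapply(r, function(rr) area * sum(d <= rr) / (n * (n - 1)), numeric(1))
}
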