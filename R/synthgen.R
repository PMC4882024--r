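# Synthetic forest-plot generator: terrain, soils, habitat structure and
# multi-species multi-stage stem tables with a ground-truth ledger, so every
# downstream analysis can be tested against known parameters.

#' Generate synthetic terrain
#'
#' A smooth random surface built from superposed Gaussian bumps, rescaled so
#' the elevation range over the corner posts equals `relief`, sitting on
#' `base_elev`. The defaults emulate a 500 x 400 m plot with about 300 m of
#' relief. Returns both the 20-m corner-post grid that the topography module
#' consumes and generator-side truth: the analytic elevation function, a 5-m
#' elevation surface, and quadrat-scale true slope (from the analytic
#' gradient) and true convexity (centre elevation minus the 8 neighbouring
#' centre elevations) for oracle checks.
#'
#' @param window a [plot_window()].
#' @param relief target max - min elevation over the posts, metres.
#' @param base_elev elevation of the lowest post, metres a.s.l.
#' @param n_broad,broad_scale count and sd range (m) of the large hills
#'   carrying the main elevation gradient.
#' @param n_bumps,bump_scale count and sd range (m) of the fine relief
#'   features that generate ridge/valley convexity structure.
#' @param fine_frac amplitude of the fine relief relative to the broad
#'   relief (sd ratio).
#' @param seed integer seed.
#' @param post_spacing corner-post spacing, metres (default 20).
#' @return list with `posts` ((ny+1) x (nx+1) matrix), `zfun(x, y)`,
#'   `elev5` (5-m [raster_surface()]), `true_slope`, `true_convexity`
#'   (ny x nx quadrat matrices), `window`, `post_spacing`.
#' @export
make_terrain <- function(window = plot_window(), relief = 300,
                         base_elev = 304, n_broad = 3,
                         broad_scale = c(160, 280), n_bumps = 16,
                         bump_scale = c(30, 60), fine_frac = 0.30,
                         seed = 1, post_spacing = 20) {
  set.seed(seed)
  xr <- xrange(window); yr <- yrange(window)
  nb <- n_broad + n_bumps
  cx <- runif(nb, xr[1] - 50, xr[2] + 50)
  cy <- runif(nb, yr[1] - 50, yr[2] + 50)
  s <- c(runif(n_broad, broad_scale[1], broad_scale[2]),
         runif(n_bumps, bump_scale[1], bump_scale[2]))
  a <- runif(nb, -1, 1)
  bump_part <- function(x, y, idx, amp) {
    z <- 0
    for (k in idx)
      z <- z + amp[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) / (2 * s[k]^2))
    z
  }
  # normalize the two components on the post grid so the fine relief has a
  # fixed amplitude share, then treat the sum as one bump list
  pgx <- rep(xr[1] + (0:round(window$x_extent / post_spacing)) * post_spacing,
             each = round(window$y_extent / post_spacing) + 1)
  pgy <- rep(yr[1] + (0:round(window$y_extent / post_spacing)) * post_spacing,
             times = round(window$x_extent / post_spacing) + 1)
  idx_b <- seq_len(n_broad); idx_f <- n_broad + seq_len(n_bumps)
  sd_b <- sd(bump_part(pgx, pgy, idx_b, a))
  sd_f <- sd(bump_part(pgx, pgy, idx_f, a))
  if (relief > 0 && n_broad > 0 && sd_b > 0) a[idx_b] <- a[idx_b] / sd_b
  if (relief > 0 && n_bumps > 0 && sd_f > 0)
    a[idx_f] <- a[idx_f] * fine_frac / sd_f
  n_bumps <- nb
  raw <- function(x, y) bump_part(x, y, seq_len(nb), a)
  nx <- round(window$x_extent / post_spacing)
  ny <- round(window$y_extent / post_spacing)
  px <- xr[1] + (0:nx) * post_spacing
  py <- yr[1] + (0:ny) * post_spacing
  praw <- outer(py, px, function(y, x) raw(x, y))  # rows = y
  lo <- min(praw); hi <- max(praw)
  scale_f <- if (hi > lo && relief > 0) relief / (hi - lo) else 0
  zfun <- function(x, y) base_elev + (raw(x, y) - lo) * scale_f
  posts <- base_elev + (praw - lo) * scale_f

  # analytic gradient for true slope at quadrat centres
  gradfun <- function(x, y) {
    gx <- 0; gy <- 0
    for (k in seq_len(n_bumps)) {
      e <- a[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) / (2 * s[k]^2))
      gx <- gx - e * (x - cx[k]) / s[k]^2
      gy <- gy - e * (y - cy[k]) / s[k]^2
    }
    cbind(gx * scale_f, gy * scale_f)
  }
  qcx <- xr[1] + (seq_len(nx) - 0.5) * post_spacing
  qcy <- yr[1] + (seq_len(ny) - 0.5) * post_spacing
  gc <- gradfun(rep(qcx, each = ny), rep(qcy, times = nx))
  true_slope <- matrix(atan(sqrt(gc[, 1]^2 + gc[, 2]^2)) * 180 / pi, ny, nx)
  zc <- matrix(zfun(rep(qcx, each = ny), rep(qcy, times = nx)), ny, nx)
  true_conv <- matrix(0, ny, nx)
  if (ny >= 3 && nx >= 3)
    for (i in 2:(ny - 1)) for (j in 2:(nx - 1))
      true_conv[i, j] <- zc[i, j] - (sum(zc[(i-1):(i+1), (j-1):(j+1)]) - zc[i, j]) / 8

  n5x <- round(window$x_extent / 5); n5y <- round(window$y_extent / 5)
  e5x <- xr[1] + (seq_len(n5x) - 0.5) * 5
  e5y <- yr[1] + (seq_len(n5y) - 0.5) * 5
  g5x <- rep(e5x, each = n5y); g5y <- rep(e5y, times = n5x)
  elev5 <- raster_surface(matrix(zfun(g5x, g5y), n5y, n5x),
                          5, origin = window$origin, name = "elev")
  # fine-scale convexity truth at 5 m: local height relative to the mean of
  # the four points one quadrat-width away (valley < 0 < ridge)
  c5 <- zfun(g5x, g5y) -
    (zfun(g5x + post_spacing, g5y) + zfun(g5x - post_spacing, g5y) +
     zfun(g5x, g5y + post_spacing) + zfun(g5x, g5y - post_spacing)) / 4
  conv5 <- raster_surface(matrix(c5, n5y, n5x), 5, origin = window$origin,
                          name = "convexity")
  list(posts = posts, zfun = zfun, elev5 = elev5, conv5 = conv5,
       true_slope = true_slope, true_convexity = true_conv, window = window,
       post_spacing = post_spacing)
}

#' Generate synthetic soil samples
#'
#' Four soil fields (total C, total N, total P, pH) built as stated linear
#' combinations of standardized elevation and an independent smooth Gaussian
#' noise field, sampled at a mixed regular (20-m grid) plus random design of
#' about `n_samples` locations with nugget measurement noise. pH is mapped
#' into the realistic 4.4-5.1 range of strongly acidic forest soils; C, N
#' and P get conventional g/kg magnitudes.
#'
#' @param terrain output of [make_terrain()].
#' @param n_samples total sample count (default 1292, the density of a
#'   high-resolution 20-ha soil survey).
#' @param correlations named numeric, target correlation of each variable
#'   with elevation (absolute value <= 1).
#' @param nugget sd of the measurement noise on the standardized scale.
#' @param seed integer seed.
#' @return list with `samples` (data.frame `x, y, totalC, totalN, totalP,
#'   pH`) and `true_fields` (named list of 5-m [raster_surface()]s).
#' @export
make_soils <- function(terrain, n_samples = 1292,
                       correlations = c(totalC = 0.7, totalN = 0.6,
                                        totalP = 0.5, pH = -0.5),
                       nugget = 0.2, seed = 2) {
  stopifnot(all(abs(correlations) <= 1))
  set.seed(seed)
  w <- terrain$window
  elev <- terrain$elev5
  ez <- as.vector(elev$values)
  ez <- if (sd(ez) > 0) (ez - mean(ez)) / sd(ez) else ez * 0
  ranges <- list(totalC = c(10, 50), totalN = c(1, 4),
                 totalP = c(0.2, 0.8), pH = c(4.4, 5.1))
  fields <- list()
  for (v in names(correlations)) {
    noise <- simulate_gaussian_field(w, 5, matern_params(1, 60, 1))
    nz <- as.vector(noise$values)
    nz <- (nz - mean(nz)) / sd(nz)
    rho <- correlations[[v]]
    f <- rho * ez + sqrt(1 - rho^2) * nz
    rg <- ranges[[v]]
    # map field into the variable's realistic range
    f01 <- (f - min(f)) / max(max(f) - min(f), 1e-12)
    fields[[v]] <- raster_surface(matrix(rg[1] + f01 * (rg[2] - rg[1]),
                                         nrow(elev$values)),
                                  5, origin = w$origin, name = v)
  }
  # mixed design: regular 20-m grid plus random fill
  xr <- xrange(w); yr <- yrange(w)
  gx <- seq(xr[1] + 10, xr[2] - 10, by = 20)
  gy <- seq(yr[1] + 10, yr[2] - 10, by = 20)
  reg <- expand.grid(x = gx, y = gy)
  n_rand <- max(0, n_samples - nrow(reg))
  sx <- c(reg$x, runif(n_rand, xr[1], xr[2] - 1e-9))
  sy <- c(reg$y, runif(n_rand, yr[1], yr[2] - 1e-9))
  samples <- data.frame(x = sx, y = sy)
  for (v in names(fields)) {
    val <- surface_value_at(fields[[v]], sx, sy)
    rgspan <- diff(ranges[[v]])
    val <- val + rnorm(length(val), 0, nugget * rgspan / 4)
    val <- pmin(pmax(val, ranges[[v]][1]), ranges[[v]][2])
    samples[[v]] <- val
  }
  list(samples = samples, true_fields = fields)
}

#' Life-stage DBH intervals per growth form
#'
#' Half-open DBH intervals (cm) assigning stems to sapling, juvenile and
#' adult stages: canopy trees `[1, 5) [5, 15) [15, Inf)`, sub-canopy trees
#' `[1, 2.5) [2.5, 5) [5, Inf)`, shrubs `[1, 1.5) [1.5, 2.5) [2.5, Inf)`.
#'
#' @return named list of numeric break vectors `c(1, b1, b2, Inf)`.
#' @export
life_stage_scheme <- function() {
  list(canopy = c(1, 5, 15, Inf),
       subcanopy = c(1, 2.5, 5, Inf),
       shrub = c(1, 1.5, 2.5, Inf))
}

stage_names <- function() c("sapling", "juvenile", "adult")

draw_dbh <- function(n, gf, stage, scheme = life_stage_scheme()) {
  br <- scheme[[gf]]
  k <- match(stage, stage_names())
  lo <- br[k]; hi <- br[k + 1]
  if (!is.finite(hi)) hi <- 2.5 * lo  # open adult class: bounded draw
  lo + runif(n) * (hi - lo) * 0.999999
}

#' Species configuration for the generator
#'
#' Per-stage generative parameters of one synthetic species. The mechanism
#' is either `"cox"` (log-Gaussian residual with Matern covariance) or
#' `"thomas"` (Poisson cluster process thinned by the environmental
#' surface). True PVE per stage is derived from the realized covariate
#' surfaces on the log-intensity scale; for the Thomas mechanism the
#' residual variance is the log-Gaussian equivalent
#' `log(1 + 1 / (4 pi kappa sigma^2)) = log g(0)`.
#'
#' @param code species code.
#' @param growth_form one of `"canopy"`, `"subcanopy"`, `"shrub"`.
#' @param syndrome one of `"gravity_ballistic"`, `"animal"`, `"wind"`.
#' @param abundance numeric length-3, expected stems per stage.
#' @param beta list of 3 coefficient vectors (one per stage) on the true
#'   covariate surfaces.
#' @param mechanism `"cox"` or `"thomas"`.
#' @param residual list of 3 [matern_params()] (cox) or [thomas_params()]
#'   (thomas), one per stage.
#' @return object of class `species_config`.
#' @export
species_config <- function(code, growth_form, syndrome, abundance, beta,
                           mechanism = c("cox", "thomas"), residual) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(abundance) == 3, length(beta) == 3, length(residual) == 3)
  structure(list(code = code, growth_form = growth_form,
                 syndrome = syndrome, abundance = abundance, beta = beta,
                 mechanism = mechanism, residual = residual),
            class = "species_config")
}

# standardized covariate matrix (cells x q) from a list of truth surfaces
covariate_cells <- function(covs) {
  X <- sapply(covs, function(s) as.vector(s$values))
  scale(X)
}

residual_variance_of <- function(resid) {
  if (inherits(resid, "matern_params")) resid$variance
  else log(1 + 1 / (4 * pi * resid$kappa * resid$sigma^2))
}

#' Generate one species-stage point pattern
#'
#' Realizes `log intensity = mu + H(u) beta (+ D(u))` where `H` are the
#' standardized truth covariates, the residual is a Matern field (cox
#' mechanism) or Thomas clustering realized by thinning a homogeneous
#' Thomas pattern with retention proportional to `exp(H beta)` (thomas
#' mechanism). `mu` is set so the expected count equals the configured
#' stage abundance. DBH marks are drawn uniformly inside the stage's
#' interval for the species' growth form.
#'
#' @param config a [species_config()].
#' @param stage `"sapling"`, `"juvenile"` or `"adult"`.
#' @param covs named list of truth covariate [raster_surface()]s (5 m).
#' @param window a [plot_window()].
#' @param seed integer seed.
#' @return list with `pattern` (a [point_pattern()]), `dbh`, `true_pve`,
#'   `v_env`, `v_resid`.
#' @export
make_species_pattern <- function(config, stage, covs, window, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- match(stage, stage_names())
  beta <- config$beta[[k]]
  A <- config$abundance[k]
  resid <- config$residual[[k]]
  s1 <- covs[[1]]
  X <- covariate_cells(covs)
  eta_env <- as.vector(X[, seq_along(beta), drop = FALSE] %*% beta)
  v_env <- var(eta_env)
  v_res <- residual_variance_of(resid)
  cellarea <- s1$cell_size^2
  env_mat <- matrix(eta_env, nrow(s1$values))
  if (config$mechanism == "cox") {
    D <- simulate_gaussian_field(window, s1$cell_size, resid)
    eta <- env_mat + D$values - resid$variance / 2
    # intercept: expected count = A given this residual draw convention
    mu <- log(A) - log(sum(exp(env_mat) ) * cellarea)
    lam <- raster_surface(exp(mu + eta), s1$cell_size, origin = s1$origin,
                          name = config$code)
    pat <- simulate_ipp(lam)
  } else {
    p_keep <- exp(env_mat); p_keep <- p_keep / max(p_keep)
    lam0 <- A / (window_area(window) * mean(p_keep))
    # keep the configured kappa (it encodes the residual clustering
    # strength); the offspring mean absorbs the abundance target
    tp <- thomas_params(resid$kappa, resid$sigma, lam0 / resid$kappa)
    base <- simulate_thomas(tp, window)
    keep <- runif(n_points(base)) <
      surface_value_at(raster_surface(p_keep, s1$cell_size,
                                      origin = s1$origin),
                       base$x, base$y)
    pat <- point_pattern(base$x[keep], base$y[keep], window)
  }
  dbh <- draw_dbh(n_points(pat), config$growth_form, stage)
  list(pattern = pat, dbh = dbh,
       true_pve = if (v_env + v_res > 0) v_env / (v_env + v_res) else NA_real_,
       v_env = v_env, v_resid = v_res)
}

#' Generate a complete synthetic community bundle
#'
#' Builds terrain, soils, a disturbed-quadrat mask (north-east corner), and
#' a multi-species, multi-stage stem table with a truth ledger. Species
#' patterns are inhomogeneous Thomas processes (environment-thinned Poisson
#' cluster): under the default trends the environmental coefficients scale
#' up and the residual clustering variance (on the log-Gaussian-equivalent
#' scale `log(1 + 1/(4 pi kappa sigma^2))`) scales down from sapling to
#' adult via the parent intensity; wind-dispersed species get a larger
#' cluster size sigma and steeper stage-wise coefficient growth than
#' animal- or gravity-dispersed species.
#'
#' @param n_species number of species (>= 2; default 12).
#' @param stage_trend list with logical flags `env_increasing` and
#'   `cluster_decreasing`; both `FALSE` makes stages exchangeable (negative
#'   control).
#' @param syndrome_mix named integer vector over
#'   `animal, wind, gravity_ballistic` summing to `n_species`.
#' @param abundance_range per-stage expected abundance range; drawn
#'   log-uniformly per species (default 150-2000).
#' @param seed master seed; regeneration with the same arguments is
#'   bit-identical.
#' @param window a [plot_window()].
#' @return object of class `synthetic_bundle`: `terrain`, `soils`,
#'   `disturbed_mask`, `covariates` (truth surfaces used by the generator),
#'   `stems` (stem data.frame), `syndromes`, `truth` (per species:
#'   config and per-stage true PVE and counts), `window`, `seed`.
#' @export
make_community <- function(n_species = 12,
                           stage_trend = list(env_increasing = TRUE,
                                              cluster_decreasing = TRUE),
                           syndrome_mix = c(animal = 8, wind = 2,
                                            gravity_ballistic = 2),
                           abundance_range = c(150, 2000),
                           seed = 1, window = plot_window()) {
  stopifnot(n_species >= 2, sum(syndrome_mix) == n_species)
  set.seed(seed)
  terrain <- make_terrain(window, seed = seed)
  soils <- make_soils(terrain, seed = seed + 1)
  # truth covariates: the two topographic drivers of the habitat scheme
  # (broad elevation, fine convexity) plus one soil axis
  covs <- list(elev = terrain$elev5,
               conv = terrain$conv5,
               soilA = soils$true_fields$totalC)
  ny <- nrow(terrain$posts) - 1; nx <- ncol(terrain$posts) - 1
  mask <- matrix(FALSE, ny, nx)
  mask[(ny - 3):ny, (nx - 4):nx] <- TRUE  # north-east corner, ~80 x 100 m

  # habitat-class indicator surfaces (5 m) for species' class preferences.
  # Specialists concentrate in distinctive minority habitats (valleys,
  # ridges): a preference for a majority class barely shifts its relative
  # density, so eligibility is capped at a 5-30% plot share (falling back
  # to the smallest class above 5% if none qualifies).
  hab_truth <- classify_habitats(quadrat_topography(terrain$posts))
  n5x <- round(window$x_extent / 5); n5y <- round(window$y_extent / 5)
  g5x <- rep(window$origin[1] + (seq_len(n5x) - 0.5) * 5, each = n5y)
  g5y <- rep(window$origin[2] + (seq_len(n5y) - 0.5) * 5, times = n5x)
  lab5 <- habitat_at(hab_truth, g5x, g5y)
  shares <- table(lab5) / length(lab5)
  eligible <- names(shares)[shares >= 0.05 & shares <= 0.30]
  if (length(eligible) == 0)
    eligible <- names(shares)[which.min(ifelse(shares >= 0.05, shares, Inf))]
  pref_ind <- lapply(eligible, function(cl)
    raster_surface(matrix(as.numeric(lab5 == cl), n5y, n5x), 5,
                   origin = window$origin, name = paste0("pref_", cl)))
  names(pref_ind) <- eligible

  syndromes <- rep(names(syndrome_mix), times = syndrome_mix)
  gf_cycle <- rep(c("canopy", "subcanopy", "shrub"), length.out = n_species)
  clu_f <- if (isTRUE(stage_trend$cluster_decreasing)) c(1.6, 1.0, 0.45)
           else c(1, 1, 1)
  Xcov <- covariate_cells(covs)
  configs <- list(); stems <- list(); truth <- list()
  for (i in seq_len(n_species)) {
    code <- sprintf("SP%02d", i)
    syn <- syndromes[i]
    # random direction in covariate space; magnitude set per stage from a
    # true-PVE target so the community means emulate the field-typical
    # 0.2 (sapling) to 0.4 (adult) range
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    vu <- var(as.vector(Xcov %*% u))
    if (isTRUE(stage_trend$env_increasing)) {
      # habitat-class preference sharpens with stage (density multiplier
      # inside the preferred class) and the smooth response strengthens;
      # wind-dispersed species get the steepest late-stage growth
      m_adult <- if (syn == "wind") runif(1, 2.8, 4.2) else runif(1, 2.3, 3.5)
      m_pref <- c(runif(1, 1.05, 1.35), runif(1, 1.5, 2.1), m_adult)
      v_smooth <- c(runif(1, 0.04, 0.12), runif(1, 0.12, 0.25),
                    runif(1, 0.20, 0.35))
    } else {
      m_pref <- rep(runif(1, 1.4, 1.9), 3)
      v_smooth <- rep(runif(1, 0.10, 0.20), 3)
    }
    pref <- sample(names(pref_ind), 1)
    ind_cells <- as.vector(pref_ind[[pref]]$values)
    s2_0 <- runif(1, 0.6, 1.1)         # sapling-stage residual log-variance
    sig <- if (syn == "wind") runif(1, 14, 25) else runif(1, 6, 12)
    v_res <- s2_0 * clu_f
    beta <- lapply(1:3, function(k)
      c(u * sqrt(v_smooth[k] / vu), log(m_pref[k]) * sd(ind_cells)))
    residual <- lapply(1:3, function(k) {
      # parent intensity hitting the target residual variance at this sigma
      thomas_params(1 / (4 * pi * sig^2 * (exp(v_res[k]) - 1)), sig, 1)
    })
    ab <- exp(runif(3, log(abundance_range[1]), log(abundance_range[2])))
    # keep per-species abundance comparable across stages
    ab <- rep(exp(mean(log(ab))), 3)
    cfg <- species_config(code, gf_cycle[i], syn, ab, beta,
                          mechanism = "thomas", residual = residual)
    cfg$preferred_habitat <- pref
    cfg$pref_multiplier <- m_pref
    configs[[code]] <- cfg
    covs_sp <- c(covs, pref_ind[pref])
    sp_seed <- (seed * 1000L + i * 101L) %% .Machine$integer.max
    pves <- numeric(3); counts <- integer(3)
    for (k in 1:3) {
      st <- stage_names()[k]
      real <- make_species_pattern(cfg, st, covs_sp, window,
                                   seed = (sp_seed + k * 7L) %%
                                     .Machine$integer.max)
      np <- n_points(real$pattern)
      pves[k] <- real$true_pve; counts[k] <- np
      if (np > 0)
        stems[[length(stems) + 1]] <- data.frame(
          tag = sprintf("%s_%s_%04d", code, st, seq_len(np)),
          sp = code, gf = cfg$growth_form,
          gx = real$pattern$x, gy = real$pattern$y, dbh = real$dbh)
    }
    truth[[code]] <- list(config = cfg, true_pve = setNames(pves, stage_names()),
                          counts = setNames(counts, stage_names()),
                          seed = sp_seed)
  }
  stems <- do.call(rbind, stems)
  structure(list(terrain = terrain, soils = soils, disturbed_mask = mask,
                 covariates = covs, stems = stems,
                 syndromes = setNames(syndromes, names(configs)),
                 truth = truth, window = window, seed = seed),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("synthetic plot bundle: %d species, %d stems, seed %d\n",
              length(x$truth), nrow(x$stems), x$seed))
  invisible(x)
}

#' Write a synthetic bundle to disk in pipeline input formats
#'
#' @param bundle a `synthetic_bundle`.
#' @param path output directory.
#' @return invisible vector of files written.
#' @export
write_bundle <- function(bundle, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  f_stems <- file.path(path, "stems.tsv")
  write_stem_table(bundle$stems, f_stems)
  f_posts <- file.path(path, "elevation_posts.asc")
  write_ascii_grid(raster_surface(bundle$terrain$posts,
                                  bundle$terrain$post_spacing,
                                  origin = bundle$window$origin,
                                  name = "posts"), f_posts)
  f_soil <- file.path(path, "soil_samples.tsv")
  write.table(bundle$soils$samples, f_soil, sep = "\t", row.names = FALSE,
              quote = FALSE)
  f_mask <- file.path(path, "disturbed_mask.tsv")
  write.table(which(bundle$disturbed_mask, arr.ind = TRUE), f_mask,
              sep = "\t", row.names = FALSE, quote = FALSE)
  f_syn <- file.path(path, "syndromes.tsv")
  write.table(data.frame(sp = names(bundle$syndromes),
                         syndrome = unname(bundle$syndromes)),
              f_syn, sep = "\t", row.names = FALSE, quote = FALSE)
  f_truth <- file.path(path, "truth.json")
  truth <- lapply(bundle$truth, function(t)
    list(true_pve = as.list(t$true_pve), counts = as.list(t$counts),
         syndrome = t$config$syndrome, mechanism = t$config$mechanism,
         seed = t$seed))
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(f_stems, f_posts, f_soil, f_mask, f_syn, f_truth))
}
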