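test_that("synthetic terrain honours relief, flatness and determinism", {
  t1 <- make_terrain(seed = 61)
  t2 <- make_terrain(seed = 61)
  expect_identical(t1$posts, t2$posts)
  expect_lt(abs(diff(range(t1$posts)) - 300), 3)  # within 1% of 300

  flat <- make_terrain(relief = 0, seed = 62)
  expect_equal(diff(range(flat$posts)), 0)
  topo <- quadrat_topography(flat$posts)
  expect_equal(max(abs(topo$slope)), 0)
  expect_equal(max(abs(topo$convexity)), 0)
  expect_equal(max(abs(flat$true_slope)), 0)

  t3 <- make_terrain(relief = 120, seed = 61)
  expect_lt(abs(diff(range(t3$posts)) - 120), 1.2)
})

test_that("synthetic soils have realistic pH and stated correlations", {
  terr <- make_terrain(seed = 63)
  soils <- make_soils(terr, seed = 64)
  expect_true(all(soils$samples$pH >= 4.4 & soils$samples$pH <= 5.1))
  expect_gte(nrow(soils$samples), 1292)

  # correlation 1, no nugget: soil field is an affine map of elevation
  s1 <- make_soils(terr, correlations = c(totalC = 1, totalN = 0.5,
                                          totalP = 0.5, pH = -0.5),
                   nugget = 0, seed = 65)
  ez <- surface_value_at(terr$elev5, s1$samples$x, s1$samples$y)
  expect_gt(cor(s1$samples$totalC, ez), 0.999)

  # correlation 0: sample correlation small on average over replicates
  cors <- vapply(1:6, function(i) {
    s0 <- make_soils(terr, correlations = c(totalC = 0, totalN = 0.5,
                                            totalP = 0.5, pH = -0.5),
                     nugget = 0, seed = 70 + i)
    cor(s0$samples$totalC, ez)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.2)
})

test_that("species patterns realize their configured world", {
  terr <- make_terrain(seed = 66)
  soils <- make_soils(terr, seed = 67)
  covs <- list(elev = terr$elev5, soilA = soils$true_fields$totalC,
               soilB = soils$true_fields$pH)
  w <- plot_window()
  cfg0 <- species_config("S1", "canopy", "animal", rep(300, 3),
                         beta = rep(list(c(0, 0, 0)), 3),
                         mechanism = "thomas",
                         residual = rep(list(thomas_params(4e-4, 8, 1)), 3))
  # zero coefficients: habitat-independent pattern, PVE truth 0
  real <- make_species_pattern(cfg0, "sapling", covs, w, seed = 68)
  expect_equal(real$true_pve, 0)
  expect_equal(length(real$dbh), n_points(real$pattern))
  expect_true(all(real$dbh >= 1 & real$dbh < 5))  # canopy sapling interval

  # realized counts match the expected abundance over seeds (3 SE)
  counts <- vapply(1:30, function(i)
    n_points(make_species_pattern(cfg0, "juvenile", covs, w,
                                  seed = 100 + i)$pattern), numeric(1))
  expect_lt(abs(mean(counts) - 300), 3 * sd(counts) / sqrt(30))
})

test_that("a strong valley-loading coefficient concentrates points in valleys", {
  terr <- make_terrain(seed = 69)
  topo <- quadrat_topography(terr$posts)
  hab <- classify_habitats(topo)
  # covariate: valley indicator at 5 m (smoothed truth surface)
  xs <- (1:100 - 0.5) * 5; ys <- (1:80 - 0.5) * 5
  val <- outer(ys, xs, function(y, x)
    as.numeric(habitat_at(hab, x, y) %in% c("low_valley", "high_valley")))
  covs <- list(valley = raster_surface(val, 5, name = "valley"),
               dummy = terr$elev5)
  cfg <- species_config("S2", "canopy", "animal", rep(600, 3),
                        beta = rep(list(c(4, 0)), 3),
                        mechanism = "thomas",
                        residual = rep(list(thomas_params(1e-3, 6, 1)), 3))
  real <- make_species_pattern(cfg, "adult", covs, plot_window(), seed = 70)
  lab <- habitat_at(hab, real$pattern$x, real$pattern$y)
  expect_gte(mean(lab %in% c("low_valley", "high_valley")), 0.7)
})

test_that("community bundles are deterministic with a faithful truth ledger", {
  mix <- c(animal = 2, wind = 1, gravity_ballistic = 1)
  b1 <- make_community(n_species = 4, syndrome_mix = mix,
                       abundance_range = c(120, 300), seed = 71)
  b2 <- make_community(n_species = 4, syndrome_mix = mix,
                       abundance_range = c(120, 300), seed = 71)
  expect_identical(b1$stems, b2$stems)

  # default trends: per-species true PVE strictly increases with stage
  for (tr in b1$truth)
    expect_true(all(diff(tr$true_pve) > 0))

  # negative control: stages exchangeable, true PVE flat
  b0 <- make_community(n_species = 4, syndrome_mix = mix,
                       stage_trend = list(env_increasing = FALSE,
                                          cluster_decreasing = FALSE),
                       abundance_range = c(120, 300), seed = 72)
  for (tr in b0$truth)
    expect_equal(unname(diff(tr$true_pve)), c(0, 0), tolerance = 1e-12)

  # generator output passes the stem-table validation untouched
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stem_table(b1$stems, f)
  st <- read_stem_table(f, b1$window)
  expect_equal(nrow(attr(st, "rejected")), 0)
  expect_equal(nrow(st), nrow(b1$stems))

  # bundle writer produces readable artefacts
  dir <- withr::local_tempdir()
  write_bundle(b1, dir)
  posts <- read_ascii_grid(file.path(dir, "elevation_posts.asc"))
  expect_equal(posts$values, b1$terrain$posts, tolerance = 1e-8)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth), 4)
})
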