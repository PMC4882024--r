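test_that("stem table reader validates rows and round-trips", {
  w <- plot_window(500, 400)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag,sp,gf,gx,gy,dbh",
               "t1,SPA,canopy,10.5,20.25,12.0",
               "t2,SPA,shrub,499.99,399.99,1.0",
               "t3,SPB,subcanopy,0,0,3.3"), f)
  st <- read_stem_table(f, w)
  expect_equal(nrow(st), 3)
  expect_equal(nrow(attr(st, "rejected")), 0)
  expect_equal(st$gx, c(10.5, 499.99, 0))

  # round trip through the writer is lossless for valid rows
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_stem_table(st, f2)
  st2 <- read_stem_table(f2, w)
  expect_equal(st2$gx, st$gx)
  expect_equal(st2$dbh, st$dbh)
  expect_equal(st2$sp, st$sp)
})

test_that("stem rows below the DBH census threshold or outside the window drop", {
  w <- plot_window(500, 400)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag,sp,gf,gx,gy,dbh",
               "t1,SPA,canopy,10,20,12.0",
               "t2,SPA,canopy,11,21,0.5",
               "t3,SPA,canopy,12,22,2.0"), f)
  expect_message(st <- read_stem_table(f, w), "dropped 1")
  expect_equal(nrow(st), 2)
  expect_match(attr(st, "rejected")$reason, "dbh below 1 cm")

  writeLines(c("tag,sp,gf,gx,gy,dbh",
               "t1,SPA,canopy,501,20,12.0",
               "t2,SPA,canopy,11,400,5.0",  # y on the upper boundary: outside
               "t3,SPA,canopy,12,22,2.0"), f)
  st <- suppressMessages(read_stem_table(f, w))
  expect_equal(nrow(st), 1)
  expect_equal(attr(st, "rejected")$line, c(2L, 3L))

  writeLines(c("tag,sp,gf,gx,gy,dbh",
               "t1,SPA,canopy,abc,20,12.0",
               "t3,SPA,canopy,12,22,2.0"), f)
  st <- suppressMessages(read_stem_table(f, w))
  expect_equal(attr(st, "rejected")$reason, "non-numeric coordinate")
  expect_equal(attr(st, "rejected")$line, 2L)

  writeLines(c("tag,sp,gx,gy,dbh", "t1,SPA,10,20,12.0"), f)
  expect_error(read_stem_table(f, w), "missing column")
})

test_that("surface lookup follows the half-open cell convention", {
  s <- raster_surface(matrix(7.5, 4, 4), 5)
  expect_equal(surface_value_at(s, c(0, 3, 19.99), c(0, 11, 19.99)),
               rep(7.5, 3))

  # 2x2 grid, distinct values, all four cell centres  [enumeration oracle]
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # m[iy, ix]
  s2 <- raster_surface(m, 10)
  expect_equal(surface_value_at(s2, 5, 5), m[1, 1])
  expect_equal(surface_value_at(s2, 15, 5), m[1, 2])
  expect_equal(surface_value_at(s2, 5, 15), m[2, 1])
  expect_equal(surface_value_at(s2, 15, 15), m[2, 2])
  # interior boundary point belongs to the upper-right cell
  expect_equal(surface_value_at(s2, 10, 10), m[2, 2])
  expect_equal(surface_value_at(s2, 10, 5), m[1, 2])
  expect_error(surface_value_at(s2, 20, 5), "outside")
  expect_error(surface_value_at(s2, -0.01, 5), "outside")
})

test_that("every in-window point maps to exactly one cell and areas tile", {
  s <- raster_surface(matrix(seq_len(20), 4, 5), 5)
  w <- surface_window(s)
  expect_equal(window_area(w), 20 * 25)
  set.seed(1)
  x <- runif(500, 0, 25 - 1e-9); y <- runif(500, 0, 20 - 1e-9)
  idx <- stagepp:::cell_index(s, x, y)
  expect_true(all(idx$ix >= 1 & idx$ix <= 5 & idx$iy >= 1 & idx$iy <= 4))
})

test_that("ASCII grid round trip preserves the surface", {
  set.seed(3)
  s <- raster_surface(matrix(rnorm(12), 3, 4), 20, origin = c(5, -5),
                      name = "elev")
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(s, f)
  s2 <- read_ascii_grid(f)
  expect_equal(s2$values, s$values, tolerance = 1e-9)
  expect_equal(s2$cell_size, 20)
  expect_equal(s2$origin, c(5, -5))
})

test_that("point pattern enforces the window", {
  w <- plot_window(10, 10)
  expect_error(point_pattern(5, 10, w), "outside")
  expect_silent(p <- point_pattern(c(0, 9.999), c(0, 5), w))
  expect_equal(n_points(p), 2)
  expect_error(plot_window(-1, 10), "positive")
})

test_that("result writer produces documented columns and round-trips", {
  dir <- withr::local_tempdir()
  empty <- list(species = data.frame(species = character(0),
                                     stage = character(0), pve = numeric(0)),
                community = data.frame(stage = character(0),
                                       mean_pve = numeric(0)))
  write_results(empty, file.path(dir, "empty"))
  out <- read_results(file.path(dir, "empty"))
  expect_equal(nrow(out$species), 0)
  expect_named(out$species, c("species", "stage", "pve"))

  res <- list(species = data.frame(species = "SP01",
                                   stage = c("sapling", "juvenile", "adult"),
                                   pve = c(0.2123456, 0.3, 0.4),
                                   dispersal_limited = c(TRUE, TRUE, FALSE)),
              community = data.frame(stage = "sapling", mean_pve = 0.2123456))
  write_results(res, file.path(dir, "one"), manifest = list(seed = 7))
  out <- read_results(file.path(dir, "one"))
  expect_equal(nrow(out$species), 3)
  expect_equal(out$species$pve, res$species$pve, tolerance = 1e-6)
  mf <- jsonlite::read_json(file.path(dir, "one", "manifest.json"))
  expect_equal(mf$seed, 7)
})
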