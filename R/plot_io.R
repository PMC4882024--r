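#' @useDynLib stagepp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var sd quantile rnorm runif rpois prcomp optim
#'   glm.fit poisson setNames fft rexp aggregate
#' @importFrom utils read.table write.table head
NULL

#' Rectangular plot window
#'
#' Observation window of a mapped forest plot, in plot-local metres with the
#' origin at the south-west corner. All point patterns and raster surfaces in
#' the package live inside such a window; cells and quadrats are half-open,
#' `[x0, x0 + cell) x [y0, y0 + cell)`, so every in-window location belongs to
#' exactly one cell.
#'
#' @param x_extent,y_extent plot side lengths in metres (strictly positive).
#'   The default 500 x 400 is the conventional 20-ha dynamics-plot layout.
#' @param origin numeric length-2, coordinates of the south-west corner.
#' @return an object of class `plot_window`.
#' @examples
#' w <- plot_window()
#' window_area(w) / 1e4  # hectares
#' @export
plot_window <- function(x_extent = 500, y_extent = 400, origin = c(0, 0)) {
  stopifnot(is.numeric(x_extent), is.numeric(y_extent), length(origin) == 2)
  if (x_extent <= 0 || y_extent <= 0)
    stop("plot_window: extents must be strictly positive")
  structure(list(x_extent = as.numeric(x_extent),
                 y_extent = as.numeric(y_extent),
                 origin = as.numeric(origin)),
            class = "plot_window")
}

#' @rdname plot_window
#' @param w a `plot_window`
#' @export
window_area <- function(w) w$x_extent * w$y_extent

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("plot window: %g m x %g m, origin (%g, %g)\n",
              x$x_extent, x$y_extent, x$origin[1], x$origin[2]))
  invisible(x)
}

xrange <- function(w) w$origin[1] + c(0, w$x_extent)
yrange <- function(w) w$origin[2] + c(0, w$y_extent)

inside_window <- function(w, x, y) {
  xr <- xrange(w); yr <- yrange(w)
  x >= xr[1] & x < xr[2] & y >= yr[1] & y < yr[2]
}

#' Planar point pattern
#'
#' A set of stem coordinates inside a [plot_window()]. Points on the upper or
#' right boundary are outside (half-open convention).
#'
#' @param x,y numeric coordinate vectors, metres.
#' @param window a [plot_window()].
#' @param check validate that all points are in the window.
#' @return object of class `point_pattern` with elements `x`, `y`, `window`.
#' @export
point_pattern <- function(x, y, window, check = TRUE) {
  stopifnot(length(x) == length(y), inherits(window, "plot_window"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (check && length(x) > 0 && !all(inside_window(window, x, y)))
    stop("point_pattern: points outside window")
  structure(list(x = x, y = y, window = window), class = "point_pattern")
}

#' @rdname point_pattern
#' @param p a `point_pattern`
#' @export
n_points <- function(p) length(p$x)

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in %g x %g m window\n",
              n_points(x), x$window$x_extent, x$window$y_extent))
  invisible(x)
}

intensity_hat <- function(p) n_points(p) / window_area(p$window)

#' Regular-grid scalar surface
#'
#' A scalar field (elevation, a soil variable, a PCA component, a fitted
#' intensity) on a regular square-cell grid covering the window exactly.
#' `values[iy, ix]` is the cell with lower-left corner
#' `(x0 + (ix-1) cell, y0 + (iy-1) cell)`; rows run south to north.
#'
#' @param values numeric matrix, `ny x nx`, no missing values.
#' @param cell_size cell side, metres.
#' @param origin lower-left corner of the grid.
#' @param name label for the surface.
#' @return object of class `raster_surface`.
#' @export
raster_surface <- function(values, cell_size, origin = c(0, 0), name = "") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("raster_surface: missing values not allowed")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), name = as.character(name)),
            class = "raster_surface")
}

#' @export
print.raster_surface <- function(x, ...) {
  cat(sprintf("raster surface '%s': %d x %d cells of %g m\n",
              x$name, ncol(x$values), nrow(x$values), x$cell_size))
  invisible(x)
}

#' @rdname raster_surface
#' @param s a `raster_surface`
#' @export
surface_window <- function(s) {
  plot_window(ncol(s$values) * s$cell_size, nrow(s$values) * s$cell_size,
              origin = s$origin)
}

# cell indices (ix, iy) for coordinates; errors if outside the grid
cell_index <- function(s, x, y) {
  ix <- floor((x - s$origin[1]) / s$cell_size) + 1L
  iy <- floor((y - s$origin[2]) / s$cell_size) + 1L
  bad <- ix < 1L | ix > ncol(s$values) | iy < 1L | iy > nrow(s$values)
  if (any(bad))
    stop(sprintf("point outside surface grid (first offender: x=%g, y=%g)",
                 x[which(bad)[1]], y[which(bad)[1]]))
  list(ix = ix, iy = iy)
}

#' Look up a surface value at point locations
#'
#' Value of the grid cell containing each point, under the half-open cell
#' convention: a point exactly on an interior cell boundary belongs to the
#' cell on its upper-right.
#'
#' @param surface a [raster_surface()].
#' @param x,y coordinates, metres; must lie on the grid.
#' @return numeric vector of cell values.
#' @export
surface_value_at <- function(surface, x, y) {
  idx <- cell_index(surface, x, y)
  surface$values[cbind(idx$iy, idx$ix)]
}

#' Read and write ESRI ASCII grids
#'
#' Minimal reader/writer for the `ncols/nrows/xllcorner/yllcorner/cellsize`
#' ASCII grid dialect used for elevation and derived surfaces.
#'
#' @param path file path.
#' @param name label attached to the surface on read.
#' @return `read_ascii_grid` returns a [raster_surface()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, name = basename(path)) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "cellsize", "nodata_value"))) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr) stop("ASCII grid: value count mismatch")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]  # file rows run north to south
  raster_surface(m, hdr$cellsize, origin = c(hdr$xllcorner, hdr$yllcorner),
                 name = name)
}

#' @rdname read_ascii_grid
#' @param surface a [raster_surface()] to write.
#' @export
write_ascii_grid <- function(surface, path) {
  v <- surface$values
  nr <- nrow(v)
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", surface$origin[1]),
           sprintf("yllcorner %.10g", surface$origin[2]),
           sprintf("cellsize %.10g", surface$cell_size),
           "NODATA_value -9999")
  body <- apply(v[nr:1, , drop = FALSE], 1, function(row)
    paste(formatC(row, format = "g", digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

normalize_growth_form <- function(gf) {
  g <- gsub("[^a-z]", "", tolower(as.character(gf)))
  g[g %in% c("subcanopy", "subcanopytrees", "subcanopytree")] <- "subcanopy"
  g[g %in% c("canopy", "canopytrees", "canopytree")] <- "canopy"
  g[g %in% c("shrub", "shrubs")] <- "shrub"
  g
}

#' Read a mapped stem table
#'
#' Reads a CTFS-style delimited census export with header columns
#' `tag, sp, gf, gx, gy, dbh` (comma or tab delimited, auto-detected from the
#' header line). Rows outside the window or with DBH below the 1-cm census
#' threshold are dropped, not fatal; diagnostics for every rejected row are
#' attached as the `"rejected"` attribute (line number and reason).
#'
#' @param path file path.
#' @param window a [plot_window()].
#' @return `data.frame` with columns `tag, sp, gf, gx, gy, dbh`;
#'   attribute `rejected` holds a data.frame of dropped rows.
#' @export
read_stem_table <- function(path, window = plot_window()) {
  hdr_line <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr_line)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", strip.white = TRUE)
  need <- c("tag", "sp", "gf", "gx", "gy", "dbh")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("stem table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  gx <- suppressWarnings(as.numeric(raw$gx))
  gy <- suppressWarnings(as.numeric(raw$gy))
  dbh <- suppressWarnings(as.numeric(raw$dbh))
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(gx) | is.na(gy)] <- "non-numeric coordinate"
  reason[is.na(reason) & is.na(dbh)] <- "non-numeric dbh"
  reason[is.na(reason) & dbh < 1.0] <- "dbh below 1 cm census threshold"
  reason[is.na(reason) & !inside_window(window, gx, gy)] <- "outside window"
  keep <- is.na(reason)
  out <- data.frame(tag = raw$tag[keep], sp = raw$sp[keep],
                    gf = normalize_growth_form(raw$gf[keep]),
                    gx = gx[keep], gy = gy[keep], dbh = dbh[keep],
                    stringsAsFactors = FALSE)
  rej <- data.frame(line = line_no[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  if (nrow(rej) > 0)
    message(sprintf("read_stem_table: dropped %d row(s); see attr(x, 'rejected')",
                    nrow(rej)))
  attr(out, "rejected") <- rej
  attr(out, "window") <- window
  out
}

#' @rdname read_stem_table
#' @param stems stem `data.frame` as returned by [read_stem_table()].
#' @param sep field delimiter.
#' @export
write_stem_table <- function(stems, path, sep = "\t") {
  write.table(stems[, c("tag", "sp", "gf", "gx", "gy", "dbh")], path,
              sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write analysis result tables
#'
#' Writes the per-species-by-stage result table, the community summary table,
#' and a JSON run manifest (configuration echo, seed, package version) into a
#' directory.
#'
#' @param results list with elements `species` (per species x stage
#'   data.frame) and `community` (per-stage summary data.frame), as produced
#'   by [run_full_analysis()]; either may be an empty data.frame.
#' @param path output directory (created if absent).
#' @param manifest named list stored as `manifest.json`.
#' @return invisible character vector of file paths written.
#' @export
write_results <- function(results, path, manifest = list()) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_results: cannot create directory ", path)
  }
  f1 <- file.path(path, "species_stage_results.tsv")
  f2 <- file.path(path, "community_summary.tsv")
  f3 <- file.path(path, "manifest.json")
  write.table(results$species, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(results$community, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$package_version <- as.character(utils::packageVersion("stagepp"))
  manifest$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, f3, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(f1, f2, f3))
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  list(species = read.table(file.path(path, "species_stage_results.tsv"),
                            header = TRUE, sep = "\t"),
       community = read.table(file.path(path, "community_summary.tsv"),
                              header = TRUE, sep = "\t"))
}
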