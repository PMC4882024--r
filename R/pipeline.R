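# Orchestration: life-stage assignment, species selection, the three
# analyses per species x stage, and community-level aggregation.

#' Assign a life stage from growth form and DBH
#'
#' Half-open interval lookup in the growth-form scheme of
#' [life_stage_scheme()]: e.g. a canopy tree of DBH 5.0 cm is a juvenile
#' (`[5, 15)`), of 15.0 cm an adult.
#'
#' @param growth_form character vector in
#'   `"canopy"/"subcanopy"/"shrub"`.
#' @param dbh DBH in cm (>= 1).
#' @param scheme stage scheme, see [life_stage_scheme()].
#' @return character vector of stages.
#' @export
assign_life_stage <- function(growth_form, dbh, scheme = life_stage_scheme()) {
  growth_form <- normalize_growth_form(growth_form)
  unknown <- setdiff(unique(growth_form), names(scheme))
  if (length(unknown) > 0)
    stop("assign_life_stage: unknown growth form(s): ",
         paste(unknown, collapse = ", "))
  if (any(dbh < 1)) stop("assign_life_stage: dbh below 1 cm")
  out <- character(length(dbh))
  for (gf in names(scheme)) {
    sel <- growth_form == gf
    if (!any(sel)) next
    out[sel] <- stage_names()[findInterval(dbh[sel], scheme[[gf]])]
  }
  out
}

#' Select analysable species
#'
#' A species enters the analysis only if in *every* life stage it has more
#' than `min_n` individuals and (optionally) passes the CSR aggregation
#' screen ([csr_aggregation_screen()]).
#'
#' @param stems stem data.frame with columns `sp, gf, gx, gy, dbh`.
#' @param window a [plot_window()].
#' @param min_n strict abundance threshold (default 40: "more than 40").
#' @param screen run the aggregation screen (default TRUE).
#' @param n_sim CSR simulations for the screen.
#' @param screen_range distance range of the screen, metres.
#' @param seed integer seed for the screen simulations.
#' @return character vector of retained species codes; attribute `detail`
#'   holds the per-species per-stage counts and screen outcomes.
#' @export
select_species <- function(stems, window = plot_window(), min_n = 40,
                           screen = TRUE, n_sim = 199,
                           screen_range = c(0, 30), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stems$stage <- assign_life_stage(stems$gf, stems$dbh)
  detail <- list(); keep <- character(0)
  for (sp in unique(stems$sp)) {
    sub <- stems[stems$sp == sp, ]
    cnt <- table(factor(sub$stage, levels = stage_names()))
    ok <- all(cnt > min_n)
    agg <- rep(NA, 3); names(agg) <- stage_names()
    if (ok && screen) {
      for (st in stage_names()) {
        p <- point_pattern(sub$gx[sub$stage == st], sub$gy[sub$stage == st],
                           window)
        agg[st] <- as.logical(csr_aggregation_screen(p, n_sim = n_sim,
                                                     range = screen_range))
      }
      ok <- all(agg)
    }
    detail[[sp]] <- data.frame(sp = sp, stage = stage_names(),
                               n = as.integer(cnt),
                               aggregated = as.logical(agg))
    if (ok) keep <- c(keep, sp)
  }
  structure(keep, detail = do.call(rbind, detail))
}

#' Exclusive process classification from the Cox model
#'
#' Maps the two Cox-model outcomes (any environmental terms retained; the
#' residual clustering term retained) onto the exclusive classes
#' `environment_only`, `dispersal_only`, `both`, `neither`.
#'
#' @param h_selected logical, environmental terms retained.
#' @param d_retained logical, residual term retained.
#' @return character class, vectorized.
#' @export
classify_process_combination <- function(h_selected, d_retained) {
  ifelse(h_selected & d_retained, "both",
         ifelse(h_selected, "environment_only",
                ifelse(d_retained, "dispersal_only", "neither")))
}

#' Pipeline configuration
#'
#' Defaults are the analysis constants of the study design: 999
#' habitat-association simulations at the 99% interval, 199
#' dispersal-limitation simulations at the 95% envelope over 0-20 m, 39
#' Cox goodness-of-fit simulations, the CSR screen over 0-30 m, Thomas and
#' Cox minimum contrast over 0-100 m, convexity breaks (-2, 2) m, the 450-m
#' elevation split and the strict > 40 abundance rule.
#'
#' @param ... overrides of any default element.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_sim_assoc = 999, level_assoc = 0.99,
              n_sim_disp = 199, level_disp = 0.95, disp_range = c(0, 20),
              n_sim_gof = 39, gof_range = c(0, 20),
              screen = TRUE, n_sim_screen = 199, screen_range = c(0, 30),
              r_max_fit = 100, min_n = 40,
              convexity_breaks = c(-2, 2), elevation_break = 450)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# deterministic child seed below 2^31 for species x stage x analysis
child_seed <- function(master, i_sp, i_stage, i_analysis) {
  as.integer((as.double(master) * 2654435761 + i_sp * 97561 +
                i_stage * 7919 + i_analysis * 104729) %% 2147483647)
}

#' Prepare environmental surfaces and habitat map from raw inputs
#'
#' Computes quadrat topography from the corner posts, classifies the seven
#' habitats, block-kriges the three topographic and four soil variables to
#' the 5-m grid (topographic quadrat values are kriged like soil samples,
#' placed at quadrat centres), and runs the PCA.
#'
#' @param posts corner-post elevation matrix, see [quadrat_topography()].
#' @param soil_samples data.frame `x, y, totalC, totalN, totalP, pH`.
#' @param window a [plot_window()].
#' @param disturbed_mask optional logical quadrat matrix.
#' @param config a [pipeline_config()].
#' @return list with `env` (an `env_stack`), `habitat_map`, `topo`,
#'   `surfaces` (the seven kriged 5-m surfaces).
#' @export
prepare_environment <- function(posts, soil_samples, window = plot_window(),
                                disturbed_mask = NULL,
                                config = pipeline_config()) {
  topo <- quadrat_topography(posts)
  hab <- classify_habitats(topo, disturbed_mask,
                           convexity_breaks = config$convexity_breaks,
                           elevation_break = config$elevation_break)
  qx <- topo$x0 + 10; qy <- topo$y0 + 10
  lag_breaks <- seq(0, min(window$x_extent, window$y_extent) / 2, by = 10)
  krige_var <- function(x, y, z, name) {
    vg <- fit_variogram(empirical_semivariogram(x, y, z, lag_breaks))
    krige_block(x, y, z, vg, window, cell_size = 5, name = name)
  }
  surfaces <- list(
    elev = krige_var(qx, qy, topo$mean_elev, "elev"),
    convexity = krige_var(qx, qy, topo$convexity, "convexity"),
    slope = krige_var(qx, qy, topo$slope, "slope"),
    totalC = krige_var(soil_samples$x, soil_samples$y, soil_samples$totalC,
                       "totalC"),
    totalN = krige_var(soil_samples$x, soil_samples$y, soil_samples$totalN,
                       "totalN"),
    totalP = krige_var(soil_samples$x, soil_samples$y, soil_samples$totalP,
                       "totalP"),
    pH = krige_var(soil_samples$x, soil_samples$y, soil_samples$pH, "pH"))
  list(env = pca_environment(surfaces), habitat_map = hab, topo = topo,
       surfaces = surfaces)
}

#' Run the full three-method analysis
#'
#' For each selected species and life stage runs (1) the species-habitat
#' association test under the Thomas null, (2) the dispersal-limitation
#' envelope test under the heterogeneous Poisson null, and (3) Cox model
#' selection with spatial variance decomposition; then aggregates to the
#' community level: percentage of species habitat-associated and
#' dispersal-limited per stage, mean PVE per stage, the exclusive
#' process-combination classes per stage (and per syndrome), the per-r
#' exceedance profile, and PVE increments by dispersal syndrome.
#' Per-species failures are quarantined and reported, not fatal.
#'
#' @param stems stem data.frame (`sp, gf, gx, gy, dbh`).
#' @param env an `env_stack`.
#' @param habitat_map a `habitat_map`.
#' @param syndromes named character vector, species -> dispersal syndrome.
#' @param config a [pipeline_config()].
#' @param seed master seed; the run is bit-for-bit reproducible given
#'   (inputs, config, seed).
#' @param species optional pre-selected species codes (skips
#'   [select_species()]).
#' @return object of class `stage_summary`: `species` (per species x stage
#'   data.frame), `community` (per-stage data.frame), `per_r` (exceedance
#'   profile), `increments`, `exceptions`.
#' @export
run_full_analysis <- function(stems, env, habitat_map, syndromes = NULL,
                              config = pipeline_config(), seed = 1,
                              species = NULL) {
  window <- env$window
  stems$stage <- assign_life_stage(stems$gf, stems$dbh)
  if (is.null(species))
    species <- select_species(stems, window, min_n = config$min_n,
                              screen = config$screen,
                              n_sim = config$n_sim_screen,
                              screen_range = config$screen_range,
                              seed = child_seed(seed, 0, 0, 0))
  rows <- list(); exceptions <- list(); per_r_flags <- list()
  for (i_sp in seq_along(species)) {
    sp <- species[i_sp]
    for (i_st in seq_along(stage_names())) {
      st <- stage_names()[i_st]
      sel <- stems$sp == sp & stems$stage == st
      pat <- point_pattern(stems$gx[sel], stems$gy[sel], window)
      res <- tryCatch({
        assoc <- habitat_association_test(pat, habitat_map,
                                          n_sim = config$n_sim_assoc,
                                          level = config$level_assoc,
                                          seed = child_seed(seed, i_sp, i_st, 1))
        hpp_model <- stepwise_select(pat, env)
        disp <- dispersal_limitation_test(pat, env,
                                          n_sim = config$n_sim_disp,
                                          level = config$level_disp,
                                          scale_range = config$disp_range,
                                          seed = child_seed(seed, i_sp, i_st, 2),
                                          model = hpp_model)
        cox <- select_cox_model(pat, env, n_sim = config$n_sim_gof,
                                gof_range = config$gof_range,
                                seed = child_seed(seed, i_sp, i_st, 3),
                                loglin = hpp_model)
        dec <- variance_decomposition(cox, env)
        habpos <- assoc$testable && any(assoc$table$classification == "positive")
        h_sel <- nrow(cox$loglin$terms) > 0
        d_ret <- !is.null(cox$matern)
        per_r_flags[[paste(sp, st)]] <-
          data.frame(stage = st, r = disp$envelope$observed$r,
                     exceeds = disp$envelope$exceeds_above)
        data.frame(species = sp, stage = st, n = n_points(pat),
                   habitat_associated = habpos,
                   assoc_testable = assoc$testable,
                   dispersal_limited = disp$significant,
                   disp_gof_p = disp$gof$p_value,
                   h_selected = h_sel, d_retained = d_ret,
                   cox_adequate = isTRUE(attr(cox, "adequate")),
                   pve = dec$pve, pvd = dec$pvd,
                   class = classify_process_combination(h_sel, d_ret),
                   syndrome = if (!is.null(syndromes)) unname(syndromes[sp])
                              else NA_character_)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        exceptions[[paste(sp, st)]] <- conditionMessage(res)
      } else rows[[paste(sp, st)]] <- res
    }
  }
  sp_tab <- if (length(rows) > 0) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame()
  community <- aggregate_stage_summary(sp_tab)
  per_r <- if (length(per_r_flags) > 0) {
    allr <- do.call(rbind, per_r_flags)
    aggregate(exceeds ~ stage + r, allr, mean)
  } else data.frame()
  incs <- if (nrow(sp_tab) > 0 && !is.null(syndromes))
    pve_increments(data.frame(species = sp_tab$species, stage = sp_tab$stage,
                              pve = sp_tab$pve),
                   syndromes = syndromes)
  else NULL
  structure(list(species = sp_tab, community = community, per_r = per_r,
                 increments = incs, exceptions = exceptions,
                 selected = species, seed = seed, config = config),
            class = "stage_summary")
}

#' Community-level aggregation of the per-species table
#'
#' Recomputes all stage-level percentages from the per-species records:
#' percent habitat-associated, percent dispersal-limited, mean PVE, and the
#' exclusive class percentages (which sum to 100 per stage).
#'
#' @param sp_tab per species x stage data.frame from [run_full_analysis()].
#' @return per-stage data.frame.
#' @export
aggregate_stage_summary <- function(sp_tab) {
  if (is.null(sp_tab) || nrow(sp_tab) == 0) {
    return(data.frame(stage = character(0), n_species = integer(0),
                      pct_habitat_associated = numeric(0),
                      pct_dispersal_limited = numeric(0),
                      mean_pve = numeric(0),
                      pct_environment_only = numeric(0),
                      pct_dispersal_only = numeric(0), pct_both = numeric(0),
                      pct_neither = numeric(0)))
  }
  out <- lapply(stage_names(), function(st) {
    sub <- sp_tab[sp_tab$stage == st, ]
    if (nrow(sub) == 0) return(NULL)
    cls <- factor(sub$class, levels = c("environment_only", "dispersal_only",
                                        "both", "neither"))
    data.frame(stage = st, n_species = nrow(sub),
               pct_habitat_associated = 100 * mean(sub$habitat_associated),
               pct_dispersal_limited = 100 * mean(sub$dispersal_limited),
               mean_pve = mean(sub$pve, na.rm = TRUE),
               pct_environment_only = 100 * mean(cls == "environment_only"),
               pct_dispersal_only = 100 * mean(cls == "dispersal_only"),
               pct_both = 100 * mean(cls == "both"),
               pct_neither = 100 * mean(cls == "neither"))
  })
  do.call(rbind, out)
}

#' @export
print.stage_summary <- function(x, ...) {
  cat("stage summary over", length(unique(x$species$species)), "species\n")
  print(x$community, digits = 3)
  if (length(x$exceptions) > 0)
    cat(length(x$exceptions), "species x stage analyses quarantined\n")
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `synth --out DIR [--seed N] [--species N]` writes a
#' synthetic bundle; `run --in DIR --out DIR [--seed N]` reads a bundle
#' directory (as written by `synth`) and runs the full pipeline, writing
#' result tables and a manifest.
#'
#' @param args character vector (default the trailing command-line
#'   arguments).
#' @return exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: stagepp synth|run [--in DIR] [--out DIR] [--seed N] [--species N]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "stagepp_out")
  if (cmd == "synth") {
    n_sp <- as.integer(opt("species", "12"))
    mix <- c(animal = n_sp - 2 * (n_sp >= 6) - 2 * (n_sp >= 4),
             wind = 2 * (n_sp >= 4), gravity_ballistic = 2 * (n_sp >= 6))
    bundle <- make_community(n_species = n_sp, syndrome_mix = mix, seed = seed)
    write_bundle(bundle, out)
    message("bundle written to ", out)
    return(invisible(0L))
  }
  if (cmd == "run") {
    ind <- opt("in")
    if (is.null(ind)) { message(usage); return(invisible(1L)) }
    posts <- read_ascii_grid(file.path(ind, "elevation_posts.asc"))
    window <- plot_window((ncol(posts$values) - 1) * posts$cell_size,
                          (nrow(posts$values) - 1) * posts$cell_size)
    soil <- read.table(file.path(ind, "soil_samples.tsv"), header = TRUE,
                       sep = "\t")
    stems <- read_stem_table(file.path(ind, "stems.tsv"), window)
    syn_f <- file.path(ind, "syndromes.tsv")
    syndromes <- if (file.exists(syn_f)) {
      s <- read.table(syn_f, header = TRUE, sep = "\t")
      setNames(s$syndrome, s$sp)
    } else NULL
    mask_f <- file.path(ind, "disturbed_mask.tsv")
    mask <- NULL
    ny <- nrow(posts$values) - 1; nx <- ncol(posts$values) - 1
    if (file.exists(mask_f)) {
      mi <- read.table(mask_f, header = TRUE, sep = "\t")
      mask <- matrix(FALSE, ny, nx)
      mask[cbind(mi$row, mi$col)] <- TRUE
    }
    prep <- prepare_environment(posts$values, soil, window, mask)
    res <- run_full_analysis(stems, prep$env, prep$habitat_map, syndromes,
                             seed = seed)
    write_results(res, out, manifest = list(seed = seed, command = "run",
                                            input = ind))
    message("results written to ", out)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
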