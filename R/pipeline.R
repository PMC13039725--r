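#' Default end-to-end run configuration
#'
#' A complete synthetic configuration exercising every pipeline stage:
#' one landscape, a species pool, two contrasting climate/land-use
#' scenarios (a mild low-emission sustainable pathway and a severe
#' fossil-fuelled pathway), the default time slices (2020-2040, 2040-2060,
#' 2060-2080), and the default metric and extinction settings.
#'
#' @param seed global seed; per-stage seeds are derived with
#'   [stage_seed()].
#' @param grid_dims landscape size (default 20 x 20).
#' @param n_species species-pool size (default 120).
#' @param n_sites surveyed sites for the turnover model (default 120).
#' @param max_pairs cap on training site pairs (default 4000).
#' @return A `run_config` list; see [validate_config()] for the schema.
#' @export
default_run_config <- function(seed = 1L, grid_dims = c(20L, 20L),
                               n_species = 120L, n_sites = 120L,
                               max_pairs = 4000L) {
  classes <- c("seminatural", "extensive_pastoral", "intensive_pastoral",
               "intensive_agriculture", "urban")
  mild_T <- matrix(0, 5, 5, dimnames = list(classes, classes))
  diag(mild_T) <- 1
  # mild: near-static land use with slight recovery toward semi-natural
  mild_T["intensive_pastoral", ] <- c(0.004, 0.004, 0.992, 0, 0)
  mild_T["intensive_agriculture", ] <- c(0.003, 0.003, 0, 0.994, 0)
  severe_T <- matrix(0, 5, 5, dimnames = list(classes, classes))
  diag(severe_T) <- 1
  # severe: intensification and urban sprawl; urban is absorbing
  severe_T["seminatural", ] <- c(0.975, 0, 0.01, 0.01, 0.005)
  severe_T["extensive_pastoral", ] <- c(0, 0.975, 0.02, 0, 0.005)
  severe_T["intensive_pastoral", ] <- c(0, 0, 0.995, 0, 0.005)
  severe_T["intensive_agriculture", ] <- c(0, 0, 0, 0.995, 0.005)
  years <- 2015:2080
  slices <- list(c(2020L, 2040L), c(2040L, 2060L), c(2060L, 2080L))
  mild_shift <- c(tmin = 0.15, tmax = 0.15, diurnal_range = 0.02,
                  annual_precip = -8, precip_seasonality = 0.3,
                  peti_driest = 0.8, sunshine = 1)
  severe_shift <- c(tmin = 0.55, tmax = 0.6, diurnal_range = 0.08,
                    annual_precip = -30, precip_seasonality = 1.2,
                    peti_driest = 3, sunshine = 4)
  list(
    seed = as.integer(seed),
    landscape = landscape_spec(grid_dims = grid_dims,
                               seed = stage_seed(seed, "landscape")),
    n_species = as.integer(n_species),
    n_sites = as.integer(n_sites),
    n_years = 3L,
    max_pairs = as.integer(max_pairs),
    species_total = as.integer(n_species),
    landuse_classes = classes,
    scenarios = list(
      "RCP2.6-SSP1" = scenario_spec("RCP2.6-SSP1", mild_shift, mild_T,
                                    years, slices),
      "RCP8.5-SSP5" = scenario_spec("RCP8.5-SSP5", severe_shift, severe_T,
                                    years, slices)
    ),
    time_slices = slices,
    bii = default_bii_table(),
    metric = metric_config(),
    extinction = extinction_config(seed = stage_seed(seed, "extinction"))
  )
}

#' Validate a run configuration
#'
#' Schema and cross-reference checks before a pipeline run: slice ordering
#' and non-overlap, scenario coverage of every slice, land-use classes all
#' present in the BII table, and parameter ranges. Defaults in effect are
#' reported as warnings, errors as a structured list.
#'
#' @param config a [default_run_config()]-style list.
#' @return list with `ok` (logical), `errors`, `warnings` (character
#'   vectors).
#' @export
validate_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  need <- c("seed", "landscape", "scenarios", "time_slices", "bii",
            "metric", "extinction")
  miss <- setdiff(need, names(config))
  if (length(miss)) errors <- c(errors, paste("missing fields:",
                                              paste(miss, collapse = ", ")))
  sl <- config$time_slices
  if (!is.null(sl) && length(sl) > 1L) {
    starts <- vapply(sl, `[`, numeric(1), 1)
    ends <- vapply(sl, `[`, numeric(1), 2)
    if (is.unsorted(starts)) errors <- c(errors, "time slices must be ordered")
    if (any(starts[-1] < ends[-length(ends)])) {
      errors <- c(errors, "time slices must not overlap")
    }
  }
  for (sc in config$scenarios) {
    if (!inherits(sc, "scenario_spec")) {
      errors <- c(errors, "scenarios must be scenario_spec objects"); next
    }
    for (s in sl) {
      if (s[1] < sc$years[1] || s[2] > sc$years[length(sc$years)]) {
        errors <- c(errors, sprintf("scenario %s does not cover slice %d-%d",
                                    sc$name, s[1], s[2]))
      }
    }
    bad <- setdiff(rownames(sc$landuse_transition), config$bii$class)
    if (length(bad)) {
      errors <- c(errors, sprintf("land-use class without BII entry: %s",
                                  paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(config$metric) &&
      isTRUE(all.equal(config$metric$dissimilarity_threshold, 0.10))) {
    warnings <- c(warnings, "dissimilarity threshold at default 0.10")
  }
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}

#' Run the full projection pipeline
#'
#' Executes every stage in dependency order on a synthetic configuration:
#' simulate (landscape, niches, communities, future climates, land use),
#' prepare (incidence pooling, coverage weights, site-pair table), fit
#' (the dissimilarity model), transform (current and future grids),
#' metrics (compositional change, disappearing/novel bioclimates,
#' overlap), habitat (condition maps), extinction (per-cell persistence
#' and aggregate counts per scenario x slice). Artefacts are written as
#' plain CSV/text files under `out_dir` with a manifest listing every
#' file, its producing stage and the configuration hash; rerunning with an
#' identical config and seed reproduces identical tables.
#'
#' @param config a validated [default_run_config()]-style list.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and returns results only.
#' @return list with per-stage results: `landscape`, `model`, `metrics`
#'   (per scenario x slice), `extinction` (data.frame of aggregate
#'   results), `baseline`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  chk <- validate_config(config)
  if (!chk$ok) {
    stop("invalid config:\n  ", paste(chk$errors, collapse = "\n  "),
         call. = FALSE)
  }
  seed <- config$seed
  manifest <- list()
  emit <- function(obj, name, stage, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = name, stage = stage, config_hash = config_hash)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  config_hash <- config_digest(config)

  # -- simulate ------------------------------------------------------------
  env <- generate_landscape(config$landscape)
  env <- fill_env_variable(env, "soil_ph")
  niches <- sample_species_niches(env, config$n_species,
                                  seed = stage_seed(seed, "niches"))
  sites <- with_seed(stage_seed(seed, "sites"),
                     sort(sample(which(valid_cells(env)), config$n_sites)))
  comm <- generate_communities(env, niches, n_years = config$n_years,
                               seed = stage_seed(seed, "communities"),
                               cells = sites)
  emit(env, "landscape.csv", "simulate", write_env_grid)
  emit(comm, "communities.csv", "simulate", write_community_table)

  # -- prepare -------------------------------------------------------------
  site_env <- env$values[sites, , drop = FALSE]
  rownames(site_env) <- as.character(sites)
  prep <- prepare_site_pairs(comm, site_env, max_pairs = config$max_pairs,
                             seed = stage_seed(seed, "pairs"))
  emit(prep$pairs, "site_pairs.csv", "prepare", write_site_pair_table)

  # -- fit + transform -----------------------------------------------------
  model <- fit_gdm(prep$pairs)
  emit(model, "gdm_model.txt", "fit", write_gdm)
  tg_cur <- gdm_transform(model, env)

  # -- per-scenario stages -------------------------------------------------
  metrics <- list()
  ext_rows <- list()
  n_cells <- prod(env$dims)
  for (sc_name in names(config$scenarios)) {
    sc <- config$scenarios[[sc_name]]
    lu <- generate_landuse(sc, config$landuse_classes, n_cells,
                           seed = stage_seed(seed, paste0("landuse.", sc_name)))
    for (sl in config$time_slices) {
      tag <- sprintf("%s_%d-%d", sc_name, sl[1], sl[2])
      env_fut <- generate_future_climate(env, sc, sl)
      tg_fut <- gdm_transform(model, env_fut)
      summ <- bioclimate_summary(model, tg_cur, tg_fut, config$metric)
      metrics[[tag]] <- summ
      hab <- habitat_condition_map(lu, config$bii, slice = sl)
      pm <- persistence_map(tg_cur, tg_fut, hab, config$extinction)
      agg <- aggregate_persistence(pm$p, config$species_total,
                                   config$extinction)
      ext_rows[[tag]] <- data.frame(
        scenario = sc_name, slice_start = sl[1], slice_end = sl[2],
        p_bar = agg$p_bar, n_extinction = agg$n_extinction,
        n_extinction_rounded = agg$n_extinction_rounded,
        percent_heading = agg$percent_heading,
        median_comp_change = summ$compositional_change$median,
        disappearing_area_pct = summ$disappearing$area_pct,
        novel_area_pct = summ$novel$area_pct,
        jaccard_overlap = summ$overlap$jaccard)
    }
    # baseline debt: today's land use against the intact benchmark
    if (sc_name == names(config$scenarios)[1]) {
      hab0 <- habitat_condition_map(lu, config$bii,
                                    slice = c(sc$years[1], sc$years[1]))
      pm0 <- persistence_map(tg_cur, tg_cur, hab0, config$extinction)
      agg0 <- aggregate_persistence(pm0$p, config$species_total,
                                    config$extinction)
      baseline <- data.frame(scenario = "baseline",
                             slice_start = sc$years[1],
                             slice_end = sc$years[1],
                             p_bar = agg0$p_bar,
                             n_extinction = agg0$n_extinction,
                             n_extinction_rounded = agg0$n_extinction_rounded,
                             percent_heading = agg0$percent_heading)
    }
  }
  extinction <- do.call(rbind, c(ext_rows, list(make.row.names = FALSE)))
  emit(extinction, "extinction.csv", "extinction",
       function(x, p) utils::write.csv(x, p, row.names = FALSE))
  metric_tab <- do.call(rbind, lapply(names(metrics), function(tag) {
    m <- metrics[[tag]]
    data.frame(run = tag, median_comp_change = m$compositional_change$median,
               disappearing_area_pct = m$disappearing$area_pct,
               novel_area_pct = m$novel$area_pct,
               jaccard_overlap = m$overlap$jaccard,
               conditional_replacement = m$overlap$conditional_replacement)
  }))
  emit(metric_tab, "metrics.csv", "metrics",
       function(x, p) utils::write.csv(x, p, row.names = FALSE))

  result <- list(landscape = env, model = model, metrics = metrics,
                 extinction = extinction, baseline = baseline,
                 coverage = prep$coverage, config_hash = config_hash)
  if (!is.null(out_dir)) {
    manifest_df <- do.call(rbind, manifest)
    utils::write.csv(manifest_df, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    result$manifest <- manifest_df
  }
  result
}

# Deterministic hash of the configuration (for provenance tagging).
config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}
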