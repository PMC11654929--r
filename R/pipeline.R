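#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with its
#' default. A single master seed deterministically spawns per-stage seeds.
#'
#' @param sim A [sim_config()] describing the synthetic world.
#' @param components Dwelling components to model.
#' @param max_edge_km Mesh resolution; default a fortieth of the domain
#'   diameter.
#' @param resolution Prediction raster resolution in degrees.
#' @param prediction_date Date the time covariate is fixed at for
#'   prediction.
#' @param holdout Fraction of clusters held out (stratified by outcome) for
#'   evaluation; 0 evaluates in-sample.
#' @param n_draws Posterior draws for the prediction bands.
#' @param n_starts Multi-starts of the hyperparameter search.
#' @param impute_k Neighbours for pixel imputation.
#' @param out_dir Output directory (`NULL` = don't write artifacts).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            components = c("floor", "wall", "roof"),
                            max_edge_km = NULL,
                            resolution = 0.05,
                            prediction_date = as.Date("2023-01-01"),
                            holdout = 0,
                            n_draws = 200,
                            n_starts = 2,
                            impute_k = 5,
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            all(components %in% c("floor", "wall", "roof")),
            holdout >= 0, holdout < 1, resolution > 0)
  structure(list(sim = sim, components = components, max_edge_km = max_edge_km,
                 resolution = resolution, prediction_date = as.Date(prediction_date),
                 holdout = holdout, n_draws = n_draws, n_starts = n_starts,
                 impute_k = impute_k, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipe_log <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline on the synthetic world
#'
#' Executes simulate -> classify -> georeference -> extract -> variogram ->
#' fit -> predict -> evaluate in order, writing each stage's outputs (and a
#' parameter log) under `out_dir` when given. A stage failure stops the
#' chain with the failing stage named; artifacts already written are kept.
#'
#' @param config A [pipeline_config()].
#' @return An artifact bundle (invisible list): the survey, per-component
#'   analysis tables, fits, prediction rasters and the evaluation report.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  od <- config$out_dir
  log_path <- NULL
  if (!is.null(od)) {
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(od, "pipeline.log")
    cat("", file = log_path)
  }
  stage <- function(name, expr) {
    pipe_log(log_path, "stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- config$seed
  bundle <- list(config = config)

  # -- simulate ---------------------------------------------------------
  bundle$landscape <- stage("simulate", simulate_landscape(config$sim))
  bundle$settlements <- stage("simulate",
    simulate_settlements(config$sim$boundary, config$sim$n_settlements, config$sim$seed))
  world <- stage("simulate", simulate_survey(bundle$settlements, bundle$landscape, config$sim))
  bundle$survey <- world
  if (!is.null(od)) {
    readr::write_csv(world$households, file.path(od, "households.csv"))
    readr::write_csv(bundle$settlements, file.path(od, "settlements.csv"))
    write_geotiff(bundle$landscape, file.path(od, "covariates.tif"))
    yaml::write_yaml(list(seed = seed, n_clusters = config$sim$n_clusters,
                          spatial_range_km = config$sim$spatial_range,
                          spatial_sd = config$sim$spatial_sd,
                          components = config$components,
                          resolution = config$resolution,
                          holdout = config$holdout),
                     file.path(od, "run_parameters.yaml"))
  }

  # -- classify + subsample --------------------------------------------
  schema <- material_schema()
  analysis <- stage("classify", {
    purrr::map(setNames(config$components, config$components), function(comp) {
      hh <- world$households
      cat_ <- classify_material(comp, hh[[paste0(comp, "_material")]], schema)
      hh$outcome <- recode_binary(cat_)
      sample_one_per_cluster(hh, "outcome", seed = derive_seed(seed, paste0("sub_", comp)))
    })
  })

  # -- georeference -----------------------------------------------------
  analysis <- stage("georef", {
    purrr::imap(analysis, function(tbl, comp) {
      loc <- assign_cluster_locations(
        tbl[, c("cluster_id", "region", "urbanicity", "lon", "lat")],
        bundle$settlements, seed = derive_seed(seed, paste0("georef_", comp)))
      tbl$lon <- loc$lon; tbl$lat <- loc$lat; tbl$provenance <- loc$provenance
      tbl
    })
  })

  # -- extract covariates + design -------------------------------------
  cfg_sim <- config$sim
  continuous <- c(if (cfg_sim$n_continuous > 0) paste0("cont_", seq_len(cfg_sim$n_continuous)),
                  if (cfg_sim$use_time) "log_time")
  factors <- c(if (cfg_sim$use_land_class) list(land_class = "class1"),
               if (cfg_sim$use_region) list(region = "R1"))
  analysis <- stage("extract", {
    purrr::map(analysis, function(tbl) {
      ex <- extract_at_points(bundle$landscape, tbl)
      if (cfg_sim$use_land_class) ex$land_class <- paste0("class", ex$land_class)
      if (cfg_sim$use_time) ex$log_time <- time_covariate(ex$interview_date)
      keep <- !ex$outside_footprint & complete.cases(ex[, c(continuous, names(factors))])
      ex[keep, ]
    })
  })
  if (!is.null(od))
    purrr::iwalk(analysis, function(tbl, comp)
      readr::write_csv(tbl, file.path(od, paste0("analysis_", comp, ".csv"))))

  # -- train/holdout split ---------------------------------------------
  splits <- purrr::imap(analysis, function(tbl, comp) {
    if (config$holdout == 0) return(list(train = tbl, test = tbl, in_sample = TRUE))
    with_seed(derive_seed(seed, paste0("split_", comp)), {
      test_idx <- unlist(lapply(split(seq_len(nrow(tbl)), tbl$outcome), function(ix)
        sample(ix, round(config$holdout * length(ix)))))
      list(train = tbl[-test_idx, ], test = tbl[test_idx, ], in_sample = FALSE)
    })
  })

  # -- exploratory variogram (first component) -------------------------
  bundle$esda <- stage("variogram", {
    tbl <- splits[[1]]$train
    spec0 <- build_design(tbl, continuous = continuous, factors = factors)
    lf <- fit_logistic(spec0$X, as.numeric(tbl$outcome == "improved"))
    r <- pearson_residuals(as.numeric(tbl$outcome == "improved"), lf$fitted)
    xy <- to_model_crs(tbl$lon, tbl$lat)
    sv <- empirical_semivariogram(r, cbind(xy$x_km, xy$y_km),
                                  seed = derive_seed(seed, "variogram"))
    sph <- tryCatch(fit_spherical(sv), error = function(e) NULL)
    if (!is.null(od)) readr::write_csv(sv, file.path(od, "semivariogram.csv"))
    list(semivariogram = sv, spherical = sph)
  })

  # -- fit --------------------------------------------------------------
  b <- cfg_sim$boundary
  bk <- to_model_crs(b$lon, b$lat)
  diam <- sqrt(diff(range(bk$x_km))^2 + diff(range(bk$y_km))^2)
  max_edge <- config$max_edge_km %||% (diam / 40)
  bundle$fits <- stage("fit", {
    purrr::imap(splits, function(sp, comp) {
      tbl <- sp$train
      spec <- build_design(tbl, continuous = continuous, factors = factors)
      xy <- to_model_crs(tbl$lon, tbl$lat)
      mesh <- build_mesh(cbind(xy$x_km, xy$y_km), boundary = b, max_edge_km = max_edge)
      A <- projector(mesh, cbind(xy$x_km, xy$y_km))
      fit_latent_gaussian_logistic(
        as.numeric(tbl$outcome == "improved"), spec$X, A, mesh,
        priors = list(range0 = diam / 5),
        design_spec = spec, n_starts = config$n_starts)
    })
  })

  # -- predict ----------------------------------------------------------
  time_value <- time_covariate(config$prediction_date)
  bundle$rasters <- stage("predict", {
    purrr::imap(bundle$fits, function(fit, comp) {
      grid <- prediction_grid(b, config$resolution)
      px <- rg_as_tibble(grid)
      pin <- px[px$inside, ]
      cov <- extract_at_points(bundle$landscape, pin[, c("lon", "lat")])
      if (cfg_sim$use_land_class) cov$land_class <- paste0("class", cov$land_class)
      if (cfg_sim$use_region) cov$region <- region_of(cov$lon, cov$lat, b)
      rg <- predict_surface(fit, grid, cov, time_value = time_value,
                            n_draws = config$n_draws,
                            seed = derive_seed(seed, paste0("draws_", comp)))
      rg <- impute_missing_pixels(rg, k = config$impute_k)
      if (!is.null(od))
        write_geotiff(rg, file.path(od, paste0("prevalence_", comp, ".tif")))
      rg
    })
  })

  # -- evaluate ---------------------------------------------------------
  bundle$report <- stage("evaluate", {
    results <- purrr::imap(bundle$fits, function(fit, comp) {
      tbl <- splits[[comp]]$test
      Xn <- apply_design(fit$design_spec, tbl)
      xy <- to_model_crs(tbl$lon, tbl$lat)
      An <- projector(fit$mesh, cbind(xy$x_km, xy$y_km))
      eta <- drop(as.matrix(An %*% fit$field_mean + Xn %*% unname(fit$beta_mean)))
      list(y = tbl$outcome, p_hat = plogis(eta))
    })
    rep <- evaluation_report(results, fits = bundle$fits)
    rep$in_sample <- config$holdout == 0
    if (!is.null(od)) {
      readr::write_csv(rep$metrics, file.path(od, "evaluation_report.csv"))
      if (!is.null(rep$importance))
        readr::write_csv(rep$importance, file.path(od, "feature_importance.csv"))
    }
    rep
  })
  pipe_log(log_path, "pipeline complete")
  invisible(bundle)
}

#' Run a small end-to-end demonstration
#'
#' A complete pipeline run on the default synthetic country (500 clusters),
#' floor component only by default, at a coarser prediction resolution so
#' it finishes in minutes.
#'
#' @param out_dir Where to write artifacts (`NULL` = in-memory only).
#' @param seed Master seed.
#' @param components Components to model.
#' @param resolution Prediction resolution in degrees.
#' @return The pipeline bundle, invisibly.
#' @export
run_demo <- function(out_dir = NULL, seed = 1L, components = "floor",
                     resolution = 0.1) {
  cfg <- pipeline_config(
    sim = sim_config(seed = derive_seed(seed, "world")),
    components = components,
    resolution = resolution,
    holdout = 0.2,
    n_draws = 100,
    n_starts = 1,
    out_dir = out_dir,
    seed = seed
  )
  run_pipeline(cfg)
}
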