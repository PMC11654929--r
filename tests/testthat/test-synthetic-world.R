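test_that("landscape stack has consistent shape and is deterministic", {
  cfg <- tiny_config()
  L1 <- simulate_landscape(cfg)
  L2 <- simulate_landscape(cfg)
  expect_named(L1$bands, c("cont_1", "cont_2", "land_class"))
  expect_true(all(vapply(L1$bands, function(m) identical(dim(m), dim(L1$bands[[1]])), logical(1))))
  expect_identical(L1, L2)
  expect_gte(length(unique(as.vector(L1$bands$land_class))), 3)
})

test_that("degenerate boundary is rejected", {
  expect_error(sim_config(boundary = data.frame(lon = c(0, 1, 2), lat = c(0, 0, 0))),
               "degenerate")
})

test_that("zero smoothing scale gives uncorrelated pixels", {
  cfg <- sim_config(boundary = default_boundary(width = 10, height = 10),
                    raster_res = 0.1, smooth_scale_deg = 0, seed = 4)
  L <- simulate_landscape(cfg)
  z <- L$bands$cont_1 # 100 x 100 = 10^4 pixels
  r_row <- cor(as.vector(z[, -1]), as.vector(z[, -ncol(z)]))
  r_col <- cor(as.vector(z[-1, ]), as.vector(z[-nrow(z), ]))
  expect_lt(abs(r_row), 0.05)
  expect_lt(abs(r_col), 0.05)
})

test_that("settlements fall inside the boundary with matchable strata", {
  b <- default_boundary()
  S <- simulate_settlements(b, 100, seed = 2)
  expect_equal(nrow(S), 100)
  expect_true(all(S$lon >= min(b$lon) & S$lon <= max(b$lon)))
  expect_true(all(S$lat >= min(b$lat) & S$lat <= max(b$lat)))
  cover <- table(S$region, S$urbanicity)
  expect_true(all(cover > 0))
  expect_error(simulate_settlements(b, 0), "n_settlements")
})

test_that("population density increases with settlement size class", {
  S <- simulate_settlements(default_boundary(), 800, seed = 3)
  expect_gt(mean(S$population_density[S$place_type == "city"]),
            mean(S$population_density[S$place_type == "hamlet"]))
})

test_that("survey generation is byte-for-byte deterministic", {
  w1 <- tiny_world(5)
  cfg <- tiny_config(5)
  W2 <- simulate_survey(w1$settlements, w1$landscape, cfg)
  expect_identical(w1$world$households, W2$households)
  expect_identical(w1$world$truth$field_values, W2$truth$field_values)
  expect_error(simulate_survey(w1$settlements[0, ], w1$landscape, cfg), "empty")
})

test_that("survey structure matches the configuration", {
  w <- tiny_world()
  hh <- w$world$households
  cfg <- w$config
  sizes <- table(hh$cluster_id)
  expect_equal(length(sizes), cfg$n_clusters)
  expect_true(all(sizes >= cfg$households_per_cluster[1] &
                    sizes <= cfg$households_per_cluster[2]))
  expect_true(all(hh$interview_date >= cfg$date_range[1] &
                    hh$interview_date <= cfg$date_range[2]))
  n_miss <- sum(is.na(w$world$clusters$lon))
  expect_equal(n_miss, round(cfg$frac_missing_coords * cfg$n_clusters))
  expect_equal(length(w$world$truth$field_values), cfg$n_clusters)
})

test_that("marginal prevalence is calibrated when the field is off", {
  # logistic(0) = 0.5 exactly
  cfg0 <- sim_config(n_clusters = 400, households_per_cluster = c(25, 30),
                     n_continuous = 0, use_land_class = FALSE, use_region = FALSE,
                     use_time = FALSE, beta = c(`(Intercept)` = 0),
                     spatial_sd = 0, seed = 8)
  W0 <- simulate_survey(simulate_settlements(cfg0$boundary, 100, 8), NULL, cfg0)
  improved <- classify_material("floor", W0$households$floor_material) == "finished"
  n <- length(improved)
  expect_lt(abs(mean(improved) - 0.5), 3 * sqrt(0.25 / n))

  # logistic(-1.3863) = 0.2000
  cfg2 <- sim_config(n_clusters = 400, n_continuous = 0, use_land_class = FALSE,
                     use_region = FALSE, use_time = FALSE,
                     beta = c(`(Intercept)` = -1.3863), spatial_sd = 0, seed = 9)
  W2 <- simulate_survey(simulate_settlements(cfg2$boundary, 100, 9), NULL, cfg2)
  improved2 <- classify_material("roof", W2$households$roof_material) == "finished"
  expect_lt(abs(mean(improved2) - 0.2), 3 * sqrt(0.2 * 0.8 / length(improved2)))
})

test_that("simulated latent field follows the dense Matern law", {
  # fixed point set, many replicates: sample covariance vs the oracle
  cfg <- sim_config(n_clusters = 8, n_settlements = 8, n_continuous = 0,
                    use_land_class = FALSE, use_region = FALSE, use_time = FALSE,
                    beta = c(`(Intercept)` = 0), spatial_range = 150,
                    spatial_sd = 1, frac_missing_coords = 0, seed = 1)
  S <- simulate_settlements(cfg$boundary, 8, seed = 1)
  reps <- 500
  # cluster locations vary slightly across replicates (settlement resampling
  # and jitter), so compare E[w w'] against the mean of the per-replicate
  # dense-Matern oracle evaluated at the replicate's true coordinates
  T_acc <- C_acc <- matrix(0, 8, 8)
  for (r in seq_len(reps)) {
    cfg$seed <- r
    W <- simulate_survey(S, NULL, cfg)
    w <- W$truth$field_values
    T_acc <- T_acc + tcrossprod(w) / reps
    xy <- to_model_crs(W$truth$true_cluster_coords$lon_true,
                       W$truth$true_cluster_coords$lat_true)
    C_acc <- C_acc + matern_covariance(cbind(xy$x_km, xy$y_km),
                                       matern_params(cfg$spatial_range, cfg$spatial_sd)) / reps
  }
  expect_lt(max(abs(T_acc - C_acc)), 0.25) # Monte-Carlo error at 500 reps
  expect_lt(mean(abs(T_acc - C_acc)), 0.1)
})

test_that("cluster-level spatial structure shows up in the variogram of empirical logits", {
  cfg <- sim_config(n_clusters = 300, n_settlements = 400, n_continuous = 0,
                    use_land_class = FALSE, use_region = FALSE, use_time = FALSE,
                    beta = c(`(Intercept)` = 0), spatial_range = 50,
                    spatial_sd = 1, households_per_cluster = c(30, 30), seed = 21)
  S <- simulate_settlements(cfg$boundary, cfg$n_settlements, seed = 21)
  W <- simulate_survey(S, NULL, cfg)
  hh <- W$households
  hh$imp <- as.numeric(classify_material("floor", hh$floor_material) == "finished")
  cl <- dplyr::summarise(dplyr::group_by(hh, cluster_id), p = mean(imp))
  cl <- dplyr::left_join(cl, W$truth$true_cluster_coords, by = "cluster_id")
  logit_emp <- qlogis(pmin(pmax(cl$p, 1 / 60), 1 - 1 / 60))
  xy <- to_model_crs(cl$lon_true, cl$lat_true)
  sv <- empirical_semivariogram(logit_emp, cbind(xy$x_km, xy$y_km),
                                n_bins = 10, max_dist = 150)
  # semivariance at short lags below the plateau beyond the range
  expect_lt(sv$gamma_hat[1], mean(sv$gamma_hat[7:10], na.rm = TRUE))
})
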