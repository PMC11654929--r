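test_that("prediction grid covers the boundary at the requested resolution", {
  b <- tibble::tibble(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
  g <- prediction_grid(b, 0.05)
  expect_equal(c(g$nrow, g$ncol), c(20L, 20L))
  px <- rg_as_tibble(g)
  expect_true(all(px$lon > 0 & px$lon < 1 & px$lat > 0 & px$lat < 1))
  expect_true(all(px$inside)) # rectangle: every center inside
  expect_error(prediction_grid(b[0, ], 0.05), "boundary")

  # non-rectangular boundary: mask area tracks polygon area within a pixel ring
  tri <- tibble::tibble(lon = c(0, 1, 0), lat = c(0, 0, 1))
  gt <- prediction_grid(tri, 0.05)
  mask_area <- sum(gt$inside) * 0.05^2
  ring <- 0.05 * (2 + sqrt(2)) # perimeter * one pixel
  expect_lt(abs(mask_area - 0.5), ring)
})

test_that("degenerate zero-variance prediction equals the plug-in surface", {
  w <- tiny_world()
  cfg <- w$config
  tbl <- w$world$clusters
  tbl$outcome <- withr::with_seed(31,
    ifelse(w$world$truth$field_values + rnorm(nrow(tbl), 0, 0.1) > 0,
           "improved", "unimproved"))
  tbl <- tbl[!is.na(tbl$lon), ]
  spec <- build_design(tbl, continuous = c("cont_1", "cont_2", "log_time"),
                       factors = list(land_class = "class1", region = "R1"))
  xy <- to_model_crs(tbl$lon, tbl$lat)
  mesh <- build_mesh(cbind(xy$x_km, xy$y_km), boundary = cfg$boundary, max_edge_km = 80)
  A <- projector(mesh, cbind(xy$x_km, xy$y_km))
  y <- as.numeric(tbl$outcome == "improved")
  fit <- fit_latent_gaussian_logistic(y, spec$X, A, mesh,
                                      theta_fixed = matern_params(150, 0.8),
                                      design_spec = spec)
  g <- prediction_grid(cfg$boundary, 0.5)
  px <- rg_as_tibble(g)
  pin <- px[px$inside, ]
  cov <- extract_at_points(w$landscape, pin[, c("lon", "lat")])
  cov$land_class <- paste0("class", cov$land_class)
  cov$region <- dwellmap:::region_of(cov$lon, cov$lat, cfg$boundary)
  r0 <- predict_surface(fit, g, cov, n_draws = 0)
  expect_true(all(r0$bands$se[!is.na(r0$bands$se)] == 0))
  rs <- predict_surface(fit, g, cov, n_draws = 50, seed = 2)
  ok <- !is.na(rs$bands$prevalence)
  expect_true(all(rs$bands$prevalence[ok] >= 0 & rs$bands$prevalence[ok] <= 1))
  expect_true(all(rs$bands$se[ok] >= 0))
  # plug-in and posterior-mean surfaces agree to Monte-Carlo accuracy
  expect_lt(max(abs(rs$bands$prevalence[ok] - r0$bands$prevalence[ok])), 0.25)
  # posterior-draw prediction is seed-deterministic
  rs2 <- predict_surface(fit, g, cov, n_draws = 50, seed = 2)
  expect_identical(rs$bands, rs2$bands)
})

test_that("kNN imputation fills holes from nearest valid pixels", {
  m <- matrix(0.4, 10, 10)
  m[5, 5] <- NA
  rg <- raster_grid(0, 0, 0.1, 10, 10, bands = list(prevalence = m))
  out <- impute_missing_pixels(rg, k = 5)
  expect_equal(out$bands$prevalence[5, 5], 0.4)

  # k = 1: exactly the nearest valid pixel's value
  m2 <- matrix(seq(0, 1, length.out = 100), 10, 10)
  m2[1, 1] <- NA
  rg2 <- raster_grid(0, 0, 0.1, 10, 10, bands = list(prevalence = m2))
  out2 <- impute_missing_pixels(rg2, k = 1)
  # nearest neighbours of (1,1) are (1,2) and (2,1); haversine ties resolve
  # to one of them
  expect_true(out2$bands$prevalence[1, 1] %in% c(m2[1, 2], m2[2, 1]))

  expect_error(impute_missing_pixels(
    raster_grid(0, 0, 0.1, 2, 2, bands = list(v = matrix(NA_real_, 2, 2)))), "valid")
})

test_that("imputation matches a brute-force neighbour search and is idempotent", {
  nr <- 30; nc <- 30
  m <- withr::with_seed(21, matrix(runif(nr * nc), nr, nc))
  holes <- withr::with_seed(22, sample(nr * nc, 40))
  m[holes] <- NA
  inside <- matrix(TRUE, nr, nc)
  inside[, 29:30] <- FALSE # exterior pixels must not participate
  m[, 29:30] <- NA
  rg <- raster_grid(0, 0, 0.1, nr, nc, bands = list(v = m), inside = inside)
  out <- impute_missing_pixels(rg, k = 5)

  ctr <- dwellmap:::rg_centers(rg)
  valid <- which(!is.na(m) & inside, arr.ind = TRUE)
  for (h in which(is.na(m) & inside)) {
    rc <- arrayInd(h, dim(m))
    dd <- geosphere::distHaversine(
      cbind(ctr$lon[rc[2]], ctr$lat[rc[1]]),
      cbind(ctr$lon[valid[, 2]], ctr$lat[valid[, 1]]))
    expected <- mean(m[valid[order(dd)[1:5], , drop = FALSE]])
    expect_equal(out$bands$v[rc], expected, tolerance = 1e-12)
  }
  expect_true(all(is.na(out$bands$v[, 29:30]))) # outside stays nodata
  again <- impute_missing_pixels(out, k = 5)
  expect_identical(again$bands, out$bands)
  # means of [0,1] values stay in [0,1]
  expect_true(all(out$bands$v[inside] >= 0 & out$bands$v[inside] <= 1))
})

test_that("GeoTIFF round-trips values, mask and georeferencing", {
  nr <- 7; nc <- 9
  prev <- withr::with_seed(23, matrix(runif(nr * nc), nr, nc))
  se <- withr::with_seed(24, matrix(runif(nr * nc, 0, 0.2), nr, nc))
  prev[2, 3] <- NA; se[2, 3] <- NA
  rg <- raster_grid(xmin = 12.25, ymin = -3.75, res = 0.05, nrow = nr, ncol = nc,
                    bands = list(prevalence = prev, se = se))
  path <- tempfile(fileext = ".tif")
  write_geotiff(rg, path)
  back <- read_geotiff(path)
  # float32 round trip is exact when values are written as float32
  expect_equal(back$bands$prevalence, prev, tolerance = 1e-7)
  expect_true(is.na(back$bands$prevalence[2, 3]))
  expect_equal(back$xmin, 12.25)
  expect_equal(back$ymin, -3.75, tolerance = 1e-12)
  expect_equal(back$res, 0.05)
  expect_equal(c(back$nrow, back$ncol), c(nr, nc))
  expect_named(back$bands, c("prevalence", "se"))
  # write-read-write is byte-identical (stable float32 payload)
  path2 <- tempfile(fileext = ".tif")
  write_geotiff(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  expect_error(read_geotiff(tempfile()), "no such file")
  expect_error(write_geotiff(rg, file.path(tempdir(), "no_dir_here", "x.tif")),
               "cannot open")
})

test_that("an independent TIFF reader agrees on the pixel payload", {
  # tiff::readTIFF knows nothing about our writer; it validates the TIFF
  # structure and float payload independently
  m <- matrix(c(0.1, 0.5, NA, 0.9, 0.25, 0.75), 2, 3)
  rg <- raster_grid(0, 0, 1, 2, 3, bands = list(v = m))
  path <- tempfile(fileext = ".tif")
  write_geotiff(rg, path)
  arr <- tiff::readTIFF(path) # float payload is returned unscaled
  vals <- if (length(dim(arr)) == 3) arr[, , 1] else arr
  expect_equal(vals[1, 1], 0.1, tolerance = 1e-7)
  expect_equal(vals[2, 2], 0.9, tolerance = 1e-7)
  expect_equal(vals[1, 2], -9999) # nodata sentinel, never a valid prevalence
})
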