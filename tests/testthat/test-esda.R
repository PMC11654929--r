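test_that("intercept-only logistic fit equals the closed-form log odds", {
  y <- c(rep(1, 30), rep(0, 70))
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_logistic(X, y)
  expect_equal(unname(f$coefficients), log(0.3 / 0.7), tolerance = 1e-8)
  expect_error(fit_logistic(X, rep(1, 100)), "constant|degenerate")
})

test_that("separation is detected", {
  x <- c(rep(0, 20), rep(1, 20))
  X <- cbind(1, x)
  y <- x
  expect_error(fit_logistic(X, y), "separation")
})

test_that("logistic estimates are consistent on simulated data", {
  beta <- c(-0.5, 1.2, -0.8)
  X <- withr::with_seed(10, cbind(1, rnorm(5000), rnorm(5000)))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- withr::with_seed(11, rbinom(5000, 1, plogis(X %*% beta)))
  f <- fit_logistic(X, y)
  se <- sqrt(diag(solve(crossprod(X * sqrt(f$fitted * (1 - f$fitted))))))
  expect_true(all(abs(f$coefficients - beta) < 3 * se))
})

test_that("Pearson residuals follow the closed form and center at zero after a fit", {
  expect_equal(pearson_residuals(1, 0.5), 1)
  expect_equal(pearson_residuals(0, 0.2), -0.5)
  expect_error(pearson_residuals(1, 1), "strictly")
  X <- withr::with_seed(12, cbind(1, rnorm(400)))
  y <- withr::with_seed(13, rbinom(400, 1, plogis(X %*% c(0.3, 0.7))))
  f <- fit_logistic(X, y)
  # the score equation of the MLE forces near-zero mean residuals
  expect_lt(abs(mean(pearson_residuals(y, f$fitted))), 0.02)
})

test_that("semivariogram handles degenerate and tiny inputs exactly", {
  coords <- cbind(c(0, 3, 6), c(0, 0, 0))
  expect_error(empirical_semivariogram(c(1, 2), rbind(c(1, 2), c(1, 2)),
                                       n_bins = 3), "coincident")
  sv0 <- empirical_semivariogram(rep(2, 3), coords, n_bins = 1, max_dist = 10)
  expect_equal(sv0$gamma_hat, 0)
  # residuals (0,1,2), all three pairs in one bin: (1+4+1)/(2*3) = 1
  sv <- empirical_semivariogram(c(0, 1, 2), coords, n_bins = 1, max_dist = 10)
  expect_equal(sv$gamma_hat, 1)
  expect_equal(sv$pair_count, 3)
})

test_that("semivariogram equals the brute-force double loop on 200 points", {
  n <- 200
  coords <- withr::with_seed(14, cbind(runif(n, 0, 100), runif(n, 0, 100)))
  vals <- withr::with_seed(15, rnorm(n))
  sv <- empirical_semivariogram(vals, coords, n_bins = 12, max_dist = 60)
  ref <- brute_semivariogram(vals, coords, n_bins = 12, max_dist = 60)
  expect_equal(sv$gamma_hat, ref$gamma_hat, tolerance = 1e-12)
  expect_equal(sv$pair_count, as.integer(ref$pair_count))
})

test_that("i.i.d. residuals give a flat semivariogram at the variance", {
  n <- 2000
  coords <- withr::with_seed(16, cbind(runif(n, 0, 100), runif(n, 0, 100)))
  vals <- withr::with_seed(17, rnorm(n, sd = 2))
  sv <- empirical_semivariogram(vals, coords, n_bins = 8)
  s2 <- var(vals)
  expect_true(all(abs(sv$gamma_hat - s2) / s2 < 0.1))
})

test_that("spherical fit recovers noiseless parameters and obeys closed forms", {
  h <- seq(5, 250, by = 10)
  g <- spherical_model(h, nugget = 0.2, psill = 0.8, range_km = 100)
  est <- tibble::tibble(bin_center = h, gamma_hat = g,
                        pair_count = rep(100L, length(h)))
  class(est) <- c("dwell_semivariogram", class(est))
  fit <- fit_spherical(est)
  expect_equal(fit$nugget, 0.2, tolerance = 1e-4)
  expect_equal(fit$psill, 0.8, tolerance = 1e-4)
  expect_equal(fit$range_km, 100, tolerance = 1e-3)
  expect_true(fit$nugget_sill_ratio >= 0 && fit$nugget_sill_ratio <= 1)
  # at h = range the model reaches the sill; just above zero, the nugget
  expect_equal(spherical_model(100, 0.2, 0.8, 100), 1.0)
  expect_equal(spherical_model(1e-9, 0.2, 0.8, 100), 0.2, tolerance = 1e-9)
  expect_error(fit_spherical(est[1:3, ]), "4")
})

test_that("spherical range roughly tracks a Matern generating range", {
  # Matern and spherical are different families; the spec-level expectation
  # is recovery within 50%
  n <- 600
  coords <- withr::with_seed(18, cbind(runif(n, 0, 600), runif(n, 0, 600)))
  C <- matern_covariance(coords, matern_params(150, 1))
  vals <- withr::with_seed(19, drop(crossprod(chol(C + diag(1e-8, n)), rnorm(n))))
  sv <- empirical_semivariogram(vals, coords, n_bins = 15, max_dist = 400)
  fit <- fit_spherical(sv)
  expect_gt(fit$range_km, 75)
  expect_lt(fit$range_km, 450)
  expect_lt(fit$nugget_sill_ratio, 0.5) # strong spatial structure, small nugget
})

test_that("semivariogram plot builds", {
  h <- seq(5, 100, by = 10)
  est <- tibble::tibble(bin_center = h,
                        gamma_hat = spherical_model(h, 0.1, 0.9, 60),
                        pair_count = rep(10L, length(h)))
  class(est) <- c("dwell_semivariogram", class(est))
  p <- ggplot2::autoplot(est, fit = fit_spherical(est))
  expect_s3_class(p, "ggplot")
})
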