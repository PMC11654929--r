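#' Non-spatial logistic regression
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`) of a binary outcome on a design matrix, used as the
#' exploratory, spatially naive baseline whose Pearson residuals feed the
#' semivariogram diagnostics. Perfect or quasi-perfect separation is raised
#' as an error.
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary 0/1 outcome vector.
#' @return A list with `coefficients`, `fitted` (probabilities), and the
#'   underlying `glm` object.
#' @export
fit_logistic <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("outcome is constant; logistic fit is degenerate", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100))
  )
  p <- fit$fitted.values
  if (!fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10) ||
      any(abs(fit$coefficients) > 30))
    stop("logistic fit did not converge cleanly (possible separation): ",
         "max |coef| = ", signif(max(abs(fit$coefficients)), 3), call. = FALSE)
  list(coefficients = fit$coefficients, fitted = p, glm = fit)
}

#' Pearson residuals for a binary outcome
#'
#' @param y Binary 0/1 vector.
#' @param p_hat Fitted probabilities strictly inside (0, 1).
#' @return `(y - p_hat) / sqrt(p_hat * (1 - p_hat))`.
#' @export
pearson_residuals <- function(y, p_hat) {
  stopifnot(length(y) == length(p_hat))
  if (any(p_hat <= 0 | p_hat >= 1))
    stop("fitted probabilities must lie strictly in (0, 1)", call. = FALSE)
  (y - p_hat) / sqrt(p_hat * (1 - p_hat))
}

#' Empirical semivariogram
#'
#' Classical (Matheron) estimator of the semivariance of `values` over
#' Euclidean distance in the model plane, with uniform bins. For large n the
#' pair set is subsampled (seeded) to at most `max_pairs`; the estimator's
#' expectation is unchanged.
#'
#' @param values Numeric vector (typically Pearson residuals).
#' @param coords_km Two-column matrix of model-plane coordinates (km).
#' @param n_bins Number of distance bins.
#' @param max_dist Maximum lag distance (km); default half the maximum
#'   pairwise distance.
#' @param max_pairs Cap on the number of point pairs used.
#' @param seed Seed for pair subsampling.
#' @return A `dwell_semivariogram` tibble: `bin_center`, `gamma_hat`,
#'   `pair_count` (empty bins have `NA` gamma).
#' @export
empirical_semivariogram <- function(values, coords_km, n_bins = 15,
                                    max_dist = NULL, max_pairs = 1e6, seed = 1L) {
  coords_km <- as.matrix(coords_km)
  n <- length(values)
  stopifnot(nrow(coords_km) == n, ncol(coords_km) == 2)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  n_pairs_total <- n * (n - 1) / 2
  if (n_pairs_total > max_pairs) {
    ij <- with_seed(seed, {
      i <- sample.int(n, max_pairs, replace = TRUE)
      j <- sample.int(n, max_pairs, replace = TRUE)
      keep <- i < j
      cbind(i[keep], j[keep])
    })
  } else {
    ij <- cbind(rep(seq_len(n - 1), times = (n - 1):1),
                unlist(lapply(seq_len(n - 1), function(i) (i + 1):n)))
  }
  dx <- coords_km[ij[, 1], 1] - coords_km[ij[, 2], 1]
  dy <- coords_km[ij[, 1], 2] - coords_km[ij[, 2], 2]
  d <- sqrt(dx^2 + dy^2)
  if (all(d == 0)) stop("all points are coincident", call. = FALSE)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  stopifnot(max_dist > 0)
  keep <- d <= max_dist & d > 0
  d <- d[keep]
  sq <- (values[ij[keep, 1]] - values[ij[keep, 2]])^2
  edges <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
  cnt <- tabulate(bin, n_bins)
  ssum <- vapply(seq_len(n_bins), function(b) sum(sq[bin == b]), numeric(1))
  out <- tibble::tibble(
    bin_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    gamma_hat = ifelse(cnt > 0, ssum / (2 * cnt), NA_real_),
    pair_count = cnt
  )
  class(out) <- c("dwell_semivariogram", class(out))
  out
}

#' Spherical semivariogram model
#'
#' `gamma(h) = nugget + psill * (1.5 h/a - 0.5 (h/a)^3)` for `h <= a`,
#' `nugget + psill` beyond the range `a`; `gamma(0) = 0` by convention but
#' the fit describes the `h > 0` limit (the nugget).
#'
#' @param h Distances (km).
#' @param nugget,psill,range_km Model parameters.
#' @return Semivariance at `h`.
#' @export
spherical_model <- function(h, nugget, psill, range_km) {
  hr <- pmin(h / range_km, 1)
  ifelse(h == 0, 0, nugget + psill * (1.5 * hr - 0.5 * hr^3))
}

#' Fit a spherical model to an empirical semivariogram
#'
#' Weighted least squares (weights = pair counts) with box constraints and a
#' multi-start over a grid of candidate ranges.
#'
#' @param estimate A `dwell_semivariogram` from [empirical_semivariogram()].
#' @return A `spherical_fit` list: `nugget`, `psill`, `range_km`,
#'   `nugget_sill_ratio`, `objective`, `converged`.
#' @export
fit_spherical <- function(estimate) {
  est <- estimate[!is.na(estimate$gamma_hat) & estimate$pair_count > 0, ]
  if (nrow(est) < 4) stop("need at least 4 non-empty bins", call. = FALSE)
  h <- est$bin_center; g <- est$gamma_hat; wt <- est$pair_count
  obj <- function(par) {
    m <- spherical_model(h, par[1], par[2], par[3])
    sum(wt * (g - m)^2)
  }
  sill0 <- max(g)
  best <- NULL
  for (a0 in quantile(h, c(0.2, 0.4, 0.6, 0.8, 1))) {
    res <- tryCatch(
      optim(c(nugget = 0.1 * sill0 + 1e-6, psill = 0.9 * sill0 + 1e-6, range_km = a0),
            obj, method = "L-BFGS-B",
            lower = c(0, 1e-9, min(h) / 10),
            upper = c(2 * sill0 + 1, 2 * sill0 + 1, 4 * max(h))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("spherical fit failed to converge", call. = FALSE)
  par <- best$par
  structure(list(nugget = unname(par[1]), psill = unname(par[2]),
                 range_km = unname(par[3]),
                 nugget_sill_ratio = unname(par[1] / (par[1] + par[2])),
                 objective = best$value,
                 converged = best$convergence == 0),
            class = "spherical_fit")
}

#' @export
print.spherical_fit <- function(x, ...) {
  cat(sprintf("Spherical semivariogram fit: nugget %.4g, partial sill %.4g, range %.4g km (nugget:sill %.3f)\n",
              x$nugget, x$psill, x$range_km, x$nugget_sill_ratio))
  invisible(x)
}

#' Plot an empirical semivariogram with an optional fitted model
#'
#' @param object A `dwell_semivariogram`.
#' @param fit Optional `spherical_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dwell_semivariogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$gamma_hat)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$pair_count), alpha = 0.7) +
    ggplot2::labs(x = "distance (km)", y = expression(hat(gamma)(h)),
                  size = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    hh <- seq(0, max(object$bin_center), length.out = 200)[-1]
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(bin_center = hh,
                            gamma_hat = spherical_model(hh, fit$nugget, fit$psill, fit$range_km)),
      color = "firebrick")
  }
  p
}
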