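log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Penalized-complexity priors on (range, sigma), evaluated on the log scale
# (Jacobian included): P(range < range0) = 0.5, P(sigma > sigma0) = 0.1.
pc_log_prior <- function(range_km, sigma, range0, sigma0 = 1) {
  lam_r <- log(2) * range0          # from exp(-lam_r / range0) = 0.5
  lam_s <- -log(0.1) / sigma0
  (log(lam_r) - 2 * log(range_km) - lam_r / range_km) +
    (log(lam_s) - lam_s * sigma) +
    log(range_km) + log(sigma)      # Jacobian of the log-scale parameterization
}

# Newton maximization of the joint log posterior of u = (w, beta) given
# theta. Returns mode, (sparse) Hessian at the mode, and the Laplace
# log marginal likelihood.
laplace_inner <- function(y, M, P, logdet_prior, u0 = NULL,
                          max_iter = 100, tol = 1e-6) {
  n_u <- ncol(M)
  u <- u0 %||% numeric(n_u)
  obj <- function(u, eta) sum(y * eta - log1pexp(eta)) - 0.5 * sum(u * as.numeric(P %*% u))
  eta <- as.numeric(M %*% u)
  f <- obj(u, eta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- plogis(eta)
    g <- as.numeric(Matrix::crossprod(M, y - p)) - as.numeric(P %*% u)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- Matrix::forceSymmetric(Matrix::crossprod(M, M * w) + P)
    delta <- tryCatch(as.numeric(Matrix::solve(H, g)), error = function(e)
      stop("Hessian is not positive definite: ", conditionMessage(e), call. = FALSE))
    step <- 1
    repeat {
      u_new <- u + step * delta
      eta_new <- as.numeric(M %*% u_new)
      f_new <- obj(u_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
    u <- u_new; eta <- eta_new; f <- f_new
  }
  if (!converged && max(abs(as.numeric(Matrix::crossprod(M, y - plogis(eta))) - as.numeric(P %*% u))) > 1e-3)
    stop("inner Newton iteration failed to converge (", max_iter, " iterations)",
         call. = FALSE)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  H <- Matrix::forceSymmetric(Matrix::crossprod(M, M * w) + P)
  logdet_H <- as.numeric(Matrix::determinant(H, logarithm = TRUE)$modulus)
  log_marginal <- f + 0.5 * logdet_prior - 0.5 * logdet_H
  list(u = u, H = H, f = f, log_marginal = log_marginal,
       iterations = it, converged = converged)
}

#' Fit the latent Gaussian spatial logistic model
#'
#' Bayesian logistic regression with a latent stationary Matern field:
#' `y_i ~ Bernoulli(logit^-1(x_i' beta + (A w)_i))`, `w ~ N(0, Q(theta)^-1)`
#' on the mesh vertices, weak `N(0, 10^2)` priors on `beta`. For fixed
#' hyperparameters `theta = (range, sigma)` the posterior of `(w, beta)` is
#' approximated by a Gaussian at its mode (Laplace approximation, found by
#' Newton iterations on the sparse joint precision); `theta` is chosen by
#' maximizing the Laplace-approximate log marginal likelihood plus
#' penalized-complexity priors over a deterministic multi-start bounded
#' search (empirical-Bayes plug-in rather than full hyperparameter
#' integration).
#'
#' @param y Binary 0/1 outcome, one per analysis cluster.
#' @param X Design matrix (with intercept), one row per cluster.
#' @param A Projector matrix from [projector()].
#' @param mesh The `dwell_mesh` the field lives on.
#' @param priors List: `range0` (prior median practical range, km; default a
#'   fifth of the mesh diameter), `sigma0` (default 1), `beta_prec`
#'   (default 0.01).
#' @param theta_fixed Optional [matern_params()]; skips hyperparameter
#'   optimization (used for reductions and oracles).
#' @param theta_lower,theta_upper Search box for `(range_km, sigma)`.
#' @param design_spec Optional `design_spec` stored for prediction.
#' @param n_starts Number of multi-start points (1-3) for the hyperparameter
#'   search.
#' @return A `dwell_fit` object.
#' @export
fit_latent_gaussian_logistic <- function(y, X, A, mesh, priors = list(),
                                         theta_fixed = NULL,
                                         theta_lower = NULL, theta_upper = NULL,
                                         design_spec = NULL, n_starts = 3) {
  stopifnot(length(y) == nrow(X), nrow(A) == length(y),
            ncol(A) == nrow(mesh$vertices), all(y %in% c(0, 1)))
  n_vert <- ncol(A); p <- ncol(X)
  diam <- sqrt(sum((apply(mesh$vertices, 2, max) - apply(mesh$vertices, 2, min))^2))
  pr <- utils::modifyList(list(range0 = diam / 5, sigma0 = 1, beta_prec = 0.01), priors)
  M <- cbind(Matrix::Matrix(A, sparse = TRUE), Matrix::Matrix(X, sparse = TRUE))

  state <- new.env()
  state$u <- NULL
  eval_theta <- function(theta) {
    Q <- matern_precision(mesh, theta)
    P <- Matrix::bdiag(Q, pr$beta_prec * Matrix::Diagonal(p))
    logdet_prior <- as.numeric(Matrix::determinant(Q, logarithm = TRUE)$modulus) +
      p * log(pr$beta_prec)
    res <- laplace_inner(y, M, P, logdet_prior, u0 = state$u)
    state$u <- res$u
    res
  }

  if (is.null(theta_fixed)) {
    lower <- theta_lower %||% c(range_km = diam / 50, sigma = 0.01)
    upper <- theta_upper %||% c(range_km = 2 * diam, sigma = 10)
    nll <- function(par) {
      th <- matern_params(exp(par[1]), exp(par[2]))
      res <- tryCatch(eval_theta(th), error = function(e) NULL)
      if (is.null(res)) return(1e10)
      -(res$log_marginal + pc_log_prior(th$range_km, th$sigma, pr$range0, pr$sigma0))
    }
    starts <- list(c(log(pr$range0), log(pr$sigma0)),
                   c(log(pr$range0 / 3), log(pr$sigma0 / 2)),
                   c(log(min(3 * pr$range0, upper[1])), log(min(2 * pr$sigma0, upper[2]))))
    starts <- starts[seq_len(max(1, min(n_starts, length(starts))))]
    best <- NULL
    for (s in starts) {
      state$u <- NULL
      o <- optim(s, nll, method = "L-BFGS-B",
                 lower = log(lower), upper = log(upper),
                 control = list(maxit = 40, factr = 1e10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    theta_hat <- matern_params(exp(best$par[1]), exp(best$par[2]))
    log_post_theta <- -best$value
  } else {
    theta_hat <- theta_fixed
    log_post_theta <- NA_real_
  }
  state$u <- NULL
  final <- eval_theta(theta_hat)
  if (!final$converged)
    stop("Laplace fit did not converge at the selected hyperparameters", call. = FALSE)

  u <- final$u
  beta_idx <- n_vert + seq_len(p)
  # marginal sds of beta from the joint precision
  E <- Matrix::sparseMatrix(i = beta_idx, j = seq_len(p), x = 1,
                            dims = c(n_vert + p, p))
  S <- Matrix::solve(final$H, E)
  beta_sd <- sqrt(pmax(Matrix::diag(Matrix::t(E) %*% S), 0))
  structure(list(
    beta_mean = setNames(u[beta_idx], colnames(X)),
    beta_sd = setNames(as.numeric(beta_sd), colnames(X)),
    field_mean = u[seq_len(n_vert)],
    joint_precision = final$H,
    theta_hat = theta_hat,
    log_marginal = final$log_marginal,
    log_posterior_theta = log_post_theta,
    mesh = mesh, design_spec = design_spec,
    n_obs = length(y), n_vertices = n_vert,
    iterations = final$iterations, converged = final$converged,
    priors = pr
  ), class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Latent Gaussian spatial logistic fit: %d obs, %d mesh vertices\n",
              x$n_obs, x$n_vertices))
  cat(sprintf("  theta-hat: range %.4g km, sigma %.4g; log-marginal %.4g\n",
              x$theta_hat$range_km, x$theta_hat$sigma, x$log_marginal))
  print(posterior_fixed_effects(x))
  invisible(x)
}

#' Posterior fixed-effect summary and feature importance
#'
#' One row per design column with posterior mean, sd, and the feature
#' importance `|mean / sd|` (a Bayesian analog of the standardized
#' coefficient).
#'
#' @param fit A `dwell_fit`.
#' @return A tibble `term`, `mean`, `sd`, `importance`.
#' @export
posterior_fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "dwell_fit"))
  tibble::tibble(term = names(fit$beta_mean),
                 mean = unname(fit$beta_mean),
                 sd = unname(fit$beta_sd),
                 importance = abs(unname(fit$beta_mean) / unname(fit$beta_sd)))
}

#' @exportS3Method generics::tidy
tidy.dwell_fit <- function(x, ...) posterior_fixed_effects(x)

#' @exportS3Method generics::glance
glance.dwell_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_vertices = x$n_vertices,
                 range_km = x$theta_hat$range_km, sigma = x$theta_hat$sigma,
                 log_marginal = x$log_marginal, converged = x$converged)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot feature importances
#'
#' @param fit A `dwell_fit` (or a tibble from [posterior_fixed_effects()]).
#' @param exclude Terms to drop, default intercept and time.
#' @return A ggplot of sorted `|mean/sd|` values.
#' @export
plot_importance <- function(fit, exclude = c("(Intercept)", "log_time")) {
  imp <- if (inherits(fit, "dwell_fit")) posterior_fixed_effects(fit) else tibble::as_tibble(fit)
  imp <- imp[!imp$term %in% exclude, ]
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                    y = stats::reorder(.data$term, .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "|posterior mean / sd|", y = NULL) +
    ggplot2::theme_minimal()
}
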