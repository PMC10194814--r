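#' Gaussian location foreground model
#'
#' The model \eqn{q(x \mid \theta) = N(x \mid \theta, \Sigma)} with fixed
#' covariance \eqn{\Sigma} and (optionally) a free mean. Its score is affine
#' in \eqn{\theta}, so it carries exponential-family structure: the NKSD
#' estimate is exactly quadratic in \eqn{\theta} and the Stein volume
#' criterion has a closed form under the conjugate Gaussian prior
#' \eqn{\theta \sim N(\mu_0, \sigma_0^2 I)}.
#'
#' With `mean_free = FALSE` the mean is pinned at `prior_mean` and the model
#' has no free parameters (`m_F = 0`), the smaller member used in nested
#' model selection comparisons.
#'
#' @param d data dimension.
#' @param mean_free logical; if `TRUE` the mean is the free parameter.
#' @param cov fixed d x d SPD covariance (default identity).
#' @param prior_mean prior mean vector (default 0).
#' @param prior_var prior variance per coordinate (default 10, the toy
#'   benchmark's choice).
#' @return An object of classes `svc_gaussian`, `svc_model`.
#' @export
gaussian_model <- function(d, mean_free = TRUE, cov = diag(d),
                           prior_mean = rep(0, d), prior_var = 10) {
  cov <- as.matrix(cov)
  if (nrow(cov) != d || ncol(cov) != d) stop("cov must be d x d")
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) stop("cov must be symmetric positive definite")
  prior_mean <- rep_len(prior_mean, d)
  m <- structure(list(type = "gaussian", d = d, mean_free = mean_free,
                      cov = cov, cov_inv = chol2inv(ch),
                      prior_mean = prior_mean, prior_var = prior_var,
                      m_F = if (mean_free) d else 0L,
                      opt_dim = if (mean_free) d else 0L),
                 class = c("svc_gaussian", "svc_model"))
  m
}

#' Score function of a model at given parameters
#'
#' Returns `function(X)` giving the N x d matrix of model score values
#' \eqn{s_{q_\theta}(x) = \nabla_x \log q(x \mid \theta)}, where `theta` is in
#' the model's unconstrained parameterization. Additive constants in the log
#' density (unknown normalizers) never enter.
#'
#' @param model an `svc_model`.
#' @param theta unconstrained parameter vector (ignored when the model has no
#'   free parameters).
#' @return A score function suitable for [nksd_ustat()].
#' @export
model_score <- function(model, theta = NULL) UseMethod("model_score")

#' @export
model_score.svc_gaussian <- function(model, theta = NULL) {
  mu <- if (model$mean_free) {
    if (is.null(theta)) stop("theta required for a free-mean model")
    as.numeric(theta)
  } else model$prior_mean
  Ki <- model$cov_inv
  function(X) -(sweep(as.matrix(X), 2, mu)) %*% Ki
}

#' Prior log density of a model
#'
#' Evaluated in the same unconstrained parameterization the optimizers use
#' (constraint-transform log-Jacobians included), which is what the Laplace
#' backend needs.
#'
#' @inheritParams model_score
#' @return Scalar log density.
#' @export
prior_logpdf <- function(model, theta) UseMethod("prior_logpdf")

#' @export
prior_logpdf.svc_gaussian <- function(model, theta) {
  if (!model$mean_free) return(0)
  sum(stats::dnorm(theta, model$prior_mean, sqrt(model$prior_var), log = TRUE))
}

#' Number of foreground parameters on an r-dimensional subspace
#'
#' @param model an `svc_model`.
#' @param r number of foreground data dimensions (defaults to the model's d).
#' @return Effective foreground parameter count `m_F`.
#' @export
param_count <- function(model, r = model$d) UseMethod("param_count")

#' @export
param_count.svc_gaussian <- function(model, r = model$d) {
  if (model$mean_free) as.integer(r) else 0L
}

# Exact Bayesian marginal likelihood of the Gaussian location model under its
# conjugate prior (used by the defective comparison score that swaps the NKSD
# for the likelihood).
gaussian_log_marginal <- function(model, X) {
  X <- as.matrix(X)
  N <- nrow(X); d <- ncol(X)
  Ki <- model$cov_inv
  loglik_const <- -N * d / 2 * log(2 * pi) - N / 2 * logdet_spd(model$cov) -
    0.5 * sum((X %*% Ki) * X)
  if (!model$mean_free) {
    mu <- model$prior_mean
    return(loglik_const + sum(X %*% Ki %*% mu) - N / 2 * sum(mu * (Ki %*% mu)))
  }
  S0i <- diag(1 / model$prior_var, d)
  Lam <- N * Ki + S0i
  eta <- Ki %*% colSums(X) + S0i %*% model$prior_mean
  loglik_const -
    0.5 * sum(model$prior_mean * (S0i %*% model$prior_mean)) -
    d / 2 * log(2 * pi * model$prior_var) +
    0.5 * sum(eta * solve(Lam, eta)) + d / 2 * log(2 * pi) - 0.5 * logdet_spd(Lam)
}
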