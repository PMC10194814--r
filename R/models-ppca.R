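#' Probabilistic PCA foreground model
#'
#' The generative model \eqn{z \sim N(0, I_k)}, \eqn{x \mid z \sim N(Hz, v
#' I_d)}, whose marginal is \eqn{x \sim N(0, C)} with \eqn{C = H H^\top + v
#' I}. Following the evidence-approximation tradition, \eqn{H} is
#' parameterized as \eqn{H = U (L - v I_k)^{1/2}} with \eqn{U} on the Stiefel
#' manifold of orthonormal d x k frames and \eqn{L} diagonal with \eqn{L_{ii}
#' > v}; the priors are uniform on \eqn{U},
#' \eqn{L_{ii} \sim \mathrm{InvGamma}(\alpha/2, \alpha/2)} and
#' \eqn{v \sim \mathrm{InvGamma}((\alpha/2+1)(d-k)-1, (\alpha/2)(d-k))}.
#'
#' The effective parameter dimension is the Stiefel quotient dimension plus
#' the k spectrum entries and the noise variance:
#' \eqn{m_F = dk - k(k+1)/2 + k + 1}.
#'
#' Optimization happens in an unconstrained chart: a free d x k matrix `A`
#' mapped to \eqn{U} by the sign-fixed QR factor, \eqn{\ell_i} with
#' \eqn{L_{ii} = v + e^{\ell_i}} (so the spectrum gaps stay positive), and
#' \eqn{\log v}.
#'
#' @param d data dimension.
#' @param k latent dimension, `1 <= k < d`.
#' @param alpha prior hyperparameter (default 0.1).
#' @return An object of classes `svc_ppca`, `svc_model`.
#' @export
ppca_model <- function(d, k, alpha = 0.1) {
  if (k < 1 || k >= d) stop("need 1 <= k < d")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(type = "ppca", d = d, k = k, alpha = alpha,
                 m_F = as.integer(d * k - k * (k + 1) / 2 + k + 1),
                 opt_dim = as.integer(d * k + k + 1)),
            class = c("svc_ppca", "svc_model"))
}

#' @export
param_count.svc_ppca <- function(model, r = model$d) {
  k <- model$k
  if (k >= r) stop("candidate foreground of dimension ", r,
                   " cannot hold a rank-", k, " pPCA model")
  as.integer(r * k - k * (k + 1) / 2 + k + 1)
}

# theta = c(vec(A), ell[1:k], log v); U = qf(A), L_ii = v + exp(ell_i).
ppca_unpack <- function(model, theta) {
  d <- model$d; k <- model$k
  A <- matrix(theta[seq_len(d * k)], d, k)
  ell <- theta[d * k + seq_len(k)]
  v <- exp(theta[d * k + k + 1])
  U <- qf_orth(A)
  L <- v + exp(ell)
  C <- U %*% (diag(L - v, k) %*% t(U)) + diag(v, d)
  list(U = U, L = L, v = v, C = C)
}

ppca_pack <- function(model, U, L, v) {
  if (any(L - v <= 0)) stop("require L_ii > v")
  c(as.numeric(U), log(L - v), log(v))
}

# C^{-1} via the spectral form: C^{-1} = U diag(1/L) U' + (1/v)(I - U U').
ppca_cov_inv <- function(p) {
  d <- nrow(p$U)
  UU <- p$U %*% t(p$U)
  p$U %*% (diag(1 / p$L, length(p$L)) %*% t(p$U)) + (diag(d) - UU) / p$v
}

#' @export
model_score.svc_ppca <- function(model, theta = NULL) {
  if (is.null(theta)) stop("theta required")
  p <- ppca_unpack(model, theta)
  M <- -ppca_cov_inv(p)
  function(X) as.matrix(X) %*% M
}

log_stiefel_volume <- function(d, k) {
  sum(log(2) + (d - seq_len(k) + 1) / 2 * log(pi) -
        lgamma((d - seq_len(k) + 1) / 2))
}

dinvgamma_log <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x

#' @export
prior_logpdf.svc_ppca <- function(model, theta) {
  p <- ppca_unpack(model, theta)
  a <- model$alpha; d <- model$d; k <- model$k
  ell <- theta[d * k + seq_len(k)]
  lv <- theta[d * k + k + 1]
  -log_stiefel_volume(d, k) +
    sum(dinvgamma_log(p$L, a / 2, a / 2)) + sum(ell) +    # L_ii, gap log-Jacobian
    dinvgamma_log(p$v, (a / 2 + 1) * (d - k) - 1, (a / 2) * (d - k)) + lv
}

# Spectral initializer: top-k eigenpairs of the sample covariance, trailing
# eigenvalues pooled into the noise variance.
ppca_init <- function(model, X) {
  d <- model$d; k <- model$k
  eg <- eigen(stats::cov(as.matrix(X)), symmetric = TRUE)
  v0 <- max(mean(eg$values[(k + 1):d]), 1e-3)
  L0 <- pmax(eg$values[seq_len(k)], v0 * 1.05)
  ppca_pack(model, eg$vectors[, seq_len(k), drop = FALSE], L0, v0)
}
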