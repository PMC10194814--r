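#' Continuous-relaxation spin glass model of gene regulation
#'
#' An energy-based model in which each gene j of a cell is a softened two-state
#' spin: \eqn{z_{j1}(x_j) = 1/(1 + e^{-\tau (x_j - \mu)})},
#' \eqn{z_{j2} = 1 - z_{j1}}, with unnormalized log density
#' \deqn{\sum_j H_j^\top z_j + \sum_{j' > j} z_j^\top J_{jj'} z_{j'}.}
#' The fields \eqn{H_j \in R^2}, couplings \eqn{J_{jj'} \in R^{2\times 2}}
#' (stored only for \eqn{j' > j}), threshold \eqn{\mu} and sharpness
#' \eqn{\tau > 0} are unknown. The normalizing constant is intractable, but
#' the model score — all that NKSD-based inference needs — does not involve
#' it: adding any constant to the log density leaves the score bit-identical.
#'
#' Priors: independent normals on the entries of H (sd `h_sd`), Laplace on the
#' entries of J (scale `j_scale`, encouraging sparse interactions), normals on
#' \eqn{\mu} and on \eqn{\log\tau}. The parameter count is
#' \eqn{m_F = 2d + 4 d(d-1)/2 + 2}.
#'
#' @param d number of genes (data dimensions), `d >= 2`.
#' @param h_sd,j_scale,mu_sd,tau_sd prior scales (defaults 1; the prior
#'   families follow the application literature, the scales are this package's
#'   defaults).
#' @return An object of classes `svc_glass`, `svc_model`.
#' @export
glass_model <- function(d, h_sd = 1, j_scale = 1, mu_sd = 1, tau_sd = 1) {
  if (d < 2) stop("need d >= 2")
  structure(list(type = "glass", d = d, h_sd = h_sd, j_scale = j_scale,
                 mu_sd = mu_sd, tau_sd = tau_sd,
                 m_F = as.integer(2 * d + 4 * d * (d - 1) / 2 + 2),
                 opt_dim = as.integer(2 * d + 4 * d * (d - 1) / 2 + 2)),
            class = c("svc_glass", "svc_model"))
}

#' @export
param_count.svc_glass <- function(model, r = model$d) {
  as.integer(2 * r + 4 * r * (r - 1) / 2 + 2)
}

# theta = c(vec(H: d x 2), J entries for pairs j < j' (4 each, column-major),
#           mu, log tau)
glass_unpack <- function(model, theta) {
  d <- model$d
  H <- matrix(theta[seq_len(2 * d)], d, 2)
  npairs <- d * (d - 1) / 2
  Jflat <- theta[2 * d + seq_len(4 * npairs)]
  J <- vector("list", npairs)
  pair_index <- glass_pairs(d)
  for (p in seq_len(npairs))
    J[[p]] <- matrix(Jflat[4 * (p - 1) + 1:4], 2, 2)
  mu <- theta[2 * d + 4 * npairs + 1]
  tau <- exp(theta[2 * d + 4 * npairs + 2])
  list(H = H, J = J, pairs = pair_index, mu = mu, tau = tau)
}

glass_pairs <- function(d) {
  idx <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE] # (j, j') with j < j'
}

# 2x2 coupling of gene a on gene b, respecting the j < j' storage convention:
# contribution of z_b to the field felt by z_a.
glass_coupling <- function(par, a, b) {
  d <- nrow(par$H)
  if (a < b) p <- which(par$pairs[, 1] == a & par$pairs[, 2] == b)
  else p <- which(par$pairs[, 1] == b & par$pairs[, 2] == a)
  J <- par$J[[p]]
  if (a < b) J else t(J)
}

# Unnormalized log density, vectorized over rows of X.
glass_logdens <- function(model, theta, X) {
  par <- glass_unpack(model, theta)
  X <- as.matrix(X)
  z1 <- stats::plogis(par$tau * (X - par$mu))
  out <- numeric(nrow(X))
  for (j in seq_len(model$d))
    out <- out + par$H[j, 1] * z1[, j] + par$H[j, 2] * (1 - z1[, j])
  for (p in seq_len(nrow(par$pairs))) {
    a <- par$pairs[p, 1]; b <- par$pairs[p, 2]
    J <- par$J[[p]]
    za <- cbind(z1[, a], 1 - z1[, a])
    zb <- cbind(z1[, b], 1 - z1[, b])
    out <- out + rowSums((za %*% J) * zb)
  }
  out
}

#' @export
model_score.svc_glass <- function(model, theta = NULL) {
  if (is.null(theta)) stop("theta required")
  par <- glass_unpack(model, theta)
  d <- model$d
  function(X) {
    X <- as.matrix(X)
    z1 <- stats::plogis(par$tau * (X - par$mu))
    dz <- par$tau * z1 * (1 - z1) # d z_{j1} / d x_j; d z_{j2}/d x_j = -dz
    S <- matrix(0, nrow(X), d)
    for (j in seq_len(d)) {
      a1 <- rep(par$H[j, 1], nrow(X))
      a2 <- rep(par$H[j, 2], nrow(X))
      for (l in seq_len(d)) {
        if (l == j) next
        Jjl <- glass_coupling(par, j, l)
        zl <- cbind(z1[, l], 1 - z1[, l])
        a1 <- a1 + zl %*% Jjl[1, ]
        a2 <- a2 + zl %*% Jjl[2, ]
      }
      S[, j] <- dz[, j] * (a1 - a2)
    }
    S
  }
}

#' @export
prior_logpdf.svc_glass <- function(model, theta) {
  d <- model$d
  npairs <- d * (d - 1) / 2
  H <- theta[seq_len(2 * d)]
  Jflat <- theta[2 * d + seq_len(4 * npairs)]
  mu <- theta[2 * d + 4 * npairs + 1]
  ltau <- theta[2 * d + 4 * npairs + 2]
  sum(stats::dnorm(H, 0, model$h_sd, log = TRUE)) +
    sum(-abs(Jflat) / model$j_scale - log(2 * model$j_scale)) +
    stats::dnorm(mu, 0, model$mu_sd, log = TRUE) +
    stats::dnorm(ltau, 0, model$tau_sd, log = TRUE)
}

#' Interaction energy of a 2x2 coupling block
#'
#' \eqn{\Delta E = J_{21} + J_{12} - J_{22} - J_{11}}: the total energy
#' difference between two genes being in the same state versus opposite
#' states. Positive values favor aligned expression. The four coefficients sum
#' to zero, so a constant shift of the block leaves it unchanged.
#'
#' @param J_block a 2 x 2 matrix.
#' @return Scalar interaction energy.
#' @export
delta_energy <- function(J_block) {
  J_block <- as.matrix(J_block)
  if (!all(dim(J_block) == c(2, 2))) stop("J_block must be 2 x 2")
  J_block[2, 1] + J_block[1, 2] - J_block[2, 2] - J_block[1, 1]
}

#' Matrix of pairwise interaction energies for a glass model fit
#'
#' @param model an `svc_glass` model.
#' @param theta parameter vector.
#' @return Symmetric d x d matrix with zero diagonal; entry (j, j') is
#'   [delta_energy()] of the coupling block between genes j and j'.
#' @export
delta_energy_matrix <- function(model, theta) {
  par <- glass_unpack(model, theta)
  d <- model$d
  DE <- matrix(0, d, d)
  for (p in seq_len(nrow(par$pairs))) {
    a <- par$pairs[p, 1]; b <- par$pairs[p, 2]
    # Delta E is invariant under transposition of the block
    DE[a, b] <- DE[b, a] <- delta_energy(par$J[[p]])
  }
  DE
}
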