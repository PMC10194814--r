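#' Stein u-function for a pair of points
#'
#' Evaluates
#' \deqn{u(x,y) = s_q(x)^\top s_q(y) k(x,y) + s_q(x)^\top \nabla_y k(x,y) +
#'   s_q(y)^\top \nabla_x k(x,y) + \mathrm{tr}\,\nabla_x \nabla_y^\top k(x,y),}
#' the kernelized Stein operator applied twice to the kernel. Only the score
#' \eqn{s_q = \nabla_x \log q} of the model enters, never the score of the
#' data distribution, and additive constants in \eqn{\log q} (normalizing
#' constants) cancel exactly.
#'
#' @param x,y points in R^d.
#' @param score a score function: `function(X)` mapping an N x d matrix to the
#'   N x d matrix of gradients of the model log density.
#' @param spec a resolved [kernel_spec()].
#' @return Scalar u(x, y); symmetric in its arguments.
#' @export
stein_u_term <- function(x, y, score, spec) {
  sx <- drop(score(matrix(x, nrow = 1)))
  sy <- drop(score(matrix(y, nrow = 1)))
  if (any(!is.finite(sx)) || any(!is.finite(sy)))
    stop("score function returned non-finite values")
  kd <- kernel_derivatives(x, y, spec)
  k <- kernel_eval(x, y, spec)
  sum(sx * sy) * k + sum(sx * kd$grad_y) + sum(sy * kd$grad_x) + kd$cross_trace
}

#' U-statistic estimate of the normalized kernelized Stein discrepancy
#'
#' Estimates \eqn{\mathrm{NKSD}(p \| q)} from samples of \eqn{p} as
#' \deqn{\widehat{\mathrm{NKSD}} = \frac{\sum_{i \ne j} u(X_i, X_j)}
#'   {\sum_{i \ne j} k(X_i, X_j)},}
#' a ratio of U-statistics. The denominator normalizes the classical KSD so
#' values are comparable across data spaces of different dimension. For a
#' single observation the estimate is defined to be 0 (with a warning), so
#' selection loops that hit tiny strata degrade gracefully.
#'
#' @param X numeric data matrix (N x d); a vector is treated as N x 1.
#' @param score model score function as in [stein_u_term()].
#' @param spec a resolved [kernel_spec()].
#' @return Object of class `nksd_estimate`: list with `value`, `numerator`,
#'   `denominator`, `n`.
#' @examples
#' sp <- kernel_spec("rbf", 1)
#' std_normal <- function(X) -X
#' nksd_ustat(matrix(c(0, 1)), std_normal, sp)$value  # exactly -1
#' @export
nksd_ustat <- function(X, score, spec) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty data matrix")
  check_resolved(spec)
  if (nrow(X) == 1) {
    warning("N = 1: NKSD estimate defined as 0 by convention")
    return(structure(list(value = 0, numerator = 0, denominator = 0, n = 1L),
                     class = "nksd_estimate"))
  }
  S <- score(X)
  S <- matrix(S, nrow = nrow(X))
  if (any(!is.finite(S))) {
    bad <- which(rowSums(!is.finite(S)) > 0)
    stop("score function returned non-finite values at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  sums <- cpp_nksd_sums(X, S, spec$bandwidth^2, family_code(spec),
                        block_ids(spec, ncol(X)))
  if (sums$bad_i > 0)
    stop("non-finite pair term at observation pair (", sums$bad_i, ", ",
         sums$bad_j, ")")
  structure(list(value = sums$num / sums$den, numerator = sums$num,
                 denominator = sums$den, n = nrow(X)),
            class = "nksd_estimate")
}

#' @export
print.nksd_estimate <- function(x, ...) {
  cat("NKSD U-statistic estimate:", format(x$value, digits = 6),
      "(n =", x$n, ")\n")
  invisible(x)
}

#' Monte-Carlo oracle for the population NKSD
#'
#' Estimates the population NKSD from its definitional form
#' \deqn{\mathrm{NKSD}(p\|q) = \frac{E[(s_q - s_p)(X)^\top (s_q - s_p)(Y)\,
#'   k(X,Y)]}{E[k(X,Y)]}}
#' using independent pairs \eqn{(X_t, Y_t) \sim p \times p}. This requires the
#' data-distribution score \eqn{s_p} and therefore exists for testing and
#' simulation-oracle use only; production estimation goes through
#' [nksd_ustat()], which does not involve \eqn{s_p}.
#'
#' @param p_sampler `function(n)` drawing n rows from p (uses the current RNG
#'   state; the seed is set internally).
#' @param p_score,q_score score functions of p and q.
#' @param spec resolved [kernel_spec()].
#' @param n_mc number of Monte-Carlo pairs (>= 2).
#' @param seed integer seed.
#' @return List with `value`, `se` (delta-method standard error), `n_mc`.
#' @export
nksd_population_mc <- function(p_sampler, p_score, q_score, spec,
                               n_mc = 20000L, seed = 1L) {
  if (n_mc < 2) stop("n_mc must be at least 2")
  check_resolved(spec)
  withr::with_seed(seed, {
    X <- as.matrix(p_sampler(n_mc))
    Y <- as.matrix(p_sampler(n_mc))
  })
  dX <- q_score(X) - p_score(X)
  dY <- q_score(Y) - p_score(Y)
  ids <- block_ids(spec, ncol(X))
  h2 <- spec$bandwidth^2
  k <- rep(1, n_mc)
  for (b in unique(ids)) {
    sel <- which(ids == b)
    r2 <- rowSums((X[, sel, drop = FALSE] - Y[, sel, drop = FALSE])^2)
    k <- k * kblock(r2, h2, spec$family)$k
  }
  w <- rowSums(dX * dY) * k
  num <- mean(w)
  den <- mean(k)
  value <- num / den
  # delta method for the ratio of means on paired draws
  resid <- w - value * k
  se <- stats::sd(resid) / sqrt(n_mc) / den
  list(value = value, se = se, n_mc = n_mc)
}

#' Exponential-family quadratic form of the NKSD estimate
#'
#' For a model density \eqn{q(x|\theta) = \lambda(x) \exp(\theta^\top t(x) -
#' \kappa(\theta))} the score is affine in \eqn{\theta}, so the NKSD
#' U-statistic is exactly quadratic:
#' \eqn{\widehat{\mathrm{NKSD}}(\theta) = \theta^\top A \theta + B^\top\theta
#' + C}. This function accumulates the pairwise sums once and returns
#' \eqn{(A, B, C)}, enabling closed-form Stein volume criteria against
#' Gaussian priors and instant re-evaluation at any \eqn{\theta}.
#'
#' @param X data matrix (N x d), N >= 2.
#' @param t_jacobian either a constant m x d matrix (sufficient-statistic
#'   Jacobian independent of x) or a `function(X)` returning an m x d x N
#'   array of per-observation Jacobians \eqn{\nabla_x t(x)}.
#' @param logbase_grad `function(X)` returning the N x d matrix of
#'   \eqn{\nabla_x \log\lambda(x)}.
#' @param spec resolved [kernel_spec()].
#' @return List with symmetric matrix `A` (m x m), vector `B`, scalar `C`,
#'   and the kernel-sum `denominator`.
#' @export
expfam_quadratic <- function(X, t_jacobian, logbase_grad, spec) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need N >= 2")
  check_resolved(spec)
  d <- ncol(X)
  G <- logbase_grad(X)
  G <- matrix(G, nrow = nrow(X))
  if (ncol(G) != d) stop("logbase_grad must return an N x d matrix")
  if (is.function(t_jacobian)) {
    Tarr <- t_jacobian(X)
    if (length(dim(Tarr)) != 3 || dim(Tarr)[2] != d || dim(Tarr)[3] != nrow(X))
      stop("t_jacobian(X) must return an m x d x N array")
    t_const <- FALSE
  } else {
    Tm <- as.matrix(t_jacobian)
    if (ncol(Tm) != d) stop("t_jacobian matrix must be m x d")
    Tarr <- array(Tm, dim = c(nrow(Tm), d, 1))
    t_const <- TRUE
  }
  s <- cpp_expfam_sums(X, Tarr, G, spec$bandwidth^2, family_code(spec),
                       block_ids(spec, d), t_const)
  A <- s$Asum / s$den
  list(A = (A + t(A)) / 2, B = as.numeric(s$Bsum) / s$den, C = s$Csum / s$den,
       denominator = s$den)
}

# Pair statistics for linear-score models (s(x) = M x, M symmetric); the NKSD
# estimate is then nksd_from_linstats(M, st). Shared by the Gaussian and pPCA
# objectives so that optimizer iterations cost O(d^2), not O(N^2).
linear_score_stats <- function(X, spec) {
  X <- as.matrix(X)
  check_resolved(spec)
  st <- cpp_linear_stats(X, spec$bandwidth^2, family_code(spec),
                         block_ids(spec, ncol(X)))
  st$P <- (st$P + t(st$P)) / 2
  st
}

nksd_from_linstats <- function(M, st) {
  (sum((M %*% M) * st$P) + 2 * sum(M * st$Q) + st$K0) / st$den
}
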