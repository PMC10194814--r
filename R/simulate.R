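#' Bivariate Gaussian toy data
#'
#' Draws N i.i.d. observations from \eqn{N((0,0)^\top, \Sigma_0)}, the data
#' generator behind the consistency toy benchmarks (a diagonal
#' \eqn{\Sigma_0 = \mathrm{diag}(1, 1/2)} makes a unit-covariance location
#' model misspecified on the second coordinate only).
#'
#' @param N sample size.
#' @param sigma0 2 x 2 (or d x d) SPD covariance.
#' @param seed integer seed.
#' @return N x d matrix.
#' @export
gen_toy <- function(N, sigma0 = diag(c(1, 0.5)), seed = 1L) {
  sigma0 <- as.matrix(sigma0)
  ch <- tryCatch(chol(sigma0), error = function(e) stop("sigma0 must be SPD"))
  d <- ncol(sigma0)
  withr::with_seed(seed, matrix(rnorm(N * d), N, d) %*% ch)
}

#' Probabilistic PCA misspecification benchmark
#'
#' Generates N observations in 6 dimensions. Dimensions 1-4 follow a
#' well-specified pPCA model with k = 2, unit noise variance and factor
#' matrix
#' \deqn{H = \begin{pmatrix} 1 & 0 \\ -1 & 1 \\ 0 & 1 \\ -1 & -1
#'   \end{pmatrix}.}
#' Dimensions 5-6 are misspecified: with a fair Bernoulli switch \eqn{W},
#' scenario `"A"` draws them from \eqn{N(0, 0.05^W I_2)} (a scale mixture;
#' marginals are visibly non-Gaussian), while scenario `"B"` draws them from
#' a unit-variance Gaussian whose correlation is \eqn{\pm 0.99} with sign
#' \eqn{(-1)^W} — the marginals stay exactly Gaussian and only the
#' dependence structure is wrong, the harder case.
#'
#' @param N sample size.
#' @param scenario `"A"` or `"B"`.
#' @param seed integer seed.
#' @return List with `X` (N x 6 matrix) and `misspecified = c(5, 6)` (ground
#'   truth by construction).
#' @export
gen_ppca_sim <- function(N, scenario = c("A", "B"), seed = 1L) {
  scenario <- match.arg(scenario)
  H <- matrix(c(1, -1, 0, -1,
                0, 1, 1, -1), 4, 2)
  withr::with_seed(seed, {
    Z <- matrix(rnorm(N * 2), N, 2)
    X14 <- Z %*% t(H) + matrix(rnorm(N * 4), N, 4)
    W <- rbinom(N, 1, 0.5)
    E <- matrix(rnorm(N * 2), N, 2)
    if (scenario == "A") {
      s <- sqrt(0.05)^W        # sd = sqrt(0.05^W)
      X56 <- E * s
    } else {
      rho <- 0.99 * (-1)^W
      # chol of [[1, rho], [rho, 1]] applied rowwise
      X56 <- cbind(E[, 1], rho * E[, 1] + sqrt(1 - rho^2) * E[, 2])
    }
    X <- cbind(X14, X56)
  })
  colnames(X) <- paste0("dim", 1:6)
  list(X = X, misspecified = c(5L, 6L), scenario = scenario, seed = seed)
}

#' Sample from the spin glass model by Metropolis MCMC
#'
#' Random-walk Metropolis targeting the unnormalized glass density, with
#' per-coordinate Gaussian proposals whose step sizes adapt toward a 0.3
#' acceptance rate during burn-in only (frozen afterwards, so the retained
#' draws are valid MCMC).
#'
#' Because the spin functions are bounded, the glass energy is bounded and
#' the density is improper on all of R^d; the sampler therefore targets its
#' truncation to the box `[-bound, bound]^d` (proposals outside are
#' rejected). Truncation does not change the model score anywhere on the
#' support, so samples remain well-specified for score-based inference.
#'
#' @param N number of retained draws.
#' @param model an `svc_glass` model (defines d and the density family).
#' @param theta glass parameter vector.
#' @param n_burn burn-in sweeps.
#' @param n_thin thinning interval.
#' @param seed integer seed.
#' @param bound half-width of the box support.
#' @return N x d matrix; the realized post-burn-in acceptance rate is
#'   attached as attribute `acceptance`.
#' @export
gen_glass <- function(N, model, theta, n_burn = 500L, n_thin = 5L,
                      seed = 1L, bound = 6) {
  d <- model$d
  logd <- function(x) glass_logdens(model, theta, matrix(x, nrow = 1))
  withr::with_seed(seed, {
    x <- rnorm(d)
    step <- rep(1, d)
    lp <- logd(x)
    acc <- att <- 0
    out <- matrix(0, N, d)
    total <- n_burn + N * n_thin
    kept <- 0
    for (it in seq_len(total)) {
      for (j in seq_len(d)) {
        xp <- x
        xp[j] <- x[j] + step[j] * rnorm(1)
        lpp <- if (abs(xp[j]) > bound) -Inf else logd(xp)
        if (log(runif(1)) < lpp - lp) {
          x <- xp; lp <- lpp
          if (it > n_burn) acc <- acc + 1
          if (it <= n_burn) step[j] <- step[j] * 1.05
        } else {
          if (it <= n_burn) step[j] <- step[j] * 0.975
        }
        if (it > n_burn) att <- att + 1
      }
      if (it > n_burn && (it - n_burn) %% n_thin == 0) {
        kept <- kept + 1
        out[kept, ] <- x
      }
    }
  })
  attr(out, "acceptance") <- acc / max(att, 1)
  out
}

#' Balanced accuracy of exclusion decisions
#'
#' \eqn{(TN/N + TP/P)/2}, treating "exclude" as the positive class: TP counts
#' truly misspecified dimensions that were excluded, TN counts well-specified
#' dimensions that were included.
#'
#' @param decisions character (`"include"`/`"exclude"`) or logical
#'   (TRUE = exclude) vector over dimensions.
#' @param truth logical vector (TRUE = truly misspecified) or integer indices
#'   of misspecified dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(decisions, truth) {
  if (is.character(decisions)) decisions <- decisions == "exclude"
  if (is.numeric(truth)) truth <- seq_along(decisions) %in% truth
  if (length(decisions) != length(truth)) stop("length mismatch")
  P <- sum(truth); Ng <- sum(!truth)
  if (P == 0 || Ng == 0) stop("truth must contain at least one positive and ",
                              "one negative")
  TP <- sum(decisions & truth)
  TN <- sum(!decisions & !truth)
  (TN / Ng + TP / P) / 2
}
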