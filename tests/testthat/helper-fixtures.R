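# Shared fixtures and small oracles used across the suite.

rbf1 <- kernel_spec("rbf", 1)
std_normal_score <- function(X) -X

# Exact SVC of a (possibly fixed-parameter) Gaussian candidate via the
# closed-form quadratic; returns the full result object.
exact_gaussian_svc <- function(model, X, spec, cols = NULL, r_b = 0, T = 5,
                               pol = background_policy("constant",
                                                       m_const = 5)) {
  obj <- svc_objective(model, X, spec, cols = cols)
  act <- obj$active
  N <- nrow(X)
  m_B <- background_dim(pol, r_b, N)
  if (length(act) == 0) {
    quad <- list(A = matrix(0, 0, 0), B = numeric(0), C = obj$fn(numeric(0)))
    return(svc_exact_quadratic(quad, numeric(0), 1, T, N, m_B, spec, pol))
  }
  quad <- list(A = obj$quad$A[act, act, drop = FALSE], B = obj$quad$B[act],
               C = obj$quad$C)
  svc_exact_quadratic(quad, model$prior_mean[act], model$prior_var, T, N,
                      m_B, spec, pol)
}

# Central finite-difference gradient oracle for kernel derivative checks.
fd_kernel_grad <- function(x, y, spec, eps = 1e-6) {
  d <- length(x)
  gx <- gy <- numeric(d)
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- eps
    gx[i] <- (kernel_eval(x + e, y, spec) - kernel_eval(x - e, y, spec)) /
      (2 * eps)
    gy[i] <- (kernel_eval(x, y + e, spec) - kernel_eval(x, y - e, spec)) /
      (2 * eps)
  }
  list(grad_x = gx, grad_y = gy)
}

# Finite-difference mixed-derivative trace oracle.
fd_kernel_cross_trace <- function(x, y, spec, eps = 1e-4) {
  d <- length(x)
  tr <- 0
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- eps
    tr <- tr + (kernel_eval(x + e, y + e, spec) -
                kernel_eval(x + e, y - e, spec) -
                kernel_eval(x - e, y + e, spec) +
                kernel_eval(x - e, y - e, spec)) / (4 * eps^2)
  }
  tr
}

# A small well-specified pPCA data set (d = 4, k = 2). The second factor
# column is scaled so the population spectrum (4, 2.08, 1, 1) is distinct:
# sorted eigenvalue estimates of a tied spectrum are order-biased for any
# consistent estimator, which would confound a recovery study.
ppca4_H <- matrix(c(1, -1, 0, -1, 0, 1, 1, -1), 4, 2) %*% diag(c(1, 0.6))
gen_ppca4 <- function(N, seed) {
  withr::with_seed(seed, {
    matrix(rnorm(N * 2), N, 2) %*% t(ppca4_H) + matrix(rnorm(N * 4), N, 4)
  })
}

glass_theta <- function(model, H = NULL, J = NULL, mu = 0, tau = 1) {
  d <- model$d
  npairs <- d * (d - 1) / 2
  th <- numeric(model$opt_dim)
  if (!is.null(H)) th[seq_len(2 * d)] <- as.numeric(H)
  if (!is.null(J)) th[2 * d + seq_len(4 * npairs)] <- as.numeric(J)
  th[model$opt_dim - 1] <- mu
  th[model$opt_dim] <- log(tau)
  th
}

# steinvc's compare() masks an older testthat generic of the same name;
# bind it explicitly for the test environment.
compare <- steinvc::compare
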