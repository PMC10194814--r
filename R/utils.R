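#' @keywords internal
"_PACKAGE"

#' @useDynLib steinvc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif rbinom cov dist median var sd integrate
#'   setNames dnorm qnorm plogis cor lm coef quantile
#' @importFrom utils read.table write.table head modifyList
NULL

# Stable log-determinant of a symmetric positive definite matrix.
logdet_spd <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) stop("matrix is not positive definite")
  2 * sum(log(diag(ch)))
}

# Symmetrize, then solve with escalating jitter. Used for Hessians of NKSD
# objectives, which can be numerically indefinite or (for gauge-invariant
# parameterizations) singular along flat directions.
jitter_solve <- function(H, b, max_tries = 4L) {
  H <- (H + t(H)) / 2
  scale <- 1 + max(abs(diag(H)))
  jit <- 0
  for (t in seq_len(max_tries)) {
    ch <- tryCatch(chol(H + diag(jit, nrow(H))), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(x = backsolve(ch, forwardsolve(t(ch), b)), jitter = jit))
    }
    jit <- if (jit == 0) 1e-8 * scale else jit * 100
  }
  stop("Hessian remains singular/indefinite after jitter escalation; ",
       "exact re-optimization is advised")
}

# Deterministic fingerprint of a configuration list (content-addressed via
# canonical deparse + md5 of a temporary file; no data values are hashed).
config_fingerprint <- function(cfg) {
  txt <- paste(deparse(cfg, control = c("keepNA", "keepInteger", "niceNames",
                                        "showAttributes")), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

# Central finite-difference gradient (objectives here are cheap closed forms
# over precomputed pair statistics, so FD is both fast and accurate).
fd_grad <- function(fn, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- eps
    g[i] <- (fn(x + e) - fn(x - e)) / (2 * eps)
  }
  g
}

# Central finite-difference Hessian, symmetrized.
fd_hess <- function(fn, x, eps = 1e-4) {
  m <- length(x)
  H <- matrix(0, m, m)
  f0 <- fn(x)
  for (i in seq_len(m)) {
    ei <- numeric(m); ei[i] <- eps
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / eps^2
    if (i < m) for (j in seq((i + 1), m)) {
      ej <- numeric(m); ej[j] <- eps
      H[i, j] <- (fn(x + ei + ej) - fn(x + ei - ej) -
                  fn(x - ei + ej) + fn(x - ei - ej)) / (4 * eps^2)
      H[j, i] <- H[i, j]
    }
  }
  (H + t(H)) / 2
}

# Orthonormal factor of the thin QR decomposition with positive diagonal R,
# so the map A -> qf(A) is a smooth chart onto the Stiefel manifold.
qf_orth <- function(A) {
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  R <- qr.R(qr_)
  s <- sign(diag(R))
  s[s == 0] <- 1
  Q * rep(s, each = nrow(Q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
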