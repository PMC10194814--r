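#' Build the NKSD objective of a model on a candidate foreground
#'
#' Constructs the function \eqn{\theta \mapsto \widehat{\mathrm{NKSD}}} for
#' the model restricted to the foreground columns `cols` (all columns by
#' default), with the O(N^2) pairwise statistics precomputed once so that
#' optimizer iterations are cheap. For the Gaussian and pPCA families the
#' candidate model is the marginal of the full model, so the objective is a
#' function of the *full* parameter vector; this shared parameterization is
#' what makes the fast approximate-optimum transfer across candidates well
#' defined. For the glass model a column subset defines a sub-glass with its
#' own parameters, so transfer is not available and candidates are refit.
#'
#' @param model an `svc_model`.
#' @param X data matrix.
#' @param spec resolved [kernel_spec()].
#' @param cols foreground column subset (default all).
#' @return List with `fn` (the objective), `quad` (A/B/C for
#'   exponential-family models, else NULL), `active` (identified parameter
#'   indices), `m_F`, `opt_dim`, `init` (seeded initializer), `transfer_ok`,
#'   and `model` (the model whose parameter space `fn` uses).
#' @export
svc_objective <- function(model, X, spec, cols = NULL) {
  UseMethod("svc_objective")
}

#' @export
svc_objective.svc_gaussian <- function(model, X, spec, cols = NULL) {
  X <- as.matrix(X)
  d <- model$d
  cols <- cols %||% seq_len(d)
  Xs <- X[, cols, drop = FALSE]
  Kss <- solve(model$cov[cols, cols, drop = FALSE])
  quad_s <- expfam_quadratic(Xs, Kss, function(Z) -Z %*% Kss, spec)
  # embed the |cols|-dim quadratic into the full mean space
  A <- matrix(0, d, d); B <- numeric(d)
  A[cols, cols] <- quad_s$A
  B[cols] <- quad_s$B
  quad <- list(A = A, B = B, C = quad_s$C)
  fixed_mean <- model$prior_mean
  fn <- function(theta) {
    th <- if (model$mean_free) as.numeric(theta) else fixed_mean
    sum(th * (A %*% th)) + sum(B * th) + quad$C
  }
  active <- if (model$mean_free) cols else integer(0)
  list(model = model, fn = fn, quad = quad, active = active,
       m_F = param_count(model, length(cols)), cols = cols,
       opt_dim = model$opt_dim, transfer_ok = TRUE,
       init = function(seed) rep(0, model$opt_dim))
}

#' @export
svc_objective.svc_ppca <- function(model, X, spec, cols = NULL) {
  X <- as.matrix(X)
  cols <- cols %||% seq_len(model$d)
  st <- linear_score_stats(X[, cols, drop = FALSE], spec)
  fn <- function(theta) {
    p <- ppca_unpack(model, theta)
    Cs <- p$C[cols, cols, drop = FALSE]
    M <- -solve(Cs)
    nksd_from_linstats(M, st)
  }
  list(model = model, fn = fn, quad = NULL, active = seq_len(model$opt_dim),
       m_F = param_count(model, length(cols)), cols = cols,
       opt_dim = model$opt_dim, transfer_ok = TRUE,
       init = function(seed) {
         base <- ppca_init(model, X)
         if (seed <= 1) base
         else withr::with_seed(seed, base + rnorm(length(base), sd = 0.1))
       })
}

#' @export
svc_objective.svc_glass <- function(model, X, spec, cols = NULL) {
  X <- as.matrix(X)
  cols <- cols %||% seq_len(model$d)
  sub <- if (length(cols) == model$d) model
         else glass_model(length(cols), model$h_sd, model$j_scale,
                          model$mu_sd, model$tau_sd)
  Xs <- X[, cols, drop = FALSE]
  fn <- function(theta) {
    nksd_ustat(Xs, model_score(sub, theta), spec)$value
  }
  list(model = sub, fn = fn, quad = NULL, active = seq_len(sub$opt_dim),
       m_F = param_count(model, length(cols)), cols = cols,
       opt_dim = sub$opt_dim, transfer_ok = FALSE,
       init = function(seed) {
         withr::with_seed(seed, rnorm(sub$opt_dim, sd = 0.1))
       })
}

#' Minimum Stein discrepancy estimation
#'
#' Finds \eqn{\hat\theta = \arg\min_\theta \widehat{\mathrm{NKSD}}(\theta)},
#' the minimum Stein discrepancy estimator, in the model's unconstrained
#' parameter space. Exponential-family models are solved in closed form (the
#' vertex of the quadratic); other models use multi-start BFGS with seeded
#' restarts, keeping the best optimum. The returned Hessian is
#' \eqn{\nabla^2_\theta \widehat{\mathrm{NKSD}}} at the optimum, symmetrized
#' (analytic \eqn{2A} for exponential families, central finite differences
#' otherwise).
#'
#' @param model an `svc_model`.
#' @param X data matrix, N >= 2.
#' @param spec resolved [kernel_spec()].
#' @param init `"default"` for the model's initializer, or a numeric vector.
#' @param seed integer seed for restarts.
#' @param restarts number of seeded restarts for non-quadratic models.
#' @param obj optionally, a prebuilt objective from internal machinery (saves
#'   recomputing pair statistics).
#' @return List with `theta` (unconstrained optimum), `value` (minimum NKSD
#'   estimate), `hessian`, `converged` (gradient norm below 1e-6), `grad_norm`.
#' @export
fit_min_nksd <- function(model, X, spec, init = "default", seed = 1L,
                         restarts = 5L, obj = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need N >= 2")
  if (is.null(obj)) obj <- svc_objective(model, X, spec)
  if (!is.null(obj$quad) && length(obj$active) > 0) {
    A <- obj$quad$A[obj$active, obj$active, drop = FALSE]
    B <- obj$quad$B[obj$active]
    th_act <- -0.5 * jitter_solve(A, B)$x
    theta <- numeric(length(obj$quad$B))
    theta[obj$active] <- th_act
    H <- matrix(0, length(theta), length(theta))
    H[obj$active, obj$active] <- 2 * A
    return(list(theta = theta, value = obj$fn(theta), hessian = 2 * obj$quad$A,
                converged = TRUE, grad_norm = 0))
  }
  if (!is.null(obj$quad) && length(obj$active) == 0) {
    # fixed-parameter model: nothing to optimize
    theta <- numeric(0)
    return(list(theta = theta, value = obj$fn(theta),
                hessian = matrix(0, 0, 0), converged = TRUE, grad_norm = 0))
  }
  inits <- list()
  if (is.numeric(init)) inits[[1]] <- init
  else inits[[1]] <- obj$init(1L)
  if (restarts > 1)
    for (r in 2:restarts) inits[[r]] <- obj$init(seed * 1000L + r)
  best <- NULL
  for (th0 in inits) {
    fit <- tryCatch(
      stats::optim(th0, obj$fn, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed on all restarts")
  g <- fd_grad(obj$fn, best$par)
  H <- fd_hess(obj$fn, best$par)
  list(theta = best$par, value = best$value, hessian = H,
       converged = sqrt(sum(g^2)) < 1e-6, grad_norm = sqrt(sum(g^2)))
}
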