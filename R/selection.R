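#' Foreground candidate
#'
#' A candidate foreground subspace: either an explicit subset of data columns
#' or a general projection matrix `V` with orthonormal columns. The candidate
#' data are always a projection of every observation, never a subset of rows.
#'
#' @param name label used in reports.
#' @param columns integer subset of `1:d`.
#' @param V d x r matrix with orthonormal columns (alternative to `columns`).
#' @param d total data dimension.
#' @return Object of class `svc_candidate` with fields `r_F` and `r_B`.
#' @export
foreground_candidate <- function(name, columns = NULL, V = NULL, d) {
  if (is.null(columns) == is.null(V))
    stop("supply exactly one of columns or V")
  if (!is.null(V)) {
    V <- as.matrix(V)
    if (nrow(V) != d) stop("V must have d rows")
    if (max(abs(crossprod(V) - diag(ncol(V)))) > 1e-8)
      stop("V must have orthonormal columns")
    r_F <- ncol(V)
  } else {
    columns <- as.integer(columns)
    if (length(columns) == 0) stop("columns must be nonempty (use V for the ",
                                   "empty foreground)")
    if (any(columns < 1 | columns > d) || anyDuplicated(columns))
      stop("columns must be a subset of 1:d without duplicates")
    r_F <- length(columns)
  }
  structure(list(name = name, columns = columns, V = V, r_F = r_F,
                 r_B = d - r_F, d = d),
            class = "svc_candidate")
}

#' Project data onto a candidate foreground
#'
#' @param X data matrix (N x d).
#' @param cand a [foreground_candidate()].
#' @return The N x r_F foreground data matrix (`X V` or the column subset).
#' @export
project <- function(X, cand) {
  X <- as.matrix(X)
  if (ncol(X) != cand$d) stop("data dimension does not match candidate")
  if (!is.null(cand$V)) X %*% cand$V
  else X[, cand$columns, drop = FALSE]
}

#' Compare two Stein volume criterion results
#'
#' Returns the pairwise log score ratio \eqn{\log \mathcal{K}_1 -
#' \log \mathcal{K}_2}. Comparisons are only meaningful when both results were
#' computed under the same temperature, kernel, sample size and background
#' policy; mismatches are an error, never silently ignored.
#'
#' @param result1,result2 `svc_result` objects.
#' @return Scalar log ratio; antisymmetric under argument exchange.
#' @export
compare <- function(result1, result2) {
  for (f in c("T", "N", "kernel", "policy")) {
    if (!isTRUE(all.equal(result1[[f]], result2[[f]])))
      stop("results are not comparable: configurations differ in ", f)
  }
  result1$log_svc - result2$log_svc
}

#' Transfer a minimum Stein discrepancy optimum to a nearby objective
#'
#' Given the optimum `theta0` of one NKSD objective, the first-order implicit
#' function approximation to the optimum of a second objective is
#' \deqn{\theta_2 \approx \theta_0 - [\nabla^2 \ell_1(\theta_0)]^{-1}
#'   \nabla \ell_2(\theta_0).}
#' The Hessian is symmetrized and jittered if singular; when comparing one
#' reference against many candidates, factor it once and reuse
#' (see [loo_scan()]).
#'
#' @param theta0 optimum of the reference objective.
#' @param grad2 gradient of the target objective at `theta0`.
#' @param hess1 Hessian of the reference objective at `theta0`.
#' @return The approximate optimum of the target objective.
#' @export
transfer_optimum <- function(theta0, grad2, hess1) {
  as.numeric(theta0) - as.numeric(jitter_solve(hess1, grad2)$x)
}

candidate_grad <- function(obj, theta0) {
  if (!is.null(obj$quad)) 2 * (obj$quad$A %*% theta0) + obj$quad$B
  else fd_grad(obj$fn, theta0)
}

score_candidate <- function(backend, obj, theta, value, m_F, m_B, N, T,
                            spec, policy) {
  if (backend == "bic") {
    return(svc_result("bic", -(N / T) * value, m_F / 2 * log(2 * pi / N),
                      bg_term(m_B, N), theta, m_F, m_B, N, T, spec, policy))
  }
  if (backend == "exact") {
    if (is.null(obj$quad)) stop("exact backend requires an exponential-",
                                "family model")
    act <- obj$active
    res <- svc_exact_quadratic(
      list(A = obj$quad$A[act, act, drop = FALSE], B = obj$quad$B[act],
           C = obj$quad$C),
      obj$model$prior_mean[act], obj$model$prior_var, T, N, m_B, spec, policy)
    return(res)
  }
  # laplace
  H <- if (!is.null(obj$quad)) 2 * obj$quad$A else fd_hess(obj$fn, theta)
  act <- obj$active
  Hact <- (H[act, act, drop = FALSE] + t(H[act, act, drop = FALSE])) / 2
  ld <- logdet_spd(Hact / T + diag(1e-10, nrow(Hact)))
  fg <- prior_logpdf(obj$model, theta) - 0.5 * ld + m_F / 2 * log(2 * pi / N)
  svc_result("laplace", -(N / T) * value, fg, bg_term(m_B, N), theta, m_F,
             m_B, N, T, spec, policy)
}

#' Leave-one-out data selection scan
#'
#' Compares the full foreground space against the d candidate foregrounds
#' that each exclude one data dimension, reporting the log SVC ratio
#' \eqn{\log\mathcal{K}_j - \log\mathcal{K}_0} for every dimension j. By
#' default each candidate optimum is obtained from the full-data optimum by
#' the fast first-order transfer ([transfer_optimum()]), with the reference
#' Hessian factored once; exact re-optimization per candidate is available
#' via `refit = TRUE`.
#'
#' A dimension is *included* when excluding it does not improve the score
#' (log ratio < 0; ties favor inclusion).
#'
#' @param X data matrix (N x d), d >= 2.
#' @param model an `svc_model` covering all d dimensions.
#' @param spec a [kernel_spec()]; a `"median"` bandwidth is resolved once on
#'   the full data and reused for every candidate.
#' @param T temperature.
#' @param policy a [background_policy()].
#' @param backend `"bic"`, `"laplace"` or `"exact"`.
#' @param transfer use the fast approximate-optimum transfer (default TRUE
#'   when the model supports it).
#' @param refit re-optimize each candidate exactly (overrides `transfer`).
#' @param mB_mode `"policy"`: each candidate's background is one excluded
#'   dimension under `policy`; `"param_delta"`: sets
#'   \eqn{m_{Bj} = m_{F0} - m_{Fj}}, the comparison device that isolates the
#'   fit terms.
#' @param seed integer seed (recorded; the scan itself is deterministic).
#' @return A `data.frame`-based report of class `svc_selection_report` with
#'   one row for the reference plus one per dimension, and attributes
#'   `fingerprint` and `seed`.
#' @export
loo_scan <- function(X, model, spec = kernel_spec(), T = 1,
                     policy = background_policy(), backend = c("bic",
                     "laplace", "exact"), transfer = TRUE, refit = FALSE,
                     mB_mode = c("policy", "param_delta"), seed = 1L) {
  backend <- match.arg(backend)
  mB_mode <- match.arg(mB_mode)
  X <- as.matrix(X)
  d <- ncol(X)
  if (d < 2) stop("need d >= 2")
  N <- nrow(X)
  spec <- resolve_bandwidth(X, spec, seed = seed)
  obj0 <- svc_objective(model, X, spec)
  fit0 <- fit_min_nksd(model, X, spec, seed = seed, obj = obj0)
  ref <- score_candidate(backend, obj0, fit0$theta, fit0$value, obj0$m_F,
                         0, N, T, spec, policy)
  use_transfer <- transfer && obj0$transfer_ok && !refit
  H0 <- NULL
  if (use_transfer) H0 <- (fit0$hessian + t(fit0$hessian)) / 2
  cand_names <- colnames(X) %||% paste0("dim", seq_len(d))
  rows <- data.frame(candidate = c("(full)", paste0("drop_", cand_names)),
                     log_svc = NA_real_, log_ratio = NA_real_,
                     m_F = NA_real_, m_B = NA_real_,
                     decision = NA_character_, error = NA_character_,
                     stringsAsFactors = FALSE)
  rows$log_svc[1] <- ref$log_svc
  rows$log_ratio[1] <- 0
  rows$m_F[1] <- ref$m_F
  rows$m_B[1] <- 0
  rows$decision[1] <- "reference"
  for (j in seq_len(d)) {
    res_j <- tryCatch({
      obj_j <- svc_objective(model, X, spec, cols = setdiff(seq_len(d), j))
      m_Bj <- if (mB_mode == "policy") background_dim(policy, 1, N)
              else obj0$m_F - obj_j$m_F
      if (use_transfer) {
        theta_j <- transfer_optimum(fit0$theta, candidate_grad(obj_j,
                                                               fit0$theta), H0)
        value_j <- obj_j$fn(theta_j)
      } else {
        fit_j <- fit_min_nksd(model, X, spec, seed = seed, obj = obj_j)
        theta_j <- fit_j$theta
        value_j <- fit_j$value
      }
      score_candidate(backend, obj_j, theta_j, value_j, obj_j$m_F, m_Bj, N,
                      T, spec, policy)
    }, error = function(e) e)
    if (inherits(res_j, "error")) {
      rows$error[j + 1] <- conditionMessage(res_j)
      next
    }
    rows$log_svc[j + 1] <- res_j$log_svc
    rows$log_ratio[j + 1] <- res_j$log_svc - ref$log_svc
    rows$m_F[j + 1] <- res_j$m_F
    rows$m_B[j + 1] <- res_j$m_B
    rows$decision[j + 1] <- if (rows$log_ratio[j + 1] < 0) "include"
                            else "exclude"
  }
  structure(rows, class = c("svc_selection_report", "data.frame"),
            fingerprint = config_fingerprint(list(
              backend = backend, T = T, kernel = spec, policy = policy,
              mB_mode = mB_mode, transfer = use_transfer, N = N, d = d)),
            seed = seed, reference = "(full)")
}

#' @export
print.svc_selection_report <- function(x, ...) {
  cat("Leave-one-out data selection scan (reference:",
      attr(x, "reference"), ")\n")
  df <- as.data.frame(x)
  if (all(is.na(df$error))) df$error <- NULL
  print.data.frame(df, digits = 4)
  invisible(x)
}

#' Stochastic search over foreground column subsets
#'
#' Maintains per-dimension Bernoulli inclusion logits and optimizes them by
#' REINFORCE with a leave-one-out control variate: each step samples
#' `batch >= 2` subsets, scores each by the (variational) SVC objective —
#' including the background volume term for the excluded dimensions — and
#' updates the logits with the advantage of each sample over the mean of the
#' others. Subset scores are cached, so revisits are free.
#'
#' @param X data matrix.
#' @param model an `svc_model`.
#' @param spec a [kernel_spec()].
#' @param T temperature.
#' @param policy a [background_policy()].
#' @param steps optimization steps; with `steps = 0` the inclusion
#'   probabilities remain at their 1/2 initialization.
#' @param batch subsets sampled per step (>= 2).
#' @param seed integer seed.
#' @param lr Adam learning rate on the logits.
#' @param vi_steps ascent steps per subset score.
#' @return List with `probs` (final inclusion probabilities), `included`
#'   (probability > 1/2), `best_subset` (best-scoring visited subset),
#'   `best_score`, `trace` (per-step mean scores), `n_rejected`.
#' @export
subset_search <- function(X, model, spec = kernel_spec(), T = 1,
                          policy = background_policy(), steps = 150L,
                          batch = 4L, seed = 1L, lr = 0.1, vi_steps = 200L) {
  if (batch < 2) stop("batch must be at least 2")
  X <- as.matrix(X)
  d <- ncol(X)
  N <- nrow(X)
  spec <- resolve_bandwidth(X, spec, seed = seed)
  cache <- new.env(parent = emptyenv())
  score_subset <- function(inc) {
    key <- paste0("s", paste(which(inc), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    r_b <- d - sum(inc)
    val <- if (sum(inc) == 0) {
      bg_term(background_dim(policy, r_b, N), N)
    } else {
      res <- svc_variational(model, X, spec, T = T, policy = policy,
                             r_b = r_b, steps = vi_steps, seed = seed,
                             obj = svc_objective(model, X, spec,
                                                 cols = which(inc)))
      res$log_svc
    }
    cache[[key]] <- val
    val
  }
  logits <- numeric(d)
  ad <- adam_new(d, lr)
  trace <- numeric(steps)
  best <- list(score = -Inf, subset = seq_len(d))
  n_rejected <- 0
  withr::with_seed(seed, {
    for (s in seq_len(steps)) {
      p <- stats::plogis(logits)
      incs <- lapply(seq_len(batch), function(b) runif(d) < p)
      f <- vapply(incs, function(inc) {
        tryCatch(score_subset(inc), error = function(e) NA_real_)
      }, numeric(1))
      if (any(!is.finite(f))) {
        n_rejected <- n_rejected + 1
        if (n_rejected > 20) stop("subset search aborted: repeated ",
                                  "non-finite objectives")
        next
      }
      for (b in seq_len(batch)) {
        if (f[b] > best$score) best <- list(score = f[b],
                                            subset = which(incs[[b]]))
      }
      g <- numeric(d)
      for (b in seq_len(batch)) {
        baseline <- mean(f[-b])
        g <- g + (f[b] - baseline) * (as.numeric(incs[[b]]) - p)
      }
      ad <- adam_step(ad, g / batch)
      logits <- logits + ad$delta
      trace[s] <- mean(f)
    }
  })
  probs <- stats::plogis(logits)
  list(probs = probs, included = probs > 0.5, best_subset = best$subset,
       best_score = best$score, trace = trace, n_rejected = n_rejected)
}

#' Conventional model criticism score for a candidate foreground
#'
#' The full-model criticism comparator to the log SVC ratio: the amount of
#' model-data mismatch attributed to the excluded subspace when the model is
#' fit once on all dimensions,
#' \deqn{\log\mathcal{E}_j - \log\mathcal{E}_0 = -\tfrac{N}{T}
#'   \widehat{\mathrm{NKSD}}_j(\theta_0) + \tfrac{N}{T}
#'   \widehat{\mathrm{NKSD}}_0(\theta_0),}
#' both terms evaluated at the full-data minimum Stein discrepancy estimate
#' \eqn{\theta_0} (no re-fit, no volume corrections).
#'
#' @param model an `svc_model`.
#' @param X data matrix.
#' @param cand a [foreground_candidate()] with `columns` set, or an integer
#'   vector of columns.
#' @param theta0 full-data fitted parameters (from [fit_min_nksd()]).
#' @param T temperature.
#' @param spec resolved [kernel_spec()].
#' @return Scalar criticism score (0 for the full candidate).
#' @export
criticism_score <- function(model, X, cand, theta0, T = 1,
                            spec = kernel_spec("rbf", 1)) {
  X <- as.matrix(X)
  cols <- if (inherits(cand, "svc_candidate")) {
    if (is.null(cand$columns)) stop("criticism_score needs a column-subset ",
                                    "candidate")
    cand$columns
  } else as.integer(cand)
  spec <- resolve_bandwidth(X, spec)
  N <- nrow(X)
  obj0 <- svc_objective(model, X, spec)
  if (length(cols) == ncol(X)) return(0)
  obj_j <- svc_objective(model, X, spec, cols = cols)
  -(N / T) * obj_j$fn(theta0) + (N / T) * obj0$fn(theta0)
}
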