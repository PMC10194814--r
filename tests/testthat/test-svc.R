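test_that("background dimension policies reproduce the printed thresholds", {
  py <- background_policy("pitman_yor", alpha = 0.5, nu = 1, D = 0.2)
  expect_equal(background_dim(py, 1, 2000), 20.185, tolerance = 1e-3)
  # smallest N with per-dimension value > 2 (and > 1)
  over2 <- which(sapply(1:50, function(N) background_dim(py, 1, N)) > 2)[1]
  expect_identical(over2, 20L)
  over1 <- which(sapply(1:50, function(N) background_dim(py, 1, N)) > 1)[1]
  expect_identical(over1, 5L)
  for (pol in list(py, background_policy("constant", m_const = 5),
                   background_policy("per_dim_sqrtN", c_b = 2))) {
    expect_identical(background_dim(pol, 0, 1000), 0)
  }
  expect_equal(background_dim(background_policy("per_dim_sqrtN", c_b = 2),
                              3, 400), 2 * 3 * 20)
  expect_equal(background_dim(background_policy("constant", m_const = 5),
                              2, 99), 10)
  expect_error(background_policy("pitman_yor", alpha = 1.2), "alpha")
  expect_error(background_dim(py, -1, 10), "nonnegative")
})

test_that("minimum Stein discrepancy fit solves the quadratic exactly", {
  m <- gaussian_model(1, cov = matrix(1))
  fit <- fit_min_nksd(m, matrix(c(0, 1)), rbf1)
  expect_equal(fit$theta, 0.5)
  expect_equal(fit$value, -1.25) # vertex of theta^2 - theta - 1
  expect_true(fit$converged)
  # vertex agrees with -A^{-1}B/2 for a 2-d model
  X <- gen_toy(300, diag(c(1, 0.5)), seed = 2)
  m2 <- gaussian_model(2)
  obj <- svc_objective(m2, X, rbf1)
  fit2 <- fit_min_nksd(m2, X, rbf1)
  expect_equal(fit2$theta, -0.5 * solve(obj$quad$A, obj$quad$B),
               tolerance = 1e-6)
  expect_equal(fit2$hessian, 2 * obj$quad$A)
})

test_that("minimum-NKSD Gaussian mean estimates recover the truth", {
  ests <- sapply(1:20, function(s) {
    X <- gen_toy(500, diag(2), seed = 100 + s) + 0.7
    fit_min_nksd(gaussian_model(2), X, rbf1)$theta
  })
  se <- apply(ests, 1, sd) / sqrt(20)
  expect_true(all(abs(rowMeans(ests) - 0.7) < 3 * se))
})

test_that("exact quadratic backend matches adaptive quadrature", {
  pol <- background_policy("constant", m_const = 0)
  # constant integrand special case
  r0 <- svc_exact_quadratic(list(A = matrix(0, 1, 1), B = 0, C = -2),
                            0, 10, 5, 100, 3, rbf1, pol)
  expect_equal(r0$log_svc, -(100 / 5) * (-2) + 3 / 2 * log(2 * pi / 100))
  # 1-d worked example against stats::integrate
  q1 <- list(A = matrix(1, 1, 1), B = -1, C = -1)
  ex <- svc_exact_quadratic(q1, 0, 10, 5, 100, 0, rbf1, pol)
  o <- stats::integrate(function(t)
    exp(-(100 / 5) * (t^2 - t - 1)) * dnorm(t, 0, sqrt(10)),
    -Inf, Inf, rel.tol = 1e-12)
  expect_equal(ex$log_svc, log(o$value), tolerance = 1e-8)
  # 2-d toy against a tensor-grid quadrature
  X <- gen_toy(200, diag(2), seed = 3)
  obj <- svc_objective(gaussian_model(2), X, rbf1)
  ex2 <- svc_exact_quadratic(obj$quad, c(0, 0), 10, 5, 200, 0, rbf1, pol)
  g <- seq(-2, 2, length.out = 401)
  f <- outer(g, g, Vectorize(function(a, b) {
    th <- c(a, b)
    exp(-(200 / 5) * (sum(th * (obj$quad$A %*% th)) + sum(obj$quad$B * th) +
                        obj$quad$C)) *
      dnorm(a, 0, sqrt(10)) * dnorm(b, 0, sqrt(10))
  }))
  expect_equal(ex2$log_svc, log(sum(f) * diff(g)[1]^2), tolerance = 1e-6)
  # result decomposes into its three displayed terms
  expect_equal(ex2$log_svc, ex2$fit_term + ex2$foreground_volume_term +
                 ex2$background_volume_term)
})

test_that("Laplace backend obeys its exact reductions and identities", {
  pol <- background_policy("constant", m_const = 5)
  X <- gen_toy(500, diag(2), seed = 4)
  m <- gaussian_model(2)
  # m_F = 0 reduces to the bare fit plus background volume
  m0 <- gaussian_model(2, mean_free = FALSE)
  la0 <- svc_laplace(m0, X, rbf1, T = 5, policy = pol, r_b = 1)
  fit0 <- fit_min_nksd(m0, X, rbf1)
  mB <- background_dim(pol, 1, 500)
  expect_equal(la0$log_svc, -(500 / 5) * fit0$value +
                 mB / 2 * log(2 * pi / 500))
  # laplace - bic equals log prior - half log det (Hessian / T)
  la <- svc_laplace(m, X, rbf1, T = 5, policy = pol, r_b = 0)
  bi <- svc_bic(m, X, rbf1, T = 5, policy = pol, r_b = 0)
  fit <- fit_min_nksd(m, X, rbf1)
  expect_equal(la$log_svc - bi$log_svc,
               prior_logpdf(m, fit$theta) -
                 0.5 * determinant(2 * svc_objective(m, X, rbf1)$quad$A / 5,
                                   logarithm = TRUE)$modulus[1])
  # doubling T halves the fit term and adds (m_F/2) log 2 via the det term
  la2 <- svc_laplace(m, X, rbf1, T = 10, policy = pol, r_b = 0)
  expect_equal(la2$fit_term, la$fit_term / 2)
  expect_equal(la2$log_svc - la2$fit_term - la2$background_volume_term,
               la$log_svc - la$fit_term - la$background_volume_term +
                 (2 / 2) * log(2))
})

test_that("BIC backend is the volume-corrected minimized NKSD", {
  pol <- background_policy("constant", m_const = 5)
  X <- gen_toy(400, diag(2), seed = 5)
  m <- gaussian_model(2)
  fit <- fit_min_nksd(m, X, rbf1)
  bi <- svc_bic(m, X, rbf1, T = 5, policy = pol, r_b = 1)
  mB <- background_dim(pol, 1, 400)
  expect_equal(bi$log_svc, -(400 / 5) * fit$value +
                 (2 + mB) / 2 * log(2 * pi / 400))
  m0 <- gaussian_model(2, mean_free = FALSE)
  bi0 <- svc_bic(m0, X, rbf1, T = 5,
                 policy = background_policy("constant", m_const = 0), r_b = 0)
  expect_equal(bi0$log_svc, -(400 / 5) * fit_min_nksd(m0, X, rbf1)$value)
})

test_that("variational bound is tight for the conjugate quadratic family", {
  pol <- background_policy("constant", m_const = 0)
  X <- gen_toy(500, diag(2), seed = 6)
  m <- gaussian_model(2)
  obj <- svc_objective(m, X, rbf1)
  ex <- svc_exact_quadratic(obj$quad, c(0, 0), 10, 5, 500, 0, rbf1, pol)
  vi <- svc_variational(m, X, rbf1, T = 5, policy = pol, steps = 10)
  expect_lte(vi$log_svc, ex$log_svc + 1e-8)   # lower-bound contract
  expect_lt(ex$log_svc - vi$log_svc, 0.1)     # tight for this family
  # zero steps: the bound at the prior is the Jensen bound E_pi[-(N/T) NKSD]
  vi0 <- svc_variational(m, X, rbf1, T = 5, policy = pol, steps = 0)
  A <- obj$quad$A; B <- obj$quad$B
  e_prior <- 10 * sum(diag(A)) + obj$quad$C  # prior mean 0, var 10
  expect_equal(vi0$log_svc, -(500 / 5) * e_prior, tolerance = 1e-8)
  # trace is monotone for the coordinate-ascent path
  expect_true(all(diff(vi$trace) > -1e-8))
})

test_that("generic variational path is seeded and its trace ascends", {
  g <- glass_model(2)
  th_true <- glass_theta(g, H = c(0.5, -0.2, 0.1, 0.3), tau = 2)
  X <- gen_glass(120, g, th_true, n_burn = 200, n_thin = 2, seed = 8,
                 bound = 4)
  pol <- background_policy("constant", m_const = 5)
  v1 <- svc_variational(g, X, rbf1, T = 1, policy = pol, steps = 25,
                        seed = 3, n_samp = 2)
  v2 <- svc_variational(g, X, rbf1, T = 1, policy = pol, steps = 25,
                        seed = 3, n_samp = 2)
  expect_identical(v1$log_svc, v2$log_svc) # bit-identical under fixed seed
  # ascent in moving average (tolerant of stochastic noise)
  tr <- v1$trace
  half1 <- mean(tr[1:8]); half2 <- mean(tr[(length(tr) - 7):length(tr)])
  expect_gt(half2, half1)
})

test_that("defective scores obey their definitional identities", {
  pol <- background_policy("constant", m_const = 5)
  X <- gen_toy(300, diag(2), seed = 7)
  m <- gaussian_model(2)
  mB <- background_dim(pol, 1, 300)
  kb <- defective_scores(m, X, rbf1, T = 5, policy = pol, r_b = 1,
                         which = "kb")
  sv <- exact_gaussian_svc(m, X, rbf1, cols = 1:2, r_b = 1, T = 5, pol = pol)
  expect_equal(kb$log_svc, sv$log_svc - mB / 2 * log(2 * pi / 300),
               tolerance = 1e-10)
  kd <- defective_scores(m, X, rbf1, T = 5, policy = pol, r_b = 1,
                         which = "kd")
  bi <- svc_bic(m, X, rbf1, T = 5, policy = pol, r_b = 1)
  expect_equal(kd$log_svc, bi$log_svc - 2 / 2 * log(2 * pi / 300),
               tolerance = 1e-10)
  ka <- defective_scores(m, X, rbf1, T = 5, policy = pol, r_b = 1,
                         which = "ka")
  expect_true(is.finite(ka$log_svc))
  expect_error(defective_scores(ppca_model(3, 1), X, rbf1, which = "ka"),
               "Gaussian")
})

test_that("temperature calibration tracks coverage monotonically", {
  simfn <- function(seed) {
    theta <- withr::with_seed(seed, rnorm(2))
    list(X = gen_toy(300, diag(2), seed + 1) +
           matrix(theta, 300, 2, byrow = TRUE),
         theta = theta)
  }
  grid <- c(0.5, 2, 10)
  ct <- calibrate_temperature(gaussian_model(2), simfn, grid,
                              replicates = 15, seed = 2, spec = rbf1)
  # interval width scales as sqrt(T): coverage non-decreasing over the grid
  expect_true(all(diff(ct$coverage) >= -2 * sqrt(0.25 / 30)))
  expect_true(ct$T %in% grid)
  # degenerate grid returns its only element; same seed reproduces
  expect_identical(calibrate_temperature(gaussian_model(2), simfn, 5,
                                         replicates = 5, seed = 1,
                                         spec = rbf1)$T, 5)
  ct2 <- calibrate_temperature(gaussian_model(2), simfn, grid,
                               replicates = 15, seed = 2, spec = rbf1)
  expect_identical(ct$T, ct2$T)
  expect_error(calibrate_temperature(gaussian_model(2), simfn, numeric(0)),
               "empty")
})
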