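test_that("projection honors orthonormality and never drops rows", {
  X <- withr::with_seed(1, matrix(rnorm(40), 20, 2))
  cid <- foreground_candidate("full", V = diag(2), d = 2)
  expect_equal(project(X, cid), X)
  c1 <- foreground_candidate("first", columns = 1, d = 2)
  expect_equal(project(X, c1), X[, 1, drop = FALSE])
  V <- qr.Q(qr(matrix(c(1, 1), 2, 1)))
  cv <- foreground_candidate("diag", V = V, d = 2)
  expect_equal(nrow(project(X, cv)), 20)
  expect_lte(norm(project(X, cv), "F"), norm(X, "F"))
  expect_error(foreground_candidate("bad", V = matrix(c(1, 1), 2, 1), d = 2),
               "orthonormal")
  expect_error(foreground_candidate("bad", columns = c(1, 1), d = 2),
               "duplicates")
})

test_that("pairwise comparison is antisymmetric and config-guarded", {
  X <- gen_toy(200, diag(2), seed = 2)
  m <- gaussian_model(2)
  a <- exact_gaussian_svc(m, X, rbf1, cols = 1, r_b = 1)
  b <- exact_gaussian_svc(m, X, rbf1, cols = 2, r_b = 1)
  expect_identical(compare(a, a), 0)
  expect_equal(compare(a, b), -compare(b, a))
  # silent comparison across temperatures is forbidden
  b5 <- exact_gaussian_svc(m, X, rbf1, cols = 2, r_b = 1, T = 50)
  expect_error(compare(a, b5), "not comparable")
  bk <- exact_gaussian_svc(m, X, kernel_spec("imq", 1), cols = 2, r_b = 1)
  expect_error(compare(a, bk), "not comparable")
})

test_that("optimum transfer is exact for shared-curvature quadratics", {
  # l2 = l1: gradient vanishes at theta0, transfer returns theta0
  H <- diag(c(2, 3))
  expect_equal(transfer_optimum(c(1, -1), c(0, 0), H), c(1, -1))
  # quadratic target with the same Hessian: one Newton step is exact
  A <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  b1 <- c(1, 0); b2 <- c(0.2, -0.8)
  th0 <- -0.5 * solve(A, b1)
  g2 <- 2 * (A %*% th0) + b2
  expect_equal(transfer_optimum(th0, g2, 2 * A), -0.5 * solve(A, b2),
               tolerance = 1e-10)
})

test_that("leave-one-out scan bookkeeping and decisions are sound", {
  X <- gen_toy(800, diag(c(1, 0.5, 1)), seed = 3)
  colnames(X) <- c("a", "b", "c")
  m <- gaussian_model(3)
  rep <- loo_scan(X, m, rbf1, T = 5,
                  policy = background_policy("constant", m_const = 5),
                  backend = "bic", seed = 1)
  expect_s3_class(rep, "svc_selection_report")
  expect_identical(nrow(rep), 4L)  # reference + d candidates
  expect_identical(rep$log_ratio[1], 0)
  expect_identical(rep$decision[1], "reference")
  expect_true(all(rep$decision[-1] %in% c("include", "exclude")))
  expect_true(all((rep$log_ratio[-1] < 0) == (rep$decision[-1] == "include")))
  expect_match(rep$candidate[2], "drop_a")
  expect_true(nzchar(attr(rep, "fingerprint")))
  # column relabeling permutes report rows but not decisions
  perm <- c(2, 3, 1)
  rep2 <- loo_scan(X[, perm], m, rbf1, T = 5,
                   policy = background_policy("constant", m_const = 5),
                   backend = "bic", seed = 1)
  expect_equal(rep2$log_ratio[-1], rep$log_ratio[-1][perm], tolerance = 1e-8)
})

test_that("scan flags the misspecified dimension of a two-column toy", {
  hits <- sapply(1:5, function(s) {
    X <- gen_toy(3000, diag(c(1, 0.5)), seed = 40 + s)
    rep <- loo_scan(X, gaussian_model(2), rbf1, T = 5,
                    policy = background_policy("constant", m_const = 5),
                    backend = "exact", seed = s)
    rep$decision[-1]
  })
  # misspecified column 2 (variance 1/2 under a unit-variance model) is
  # excluded, the well-specified column kept, in the majority of seeds
  expect_gte(sum(hits[2, ] == "exclude"), 3)
  expect_gte(sum(hits[1, ] == "include"), 3)
})

test_that("transferred and re-optimized scans agree on the Gaussian toy", {
  X <- gen_toy(2000, diag(c(1, 1, 1, 0.6, 1.5, 0.5)), seed = 5)
  m <- gaussian_model(6)
  pol <- background_policy("pitman_yor")
  tr <- loo_scan(X, m, rbf1, T = 5, policy = pol, backend = "bic",
                 transfer = TRUE, seed = 1)
  ex <- loo_scan(X, m, rbf1, T = 5, policy = pol, backend = "bic",
                 refit = TRUE, seed = 1)
  expect_gt(cor(tr$log_ratio[-1], ex$log_ratio[-1]), 0.99)
  for (j in 2:7) {
    expect_lt(abs(tr$log_svc[j] - ex$log_svc[j]),
              0.05 * max(1, abs(ex$log_svc[j])))
  }
})

test_that("subset search recovers the well-specified column subset", {
  sp <- rbf1
  pol <- background_policy("constant", m_const = 5)
  # dims 3-4 misspecified (variance 1/2 under a unit-covariance model)
  ok <- sapply(1:3, function(s) {
    X <- gen_toy(2000, diag(c(1, 1, 0.5, 0.5)), seed = 50 + s)
    ss <- subset_search(X, gaussian_model(4), sp, T = 5, policy = pol,
                        steps = 120, seed = s)
    c(good = min(ss$probs[1:2]), bad = max(ss$probs[3:4]))
  })
  expect_gte(sum(ok["good", ] > 0.9 & ok["bad", ] < 0.1), 2)
  # all well-specified: background penalty keeps the full set preferred
  Xw <- gen_toy(2000, diag(4), seed = 60)
  ssw <- subset_search(Xw, gaussian_model(4), sp, T = 5, policy = pol,
                       steps = 120, seed = 1)
  expect_true(all(ssw$probs > 0.5))
  # zero steps leaves the Bernoulli probabilities at 1/2
  ss0 <- subset_search(Xw, gaussian_model(4), sp, T = 5, policy = pol,
                       steps = 0, seed = 1)
  expect_identical(ss0$probs, rep(0.5, 4))
})

test_that("criticism score is zero at the full space and tracks the scan", {
  X <- gen_toy(2000, diag(4), seed = 6)
  m <- gaussian_model(4)
  fit <- fit_min_nksd(m, X, rbf1)
  expect_identical(criticism_score(m, X, 1:4, fit$theta, T = 5, rbf1), 0)
  cs <- sapply(1:4, function(j)
    criticism_score(m, X, setdiff(1:4, j), fit$theta, T = 5, rbf1))
  rep <- loo_scan(X, m, rbf1, T = 5,
                  policy = background_policy("constant", m_const = 5),
                  backend = "bic", seed = 1)
  # on well-specified data the two diagnostics agree
  expect_gt(cor(cs, rep$log_ratio[-1]), 0.8)
})

test_that("the SVC attributes more mismatch to bad dimensions than
           conventional criticism", {
  sp <- kernel_spec("imq", 2)
  wins <- sapply(1:5, function(s) {
    sim <- gen_ppca_sim(1000, "A", seed = 70 + s)
    m <- ppca_model(6, 2)
    fit <- fit_min_nksd(m, sim$X, sp, restarts = 2)
    rep <- loo_scan(sim$X, m, sp, T = 0.05,
                    policy = background_policy("pitman_yor"),
                    backend = "bic", mB_mode = "param_delta", seed = s)
    cs <- sapply(5:6, function(j)
      criticism_score(m, sim$X, setdiff(1:6, j), fit$theta, T = 0.05, sp))
    all(rep$log_ratio[c(6, 7)] > cs)
  })
  expect_gte(sum(wins), 3)
})
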