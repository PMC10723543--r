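test_that("participation ratio hits its analytic limits and formula", {
  x1 <- cbind(rnorm(60), matrix(0.7, 60, 9))
  expect_equal(participation_ratio(x1), 1, tolerance = 1e-10)
  # exactly isotropic spectrum: PR = N
  xi <- data_with_spectrum(rep(1, 8), n = 40, seed = 2)
  expect_equal(participation_ratio(xi), 8, tolerance = 1e-8)
  # eigenvalues (2, 1, 1): PR = 16/6
  x3 <- data_with_spectrum(c(2, 1, 1), n = 30, seed = 3)
  expect_equal(participation_ratio(x3), 16 / 6, tolerance = 1e-8)
  expect_error(participation_ratio(matrix(1, 10, 3)), "variance")
})

test_that("explained-variance dimension matches analytic spectra", {
  x <- data_with_spectrum(c(9, 1), n = 25, seed = 4)
  expect_equal(explained_variance_dims(x, 0.9), 1L)
  xi <- data_with_spectrum(rep(1, 10), n = 40, seed = 5)
  expect_equal(explained_variance_dims(xi, 0.9), ceiling(0.9 * 10))
  # random rank-r data
  withr::with_seed(6, {
    r <- 4
    xr <- matrix(rnorm(50 * r), 50) %*% matrix(rnorm(r * 20), r)
    expect_equal(explained_variance_dims(xr, 0.999), r)
  })
})

test_that("center correlation matches a brute-force pairwise oracle", {
  # two antipodal centers
  pts <- array(0, c(2, 3, 4))
  v <- c(1, -2, 3, 0.5)
  for (m in 1:3) { pts[1, m, ] <- v; pts[2, m, ] <- -v }
  ms <- manifold_set(pts)
  expect_equal(center_correlation(ms), 1, tolerance = 1e-12)
  # random centers: brute force over all pairs
  withr::with_seed(7, {
    P <- 6; N <- 15
    pts2 <- array(rnorm(P * 4 * N), c(P, 4, N))
    ms2 <- manifold_set(pts2)
    centers <- apply(pts2, c(1, 3), mean)
    centers <- sweep(centers, 2, colMeans(centers))
    acc <- c()
    for (i in 1:(P - 1)) for (j in (i + 1):P)
      acc <- c(acc, abs(cor(centers[i, ], centers[j, ])))
    expect_equal(center_correlation(ms2), mean(acc), tolerance = 1e-12)
  })
  # identical centers: zero variance between pairs is undefined
  pts3 <- array(rep(c(1, 1, 1, 1), each = 6), c(2, 3, 4))
  expect_error(center_correlation(manifold_set(pts3)), "undefined|variance")
})

test_that("the anchor-point program satisfies its optimality conditions", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      M <- 6; D1 <- 4
      S <- rbind(matrix(rnorm((D1 - 1) * M), D1 - 1), rep(1, M))
      tv <- rnorm(D1)
      qp <- qp_anchor(S, tv, kappa = 0)
      # primal feasibility, dual feasibility, complementary slackness
      margins <- drop(crossprod(S, qp$v))
      expect_true(all(margins <= 1e-7))
      expect_true(all(qp$alpha >= 0))
      expect_lt(sum(qp$alpha * abs(margins)), 1e-6)
      expect_equal(qp$v, tv - drop(S %*% qp$alpha), tolerance = 1e-8)
      # agreement with a generic constrained optimizer on the primal
      # (start strictly feasible at -e_last: every s_j has last coord 1)
      if (max(drop(crossprod(S, tv))) > 0) {
        co <- stats::constrOptim(c(rep(0, D1 - 1), -1),
                                 function(v) sum((v - tv)^2),
                                 grad = function(v) 2 * (v - tv),
                                 ui = -t(S), ci = rep(0, M),
                                 method = "BFGS")
        expect_equal(co$value, qp$lambda^2,
                     tolerance = 0.05 * max(1, qp$lambda^2))
        expect_gte(co$value + 1e-6, qp$lambda^2)
      }
    }
  })
})

test_that("mean-field geometry of zero-extent manifolds hits the limits", {
  withr::with_seed(9, {
    # single-point manifolds: alpha = 2, D = 0, R = 0
    pts <- array(rnorm(12 * 1 * 40), c(12, 1, 40))
    g <- meanfield_geometry(manifold_set(pts), n_gaussian_samples = 400,
                            seed = 1)
    expect_equal(g$alpha_c_mean, 2, tolerance = 0.15)
    expect_equal(g$D_M_mean, 0)
    expect_equal(g$R_M_mean, 0)
    # M copies of the same point behave identically
    ptsM <- array(0, c(12, 5, 40))
    for (m in 1:5) ptsM[, m, ] <- pts[, 1, ]
    gM <- meanfield_geometry(manifold_set(ptsM), n_gaussian_samples = 400,
                             seed = 1)
    expect_equal(gM$alpha_c_mean, g$alpha_c_mean, tolerance = 1e-6)
  })
})

test_that("capacity respects the 2/M and 2 bounds on random ensembles", {
  for (cfg in list(c(8, 3, 60, 11), c(10, 6, 80, 12), c(6, 2, 40, 13))) {
    ms <- gaussian_manifolds(cfg[1], cfg[2], cfg[3], seed = cfg[4])
    g <- meanfield_geometry(ms, n_gaussian_samples = 150, seed = 2)
    M <- cfg[2]
    expect_gte(mean(g$alpha_c), 2 / M - 0.05)
    expect_lte(g$alpha_c_mean, 2 + 0.05)
    expect_true(all(g$D_M >= 0) && all(g$R_M >= 0))
  }
})

test_that("alpha_c is invariant under rotation and exactly under scaling", {
  ms <- gaussian_manifolds(8, 4, 50, seed = 21)
  g0 <- meanfield_geometry(ms, n_gaussian_samples = 300, seed = 3)
  # global scaling: identical after center normalization
  ms_scaled <- ms; ms_scaled$points <- ms$points * 7.3
  g_s <- meanfield_geometry(ms_scaled, n_gaussian_samples = 300, seed = 3)
  expect_equal(g_s$alpha_c, g0$alpha_c, tolerance = 1e-10)
  expect_equal(g_s$R_M, g0$R_M, tolerance = 1e-10)
  # rotation: invariant in distribution (finite-sample tolerance)
  Q <- random_orthogonal(50, seed = 4)
  ms_rot <- ms
  ms_rot$points <- array(matrix(ms$points, 8 * 4) %*% Q, dim(ms$points))
  g_r <- meanfield_geometry(ms_rot, n_gaussian_samples = 300, seed = 3)
  expect_equal(g_r$alpha_c_mean, g0$alpha_c_mean, tolerance = 0.12)
})

test_that("shrinking manifolds toward centers drives the expected limits", {
  ms <- gaussian_manifolds(8, 4, 60, seed = 31)
  centers <- apply(ms$points, c(1, 3), mean)
  vals <- lapply(c(1, 0.3, 0.03), function(sc) {
    m2 <- ms
    for (p in 1:8) for (m in 1:4)
      m2$points[p, m, ] <- centers[p, ] +
        sc * (ms$points[p, m, ] - centers[p, ])
    meanfield_geometry(m2, n_gaussian_samples = 200, seed = 5)
  })
  a <- vapply(vals, function(g) g$alpha_c_mean, numeric(1))
  d <- vapply(vals, function(g) g$D_M_mean, numeric(1))
  r <- vapply(vals, function(g) g$R_M_mean, numeric(1))
  expect_true(all(diff(a) > 0))   # alpha_c -> 2
  expect_true(all(diff(d) < 0))   # D_M -> 0
  expect_true(all(diff(r) < 0))   # R_M -> 0
  expect_gt(a[3], 1.8)
})

test_that("the separability decision agrees with a maximum-margin SVM", {
  skip_if_not_installed("e1071")
  withr::with_seed(41, {
    agree <- 0; total <- 0
    for (rep in 1:12) {
      n <- 40; N <- sample(10:30, 1)
      X <- matrix(rnorm(n * N), n)
      y <- sample(rep(c(-1, 1), each = n / 2))
      ours <- linear_separable(X, y)
      fit <- e1071::svm(X, factor(y), kernel = "linear", cost = 1e6,
                        scale = FALSE)
      svm_sep <- all(as.numeric(as.character(fitted(fit))) == y)
      total <- total + 1
      if (ours == svm_sep) agree <- agree + 1
    }
    expect_gte(agree / total, 0.9)
  })
})

test_that("separability is certain in the extreme dimension regimes", {
  withr::with_seed(42, {
    # N >= n points in general position: always separable
    X <- matrix(rnorm(30 * 35), 30)
    y <- sample(rep(c(-1, 1), 15))
    expect_true(linear_separable(X, y))
    # N far below n/2: essentially never separable
    X2 <- matrix(rnorm(200 * 8), 200)
    y2 <- sample(rep(c(-1, 1), 100))
    expect_false(linear_separable(X2, y2))
  })
})

test_that("simulation capacity reproduces the single-point transition", {
  ms <- gaussian_manifolds(60, 1, 150, seed = 51)
  est <- simulation_capacity(ms, n_dichotomies = 30, seed = 1)
  expect_equal(est$alpha_sim, 2, tolerance = 0.25)
  expect_equal(est$alpha_sim, est$P / est$N_c, tolerance = 1e-12)
  # duplicated points match the M = 1 case
  pts <- array(0, c(60, 3, 150))
  for (m in 1:3) pts[, m, ] <- ms$points[, 1, ]
  est_dup <- simulation_capacity(manifold_set(pts), n_dichotomies = 30,
                                 seed = 1)
  expect_equal(est_dup$alpha_sim, est$alpha_sim, tolerance = 0.2)
})

test_that("simulation capacity is invariant to rotation and scale", {
  ms <- gaussian_manifolds(24, 2, 100, seed = 61)
  e0 <- simulation_capacity(ms, n_dichotomies = 24, seed = 2)
  ms_s <- ms; ms_s$points <- ms$points * 0.2
  e_s <- simulation_capacity(ms_s, n_dichotomies = 24, seed = 2)
  expect_equal(e_s$alpha_sim, e0$alpha_sim, tolerance = 1e-10)
  Q <- random_orthogonal(100, seed = 5)
  ms_r <- ms
  ms_r$points <- array(matrix(ms$points, 48) %*% Q, dim(ms$points))
  e_r <- simulation_capacity(ms_r, n_dichotomies = 24, seed = 2)
  expect_equal(e_r$alpha_sim, e0$alpha_sim, tolerance = 0.3)
})

test_that("the separability curve is recorded and monotone-consistent", {
  ms <- gaussian_manifolds(20, 2, 80, seed = 71)
  est <- simulation_capacity(ms, n_dichotomies = 20, seed = 3)
  curve <- est$separability_curve
  expect_true(all(c("n_dims", "frac") %in% names(curve)))
  expect_gte(curve$frac[which.max(curve$n_dims)], 0.5)
  expect_lte(curve$frac[which.min(curve$n_dims)], 0.5)
})
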