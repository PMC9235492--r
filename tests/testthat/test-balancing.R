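test_that("cost matrix matches the double-loop definition", {
  expect_equal(cost_matrix(matrix(1, 1, 2), matrix(1, 1, 2)),
               matrix(0, 1, 1))
  expect_equal(cost_matrix(matrix(0), matrix(3), p = 2), matrix(9, 1, 1))
  set.seed(1)
  A <- matrix(rnorm(6), 2); B <- matrix(rnorm(6), 2)
  for (p in c(1, 2, 3)) {
    C <- cost_matrix(A, B, p)
    ref <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2)
      ref[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))^p
    expect_equal(C, ref)
  }
  expect_error(cost_matrix(matrix(0, 1, 2), matrix(0, 1, 3)), "dimensionality")
})

test_that("exact assignment solver matches exhaustive enumeration", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    a <- matrix(rnorm(n * 2), n)
    b <- matrix(rnorm(n * 2), n) + 0.5
    v <- smoothed_ot(a, b, ipm_config(epsilon = 0))
    expect_equal(as.numeric(v), brute_force_ot(a, b), tolerance = 1e-12)
  }
  big <- matrix(rnorm(65 * 2), 65)
  expect_error(smoothed_ot(big, big, ipm_config(epsilon = 0)), "64 points")
  pc <- point_cloud(matrix(rnorm(4), 2), weights = c(0.7, 0.3))
  expect_error(smoothed_ot(pc, pc, ipm_config(epsilon = 0)), "uniform")
})

test_that("smoothed transport: closed forms and the epsilon -> 0 limit", {
  # single points at distance d: unique coupling, KL term vanishes
  p1 <- matrix(c(0, 0), 1); p2 <- matrix(c(3, 4), 1)
  for (eps in c(0.01, 1, 100)) {
    expect_equal(as.numeric(smoothed_ot(p1, p2, ipm_config(epsilon = eps))),
                 25, tolerance = 1e-8)
  }
  # identical clouds: the transport cost vanishes and only the entropic
  # self-cost eps * log(m) of the (permutation) plan remains, -> 0 with eps
  set.seed(3)
  a <- matrix(rnorm(8), 4)
  v <- smoothed_ot(a, a, ipm_config(epsilon = 1e-3, tolerance = 1e-6,
                                    max_iters = 10000))
  expect_equal(as.numeric(v), 1e-3 * log(4), tolerance = 0.01)
  # uniform 4-vs-4 one-dimensional clouds at epsilon = 0: assignment optimum
  x1 <- matrix(c(0, 1, 2, 5), 4); x2 <- matrix(c(0.5, 1.5, 3, 4), 4)
  expect_equal(as.numeric(smoothed_ot(x1, x2, ipm_config(epsilon = 0))),
               brute_force_ot(x1, x2))
})

test_that("Sinkhorn divergence is zero on identical clouds and symmetric", {
  set.seed(4)
  cfg <- ipm_config(epsilon = 2, tolerance = 1e-7, max_iters = 50000)
  for (rep in 1:3) {
    a <- matrix(rnorm(10), 5); b <- matrix(rnorm(10), 5) + rep
    expect_lt(abs(as.numeric(sinkhorn_divergence(a, a, cfg))), 1e-8)
    s_ab <- as.numeric(sinkhorn_divergence(a, b, cfg))
    s_ba <- as.numeric(sinkhorn_divergence(b, a, cfg))
    expect_equal(s_ab, s_ba, tolerance = 1e-5)
    expect_gt(s_ab, -1e-8)  # non-negativity up to solver tolerance
  }
  # single points: self-terms vanish, divergence is the squared distance
  expect_equal(as.numeric(sinkhorn_divergence(matrix(0), matrix(2),
                                              ipm_config(epsilon = 1))), 4)
})

test_that("Sinkhorn divergence approaches exact transport as epsilon -> 0", {
  set.seed(5)
  for (n in c(4, 8)) {
    a <- matrix(rnorm(n * 2), n)
    b <- matrix(rnorm(n * 2), n) + 1
    exact <- brute_force_ot(a, b)
    eps <- 1e-3 * median(cost_matrix(a, b))
    s <- suppressWarnings(as.numeric(
      sinkhorn_divergence(a, b, ipm_config(epsilon = eps, tolerance = 1e-6,
                                           max_iters = 50000,
                                           strict = FALSE))))
    expect_lt(abs(s - exact) / exact, 0.01)
  }
})

test_that("Sinkhorn divergence approaches the kernel MMD as epsilon grows", {
  set.seed(6)
  a <- matrix(rnorm(12), 6); b <- matrix(rnorm(12), 6) + 0.8
  s_big <- as.numeric(sinkhorn_divergence(a, b, ipm_config(epsilon = 1e4,
                                                           tolerance = 1e-10,
                                                           max_iters = 5000)))
  m <- mmd(a, b, kernel = "energy", p = 2)
  expect_lt(abs(s_big - m) / m, 0.05)
})

test_that("divergence scales quadratically and responds to translation", {
  set.seed(7)
  a <- matrix(rnorm(8), 4); b <- matrix(rnorm(8), 4) + 0.3
  s1 <- as.numeric(sinkhorn_divergence(a, b, ipm_config(epsilon = 2, tolerance = 1e-7,
                                                        max_iters = 50000)))
  s3 <- as.numeric(sinkhorn_divergence(3 * a, 3 * b,
                                       ipm_config(epsilon = 18, tolerance = 1e-7,
                                                  max_iters = 50000)))
  expect_equal(s3, 9 * s1, tolerance = 1e-5)
  # translating a cloud against itself: exact quadratic transport is ||v||^2
  v <- c(0.7, -0.2)
  shifted <- sweep(a, 2, v, "+")
  expect_equal(as.numeric(smoothed_ot(a, shifted, ipm_config(epsilon = 0))),
               sum(v^2), tolerance = 1e-10)
})

test_that("Sinkhorn divergence gradients match finite differences", {
  set.seed(8)
  a <- matrix(rnorm(8), 4); b <- matrix(rnorm(8), 4) + 1
  cfg <- ipm_config(epsilon = 2, tolerance = 1e-9, max_iters = 20000)
  s <- sinkhorn_divergence(a, b, cfg, gradient = TRUE)
  ga <- attr(s, "grad_a"); gb <- attr(s, "grad_b")
  d <- 1e-5
  for (probe in list(c(1, 1), c(3, 2), c(4, 1))) {
    i <- probe[1]; j <- probe[2]
    ap <- a; ap[i, j] <- a[i, j] + d
    am <- a; am[i, j] <- a[i, j] - d
    fd <- (as.numeric(sinkhorn_divergence(ap, b, cfg)) -
             as.numeric(sinkhorn_divergence(am, b, cfg))) / (2 * d)
    expect_equal(ga[i, j], fd, tolerance = 1e-4)
    bp <- b; bp[i, j] <- b[i, j] + d
    bm <- b; bm[i, j] <- b[i, j] - d
    fdb <- (as.numeric(sinkhorn_divergence(a, bp, cfg)) -
              as.numeric(sinkhorn_divergence(a, bm, cfg))) / (2 * d)
    expect_equal(gb[i, j], fdb, tolerance = 1e-4)
  }
})

test_that("MMD closed forms", {
  set.seed(9)
  a <- matrix(rnorm(10), 5)
  expect_equal(mmd(a, a), 0)
  expect_equal(mmd(a, a, kernel = "gaussian"), 0, tolerance = 1e-12)
  # two point masses under the energy kernel: cross term only
  expect_equal(mmd(matrix(c(0, 0), 1), matrix(c(1, 2), 1)), 5)
  b <- matrix(rnorm(10), 5) + 1
  expect_gt(mmd(a, b, kernel = "gaussian", bandwidth = 1), 0)
  expect_error(mmd(a, b, kernel = "gaussian", bandwidth = 0), "bandwidth")
})

test_that("non-convergence raises an informative error in strict mode", {
  set.seed(10)
  a <- matrix(rnorm(20), 10); b <- matrix(rnorm(20), 10) + 2
  hard <- ipm_config(epsilon = 0.01, tolerance = 1e-12, max_iters = 5L)
  expect_error(smoothed_ot(a, b, hard), "iterations")
  soft <- ipm_config(epsilon = 0.01, tolerance = 1e-12, max_iters = 5L,
                     strict = FALSE)
  expect_warning(v <- smoothed_ot(a, b, soft), "iterations")
  expect_true(is.finite(as.numeric(v)))
})
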