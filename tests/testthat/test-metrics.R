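# analytic square root of a 2x2 symmetric PSD matrix, for the scalar FID
# oracle: sqrt(M) = (M + sqrt(det) I) / sqrt(tr + 2 sqrt(det))
sqrt2x2 <- function(M) {
  s <- sqrt(max(det(M), 0))
  (M + s * diag(2)) / sqrt(sum(diag(M)) + 2 * s)
}

test_that("fid of a set with itself is zero and fid is symmetric", {
  set.seed(1)
  a <- uro_features(matrix(rnorm(50 * 4), 50, 4))
  b <- uro_features(matrix(rnorm(50 * 4, 1), 50, 4))
  expect_lt(fid(a, a), 1e-6)
  expect_equal(fid(a, b), fid(b, a), tolerance = 1e-10)
  expect_gt(fid(a, b), 0)
})

test_that("fid recovers the Gaussian mean-shift closed form d*m^2", {
  set.seed(42)
  d <- 8; m <- 0.5
  a <- uro_features(matrix(rnorm(10000 * d), ncol = d))
  b <- uro_features(matrix(rnorm(10000 * d, mean = m), ncol = d))
  expect_equal(fid(a, b), d * m^2, tolerance = 0.1)
})

test_that("fid matches a hand-rolled 2x2 evaluation on a tiny matrix", {
  A <- matrix(c(0, 1, 2, 0.5, -1, 1), 3, 2)
  B <- matrix(c(1, 2, 0, -0.5, 0, 2), 3, 2)
  Sa <- cov(A); Sb <- cov(B)
  want <- sum((colMeans(A) - colMeans(B))^2) + sum(diag(Sa)) + sum(diag(Sb)) -
    2 * sum(diag(sqrt2x2(sqrt2x2(Sa) %*% Sb %*% sqrt2x2(Sa))))
  expect_equal(fid(uro_features(A), uro_features(B)), want, tolerance = 1e-8)
})

test_that("fid is invariant under a common rotation of both feature sets", {
  set.seed(7)
  a <- matrix(rnorm(60 * 3), 60, 3)
  b <- matrix(rnorm(60 * 3, 0.7), 60, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  f0 <- fid(uro_features(a), uro_features(b))
  f1 <- fid(uro_features(a %*% Q), uro_features(b %*% Q))
  expect_equal(f0, f1, tolerance = 1e-8)
  expect_error(fid(uro_features(a), uro_features(matrix(0, 5, 2))),
               "dimensions differ")
  expect_error(fid(uro_features(matrix(0, 1, 3)), uro_features(a)),
               "at least 2")
})

test_that("kid equals the exhaustive kernel double sum on 4 + 4 vectors", {
  set.seed(3)
  X <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(12), 4, 3)
  got <- kid(uro_features(X), uro_features(Y), subset_size = 4, n_subsets = 1,
             rng_seed = 1)
  kp <- function(x, y) (sum(x * y) / 3 + 1)^3
  s_xx <- 0; s_yy <- 0; s_xy <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      s_xx <- s_xx + kp(X[i, ], X[j, ])
      s_yy <- s_yy + kp(Y[i, ], Y[j, ])
    }
    s_xy <- s_xy + kp(X[i, ], Y[j, ])
  }
  expect_equal(got, s_xx / 12 + s_yy / 12 - 2 * s_xy / 16, tolerance = 1e-12)
})

test_that("kid is near zero at the null and exactly zero for constant kernels", {
  set.seed(11)
  ests <- vapply(1:20, function(s) {
    a <- uro_features(matrix(rnorm(200 * 6), ncol = 6))
    b <- uro_features(matrix(rnorm(200 * 6), ncol = 6))
    kid(a, b, subset_size = 100, n_subsets = 5, rng_seed = s)
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * se + 1e-3)
  z <- uro_features(matrix(0, 10, 4))
  expect_equal(kid(z, z, subset_size = 5, n_subsets = 2, rng_seed = 1), 0)
  expect_error(kid(z, z, subset_size = 1), "subset_size")
})

test_that("kid is deterministic under a seed and stabilizes with subsets", {
  set.seed(2)
  a <- uro_features(matrix(rnorm(300 * 5), ncol = 5))
  b <- uro_features(matrix(rnorm(300 * 5, 0.3), ncol = 5))
  expect_identical(kid(a, b, 50, 10, rng_seed = 9),
                   kid(a, b, 50, 10, rng_seed = 9))
  spread <- function(ns) sd(vapply(1:12, function(s) kid(a, b, 50, ns, s),
                                   numeric(1)))
  expect_lt(spread(16), spread(1))
})

test_that("patch NCE loss matches hand-computed values", {
  q <- c(1, 0)
  # uniform logits: q.p == q.neg for 5 negatives -> log(6)
  negs <- matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE)
  expect_equal(patch_nce_loss(q, c(1, 0), negs, temperature = 1), log(6),
               tolerance = 1e-12)
  # single negative, tau = 1, q.p = 1, q.neg = 0 -> log(1 + e^-1)
  expect_equal(patch_nce_loss(q, c(1, 0), matrix(c(0, 0), 1), 1),
               log(1 + exp(-1)), tolerance = 1e-12)
  # overwhelming positive -> loss ~ 0
  expect_lt(patch_nce_loss(100 * q, c(1, 0), matrix(c(0, 0), 1), 0.07), 1e-6)
  expect_error(patch_nce_loss(q, c(1, 0), matrix(c(0, 0), 1), 0), "temperature")
})

test_that("NCE loss strictly decreases as the positive alignment grows", {
  negs <- matrix(rnorm(10), 5, 2)
  losses <- vapply(seq(0, 2, by = 0.25), function(a)
    patch_nce_loss(c(1, 0), c(a, 0), negs, 0.5), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("feature sets round-trip through the binary format", {
  set.seed(4)
  fs <- uro_features(matrix(rnorm(12 * 5), 12, 5), "random-projection-5")
  f <- withr::local_tempfile()
  write_features(fs, f)
  back <- read_features(f)
  expect_equal(back$matrix, fs$matrix, tolerance = 1e-15, ignore_attr = TRUE)
  expect_identical(back$extractor_id, fs$extractor_id)
})

test_that("the random-projection extractor is deterministic", {
  imgs <- lapply(1:4, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  f1 <- extract_features_rp(imgs, d_out = 8, rng_seed = 3)
  f2 <- extract_features_rp(imgs, d_out = 8, rng_seed = 3)
  expect_identical(f1$matrix, f2$matrix)
  expect_equal(dim(f1$matrix), c(4L, 8L))
})
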