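# literal brute force at coarse binning (no shared cumulative machinery)
oracle_otsu3_naive <- function(values, n_bins = 32L) {
  lo <- min(values); hi <- max(values)
  w <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((values - lo) / w), 0), n_bins - 1) + 1L
  cnt <- tabulate(idx, nbins = n_bins)
  ctr <- lo + (seq_len(n_bins) - 0.5) * w
  best <- -Inf; bt <- c(NA, NA)
  for (t1 in 1:(n_bins - 2L)) for (t2 in (t1 + 1L):(n_bins - 1L)) {
    cls <- list(1:t1, (t1 + 1L):t2, (t2 + 1L):n_bins)
    ws <- vapply(cls, function(k) sum(cnt[k]), numeric(1))
    if (any(ws == 0)) next
    mus <- vapply(cls, function(k) sum(cnt[k] * ctr[k]), numeric(1)) / ws
    obj <- sum(ws * mus^2)
    if (obj > best) { best <- obj; bt <- c(t1, t2) }
  }
  lo + w * bt
}

test_that("box dilation matches the element volume and is extensive", {
  m <- array(0L, c(17, 17, 17)); m[9, 9, 9] <- 1L
  lab <- uro_labelmap(m, semantics = c(background = 0L, foreground = 1L))
  d <- dilate(lab, structuring_element(c(5, 9, 9)))
  expect_equal(sum(d$data), 5 * 9 * 9)
  box <- d$data[7:11, 5:13, 5:13]
  expect_true(all(box == 1L))

  empty <- uro_labelmap(array(0L, c(5, 5, 5)),
                        semantics = c(background = 0L, foreground = 1L))
  expect_equal(sum(dilate(empty)$data), 0)
  full <- uro_labelmap(array(1L, c(5, 5, 5)),
                       semantics = c(background = 0L, foreground = 1L))
  expect_true(all(dilate(full)$data == 1L))
  expect_error(structuring_element(c(4, 9, 9)), "odd")
})

test_that("dilation is monotone and translation-equivariant", {
  set.seed(11)
  a <- array(as.integer(runif(14^3) < 0.05), c(14, 14, 14))
  b <- a; b[3, 4, 5] <- 1L  # superset
  sem <- c(background = 0L, foreground = 1L)
  da <- dilate(uro_labelmap(a, semantics = sem))$data
  db <- dilate(uro_labelmap(b, semantics = sem))$data
  expect_true(all(da <= db))          # increasing
  expect_true(all(a <= da))           # extensive
  # translation equivariance: shift input by 1 voxel in z
  sh <- array(0L, dim(a)); sh[2:14, , ] <- a[1:13, , ]
  dsh <- dilate(uro_labelmap(sh, semantics = sem))$data
  expect_equal(dsh[3:13, , ], da[2:12, , ])
})

test_that("three perfectly separated clusters are split exactly", {
  vals <- rep(c(0, 100, 200), each = 3)
  th <- otsu_thresholds(vals, 3)
  cls <- findInterval(vals, th, left.open = TRUE)
  expect_equal(cls, rep(0:2, each = 3))
})

test_that("otsu equals the exhaustive pair search on random histograms", {
  for (s in 1:50) {
    set.seed(s)
    k <- sample(2:4, 1)
    n <- sample(c(300, 1000, 4096), 1)
    centers <- sort(runif(k, 0, 1000))
    vals <- rnorm(n, sample(centers, n, TRUE), runif(1, 5, 60))
    th <- otsu_thresholds(vals, 3)
    expect_equal(th, oracle_otsu3(vals), tolerance = 1e-12,
                 label = sprintf("seed %d", s))
  }
})

test_that("otsu matches a literal brute force at coarse binning", {
  for (s in 1:5) {
    set.seed(100 + s)
    vals <- c(rnorm(200, 0, 10), rnorm(200, 70, 12), rnorm(150, 180, 15))
    expect_equal(otsu_thresholds(vals, 3, n_bins = 32L),
                 oracle_otsu3_naive(vals), tolerance = 1e-12)
  }
})

test_that("otsu rejects degenerate inputs", {
  expect_error(otsu_thresholds(rep(1, 10), 3), "distinct")
  expect_error(otsu_thresholds(c(1, 2), 3), "distinct")
  expect_error(otsu_thresholds(numeric(0)), "empty")
})

test_that("dice handles the standard cases", {
  sem <- c(background = 0L, foreground = 1L)
  a <- uro_labelmap(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), c(2, 2, 2)),
                    semantics = sem)
  b <- uro_labelmap(array(c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L), c(2, 2, 2)),
                    semantics = sem)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)            # |A|=4, |B|=4, overlap 2
  expect_equal(dice(a, b), dice(b, a))
  z <- uro_labelmap(array(0L, c(2, 2, 2)), semantics = sem)
  expect_equal(dice(a, z), 0)
  expect_equal(dice(z, z), 1)
  expect_error(dice(a, uro_labelmap(array(0L, c(3, 3, 3)), semantics = sem)),
               "shape")
})

test_that("sliding-window starts snap to the boundary", {
  expect_equal(uroscope:::window_starts(256L, 128L, 0.5), c(1L, 65L, 129L))
  expect_equal(uroscope:::window_starts(100L, 40L, 0.5), c(1L, 21L, 41L, 61L))
  expect_equal(uroscope:::window_starts(64L, 64L, 0.5), 1L)
})

test_that("sliding-window fusion averages predictions", {
  v <- uro_volume(array(runif(40^3), c(40, 40, 40)))
  out <- sliding_window_predict(v, function(p) array(0.7, dim(p)),
                                patch = c(16, 16, 16))
  expect_equal(range(out$data), c(0.7, 0.7))
  outi <- sliding_window_predict(v, identity, patch = c(16, 16, 16))
  expect_equal(outi$data, v$data, tolerance = 1e-12)
  expect_error(sliding_window_predict(v, identity, patch = c(64, 16, 16)),
               "exceeds")
})

test_that("augmentations are seeded and bounded", {
  p <- array(runif(10^3), c(10, 10, 10))
  a1 <- augment_intensity_shift(p, seed = 5)
  a2 <- augment_intensity_shift(p, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(abs(a1 - p) <= 0.026))
  s1 <- augment_random_smooth(p, seed = 2)
  expect_identical(s1, augment_random_smooth(p, seed = 2))
  f1 <- augment_random_affine(p, seed = 3)
  expect_identical(f1, augment_random_affine(p, seed = 3))
  expect_identical(dim(f1), dim(p))
})

test_that("balanced crops alternate foreground and background centers", {
  set.seed(2)
  lab <- array(0L, c(40, 40, 40)); lab[15:25, 15:25, 15:25] <- 1L
  ct <- uro_volume(array(runif(40^3), c(40, 40, 40)))
  lm <- uro_labelmap(lab, semantics = c(background = 0L, foreground = 1L))
  crops <- augment_balanced_crop(ct, lm, n_crops = 16, size = c(16, 16, 16),
                                 seed = 4)
  centers <- vapply(crops, function(cr) cr$center_label, integer(1))
  expect_equal(sum(centers > 0), 8)
  expect_equal(sum(centers == 0), 8)
  expect_true(all(vapply(crops, function(cr) all(dim(cr$ct) == 16), logical(1))))
  allbg <- uro_labelmap(array(0L, c(40, 40, 40)),
                        semantics = c(background = 0L, foreground = 1L))
  expect_warning(cr0 <- augment_balanced_crop(ct, allbg, 16, c(16, 16, 16), 1),
                 "foreground")
  expect_true(all(vapply(cr0, function(cr) cr$center_label, integer(1)) == 0L))
})

test_that("collecting-system extraction recovers the phantom ground truth", {
  ph0 <- fix_phantom0()
  km <- phantom_kidney_mask(ph0)
  ext0 <- extract_collecting_system(ph0$ct, km)
  truth <- phantom_collecting_mask(ph0)
  # noiseless: exact recovery within the dilated mask (truth is inside it)
  expect_identical(ext0$data, truth$data)
  # with default noise, Dice stays high
  ph <- make_phantom(phantom_spec(rng_seed = 7L))
  ext <- extract_collecting_system(ph$ct, phantom_kidney_mask(ph))
  expect_gte(dice(ext, truth), 0.95)
  # output never escapes the dilated kidney mask
  dil <- dilate(km, structuring_element())
  expect_true(all(ext0$data <= dil$data))
  empty <- uro_labelmap(array(0L, dim(ph0$ct$data)),
                        semantics = c(background = 0L, foreground = 1L))
  expect_error(extract_collecting_system(ph0$ct, empty), "empty")
})
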