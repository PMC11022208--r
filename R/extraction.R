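#' Box structuring element
#'
#' Axis-aligned box used for binary dilation, specified as odd extents in
#' `(z, y, x)` index order.  The default 5 x 9 x 9 matches a roughly isotropic
#' physical element on thick-slice CT (5 voxels across slices, 9 x 9 in
#' plane).
#'
#' @param shape Integer length-3 `(z, y, x)`, all odd and >= 1.
#' @export
structuring_element <- function(shape = c(5L, 9L, 9L)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L) || any(shape %% 2L == 0L))
    stopf("structuring element dimensions must be odd and >= 1, got %s",
          paste(shape, collapse = "x"))
  structure(list(shape = shape), class = "uro_selem")
}

#' Binary dilation with a box structuring element
#'
#' @param mask A binary [uro_labelmap()].
#' @param elem A [structuring_element()].
#' @return Dilated binary label map (a superset of `mask`).
#' @export
dilate <- function(mask, elem = structuring_element()) {
  stopifnot(inherits(mask, "uro_volume"), inherits(elem, "uro_selem"))
  if (!is_binary(mask)) stopf("dilate requires a binary mask")
  r <- (elem$shape - 1L) %/% 2L
  out <- cpp_box_dilate(as.integer(mask$data), dim(mask$data), r[1], r[2], r[3])
  dim(out) <- dim(mask$data)
  uro_labelmap(out, mask$spacing, mask$origin,
               semantics = c(background = 0L, foreground = 1L))
}

#' Multilevel Otsu thresholds
#'
#' Finds the `n_classes - 1` thresholds that maximize the between-class
#' variance of a 256-bin histogram of the input sample.  The search is
#' exhaustive over all bin-boundary combinations, so the result is the global
#' optimum of the discretized criterion.
#'
#' @param values Non-empty numeric sample.
#' @param n_classes Number of classes, >= 2 (default 3).
#' @param n_bins Histogram bins over the observed range (default 256).
#' @return Strictly increasing numeric thresholds of length `n_classes - 1`;
#'   class `k` is `t[k-1] < v <= t[k]`.
#' @export
otsu_thresholds <- function(values, n_classes = 3L, n_bins = 256L) {
  values <- as.numeric(values)
  if (length(values) == 0L) stopf("otsu_thresholds: empty sample")
  if (any(!is.finite(values))) stopf("otsu_thresholds: non-finite values")
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stopf("otsu_thresholds: need at least 2 classes")
  if (length(unique(values)) < n_classes)
    stopf("otsu_thresholds: only %d distinct values for %d classes",
          length(unique(values)), n_classes)
  lo <- min(values); hi <- max(values)
  w <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((values - lo) / w), 0), n_bins - 1) + 1L
  cnt <- tabulate(idx, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * w
  Cc <- cumsum(cnt)                  # cumulative counts
  Sc <- cumsum(cnt * centers)        # cumulative first moments
  B <- n_bins
  seg_w <- function(i, j) Cc[j] - ifelse(i > 1, Cc[i - 1], 0)
  seg_s <- function(i, j) Sc[j] - ifelse(i > 1, Sc[i - 1], 0)
  # objective: sum_k w_k * mu_k^2 (equivalent to between-class variance up to
  # a constant); combos with an empty class are invalid
  term <- function(i, j) {
    wt <- seg_w(i, j); s <- seg_s(i, j)
    ifelse(wt > 0, s * s / wt, -Inf)
  }
  if (n_classes == 2L) {
    t1 <- seq_len(B - 1L)
    obj <- term(1, t1) + term(t1 + 1L, B)
    best <- t1[which.max(obj)]
    if (!is.finite(max(obj))) stopf("otsu_thresholds: degenerate histogram")
    return(lo + w * best)
  }
  if (n_classes == 3L) {
    t1 <- seq_len(B - 2L)
    lead <- term(1, t1)                       # class 1 term per t1
    obj_best <- -Inf; bt <- c(NA, NA)
    for (a in t1) {
      if (!is.finite(lead[a])) next
      t2 <- seq.int(a + 1L, B - 1L)
      o <- lead[a] + term(a + 1L, t2) + term(t2 + 1L, B)
      m <- which.max(o)
      if (o[m] > obj_best) { obj_best <- o[m]; bt <- c(a, t2[m]) }
    }
    if (!is.finite(obj_best)) stopf("otsu_thresholds: degenerate histogram")
    return(lo + w * bt)
  }
  combos <- utils::combn(B - 1L, n_classes - 1L)
  obj_best <- -Inf; bt <- NULL
  for (k in seq_len(ncol(combos))) {
    bnd <- combos[, k]
    lo_i <- c(1L, bnd + 1L); hi_i <- c(bnd, B)
    o <- sum(term(lo_i, hi_i))
    if (is.finite(o) && o > obj_best) { obj_best <- o; bt <- bnd }
  }
  if (is.null(bt)) stopf("otsu_thresholds: degenerate histogram")
  lo + w * bt
}

#' Isolate the collecting system from a kidney segmentation
#'
#' Post-processing of a whole-kidney segmentation on delayed-phase CT: the
#' kidney mask is dilated with a box element so the whole collecting system is
#' covered, the CT is masked to the dilated region, a three-class Otsu
#' threshold separates background / parenchyma / contrast-filled cavity among
#' the masked voxels only, and the highest-intensity class is returned.
#'
#' @param ct A [uro_volume()] (HU or normalized; only ordering matters).
#' @param kidney_mask Binary [uro_labelmap()] of the whole kidney, aligned
#'   with `ct`.
#' @param elem Dilation element, default [structuring_element()] (5 x 9 x 9).
#' @param largest_cc Keep only the largest 6-connected component (default
#'   `FALSE`).
#' @return Binary `uro_labelmap` of the collecting system; always a subset of
#'   the dilated kidney mask.
#' @export
extract_collecting_system <- function(ct, kidney_mask,
                                      elem = structuring_element(),
                                      largest_cc = FALSE) {
  stopifnot(inherits(ct, "uro_volume"), inherits(kidney_mask, "uro_volume"))
  check_aligned(ct, kidney_mask)
  km <- kidney_mask$data > 0
  if (!any(km)) stopf("extract_collecting_system: kidney mask is empty")
  bin <- uro_labelmap(array(as.integer(km), dim(ct$data)),
                      ct$spacing, ct$origin,
                      semantics = c(background = 0L, foreground = 1L))
  dil <- dilate(bin, elem)$data > 0
  th <- otsu_thresholds(ct$data[dil], n_classes = 3L)
  out <- dil & (ct$data > th[2])
  if (largest_cc && any(out)) {
    lab <- cpp_label_components(as.integer(out), dim(ct$data))
    keep <- which.max(tabulate(lab[lab > 0L]))
    out <- array(lab == keep, dim(ct$data))
  }
  uro_labelmap(array(as.integer(out), dim(ct$data)), ct$spacing, ct$origin,
               semantics = c(background = 0L, collecting_system = 1L))
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Binary [uro_labelmap()]s (or `uro_volume`s) of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "uro_volume"), inherits(b, "uro_volume"))
  if (!identical(dim(a$data), dim(b$data)))
    stopf("dice: shape mismatch %s vs %s",
          paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x"))
  av <- a$data > 0; bv <- b$data > 0
  denom <- sum(av) + sum(bv)
  if (denom == 0) return(1.0)
  2 * sum(av & bv) / denom
}

#' Sliding-window prediction over a volume
#'
#' Tiles the volume with windows of shape `patch` at stride
#' `patch * (1 - overlap)` per axis, snapping the final window to the volume
#' boundary, applies `predictor` to each window, and averages overlapping
#' predictions voxelwise.
#'
#' @param vol A [uro_volume()].
#' @param predictor Function mapping a 3D array (patch, values in `[0, 1]`) to
#'   a same-shape array of scores in `[0, 1]`.
#' @param patch Window shape `(z, y, x)`, each <= the volume shape.
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return A `uro_volume` of fused scores.
#' @export
sliding_window_predict <- function(vol, predictor, patch = c(128L, 128L, 128L),
                                   overlap = 0.5) {
  stopifnot(inherits(vol, "uro_volume"), is.function(predictor))
  patch <- as.integer(patch)
  dms <- dim(vol$data)
  if (any(patch > dms))
    stopf("patch %s exceeds volume shape %s",
          paste(patch, collapse = "x"), paste(dms, collapse = "x"))
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  starts <- lapply(1:3, function(a) window_starts(dms[a], patch[a], overlap))
  acc <- array(0, dms); cntv <- array(0L, dms)
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]]) {
    iz <- sz:(sz + patch[1] - 1L)
    iy <- sy:(sy + patch[2] - 1L)
    ix <- sx:(sx + patch[3] - 1L)
    p <- vol$data[iz, iy, ix, drop = FALSE]
    s <- predictor(p)
    if (!identical(dim(s), dim(p)))
      stopf("predictor returned shape %s for patch %s",
            paste(dim(s), collapse = "x"), paste(dim(p), collapse = "x"))
    if (any(!is.finite(s))) stopf("predictor returned non-finite scores")
    acc[iz, iy, ix] <- acc[iz, iy, ix] + s
    cntv[iz, iy, ix] <- cntv[iz, iy, ix] + 1L
  }
  uro_volume(acc / cntv, vol$spacing, vol$origin)
}

# 1-based window start offsets: stride = patch * (1 - overlap), final window
# snapped inside the axis
window_starts <- function(n, p, overlap) {
  stride <- max(1L, as.integer(round(p * (1 - overlap))))
  s <- seq.int(0L, n - p, by = stride)
  if (s[length(s)] != n - p) s <- c(s, n - p)
  s + 1L
}

#' Training-time augmentation operators
#'
#' Seeded augmentations matching a 3D segmentation training recipe: uniform
#' intensity shifts within `+/- 0.026`, class-balanced patch cropping, random
#' affine transforms (rotation within `+/- 30` degrees and per-axis scaling
#' within `+/- 10%`), and Gaussian smoothing with sigma drawn from
#' `[0.5, 1.5]` voxels.
#'
#' @param patch 3D numeric array (values in `[0, 1]` for intensity ops).
#' @param max_shift Intensity shift bound (default 0.026).
#' @param seed Optional integer; when given, the operator is deterministic and
#'   the caller's RNG stream is untouched.
#' @return The augmented array (`augment_balanced_crop` returns a list of
#'   crops, each `list(ct=, labels=, center_label=)`).
#' @name augment
NULL

#' @rdname augment
#' @export
augment_intensity_shift <- function(patch, max_shift = 0.026, seed = NULL) {
  with_seed(seed, patch + runif(1, -max_shift, max_shift))
}

#' @rdname augment
#' @param sigma_range Range for the smoothing sigma in voxels.
#' @export
augment_random_smooth <- function(patch, sigma_range = c(0.5, 1.5), seed = NULL) {
  sigma <- with_seed(seed, runif(1, sigma_range[1], sigma_range[2]))
  out <- cpp_gauss3d(as.numeric(patch), dim(patch), sigma)
  dim(out) <- dim(patch)
  out
}

#' @rdname augment
#' @param max_rot_deg Rotation bound per axis, degrees.
#' @param max_scale Scaling bound per axis (0.1 = +/- 10%).
#' @export
augment_random_affine <- function(patch, max_rot_deg = 30, max_scale = 0.1,
                                  seed = NULL) {
  prm <- with_seed(seed, list(rot = runif(3, -max_rot_deg, max_rot_deg),
                              scl = runif(3, 1 - max_scale, 1 + max_scale)))
  th <- prm$rot * pi / 180
  # rotations about the three index axes (z, y, x); applied as Rz Ry Rx
  rot1 <- function(a, i, j) {
    m <- diag(3); m[i, i] <- cos(a); m[j, j] <- cos(a)
    m[i, j] <- -sin(a); m[j, i] <- sin(a); m
  }
  R <- rot1(th[1], 2, 3) %*% rot1(th[2], 1, 3) %*% rot1(th[3], 1, 2)
  A <- R %*% diag(prm$scl)
  M <- solve(A)  # output index -> source index
  ctr <- (dim(patch) - 1) / 2
  t_off <- as.numeric(ctr - M %*% ctr)
  out <- cpp_affine_sample(as.numeric(patch), dim(patch), M, t_off,
                           nearest = FALSE, outside = 0)
  dim(out) <- dim(patch)
  out
}

#' @rdname augment
#' @param ct A [uro_volume()]; `labels` an aligned [uro_labelmap()].
#' @param labels Label map supplying the foreground class (> 0).
#' @param n_crops Number of crops (default 16).
#' @param size Crop shape `(z, y, x)`.
#' @export
augment_balanced_crop <- function(ct, labels, n_crops = 16L,
                                  size = c(128L, 128L, 128L), seed = NULL) {
  stopifnot(inherits(ct, "uro_volume"), inherits(labels, "uro_volume"))
  check_aligned(ct, labels)
  size <- as.integer(size)
  dms <- dim(ct$data)
  if (any(size > dms))
    stopf("crop size %s exceeds volume shape %s",
          paste(size, collapse = "x"), paste(dms, collapse = "x"))
  fg <- which(labels$data > 0)
  bg <- which(labels$data == 0)
  if (length(fg) == 0L) warning("balanced crop: no foreground voxels; all centers background")
  if (length(bg) == 0L) warning("balanced crop: no background voxels; all centers foreground")
  with_seed(seed, {
    lapply(seq_len(n_crops), function(i) {
      want_fg <- (i %% 2L == 1L)
      pool <- if (want_fg && length(fg) > 0L) fg else if (!want_fg && length(bg) > 0L) bg
              else if (length(fg) > 0L) fg else bg
      v <- pool[sample.int(length(pool), 1L)]
      idx <- arrayInd(v, dms)[1, ]
      lo <- pmin(pmax(idx - size %/% 2L, 1L), dms - size + 1L)
      rng <- lapply(1:3, function(a) lo[a]:(lo[a] + size[a] - 1L))
      list(ct = ct$data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
           labels = labels$data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
           center_label = labels$data[idx[1], idx[2], idx[3]])
    })
  })
}
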