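#' Image feature sets
#'
#' An `n x d` matrix of image embeddings tagged with the extractor that
#' produced it.  FID requires `n >= 2`.  The default extractor identifier
#' used for parity with inception-based reporting is
#' `"inception-v3-pool3"`; the package itself ships a deterministic
#' random-projection extractor so no pretrained weights are needed.
#'
#' @param matrix `n x d` numeric matrix.
#' @param extractor_id Character tag.
#' @export
uro_features <- function(matrix, extractor_id = "unknown") {
  matrix <- as.matrix(matrix)
  if (any(!is.finite(matrix))) stopf("feature matrix contains non-finite values")
  structure(list(matrix = matrix, extractor_id = extractor_id),
            class = "uro_features")
}

#' Deterministic random-projection feature extractor
#'
#' Flattens each image and projects it with a fixed seeded Gaussian matrix to
#' `d_out` dimensions.  All images in one call must share a resolution.
#'
#' @param images List of `H x W x 3` arrays in `[0, 1]`.
#' @param d_out Embedding dimension (default 64).
#' @param rng_seed Seed fixing the projection.
#' @return A [uro_features()] set.
#' @export
extract_features_rp <- function(images, d_out = 64L, rng_seed = 7L) {
  if (length(images) == 0L) stopf("no images")
  flat <- vapply(images, function(im) as.numeric(im), numeric(length(images[[1]])))
  d_in <- nrow(flat)
  P <- with_seed(rng_seed, matrix(rnorm(d_in * d_out), d_in, d_out) / sqrt(d_in))
  uro_features(t(flat) %*% P,
               extractor_id = sprintf("random-projection-%d-seed%d", d_out, rng_seed))
}

#' Frechet distance between Gaussian fits of two feature sets
#'
#' `||mu_a - mu_b||^2 + Tr(Sa + Sb - 2 (Sa Sb)^(1/2))` with covariances using
#' the `1/(n-1)` normalization.  The matrix square root is taken through the
#' symmetric form `(Sa^(1/2) Sb Sa^(1/2))^(1/2)` by eigen-decomposition;
#' small negative eigenvalues (above `-1e-8` relative) are clamped to zero,
#' while large negative ones signal ill-conditioning and raise an error.
#'
#' @param a,b [uro_features()] sets with matching dimension, `n >= 2` each.
#' @return Non-negative FID value (symmetric in its arguments).
#' @export
fid <- function(a, b) {
  stopifnot(inherits(a, "uro_features"), inherits(b, "uro_features"))
  A <- a$matrix; B <- b$matrix
  if (ncol(A) != ncol(B)) stopf("feature dimensions differ: %d vs %d", ncol(A), ncol(B))
  if (nrow(A) < 2L || nrow(B) < 2L) stopf("fid needs at least 2 samples per set")
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  Sa <- cov(A); Sb <- cov(B)
  sqrtm_sym <- function(S, rel_tol = 1e-8) {
    e <- eigen(S, symmetric = TRUE)
    lam <- e$values
    sn <- max(abs(lam), 1e-300)
    if (min(lam) < -1e-4 * sn)
      stopf("covariance square root ill-conditioned (eigenvalue %g)", min(lam))
    lam[lam < 0] <- 0
    e$vectors %*% (sqrt(lam) * t(e$vectors))
  }
  Ra <- sqrtm_sym(Sa)
  M <- Ra %*% Sb %*% Ra
  M <- (M + t(M)) / 2
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sn <- max(abs(lam), 1e-300)
  if (min(lam) < -1e-4 * sn)
    stopf("covariance product square root ill-conditioned (eigenvalue %g)", min(lam))
  lam[lam < 0] <- 0
  val <- sum((mu_a - mu_b)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * sum(sqrt(lam))
  max(val, 0)
}

#' Kernel inception distance (unbiased, subset-averaged)
#'
#' Unbiased squared MMD with the cubic polynomial kernel
#' `k(x, y) = (x.y/d + 1)^3`, averaged over `n_subsets` random subsets of
#' size `subset_size` drawn without replacement from each set.
#'
#' @param a,b [uro_features()] sets.
#' @param subset_size Per-subset sample count (default 100, capped at the
#'   smaller set; must be >= 2).
#' @param n_subsets Number of subsets averaged (default 10).
#' @param rng_seed Seed for the subset draws.
#' @return KID estimate (can be slightly negative at the null).
#' @export
kid <- function(a, b, subset_size = 100L, n_subsets = 10L, rng_seed = 1L) {
  stopifnot(inherits(a, "uro_features"), inherits(b, "uro_features"))
  A <- a$matrix; B <- b$matrix
  if (ncol(A) != ncol(B)) stopf("feature dimensions differ: %d vs %d", ncol(A), ncol(B))
  subset_size <- min(as.integer(subset_size), nrow(A), nrow(B))
  if (subset_size < 2L) stopf("subset_size must be >= 2")
  d <- ncol(A)
  kpoly <- function(X, Y) (X %*% t(Y) / d + 1)^3
  with_seed(rng_seed, {
    ests <- vapply(seq_len(n_subsets), function(i) {
      ia <- sample.int(nrow(A), subset_size)
      ib <- sample.int(nrow(B), subset_size)
      X <- A[ia, , drop = FALSE]; Y <- B[ib, , drop = FALSE]
      m <- subset_size
      Kxx <- kpoly(X, X); Kyy <- kpoly(Y, Y); Kxy <- kpoly(X, Y)
      (sum(Kxx) - sum(diag(Kxx))) / (m * (m - 1)) +
        (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1)) -
        2 * mean(Kxy)
    }, numeric(1))
    mean(ests)
  })
}

#' Patchwise contrastive (InfoNCE) loss
#'
#' `-log( exp(q.p/t) / (exp(q.p/t) + sum_n exp(q.neg_n/t)) )`, computed with
#' log-sum-exp stabilization.  This is the correspondence loss used by
#' patch-based unpaired style transfer: a query patch embedding should match
#' its positive (same location in the source) against negatives (other
#' locations).
#'
#' @param query Numeric d-vector.
#' @param positive Numeric d-vector.
#' @param negatives `N x d` matrix, `N >= 1`.
#' @param temperature Softmax temperature (> 0; default 0.07).
#' @return Non-negative scalar loss.
#' @export
patch_nce_loss <- function(query, positive, negatives, temperature = 0.07) {
  query <- as.numeric(query); positive <- as.numeric(positive)
  negatives <- matrix(as.numeric(as.matrix(negatives)), ncol = length(query))
  if (temperature <= 0) stopf("temperature must be > 0")
  if (nrow(negatives) < 1L) stopf("need at least one negative")
  logits <- c(sum(query * positive), as.numeric(negatives %*% query)) / temperature
  if (any(!is.finite(logits))) stopf("non-finite logits")
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  lse - logits[1]
}

#' Feature set binary I/O
#'
#' Features are stored as a flat little-endian float64 file (row-major) with
#' a JSON sidecar `{n, d, extractor_id}` at `<path>.json`.
#'
#' @param fs A [uro_features()] set.
#' @param path Path of the binary payload (sidecar adds `.json`).
#' @export
write_features <- function(fs, path) {
  stopifnot(inherits(fs, "uro_features"))
  con <- file(path, "wb")
  writeBin(as.numeric(t(fs$matrix)), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(n = nrow(fs$matrix), d = ncol(fs$matrix),
                            extractor_id = fs$extractor_id),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "double", n = meta$n * meta$d, size = 8, endian = "little")
  close(con)
  uro_features(matrix(x, meta$n, meta$d, byrow = TRUE), meta$extractor_id)
}
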