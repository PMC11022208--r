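#' Synthetic endoscopy-style image domain
#'
#' Maps grayscale-ish renders to a pinkish tissue palette with low-frequency
#' mottling, a radial vignette, and a few specular highlights, giving the
#' style-transfer smoke harness a reachable target domain that stands in for
#' real ureteroscopy frames (which are private clinical data).  Deterministic
#' under the seed.
#'
#' @param images List of `H x W x 3` arrays in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @return List of styled `H x W x 3` arrays; per-pixel channel ordering is
#'   R >= G >= B before highlights, so channel means order R > G >= B.
#' @export
make_style_domain <- function(images, rng_seed = 1L) {
  if (length(images) == 0L) stopf("no input images")
  with_seed(rng_seed, lapply(images, style_one))
}

style_one <- function(im) {
  d <- dim(im)
  H <- d[1]; W <- d[2]
  lum <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
  yy <- matrix(seq(-1, 1, length.out = H), H, W)
  xx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  # low-frequency mottling: a few random sinusoids
  field <- matrix(0, H, W)
  for (k in 1:3) {
    fx <- runif(1, 0.5, 2.5); fy <- runif(1, 0.5, 2.5)
    ph <- runif(2, 0, 2 * pi)
    field <- field + sin(pi * fx * xx + ph[1]) * sin(pi * fy * yy + ph[2])
  }
  field <- field / 3
  shade <- 0.25 + 0.75 * lum
  mottle <- 1 + 0.25 * field
  vig <- 1 - 0.45 * (xx^2 + yy^2) / 2
  base <- pmax(shade * mottle * vig, 0)
  # specular highlights near bright regions
  spec <- matrix(0, H, W)
  n_blobs <- sample(2:4, 1)
  for (k in seq_len(n_blobs)) {
    cx <- runif(1, -0.6, 0.6); cy <- runif(1, -0.6, 0.6)
    s <- runif(1, 0.02, 0.06)
    spec <- spec + 0.6 * exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * s)) * lum
  }
  out <- array(0, d)
  out[, , 1] <- pmin(1, 0.95 * base + spec)
  out[, , 2] <- pmin(1, 0.45 * base + spec)
  out[, , 3] <- pmin(1, 0.40 * base + spec)
  out
}

# -- miniature style-transfer harness ---------------------------------------
# Generator: per-pixel color map out = sigmoid(W rgb + b) (12 parameters),
# initialized near the identity and perturbed.  Discriminator: logistic
# regression on channel means and second moments (7 parameters).  Trained by
# central-difference gradient descent on the full batch, alternating D and G.

smoke_generator_apply <- function(theta, pix) {
  W <- matrix(theta[1:9], 3, 3)
  b <- theta[10:12]
  z <- pix %*% t(W) + rep(b, each = nrow(pix))
  1 / (1 + exp(-z))
}

smoke_identity_theta <- function() c(as.numeric(diag(3) * 4), rep(-2, 3))

smoke_disc_features <- function(pix) {
  c(colMeans(pix), colMeans(pix^2))
}

smoke_disc_apply <- function(phi, f) {
  1 / (1 + exp(-(sum(phi[1:6] * f) + phi[7])))
}

smoke_patch_index <- function(H, W, n_locs, patch = 4L) {
  ys <- sample.int(H - patch + 1L, n_locs, replace = TRUE)
  xs <- sample.int(W - patch + 1L, n_locs, replace = TRUE)
  idx <- matrix(0L, n_locs, patch * patch)
  for (i in seq_len(n_locs)) {
    gy <- ys[i]:(ys[i] + patch - 1L)
    gx <- xs[i]:(xs[i] + patch - 1L)
    idx[i, ] <- as.integer(outer(gy, (gx - 1L) * H, `+`))
  }
  idx
}

smoke_encode <- function(pix, idx, P) {
  # gather patch RGB blocks and project; rows L2-normalized
  n_locs <- nrow(idx)
  feats <- cbind(matrix(pix[idx, 1], n_locs), matrix(pix[idx, 2], n_locs),
                 matrix(pix[idx, 3], n_locs))
  f <- feats %*% P
  f / pmax(sqrt(rowSums(f^2)), 1e-12)
}

smoke_nce_images <- function(theta, raw_list, idx_list, P, temperature) {
  total <- 0; cnt <- 0
  for (i in seq_along(raw_list)) {
    pix <- raw_list[[i]]
    out <- smoke_generator_apply(theta, pix)
    fq <- smoke_encode(out, idx_list[[i]], P)
    fp <- smoke_encode(pix, idx_list[[i]], P)
    logits <- fq %*% t(fp) / temperature     # row q vs all source patches
    m <- apply(logits, 1, max)
    lse <- m + log(rowSums(exp(logits - m)))
    total <- total + sum(lse - diag(logits))
    cnt <- cnt + nrow(logits)
  }
  total / cnt
}

#' Desk-scale style-transfer smoke training
#'
#' Trains a miniature generator (a per-pixel color transform) against a
#' logistic discriminator on channel statistics, with an adversarial loss
#' plus the patchwise contrastive correspondence loss, by central-difference
#' gradient descent.  This exercises the unpaired translation contract at
#' desk scale; it is not a substitute for a full convolutional model.
#'
#' @param rendered,styled Lists of small `H x W x 3` arrays (<= 64 x 64).
#' @param steps Training steps (<= 500).
#' @param rng_seed Seed controlling initialization and patch locations.
#' @param lr_g,lr_d Learning rates.
#' @param temperature NCE temperature (default 0.07).
#' @param lambda_nce Weight of the NCE term (default 1).
#' @param n_locs Patch locations per image for the NCE term.
#' @return Data frame with one row per step: `loss_d`, `loss_adv`,
#'   `loss_nce`, `loss_g` (the combined generator loss); empty for
#'   `steps = 0`.
#' @export
style_smoke_train <- function(rendered, styled, steps = 200L, rng_seed = 1L,
                              lr_g = 0.3, lr_d = 0.05, temperature = 0.07,
                              lambda_nce = 1, n_locs = 16L) {
  if (length(rendered) == 0L || length(styled) == 0L)
    stopf("rendered and styled image sets must be non-empty")
  d <- dim(rendered[[1]])
  if (max(d[1:2]) > 64L) stopf("smoke harness images must be <= 64 x 64")
  if (steps > 500L) stopf("smoke harness is limited to 500 steps")
  if (steps == 0L) {
    return(data.frame(step = integer(), loss_d = numeric(), loss_adv = numeric(),
                      loss_nce = numeric(), loss_g = numeric()))
  }
  H <- d[1]; W <- d[2]
  raw <- lapply(rendered, function(im) matrix(as.numeric(im), H * W, 3))
  sty <- lapply(styled, function(im) matrix(as.numeric(im), H * W, 3))
  sty_feats <- t(vapply(sty, smoke_disc_features, numeric(6)))
  with_seed(rng_seed, {
    idx_list <- lapply(raw, function(p) smoke_patch_index(H, W, n_locs))
    P <- matrix(rnorm(48L * 16L), 48L, 16L) / sqrt(48)
    theta <- smoke_identity_theta() + rnorm(12, 0, 0.6)
    phi <- rnorm(7, 0, 0.1)
    eps <- 1e-4
    d_loss <- function(phi, theta) {
      pr <- vapply(seq_len(nrow(sty_feats)), function(i)
        smoke_disc_apply(phi, sty_feats[i, ]), numeric(1))
      pf <- vapply(raw, function(p)
        smoke_disc_apply(phi, smoke_disc_features(smoke_generator_apply(theta, p))),
        numeric(1))
      -mean(log(pmax(pr, 1e-12))) - mean(log(pmax(1 - pf, 1e-12)))
    }
    g_losses <- function(theta, phi) {
      pf <- vapply(raw, function(p)
        smoke_disc_apply(phi, smoke_disc_features(smoke_generator_apply(theta, p))),
        numeric(1))
      adv <- -mean(log(pmax(pf, 1e-12)))
      nce <- smoke_nce_images(theta, raw, idx_list, P, temperature)
      c(adv = adv, nce = nce)
    }
    fd_grad <- function(f, x) {
      g <- numeric(length(x))
      for (i in seq_along(x)) {
        xp <- x; xp[i] <- x[i] + eps
        xm <- x; xm[i] <- x[i] - eps
        g[i] <- (f(xp) - f(xm)) / (2 * eps)
      }
      g
    }
    trace <- vector("list", steps)
    for (s in seq_len(steps)) {
      gd <- fd_grad(function(p) d_loss(p, theta), phi)
      phi <- phi - lr_d * gd
      g_obj <- function(th) {
        l <- g_losses(th, phi)
        l[["adv"]] + lambda_nce * l[["nce"]]
      }
      gg <- fd_grad(g_obj, theta)
      theta <- theta - lr_g * gg
      l <- g_losses(theta, phi)
      trace[[s]] <- data.frame(step = s, loss_d = d_loss(phi, theta),
                               loss_adv = l[["adv"]], loss_nce = l[["nce"]],
                               loss_g = l[["adv"]] + lambda_nce * l[["nce"]])
    }
    do.call(rbind, trace)
  })
}
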