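#' Phantom kidney specification
#'
#' Describes a synthetic delayed-phase CT phantom: a contrast-bright
#' collecting system (a pelvis ellipsoid with an entry tube and branching
#' calyces) wrapped in a mid-intensity parenchyma shell on a dark background.
#' Default intensities (-100 / 80 / 300 HU, noise SD 20) give three
#' well-separated modes, emulating the contrast pooling that makes the renal
#' pelvis bright on delayed-phase CT.
#'
#' @param grid_shape Voxels `(z, y, x)` (default 128^3).
#' @param spacing mm per voxel `(x, y, z)`.
#' @param pelvis_semiaxes Ellipsoid semi-axes `(x, y, z)` in mm; the
#'   default is prolate along z, funnel-like toward the entry tube.
#' @param n_calyces Number of calyx branches (2-12; default 6).
#' @param branch_length_range,branch_radius_range Ranges in mm.
#' @param entry_radius Entry (ureter) tube radius, mm.
#' @param intensities Named `(background, parenchyma, contrast)` HU; must be
#'   strictly increasing.
#' @param noise_sd_HU Additive Gaussian noise SD (default 20).
#' @param rng_seed Integer seed; the phantom is deterministic under it.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         spacing = c(1, 1, 1),
                         pelvis_semiaxes = c(10, 9, 13),
                         n_calyces = 6L,
                         branch_length_range = c(18, 30),
                         branch_radius_range = c(3, 5),
                         entry_radius = 4,
                         intensities = c(background = -100, parenchyma = 80,
                                         contrast = 300),
                         noise_sd_HU = 20,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (n_calyces < 2L || n_calyces > 12L) stopf("n_calyces must be in [2, 12]")
  if (!(intensities[3] > intensities[2] && intensities[2] > intensities[1]))
    stopf("intensities must satisfy contrast > parenchyma > background")
  if (min(branch_radius_range) <= max(spacing) || entry_radius <= max(spacing))
    stopf("tube radii must exceed the voxel spacing")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 pelvis_semiaxes = as.numeric(pelvis_semiaxes),
                 n_calyces = as.integer(n_calyces),
                 branch_length_range = as.numeric(branch_length_range),
                 branch_radius_range = as.numeric(branch_radius_range),
                 entry_radius = as.numeric(entry_radius),
                 intensities = intensities, noise_sd_HU = noise_sd_HU,
                 rng_seed = as.integer(rng_seed)),
            class = "uro_phantom_spec")
}

# voxel-center coordinate vectors (x, y, z), mm
grid_axes <- function(shape, spacing) {
  list(x = (seq_len(shape[3]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[1]) - 0.5) * spacing[3])
}

# mark voxels within `radius` of segment a-b (capsule); operates on a bounding
# sub-box only.  mask is modified and returned.
stamp_capsule <- function(mask, axes, a, b, radius) {
  shape <- dim(mask)
  lo <- pmin(a, b) - radius; hi <- pmax(a, b) + radius
  ixr <- which(axes$x >= lo[1] & axes$x <= hi[1])
  iyr <- which(axes$y >= lo[2] & axes$y <= hi[2])
  izr <- which(axes$z >= lo[3] & axes$z <= hi[3])
  if (!length(ixr) || !length(iyr) || !length(izr)) return(mask)
  dz <- length(izr); dy <- length(iyr); dx <- length(ixr)
  Z <- array(rep(axes$z[izr], times = dy * dx), c(dz, dy, dx))
  Y <- array(rep(rep(axes$y[iyr], each = dz), times = dx), c(dz, dy, dx))
  X <- array(rep(axes$x[ixr], each = dz * dy), c(dz, dy, dx))
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- (X - a[1])^2 + (Y - a[2])^2 + (Z - a[3])^2
  } else {
    t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2] + (Z - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (X - a[1] - t * ab[1])^2 + (Y - a[2] - t * ab[2])^2 +
          (Z - a[3] - t * ab[3])^2
  }
  sub <- mask[izr, iyr, ixr, drop = FALSE]
  sub[d2 <= radius^2] <- TRUE
  mask[izr, iyr, ixr] <- sub
  mask
}

#' Generate a phantom kidney with ground truth
#'
#' Builds the collecting-system cavity as a pelvis ellipsoid plus an entry
#' tube and `n_calyces` capsule branches at stratified random azimuths,
#' voxelizes it, wraps it in a parenchyma shell (morphological closing
#' followed by dilation), assigns the three tissue intensities, and adds
#' Gaussian noise.  Ground truth includes the three-class label map and the
#' branch-structured centerline.
#'
#' @param spec A [phantom_spec()].
#' @return `uro_phantom`: list with `ct` ([uro_volume()], HU), `labels`
#'   ([uro_labelmap()]: 0 background / 1 kidney / 2 collecting system),
#'   `centerline` (list with `points` K x 3 mm and `branch` ids; branch 0 is
#'   the entry tube, branches 1..n the calyces), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "uro_phantom_spec"))
  shape <- spec$grid_shape; sp <- spec$spacing
  extent <- shape[c(3, 2, 1)] * sp
  axes <- grid_axes(shape, sp)
  margin <- 6 * max(sp)  # room for the parenchyma shell
  with_seed(spec$rng_seed, {
    c0 <- c(extent[1] / 2, extent[2] / 2, extent[3] * 0.45)
    ax <- spec$pelvis_semiaxes
    # branch geometry
    n <- spec$n_calyces
    # calyx directions on a jittered Fibonacci spiral over the upper polar
    # cap: the first mouth covers the pole and pairwise angles stay large, so
    # neighbouring calyces do not merge into one lumen
    cap <- cos(65 * pi / 180)
    golden <- pi * (3 - sqrt(5))
    mu <- 1 - (1 - cap) * (seq_len(n) - 0.5) / n  # cos(theta), pole first
    thetas <- acos(mu) + runif(n, -0.03, 0.03)
    phis <- golden * seq_len(n) + runif(n, -0.15, 0.15)
    branches <- vector("list", n)
    for (i in seq_len(n)) {
      phi <- phis[i]; theta <- thetas[i]
      dir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      len <- runif(1, spec$branch_length_range[1], spec$branch_length_range[2])
      rad <- runif(1, spec$branch_radius_range[1], spec$branch_radius_range[2])
      # start just inside the pelvis surface along dir
      surf <- 1 / sqrt(sum((dir / ax)^2))
      start <- c0 + dir * (0.8 * surf)
      end <- start + dir * len
      if (any(end - rad - margin < 0) || any(end + rad + margin > extent))
        stopf("branch %d exceeds the grid (tip at %.1f, %.1f, %.1f mm)",
              i, end[1], end[2], end[3])
      branches[[i]] <- list(start = start, end = end, radius = rad)
    }
    entry_end <- c(c0[1], c0[2], margin + spec$entry_radius)
    # voxelize collecting system
    cs <- array(FALSE, shape)
    Z <- array(rep(axes$z, times = shape[2] * shape[3]), shape)
    Y <- array(rep(rep(axes$y, each = shape[1]), times = shape[3]), shape)
    X <- array(rep(axes$x, each = shape[1] * shape[2]), shape)
    cs <- cs | (((X - c0[1]) / ax[1])^2 + ((Y - c0[2]) / ax[2])^2 +
                ((Z - c0[3]) / ax[3])^2 <= 1)
    rm(X, Y, Z)
    cs <- stamp_capsule(cs, axes, c0, entry_end, spec$entry_radius)
    for (b in branches) cs <- stamp_capsule(cs, axes, b$start, b$end, b$radius)
    # parenchyma: closing (dilate+erode, box 7^3) then dilation (box 9^3)
    csi <- array(as.integer(cs), shape)
    dil <- cpp_box_dilate(csi, shape, 3L, 3L, 3L)
    ero <- 1L - cpp_box_dilate(1L - dil, shape, 3L, 3L, 3L)
    kid <- cpp_box_dilate(ero, shape, 4L, 4L, 4L)
    dim(kid) <- shape
    labels <- array(0L, shape)
    labels[kid == 1L] <- 1L
    labels[cs] <- 2L
    intens <- spec$intensities
    ct <- array(intens[[1]], shape)
    ct[labels == 1L] <- intens[[2]]
    ct[labels == 2L] <- intens[[3]]
    if (spec$noise_sd_HU > 0)
      ct <- ct + array(rnorm(length(ct), 0, spec$noise_sd_HU), shape)
    # centerline: points every ~1 mm along entry + branches (pelvis center out)
    polyline <- function(a, b, step = 1) {
      len <- vnorm(b - a)
      tt <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
            a[3] + tt * (b[3] - a[3]))
    }
    pts <- polyline(c0, entry_end)
    branch_id <- rep(0L, nrow(pts))
    for (i in seq_len(n)) {
      pl <- polyline(c0, branches[[i]]$end)
      pts <- rbind(pts, pl)
      branch_id <- c(branch_id, rep(i, nrow(pl)))
    }
    structure(list(ct = uro_volume(ct, sp),
                   labels = uro_labelmap(labels, sp),
                   centerline = list(points = pts, branch = branch_id),
                   spec = spec),
              class = "uro_phantom")
  })
}

#' @export
print.uro_phantom <- function(x, ...) {
  cat(sprintf("<uro_phantom> %s voxels, %d calyces, noise SD %g HU, seed %d\n",
              paste(x$spec$grid_shape, collapse = "x"), x$spec$n_calyces,
              x$spec$noise_sd_HU, x$spec$rng_seed))
  invisible(x)
}

#' Whole-kidney mask of a phantom
#'
#' Binary mask of labels > 0 (parenchyma plus collecting system), the input
#' a kidney segmentation model would produce.
#'
#' @param phantom A `uro_phantom`.
#' @export
phantom_kidney_mask <- function(phantom) {
  uro_labelmap(array(as.integer(phantom$labels$data > 0L),
                     dim(phantom$labels$data)),
               phantom$labels$spacing, phantom$labels$origin,
               semantics = c(background = 0L, foreground = 1L))
}

#' Ground-truth collecting-system mask of a phantom
#'
#' @param phantom A `uro_phantom`.
#' @export
phantom_collecting_mask <- function(phantom) {
  uro_labelmap(array(as.integer(phantom$labels$data == 2L),
                     dim(phantom$labels$data)),
               phantom$labels$spacing, phantom$labels$origin,
               semantics = c(background = 0L, collecting_system = 1L))
}

#' Voxelize a union of capsule tubes
#'
#' Fixture generator for tube phantoms (straight tubes, Y-bifurcations):
#' marks every voxel within `radius` of any segment.
#'
#' @param segments List of `list(a = c(x,y,z), b = c(x,y,z), radius = r)` in
#'   mm.
#' @param grid_shape Voxels `(z, y, x)`.
#' @param spacing mm per voxel `(x, y, z)`.
#' @return Binary [uro_labelmap()].
#' @export
make_tube_mask <- function(segments, grid_shape = c(96L, 96L, 96L),
                           spacing = c(1, 1, 1)) {
  grid_shape <- as.integer(grid_shape)
  axes <- grid_axes(grid_shape, spacing)
  m <- array(FALSE, grid_shape)
  for (s in segments) m <- stamp_capsule(m, axes, s$a, s$b, s$radius)
  uro_labelmap(array(as.integer(m), grid_shape), spacing,
               semantics = c(background = 0L, foreground = 1L))
}
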