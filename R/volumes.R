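#' Volume and label-map containers
#'
#' A `uro_volume` holds a 3D scalar grid together with its voxel spacing and
#' physical origin.  Arrays are indexed `(z, y, x)` throughout the package;
#' `spacing` and `origin` are given in world axis order `(x, y, z)`, in mm.
#' Voxel centers are cell-centered: the voxel with zero-based index `i` along
#' an axis with spacing `s` sits at `origin + (i + 0.5) * s`.
#'
#' A `uro_labelmap` is a `uro_volume` whose data are integer class labels with
#' declared semantics (default `0` background, `1` kidney, `2` collecting
#' system).
#'
#' @param data 3D numeric array indexed `(z, y, x)`.
#' @param spacing Numeric length-3, mm per voxel in `(x, y, z)` order;
#'   strictly positive.
#' @param origin Numeric length-3, mm, world position of the volume corner.
#' @param semantics Named integer vector mapping label values to roles.
#' @return An object of class `uro_volume` (or `uro_labelmap`).
#' @examples
#' v <- uro_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(v$data)
#' @export
uro_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume data must be a 3D array, got %s dimensions",
          paste(length(dim(data)), collapse = "x"))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("origin must be 3 finite values")
  if (any(!is.finite(data)))
    stopf("volume data contains non-finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "uro_volume")
}

#' @rdname uro_volume
#' @export
uro_labelmap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         semantics = c(background = 0L, kidney = 1L,
                                       collecting_system = 2L)) {
  storage.mode(data) <- "integer"
  v <- uro_volume(data, spacing, origin)
  if (!all(unique(as.vector(data)) %in% semantics))
    stopf("label map contains values outside the declared semantics (%s)",
          paste(semantics, collapse = ", "))
  v$semantics <- semantics
  class(v) <- c("uro_labelmap", "uro_volume")
  v
}

#' @export
print.uro_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels (z,y,x), spacing %.4g x %.4g x %.4g mm (x,y,z)\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

is_binary <- function(x) all(as.vector(x$data) %in% c(0, 1))

check_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stopf("volumes are not aligned: shapes %s vs %s",
          paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stopf("volumes are not aligned: spacings differ")
  invisible(TRUE)
}

#' Read and write NIfTI volumes
#'
#' Volumes are stored on disk in NIfTI-1 (`.nii` / `.nii.gz`) with the usual
#' `(x, y, z)` on-disk axis order; in memory the package uses `(z, y, x)`
#' indexing, so arrays are transposed on the way in and out.  Spacing maps to
#' `pixdim` and the origin to the sform translation.
#'
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param vol A [uro_volume()] or [uro_labelmap()].
#' @return `read_volume` returns a `uro_volume`; `read_labelmap` a
#'   `uro_labelmap`; `write_volume` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stopf("%s is not a 3D image (found %d dimensions)", path, length(dim(arr)))
  sp <- RNifti::pixdim(im)[1:3]
  xf <- RNifti::xform(im)
  org <- as.numeric(xf[1:3, 4])
  uro_volume(aperm(arr, c(3, 2, 1)), spacing = sp, origin = org)
}

#' @rdname read_volume
#' @export
read_labelmap <- function(path) {
  v <- read_volume(path)
  if (max(abs(v$data - round(v$data))) > 1e-6)
    stopf("%s does not contain integer labels", path)
  uro_labelmap(array(as.integer(round(v$data)), dim(v$data)),
               spacing = v$spacing, origin = v$origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "uro_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("volume paths must end in .nii or .nii.gz, got %s", path)
  arr <- aperm(vol$data, c(3, 2, 1))
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- vol$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  RNifti::sform(im) <- structure(xf, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Resample a volume to a target grid shape
#'
#' The physical extent (`shape * spacing` per axis) is preserved; the output
#' spacing is the input extent divided by the target shape.  Intensities are
#' interpolated trilinearly; label maps use nearest-neighbour interpolation so
#' class labels are never mixed.
#'
#' @param vol A [uro_volume()] or [uro_labelmap()].
#' @param target_shape Integer length-3 `(nz, ny, nx)`, all at least 2.
#' @param method `"linear"` or `"nearest"`; defaults to `"nearest"` for label
#'   maps and `"linear"` otherwise.
#' @return Resampled volume of the same class as `vol`.
#' @export
resample_to_shape <- function(vol, target_shape,
                              method = if (inherits(vol, "uro_labelmap")) "nearest" else "linear") {
  stopifnot(inherits(vol, "uro_volume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2L))
    stopf("target_shape must be 3 integers, all >= 2")
  method <- match.arg(method, c("linear", "nearest"))
  din <- dim(vol$data)
  out <- cpp_resample(as.numeric(vol$data), din, target_shape,
                      method == "nearest")
  dim(out) <- target_shape
  # dims are (z,y,x) but spacing is (x,y,z)
  sp <- vol$spacing * din[c(3, 2, 1)] / target_shape[c(3, 2, 1)]
  if (inherits(vol, "uro_labelmap")) {
    uro_labelmap(array(as.integer(round(out)), target_shape), sp, vol$origin,
                 semantics = vol$semantics)
  } else {
    uro_volume(out, sp, vol$origin)
  }
}

#' Clip CT intensities to a HU window and normalize to [0, 1]
#'
#' Values are clamped to `[lo, hi]` and mapped affinely so `lo -> 0` and
#' `hi -> 1`.  The defaults are the soft-tissue/contrast window used for
#' delayed-phase CT of the collecting system.
#'
#' @param vol A [uro_volume()] in Hounsfield units.
#' @param lo,hi Window bounds in HU, `lo < hi`.
#' @return A `uro_volume` with values in `[0, 1]`.
#' @export
clip_normalize <- function(vol, lo = -256, hi = 512) {
  stopifnot(inherits(vol, "uro_volume"))
  if (!(lo < hi)) stopf("clip window requires lo < hi (got %g >= %g)", lo, hi)
  d <- pmin(pmax(vol$data, lo), hi)
  uro_volume((d - lo) / (hi - lo), vol$spacing, vol$origin)
}
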