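#' Triangle mesh container
#'
#' Vertices are world coordinates in mm, columns `(x, y, z)`; faces are
#' 1-based vertex index triples.  Degenerate faces (repeated vertices) and
#' out-of-range indices are rejected.
#'
#' @param vertices `n x 3` numeric matrix, mm.
#' @param faces `m x 3` integer matrix of vertex indices (1-based).
#' @export
uro_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stopf("mesh vertices must be n x 3")
  if (any(!is.finite(vertices))) stopf("mesh vertices contain non-finite values")
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stopf("mesh face indices out of range [1, %d]", nrow(vertices))
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
             faces[, 1] == faces[, 3]
    if (any(degen)) stopf("%d degenerate faces (repeated vertex)", sum(degen))
  }
  structure(list(vertices = vertices, faces = faces), class = "uro_mesh")
}

#' @export
print.uro_mesh <- function(x, ...) {
  cat(sprintf("<uro_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] mm\n",
              bb[1,1], bb[2,1], bb[1,2], bb[2,2], bb[1,3], bb[2,3]))
  invisible(x)
}

# undirected edges as a 2-column matrix with sorted rows (may repeat per face)
mesh_edge_list <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Mesh diagnostics
#'
#' `is_closed_manifold` checks that every undirected edge is shared by exactly
#' two faces; `euler_characteristic` returns `V - E + F` (2 for a closed
#' genus-0 surface); `mesh_area` is the total triangle area in mm^2.
#'
#' @param mesh A [uro_mesh()].
#' @export
is_closed_manifold <- function(mesh) {
  e <- mesh_edge_list(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' @rdname is_closed_manifold
#' @export
euler_characteristic <- function(mesh) {
  e <- mesh_edge_list(mesh)
  n_edges <- nrow(unique(e))
  nrow(mesh$vertices) - n_edges + nrow(mesh$faces)
}

#' @rdname is_closed_manifold
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Gaussian smoothing of a binary mask
#'
#' Convolves the `{0, 1}` indicator field with a separable Gaussian
#' (reflective boundary), producing a smooth field in `[0, 1]` suitable for
#' iso-surfacing at 0.5.
#'
#' @param mask Binary [uro_labelmap()].
#' @param sigma_vox Kernel sigma in voxels (default 0.8).
#' @return A [uro_volume()] in `[0, 1]`.
#' @export
smooth_binary <- function(mask, sigma_vox = 0.8) {
  stopifnot(inherits(mask, "uro_volume"))
  if (!is_binary(mask)) stopf("smooth_binary requires a binary mask")
  if (sigma_vox <= 0) stopf("sigma_vox must be > 0")
  out <- cpp_gauss3d(as.numeric(mask$data), dim(mask$data), sigma_vox)
  dim(out) <- dim(mask$data)
  uro_volume(out, mask$spacing, mask$origin)
}

#' Iso-surface extraction
#'
#' Extracts the `iso` level set of a scalar volume as a triangle mesh with
#' vertices in physical mm (spacing and origin applied) and consistent
#' outward orientation.  Cells are decomposed into six tetrahedra, which has
#' no ambiguous sign cases, so the surface of any field not touching the
#' volume boundary is closed and manifold.
#'
#' @param field A [uro_volume()] whose values straddle `iso`.
#' @param iso Iso level (default 0.5, for smoothed binary masks).
#' @return A [uro_mesh()].
#' @export
marching_cubes <- function(field, iso = 0.5) {
  stopifnot(inherits(field, "uro_volume"))
  if (min(field$data) >= iso || max(field$data) <= iso)
    stopf("empty surface: volume values do not straddle iso level %g", iso)
  res <- cpp_marching_tetrahedra(as.numeric(field$data), dim(field$data),
                                 field$spacing, field$origin, iso)
  uro_mesh(res$vertices, res$faces)
}

#' Read and write triangle meshes (PLY / OBJ)
#'
#' PLY is written binary little-endian with double-precision coordinates;
#' ASCII PLY and single-precision files are also read.  OBJ uses the usual
#' 1-based `v`/`f` records.  Meshes round-trip without repair or
#' deduplication.
#'
#' @param path File ending in `.ply` or `.obj`.
#' @param mesh A [uro_mesh()].
#' @param format For `write_mesh(.ply)`: `"binary"` (default) or `"ascii"`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stopf("unknown mesh extension '.%s' (use .ply or .obj)", ext))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "uro_mesh"))
  format <- match.arg(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, binary = format == "binary"),
         obj = write_obj(mesh, path),
         stopf("unknown mesh extension '.%s' (use .ply or .obj)", ext))
  invisible(path)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    if (nf > 0) {
      f0 <- t(mesh$faces) - 1L
      buf <- raw(nf * 13L)
      for (i in seq_len(nf)) {
        off <- (i - 1L) * 13L
        buf[off + 1L] <- as.raw(3L)
        buf[off + 2:13] <- writeBin(as.integer(f0[, i]), raw(), size = 4,
                                    endian = "little")
      }
      writeBin(buf, con)
    }
  } else {
    writeLines(apply(mesh$vertices, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    if (nf > 0)
      writeLines(apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fmt <- NULL; nv <- 0L; nf <- 0L
  vprops <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stopf("%s: truncated PLY header", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex && tok[2] != "list") {
      vprops <- c(vprops, paste(tok[2], tok[3]))
    } else if (tok[1] == "end_header") break
  }
  npp <- length(vprops)
  types <- sub(" .*", "", vprops)
  names <- sub(".* ", "", vprops)
  xyz <- match(c("x", "y", "z"), names)
  if (any(is.na(xyz))) stopf("%s: PLY vertex element lacks x/y/z", path)
  if (identical(fmt, "ascii")) {
    lines <- readLines(con)
    vlines <- lines[seq_len(nv)]
    vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
    V <- vm[, xyz, drop = FALSE]
    Fm <- if (nf > 0) {
      flines <- lines[nv + seq_len(nf)]
      do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
        n <- as.integer(t[1])
        if (n != 3L) stopf("%s: only triangle faces supported", path)
        as.integer(t[2:4]) + 1L
      }))
    } else matrix(integer(), 0, 3)
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(float = 4L, double = 8L, float32 = 4L, float64 = 8L,
               uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L)
    V <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(npp)
      for (p in seq_len(npp)) {
        sz <- sizes[[types[p]]]
        row[p] <- if (types[p] %in% c("float", "float32", "double", "float64"))
          readBin(con, "double", 1, size = sz, endian = "little")
        else readBin(con, "integer", 1, size = sz, endian = "little")
      }
      V[i, ] <- row[xyz]
    }
    Fm <- matrix(integer(), nf, 3)
    for (i in seq_len(nf)) {
      n <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      if (n != 3L) stopf("%s: only triangle faces supported", path)
      Fm[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else stopf("%s: unsupported PLY format '%s'", path, fmt)
  uro_mesh(V, Fm)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " "))), con)
  if (nrow(mesh$faces) > 0)
    writeLines(apply(mesh$faces, 1, function(r)
      paste("f", paste(r, collapse = " "))), con)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t) as.numeric(t[2:4])))
  Fm <- if (length(fl)) do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t) {
    idx <- as.integer(sub("/.*", "", t[-1]))
    if (length(idx) != 3L) stopf("%s: only triangle faces supported", path)
    idx
  })) else matrix(integer(), 0, 3)
  uro_mesh(V %||% matrix(numeric(), 0, 3), Fm)
}

#' Analytic mesh primitives
#'
#' Closed-manifold reference meshes used as fixtures: a UV sphere and a capped
#' cylinder along the z axis.  Both are watertight by construction.
#'
#' @param radius Radius in mm.
#' @param center Center `(x, y, z)` in mm.
#' @param n_theta Azimuthal resolution.
#' @param n_phi,n_axial Polar / axial resolution.
#' @param length Cylinder length in mm (centered on `center`).
#' @export
make_sphere_mesh <- function(radius = 10, center = c(0, 0, 0),
                             n_theta = 48L, n_phi = 24L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ph <- seq(0, pi, length.out = n_phi + 1L)[-c(1L, n_phi + 1L)]
  grid <- expand.grid(phi = ph, theta = th)
  V <- cbind(radius * sin(grid$phi) * cos(grid$theta),
             radius * sin(grid$phi) * sin(grid$theta),
             radius * cos(grid$phi))
  np <- length(ph)
  top <- nrow(V) + 1L; bot <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, radius), c(0, 0, -radius))
  V <- sweep(V, 2, center, `+`)
  idx <- function(i, j) (j - 1L) * np + i  # i over phi, j over theta (1-based)
  faces <- list()
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(top, idx(1L, j), idx(1L, jn))
    faces[[length(faces) + 1L]] <- c(bot, idx(np, jn), idx(np, j))
    for (i in seq_len(np - 1L)) {
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, jn), idx(i, jn))
    }
  }
  uro_mesh(V, do.call(rbind, faces))
}

#' @rdname make_sphere_mesh
#' @export
make_cylinder_mesh <- function(radius = 5, length = 40, center = c(0, 0, 0),
                               n_theta = 32L, n_axial = 40L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(-length / 2, length / 2, length.out = n_axial + 1L)
  V <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  topc <- nrow(V) + 1L; botc <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, length / 2), c(0, 0, -length / 2))
  V <- sweep(V, 2, center, `+`)
  idx <- function(i, j) (i - 1L) * n_theta + j  # i over z rings, j over theta
  faces <- list()
  nr <- n_axial + 1L
  for (i in seq_len(n_axial)) {
    for (j in seq_len(n_theta)) {
      jn <- if (j == n_theta) 1L else j + 1L
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i, jn), idx(i + 1L, jn))
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, jn), idx(i + 1L, j))
    }
  }
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(botc, idx(1L, jn), idx(1L, j))
    faces[[length(faces) + 1L]] <- c(topc, idx(nr, j), idx(nr, jn))
  }
  uro_mesh(V, do.call(rbind, faces))
}
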