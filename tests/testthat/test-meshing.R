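voxel_sphere <- function(n = 32, r = 10) {
  cc <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  uro_labelmap(array(as.integer((g$x - cc)^2 + (g$y - cc)^2 +
                                (g$z - cc)^2 <= r^2), c(n, n, n)),
               semantics = c(background = 0L, foreground = 1L))
}

test_that("smoothing a constant mask is the identity", {
  m <- uro_labelmap(array(1L, c(8, 8, 8)),
                    semantics = c(background = 0L, foreground = 1L))
  s <- smooth_binary(m, 0.8)
  expect_lt(max(abs(s$data - 1)), 1e-6)
})

test_that("a single voxel smooths to the separable kernel center weight", {
  n <- 15
  m <- array(0L, c(n, n, n)); m[8, 8, 8] <- 1L
  sigma <- 0.8
  s <- smooth_binary(uro_labelmap(m, semantics = c(background = 0L,
                                                   foreground = 1L)), sigma)
  r <- max(1, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  w0 <- (k / sum(k))[r + 1]
  expect_equal(s$data[8, 8, 8], w0^3, tolerance = 1e-12)
})

test_that("small sigma approaches the identity", {
  set.seed(1)
  m <- uro_labelmap(array(as.integer(runif(10^3) < 0.3), c(10, 10, 10)),
                    semantics = c(background = 0L, foreground = 1L))
  s <- smooth_binary(m, 0.05)
  expect_lt(max(abs(s$data - m$data)), 1e-6)
  expect_error(smooth_binary(m, 0), "sigma")
})

test_that("sphere label yields a closed manifold mesh with the right area", {
  sph <- voxel_sphere()
  mesh <- marching_cubes(smooth_binary(sph, 0.8))
  expect_true(is_closed_manifold(mesh))
  expect_equal(euler_characteristic(mesh), 2)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  # vertices inside the physical bounding box of the label map
  expect_true(all(mesh$vertices >= 0 & mesh$vertices <= 32))
})

test_that("iso-surfacing an empty field fails loudly", {
  flat <- uro_volume(array(0, c(4, 4, 4)))
  expect_error(marching_cubes(flat), "empty surface")
})

test_that("stronger smoothing does not grow the area of convex solids", {
  sph <- voxel_sphere()
  areas <- vapply(c(0.8, 1.2, 1.8, 2.6), function(s)
    mesh_area(marching_cubes(smooth_binary(sph, s))), numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  # ellipsoid
  n <- 32; cc <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  ell <- uro_labelmap(array(as.integer(((g$x - cc) / 12)^2 + ((g$y - cc) / 9)^2 +
                                       ((g$z - cc) / 7)^2 <= 1), c(n, n, n)),
                      semantics = c(background = 0L, foreground = 1L))
  areas2 <- vapply(c(0.8, 1.6, 2.4), function(s)
    mesh_area(marching_cubes(smooth_binary(ell, s))), numeric(1))
  expect_true(all(diff(areas2) <= 1e-9))
})

test_that("PLY round-trips binary and ascii exactly", {
  mesh <- marching_cubes(smooth_binary(voxel_sphere(16, 5), 0.8))
  for (fmt in c("binary", "ascii")) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_mesh(mesh, f, format = fmt)
    m2 <- read_mesh(f)
    expect_lt(max(abs(mesh$vertices - m2$vertices)), 1e-6)
    expect_identical(mesh$faces, m2$faces)
  }
})

test_that("OBJ uses 1-based indices and round-trips a single triangle", {
  tri <- uro_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)))
  f <- withr::local_tempfile(fileext = ".obj")
  write_mesh(tri, f)
  txt <- readLines(f)
  expect_true("f 1 2 3" %in% txt)
  m2 <- read_mesh(f)
  expect_equal(m2$vertices, tri$vertices, ignore_attr = TRUE)
  expect_identical(m2$faces, tri$faces)
})

test_that("non-manifold meshes round-trip without silent repair", {
  # two triangles sharing an edge plus a dangling third on the same edge
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  f3 <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  m <- uro_mesh(v, f3)
  expect_false(is_closed_manifold(m))
  f <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_identical(m2$faces, m$faces)
  expect_equal(nrow(m2$vertices), 5)
  expect_error(read_mesh(withr::local_tempfile(fileext = ".stl")), "no such file")
  fbad <- withr::local_tempfile(fileext = ".stl")
  writeLines("solid", fbad)
  expect_error(read_mesh(fbad), "unknown mesh extension")
})

test_that("mesh constructor rejects bad faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(uro_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(uro_mesh(v, rbind(c(1, 2, 2))), "degenerate")
})
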