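# triangle strip: vertices in two rows, t sequential triangles
strip_mesh <- function(t = 10) {
  n <- t + 2
  v <- cbind(seq_len(n), rep(c(0, 1), length.out = n), 0)
  f <- do.call(rbind, lapply(seq_len(t), function(i) c(i, i + 1, i + 2)))
  uro_mesh(v, f)
}

test_that("wave propagation equals brute-force BFS hop counts", {
  m <- strip_mesh(15)
  s1 <- propagate_wave(m, 1)
  expect_identical(as.integer(s1), oracle_bfs(m, 1))
  expect_equal(s1[1], 0L)
  expect_equal(max(s1), max(oracle_bfs(m, 1)))  # farthest vertex agreement
  sph <- make_sphere_mesh(5, n_theta = 16, n_phi = 8)
  s2 <- propagate_wave(sph, 3)
  expect_identical(as.integer(s2), oracle_bfs(sph, 3))
  expect_error(propagate_wave(m, 99), "out of range")
})

test_that("step numbers differ by at most one across any mesh edge", {
  m <- fix_tube_mesh()
  s <- propagate_wave(m, 1)
  e <- unique(uroscope:::mesh_edge_list(m))
  expect_true(all(abs(s[e[, 1]] - s[e[, 2]]) <= 1L))
})

test_that("disconnected components are reported as unreached", {
  a <- make_sphere_mesh(3, c(0, 0, 0), 12, 6)
  b <- make_sphere_mesh(3, c(20, 0, 0), 12, 6)
  both <- uro_mesh(rbind(a$vertices, b$vertices),
                   rbind(a$faces, b$faces + nrow(a$vertices)))
  s <- propagate_wave(both, 1)
  expect_true(anyNA(s))
  expect_equal(sort(unique(attr(s, "components"))), 1:2)
  expect_true(all(attr(s, "unreached") > nrow(a$vertices)))
})

test_that("cylinder skeleton nodes sit on the axis", {
  cy <- make_cylinder_mesh(radius = 5, length = 60, center = c(10, 12, 30),
                           n_theta = 48, n_axial = 60)
  sk <- skeletonize(cy, wave_params(step_size = 5, wave_count = 1))
  off <- sqrt((sk$nodes[, 1] - 10)^2 + (sk$nodes[, 2] - 12)^2)
  expect_lt(max(off), 0.1 * 5)
  # all nodes strictly inside the closed tube
  expect_true(all(sk$nodes[, 3] > 0 & sk$nodes[, 3] < 60))
})

test_that("doubling the step size never increases the node count", {
  for (m in list(fix_tube_mesh(), fix_y_mesh())) {
    s <- propagate_wave(m, 1)
    counts <- vapply(c(1L, 2L, 5L, 10L), function(ss)
      nrow(contract_to_skeleton(m, s, ss)$nodes), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a Y-shaped tube gives exactly one bifurcation node", {
  sk <- skeletonize(fix_y_mesh(), wave_params(step_size = 5, wave_count = 2))
  deg <- tabulate(c(sk$edges), nbins = nrow(sk$nodes))
  expect_equal(sum(deg == 3), 1)
  expect_equal(sum(deg == 1), 3)  # entry + two branch tips
})

test_that("single-wave skeletonization reduces to plain contraction", {
  m <- fix_tube_mesh()
  sk1 <- skeletonize(m, wave_params(step_size = 5, wave_count = 1))
  seed <- sk1$meta$seeds[1]
  ref <- contract_to_skeleton(m, propagate_wave(m, seed), 5L)
  expect_equal(sk1$nodes, ref$nodes)
  expect_identical(sk1$edges, ref$edges)
})

test_that("skeletonization is deterministic under a fixed seed", {
  m <- fix_tube_mesh()
  a <- skeletonize(m, wave_params(rng_seed = 17))
  b <- skeletonize(m, wave_params(rng_seed = 17))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
})

test_that("a second wave does not worsen surface coverage on tubes", {
  m <- fix_tube_mesh()
  c1 <- coverage_distance(m, skeletonize(m, wave_params(wave_count = 1)),
                          2000, rng_seed = 3)
  c2 <- coverage_distance(m, skeletonize(m, wave_params(wave_count = 2)),
                          2000, rng_seed = 3)
  expect_lte(c2, c1 * 1.05)
})

test_that("coverage distance matches the exhaustive point-segment oracle", {
  set.seed(5)
  for (rep in 1:3) {
    nodes <- matrix(runif(15, 0, 50), 5, 3)
    edges <- cbind(1:4, 2:5)
    sk <- uro_skeleton(nodes, edges)
    pts <- matrix(runif(600, 0, 50), 200, 3)
    got <- points_to_skeleton_distance(pts, sk)
    want <- apply(pts, 1, function(p) {
      min(apply(edges, 1, function(e) {
        a <- nodes[e[1], ]; b <- nodes[e[2], ]
        ab <- b - a
        t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
        sqrt(sum((p - a - t * ab)^2))
      }))
    })
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("coverage of a sphere around a center node is the radius", {
  sm <- make_sphere_mesh(radius = 10, center = c(5, 5, 5),
                         n_theta = 64, n_phi = 32)
  sk <- uro_skeleton(matrix(c(5, 5, 5), 1, 3), matrix(integer(), 0, 2))
  expect_equal(coverage_distance(sm, sk, 5000, rng_seed = 1), 10,
               tolerance = 0.02)
})

test_that("a skeleton through every sample point has zero distance", {
  m <- make_cylinder_mesh(3, 20)
  pts <- sample_mesh_surface(m, 50, rng_seed = 2)
  sk <- uro_skeleton(pts, cbind(seq_len(49), seq_len(49) + 1))
  expect_lt(mean(points_to_skeleton_distance(pts, sk)), 1e-12)
  expect_error(coverage_distance(m, uro_skeleton(matrix(numeric(), 0, 3),
                                                 matrix(integer(), 0, 2))),
               "empty skeleton")
})

test_that("skeleton JSON round-trips", {
  sk <- skeletonize(fix_tube_mesh(), wave_params(rng_seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_skeleton(sk, f)
  sk2 <- read_skeleton(f)
  expect_equal(sk2$nodes, sk$nodes, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(as.matrix(sk2$edges)), unname(as.matrix(sk$edges)))
  expect_equal(sk2$meta$step_size, 5)
})
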