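# Shared fixtures, memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(build), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# noiseless default phantom plus its mesh and skeleton
fix_phantom0 <- function() fixture("phantom0", {
  make_phantom(phantom_spec(rng_seed = 7L, noise_sd_HU = 0))
})

fix_mesh0 <- function() fixture("mesh0", {
  marching_cubes(smooth_binary(phantom_collecting_mask(fix_phantom0()), 0.8))
})

# voxelized straight tube and Y-bifurcation masks / meshes
fix_tube_mask <- function() fixture("tube_mask", {
  make_tube_mask(list(list(a = c(48, 48, 12), b = c(48, 48, 84), radius = 6)))
})

fix_tube_mesh <- function() fixture("tube_mesh", {
  marching_cubes(smooth_binary(fix_tube_mask(), 0.8))
})

fix_y_mesh <- function() fixture("y_mesh", {
  ym <- make_tube_mask(list(
    list(a = c(48, 48, 12), b = c(48, 48, 48), radius = 6),
    list(a = c(48, 48, 48), b = c(28, 48, 80), radius = 5),
    list(a = c(48, 48, 48), b = c(68, 48, 80), radius = 5)))
  marching_cubes(smooth_binary(ym, 0.8))
})

# single flat quad wall at x = d, spanning far in y/z
wall_mesh <- function(d = 50) {
  uro_mesh(rbind(c(d, -200, -200), c(d, 200, -200), c(d, 200, 200),
                 c(d, -200, 200)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

# ground-truth centerline as a skeleton (polyline per branch)
centerline_skeleton <- function(phantom) {
  pts <- phantom$centerline$points
  br <- phantom$centerline$branch
  edges <- do.call(rbind, lapply(unique(br), function(b) {
    idx <- which(br == b)
    cbind(idx[-length(idx)], idx[-1])
  }))
  uro_skeleton(pts, edges)
}
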