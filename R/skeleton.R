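#' Curve skeleton container
#'
#' A skeleton is a graph of 3D nodes (mm) produced by contracting rings of
#' mesh vertices reached at the same wave-propagation step.
#'
#' @param nodes `k x 3` numeric matrix of node positions, mm.
#' @param edges 2-column integer matrix of node index pairs (1-based).
#' @param node_ring_size Integer vector: mesh vertices contracted into each
#'   node.
#' @param meta Named list of provenance (step_size, wave_count, rng_seed).
#' @export
uro_skeleton <- function(nodes, edges, node_ring_size = NULL, meta = list()) {
  nodes <- as.matrix(nodes)
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  if (ncol(nodes) != 3L) stopf("skeleton nodes must be k x 3")
  if (nrow(edges) > 0 && (min(edges) < 1L || max(edges) > nrow(nodes)))
    stopf("skeleton edge indices out of range")
  structure(list(nodes = nodes, edges = edges,
                 node_ring_size = node_ring_size %||% rep(1L, nrow(nodes)),
                 meta = meta),
            class = "uro_skeleton")
}

#' @export
print.uro_skeleton <- function(x, ...) {
  deg <- tabulate(c(x$edges), nbins = nrow(x$nodes))
  cat(sprintf("<uro_skeleton> %d nodes, %d edges, %d tips\n",
              nrow(x$nodes), nrow(x$edges), sum(deg == 1L)))
  invisible(x)
}

#' Wave-propagation parameters
#'
#' @param step_size Rings collapsed per skeleton node (>= 1; default 5).
#' @param wave_count Number of propagation passes averaged (>= 1; default 2).
#' @param seed_strategy Seed vertex selection; `"farthest_point"` picks
#'   maximally separated extremes deterministically.
#' @param rng_seed Integer seed controlling any randomized choices.
#' @export
wave_params <- function(step_size = 5L, wave_count = 2L,
                        seed_strategy = "farthest_point", rng_seed = 1L) {
  step_size <- as.integer(step_size); wave_count <- as.integer(wave_count)
  if (step_size < 1L || wave_count < 1L)
    stopf("step_size and wave_count must be >= 1")
  seed_strategy <- match.arg(seed_strategy, "farthest_point")
  structure(list(step_size = step_size, wave_count = wave_count,
                 seed_strategy = seed_strategy, rng_seed = as.integer(rng_seed)),
            class = "uro_wave_params")
}

mesh_graph <- function(mesh) {
  e <- unique(mesh_edge_list(mesh))
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  igraph::add_edges(g, t(e))
}

#' Propagate a wave across a mesh surface
#'
#' Breadth-first front propagation over the mesh edge graph from a source
#' vertex; the step number of a vertex is its hop distance from the source.
#' Vertices in other connected components are unreachable and returned as
#' `NA`, with a per-component report attached.
#'
#' @param mesh A [uro_mesh()].
#' @param source_vertex Vertex index (1-based).
#' @return Integer vector of step numbers (source = 0; unreached = `NA`),
#'   with attribute `components` (igraph membership) when the mesh is
#'   disconnected.
#' @export
propagate_wave <- function(mesh, source_vertex) {
  stopifnot(inherits(mesh, "uro_mesh"))
  nv <- nrow(mesh$vertices)
  source_vertex <- as.integer(source_vertex)
  if (source_vertex < 1L || source_vertex > nv)
    stopf("source vertex %d out of range [1, %d]", source_vertex, nv)
  g <- mesh_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = source_vertex, weights = NA))
  steps <- rep(NA_integer_, nv)
  steps[is.finite(d)] <- as.integer(d[is.finite(d)])
  if (anyNA(steps)) {
    comp <- igraph::components(g)
    attr(steps, "components") <- comp$membership
    attr(steps, "unreached") <- which(is.na(steps))
  }
  steps
}

#' Contract wave rings to a skeleton
#'
#' Vertices are grouped by `floor(step / step_size)`; within a group, vertices
#' connected through mesh edges form one ring (so two branches at the same
#' depth contract to separate nodes).  Each ring contracts to the centroid of
#' its vertices; rings in adjacent step groups sharing a mesh edge are joined
#' by a skeleton edge.
#'
#' Mesh triangulation irregularity can split one wavefront into several
#' same-step fragments (typically one or two stray vertices at a branch-tip
#' cap).  Fragments are re-joined before contraction: rings at the same
#' quantized step that share a neighbouring ring and whose centroids lie
#' within the sum of their ring radii (RMS vertex-to-centroid distance) are
#' treated as one ring, and a ring with fewer than 3 vertices -- too few to
#' bound a wavefront cross-section -- is absorbed into the neighbouring ring
#' it shares the most mesh edges with.
#'
#' @param mesh A [uro_mesh()].
#' @param steps Per-vertex step numbers from [propagate_wave()].
#' @param step_size Ring quantization (>= 1).
#' @return A [uro_skeleton()].
#' @export
contract_to_skeleton <- function(mesh, steps, step_size = 5L) {
  stopifnot(inherits(mesh, "uro_mesh"))
  nv <- nrow(mesh$vertices)
  if (nv == 0L) stopf("empty mesh")
  if (length(steps) != nv) stopf("steps length %d != vertex count %d", length(steps), nv)
  step_size <- as.integer(step_size)
  if (step_size < 1L) stopf("step_size must be >= 1")
  keep <- !is.na(steps)
  if (!all(keep)) warning(sprintf("%d unreached vertices dropped", sum(!keep)))
  grp <- rep(NA_integer_, nv)
  grp[keep] <- as.integer(steps[keep]) %/% step_size
  e <- unique(mesh_edge_list(mesh))
  e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
  same <- grp[e[, 1]] == grp[e[, 2]]
  g_in <- igraph::make_empty_graph(n = nv, directed = FALSE)
  g_in <- igraph::add_edges(g_in, t(e[same, , drop = FALSE]))
  memb <- igraph::components(g_in)$membership
  memb[!keep] <- NA
  rings <- sort(unique(memb[keep]))
  ring_id <- match(memb, rings)           # per-vertex ring index
  cross <- e[!same, , drop = FALSE]
  # re-join wavefront fragments: same-group rings sharing a neighbour ring
  # whose centroids are closer than the sum of their ring radii
  repeat {
    k <- max(ring_id, na.rm = TRUE)
    cen <- matrix(0, k, 3)
    for (a in 1:3) cen[, a] <- tapply(mesh$vertices[keep, a], ring_id[keep], mean)
    rad <- sqrt(tapply(rowSums((mesh$vertices[keep, , drop = FALSE] -
                                cen[ring_id[keep], , drop = FALSE])^2),
                       ring_id[keep], mean))
    rgrp <- tapply(grp[keep], ring_id[keep], function(g) g[1])
    adj <- unique(cbind(pmin(ring_id[cross[, 1]], ring_id[cross[, 2]]),
                        pmax(ring_id[cross[, 1]], ring_id[cross[, 2]])))
    nbr <- lapply(seq_len(k), function(i)
      c(adj[adj[, 1] == i, 2], adj[adj[, 2] == i, 1]))
    merged <- FALSE
    remap <- seq_len(k)
    for (g in unique(rgrp)) {
      members <- which(rgrp == g)
      if (length(members) < 2L) next
      for (ii in seq_along(members)) for (jj in seq_len(ii - 1L)) {
        a <- members[ii]; b <- members[jj]
        if (length(intersect(nbr[[a]], nbr[[b]])) == 0L) next
        if (vnorm(cen[a, ] - cen[b, ]) < rad[a] + rad[b]) {
          remap[remap == remap[a]] <- remap[b]
          merged <- TRUE
        }
      }
    }
    if (!merged) {
      # absorb degenerate rings (< 3 vertices) into their strongest neighbour
      sizes <- tabulate(ring_id[keep], nbins = k)
      small <- which(sizes > 0L & sizes < 3L)
      ca <- ring_id[cross[, 1]]; cb <- ring_id[cross[, 2]]
      for (s in small) {
        touching <- c(cb[ca == s], ca[cb == s])
        touching <- touching[touching != s]
        if (length(touching) == 0L) next
        tab <- table(touching)
        target <- as.integer(names(tab)[which.max(tab)])
        remap[remap == remap[s]] <- remap[target]
        merged <- TRUE
      }
      if (!merged) break
    }
    ring_id <- match(remap[ring_id], sort(unique(remap)))
  }
  k <- max(ring_id, na.rm = TRUE)
  nodes <- matrix(0, k, 3)
  for (a in 1:3) nodes[, a] <- tapply(mesh$vertices[keep, a], ring_id[keep], mean)
  ring_size <- as.integer(table(ring_id[keep]))
  se <- unique(cbind(pmin(ring_id[cross[, 1]], ring_id[cross[, 2]]),
                     pmax(ring_id[cross[, 1]], ring_id[cross[, 2]])))
  se <- se[se[, 1] != se[, 2], , drop = FALSE]
  uro_skeleton(nodes, se, ring_size,
               meta = list(step_size = step_size, wave_count = 1L))
}

# deterministic farthest-point seed sequence: v1 = farthest from vertex 1,
# v2 = farthest from v1, further seeds maximize the minimum hop distance to
# the chosen set
wave_seeds <- function(mesh, n_seeds) {
  g <- mesh_graph(mesh)
  d0 <- as.numeric(igraph::distances(g, v = 1L, weights = NA))
  d0[!is.finite(d0)] <- -1
  s1 <- which.max(d0)
  seeds <- s1
  dmat <- as.numeric(igraph::distances(g, v = s1, weights = NA))
  dmat[!is.finite(dmat)] <- -1
  dmin <- dmat
  while (length(seeds) < n_seeds) {
    cand <- which.max(dmin)
    if (dmin[cand] <= 0)
      stopf("wave_count %d exceeds the number of distinct seed vertices", n_seeds)
    seeds <- c(seeds, cand)
    dn <- as.numeric(igraph::distances(g, v = cand, weights = NA))
    dn[!is.finite(dn)] <- -1
    dmin <- pmin(dmin, dn)
  }
  seeds
}

#' Wave-propagation skeletonization
#'
#' Runs `wave_count` wave propagations from deterministic farthest-point
#' seeds, contracts each into a skeleton, and averages node positions across
#' waves: every node of the first (reference) wave is matched to the nearest
#' node of each later wave (within twice the median skeleton segment length)
#' and matched positions are averaged.  The reference wave supplies the
#' topology; with `wave_count = 1` the result is exactly
#' [contract_to_skeleton()].
#'
#' @param mesh A [uro_mesh()].
#' @param params A [wave_params()].
#' @return A [uro_skeleton()].
#' @export
skeletonize <- function(mesh, params = wave_params()) {
  stopifnot(inherits(mesh, "uro_mesh"), inherits(params, "uro_wave_params"))
  seeds <- wave_seeds(mesh, params$wave_count)
  skels <- lapply(seeds, function(s)
    contract_to_skeleton(mesh, propagate_wave(mesh, s), params$step_size))
  ref <- skels[[1]]
  if (params$wave_count > 1L) {
    seg_len <- if (nrow(ref$edges) > 0) {
      d <- ref$nodes[ref$edges[, 1], , drop = FALSE] -
           ref$nodes[ref$edges[, 2], , drop = FALSE]
      stats::median(sqrt(rowSums(d^2)))
    } else Inf
    radius <- 2 * seg_len
    acc <- ref$nodes
    wt <- rep(1, nrow(ref$nodes))
    for (w in 2:params$wave_count) {
      other <- skels[[w]]$nodes
      for (i in seq_len(nrow(ref$nodes))) {
        d2 <- colSums((t(other) - ref$nodes[i, ])^2)
        j <- which.min(d2)
        if (sqrt(d2[j]) <= radius) {
          acc[i, ] <- acc[i, ] + other[j, ]
          wt[i] <- wt[i] + 1
        }
      }
    }
    ref$nodes <- acc / wt
  }
  ref$meta <- list(step_size = params$step_size, wave_count = params$wave_count,
                   rng_seed = params$rng_seed, seeds = seeds)
  ref
}

#' Mean surface-to-skeleton distance
#'
#' Samples points uniformly by area on the mesh surface and returns the mean
#' Euclidean distance from each sample to the nearest point on any skeleton
#' edge segment (isolated nodes count as degenerate segments).  Lower values
#' mean the skeleton covers the surface better.
#'
#' @param mesh A [uro_mesh()].
#' @param skel A [uro_skeleton()] with at least one node.
#' @param n_samples Surface samples (default 5000).
#' @param rng_seed Seed for the area-weighted sampling.
#' @return Mean distance in mm.
#' @export
coverage_distance <- function(mesh, skel, n_samples = 5000L, rng_seed = 1L) {
  stopifnot(inherits(mesh, "uro_mesh"), inherits(skel, "uro_skeleton"))
  if (nrow(skel$nodes) == 0L) stopf("empty skeleton")
  pts <- sample_mesh_surface(mesh, n_samples, rng_seed)
  mean(points_to_skeleton_distance(pts, skel))
}

#' @rdname coverage_distance
#' @param pts `n x 3` matrix of query points.
#' @export
points_to_skeleton_distance <- function(pts, skel) {
  pts <- as.matrix(pts)
  segs <- if (nrow(skel$edges) > 0) {
    list(a = skel$nodes[skel$edges[, 1], , drop = FALSE],
         b = skel$nodes[skel$edges[, 2], , drop = FALSE])
  } else {
    list(a = skel$nodes, b = skel$nodes)
  }
  # include isolated nodes as zero-length segments
  deg <- tabulate(c(skel$edges), nbins = nrow(skel$nodes))
  iso <- which(deg == 0L)
  if (length(iso) > 0) {
    segs$a <- rbind(segs$a, skel$nodes[iso, , drop = FALSE])
    segs$b <- rbind(segs$b, skel$nodes[iso, , drop = FALSE])
  }
  best <- rep(Inf, nrow(pts))
  ab <- segs$b - segs$a
  len2 <- rowSums(ab^2)
  for (s in seq_len(nrow(segs$a))) {
    ap <- sweep(pts, 2, segs$a[s, ])
    t <- if (len2[s] > 0) pmin(pmax(ap %*% ab[s, ] / len2[s], 0), 1) else rep(0, nrow(pts))
    dd <- ap - outer(as.numeric(t), ab[s, ])
    best <- pmin(best, sqrt(rowSums(dd^2)))
  }
  best
}

#' Uniform area-weighted surface sampling
#'
#' @param mesh A [uro_mesh()].
#' @param n Number of samples.
#' @param rng_seed Seed.
#' @return `n x 3` matrix of surface points.
#' @export
sample_mesh_surface <- function(mesh, n, rng_seed = 1L) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cxm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  areas <- sqrt(rowSums(cxm^2)) / 2
  with_seed(rng_seed, {
    fi <- sample.int(nrow(f), n, replace = TRUE, prob = areas)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    w0 <- 1 - r1; w1 <- r1 * (1 - r2); w2 <- r1 * r2
    v[f[fi, 1], , drop = FALSE] * w0 + v[f[fi, 2], , drop = FALSE] * w1 +
      v[f[fi, 3], , drop = FALSE] * w2
  })
}

#' Skeleton JSON serialization
#'
#' `{"nodes": [[x,y,z], ...], "edges": [[i,j], ...], "meta": {...}}` with
#' 1-based edge indices.
#'
#' @param skel A [uro_skeleton()].
#' @param path Output/input JSON path.
#' @export
write_skeleton <- function(skel, path) {
  stopifnot(inherits(skel, "uro_skeleton"))
  obj <- list(nodes = unname(apply(skel$nodes, 1, as.numeric, simplify = FALSE)),
              edges = unname(apply(skel$edges, 1, as.integer, simplify = FALSE)),
              node_ring_size = as.integer(skel$node_ring_size),
              meta = skel$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges)) matrix(as.integer(obj$edges), ncol = 2)
           else matrix(integer(), 0, 2)
  uro_skeleton(matrix(as.numeric(obj$nodes), ncol = 3),
               edges, obj$node_ring_size, as.list(obj$meta))
}
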