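#' Camera pose
#'
#' Position in mm with a unit view direction, a unit up vector orthogonal to
#' it (re-orthogonalized on construction), and a vertical field of view.
#'
#' @param position 3-vector, mm.
#' @param view_dir 3-vector; normalized.
#' @param up 3-vector; orthogonalized against `view_dir` and normalized.
#' @param vfov_deg Vertical field of view in degrees (default 60).
#' @export
camera_pose <- function(position, view_dir, up = c(0, 0, 1), vfov_deg = 60) {
  position <- as.numeric(position)
  view_dir <- unitv(as.numeric(view_dir))
  up <- as.numeric(up)
  up <- up - sum(up * view_dir) * view_dir
  if (vnorm(up) < 1e-9) stopf("up vector is parallel to view direction")
  up <- unitv(up)
  if (vfov_deg <= 0 || vfov_deg >= 180) stopf("vfov_deg must be in (0, 180)")
  structure(list(position = position, view_dir = view_dir, up = up,
                 vfov_deg = vfov_deg),
            class = "uro_pose")
}

#' Sample camera poses along a skeleton
#'
#' Walks the skeleton edges depth-first from a degree-1 node (smallest index;
#' the entry point on tubular anatomy) and places poses at arc-length
#' intervals of `spacing_mm` along each contiguous edge chain.  The view
#' direction is the local edge tangent in traversal direction; the up vector
#' is parallel-transported along each chain from an initial world-up
#' projection.
#'
#' @param skel A [uro_skeleton()] with at least one edge.
#' @param spacing_mm Arc-length spacing between poses (> 0).
#' @param vfov_deg Field of view given to every pose.
#' @return List of [camera_pose()] objects in traversal order.
#' @export
sample_trajectory <- function(skel, spacing_mm, vfov_deg = 60) {
  stopifnot(inherits(skel, "uro_skeleton"))
  if (nrow(skel$edges) == 0L) stopf("skeleton has no edges")
  if (spacing_mm <= 0) stopf("spacing_mm must be > 0")
  nn <- nrow(skel$nodes)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(skel$edges))) {
    a <- skel$edges[i, 1]; b <- skel$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  root <- if (any(deg == 1L)) which(deg == 1L)[1] else which(deg > 0L)[1]
  # iterative DFS over edges
  visited_e <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  stack <- list(root)
  seen <- rep(FALSE, nn); seen[root] <- TRUE
  chains <- list(); cur <- NULL
  dfs <- function(v) {
    for (w in sort(adj[[v]])) {
      k <- ekey(v, w)
      if (!is.null(visited_e[[k]])) next
      visited_e[[k]] <- TRUE
      if (is.null(cur) || cur[length(cur)] != v) {
        if (!is.null(cur)) chains[[length(chains) + 1L]] <<- cur
        cur <<- c(v, w)
      } else {
        cur <<- c(cur, w)
      }
      dfs(w)
    }
  }
  cur <- NULL
  dfs(root)
  if (!is.null(cur)) chains[[length(chains) + 1L]] <- cur
  poses <- list()
  world_up <- c(0, 0, 1)
  for (chain in chains) {
    P <- skel$nodes[chain, , drop = FALSE]
    seg <- diff(P)
    seg_len <- sqrt(rowSums(seg^2))
    keep <- seg_len > 1e-12
    if (!any(keep)) next
    cum <- c(0, cumsum(seg_len))
    total <- cum[length(cum)]
    ts <- seq(0, total, by = spacing_mm)
    # up transport init
    t0 <- unitv(seg[which(keep)[1], ])
    upv <- world_up - sum(world_up * t0) * t0
    if (vnorm(upv) < 1e-9) upv <- c(0, 1, 0) - sum(c(0, 1, 0) * t0) * t0
    upv <- unitv(upv)
    prev_t <- t0
    for (s in ts) {
      si <- findInterval(s, cum, rightmost.closed = TRUE)
      si <- min(max(si, 1L), nrow(seg))
      if (seg_len[si] <= 1e-12) next
      frac <- (s - cum[si]) / seg_len[si]
      pos <- P[si, ] + frac * seg[si, ]
      tan <- unitv(seg[si, ])
      # parallel transport the up vector onto the new tangent plane
      upv <- upv - sum(upv * tan) * tan
      if (vnorm(upv) < 1e-9) {
        upv <- world_up - sum(world_up * tan) * tan
        if (vnorm(upv) < 1e-9) upv <- c(0, 1, 0) - sum(c(0, 1, 0) * tan) * tan
      }
      upv <- unitv(upv)
      prev_t <- tan
      poses[[length(poses) + 1L]] <- camera_pose(pos, tan, upv, vfov_deg)
    }
  }
  poses
}

#' Pose JSON serialization
#'
#' @param poses List of [camera_pose()] objects.
#' @param path JSON file path.
#' @export
write_poses <- function(poses, path) {
  obj <- lapply(poses, function(p)
    list(position = p$position, view_dir = p$view_dir, up = p$up,
         vfov_deg = p$vfov_deg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(i)
    camera_pose(unlist(obj$position[i]), unlist(obj$view_dir[i]),
                unlist(obj$up[i]), obj$vfov_deg[i]))
}
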