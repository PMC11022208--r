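# Independent reference implementations used to cross-check package routines.

# exhaustive three-class Otsu search: canonical between-class variance
# sum_k w_k (mu_k - mu)^2 scanned over every (t1 < t2) bin boundary pair,
# first-maximum update order
oracle_otsu3 <- function(values, n_bins = 256L) {
  lo <- min(values); hi <- max(values)
  w <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((values - lo) / w), 0), n_bins - 1) + 1L
  cnt <- tabulate(idx, nbins = n_bins)
  ctr <- lo + (seq_len(n_bins) - 0.5) * w
  N <- sum(cnt)
  mu <- sum(cnt * ctr) / N
  cw <- cumsum(cnt); cm <- cumsum(cnt * ctr)
  best <- -Inf; bt <- c(NA, NA)
  for (t1 in seq_len(n_bins - 2L)) {
    w1 <- cw[t1] / N
    if (w1 == 0) next
    mu1 <- cm[t1] / cw[t1]
    t2 <- (t1 + 1L):(n_bins - 1L)
    w2 <- (cw[t2] - cw[t1]) / N
    w3 <- (N - cw[t2]) / N
    mu2 <- (cm[t2] - cm[t1]) / pmax(cw[t2] - cw[t1], 1)
    mu3 <- (cm[n_bins] - cm[t2]) / pmax(N - cw[t2], 1)
    obj <- w1 * (mu1 - mu)^2 + w2 * (mu2 - mu)^2 + w3 * (mu3 - mu)^2
    obj[w2 == 0 | w3 == 0] <- -Inf
    j <- which.max(obj)
    if (obj[j] > best) { best <- obj[j]; bt <- c(t1, t2[j]) }
  }
  lo + w * bt
}

# plain queue-based BFS over the face edge list
oracle_bfs <- function(mesh, source) {
  nv <- nrow(mesh$vertices)
  adj <- vector("list", nv)
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    tr <- f[i, ]
    for (p in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tr[p[1]]; b <- tr[p[2]]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  d <- rep(NA_integer_, nv)
  d[source] <- 0L
  q <- source
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
  }
  d
}

# exhaustive point-to-segment distances (double loop)
oracle_point_segment <- function(pts, nodes, edges) {
  apply(pts, 1, function(p) {
    min(apply(edges, 1, function(e) {
      a <- nodes[e[1], ]; b <- nodes[e[2], ]
      ab <- b - a
      t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((p - a - t * ab)^2))
    }))
  })
}
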