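# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and igraph where the package delegates to it): distances by
# Floyd-Warshall, geodesic counts by matrix powers, descendant counts by
# ancestor-chain walking, common neighbors by double loop.

oracle_dist <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# geodesic counts: walks of length dist(s,t) are exactly the shortest paths
oracle_geodesic_counts <- function(a, d) {
  n <- nrow(a)
  g <- (d == 1) * 1
  ak <- a
  if (n > 2L) {
    for (l in 2:(n - 1L)) {
      ak <- ak %*% a
      g <- g + ak * (d == l)
    }
  }
  g
}

oracle_bc <- function(a) {
  n <- nrow(a)
  d <- oracle_dist(a)
  g <- oracle_geodesic_counts(a, d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- is.finite(d) & (outer(d[, v], d[v, ], `+`) == d)
    frac <- outer(g[, v], g[v, ]) / pmax(g, 1)
    contrib <- ifelse(on_path & g > 0, frac, 0)
    contrib[v, ] <- 0
    contrib[, v] <- 0
    bc[v] <- sum(contrib[upper.tri(contrib)])
  }
  bc
}

oracle_cc <- function(a) {
  d <- oracle_dist(a)
  vapply(seq_len(nrow(a)), function(v) {
    reach <- is.finite(d[v, ]) & seq_len(nrow(a)) != v
    if (!any(reach)) 0 else sum(reach) / sum(d[v, reach])
  }, numeric(1L))
}

# Bottleneck oracle: same lexicographic BFS tie rule, but descendant counts
# obtained by walking each node's ancestor chain to the root.
oracle_bn <- function(a, nms) {
  n <- nrow(a)
  dimnames(a) <- list(nms, nms)
  score <- stats::setNames(numeric(n), nms)
  for (root in sort(nms)) {
    parent <- stats::setNames(rep(NA_character_, n), nms)
    visited <- stats::setNames(logical(n), nms)
    visited[root] <- TRUE
    queue <- root
    disc <- root
    while (length(queue) > 0L) {
      x <- queue[1L]
      queue <- queue[-1L]
      for (nb in sort(nms[a[x, ] > 0])) {
        if (!visited[[nb]]) {
          visited[nb] <- TRUE
          parent[nb] <- x
          queue <- c(queue, nb)
          disc <- c(disc, nb)
        }
      }
    }
    desc <- stats::setNames(numeric(n), nms)
    for (w in disc) {
      x <- w
      repeat {
        desc[x] <- desc[[x]] + 1
        if (x == root) break
        x <- parent[[x]]
      }
    }
    hit <- disc[desc[disc] > length(disc) / 4]
    score[hit] <- score[hit] + 1
  }
  score
}

# truncated power series for subgraph centrality: sum_k diag(A^k)/k!
oracle_sc_series <- function(a, kmax = 20L) {
  n <- nrow(a)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(kmax)) {
    term <- term %*% a / k
    acc <- acc + term
  }
  diag(acc)
}

# truncated Katz series for alpha-centrality: sum_k alpha^k A^k 1, unit sum
oracle_nc_series <- function(a, alpha, kmax = 400L) {
  n <- nrow(a)
  ones <- rep(1, n)
  acc <- ones
  term <- ones
  for (k in seq_len(kmax)) {
    term <- alpha * (a %*% term)
    acc <- acc + term
  }
  as.numeric(acc / sum(acc))
}

# common-neighbor count by explicit double loop over adjacency lists
oracle_ecc <- function(edges) {
  adj <- split(c(edges$v, edges$u), c(edges$u, edges$v))
  vapply(seq_len(nrow(edges)), function(i) {
    nu <- adj[[edges$u[i]]]
    nv <- adj[[edges$v[i]]]
    cn <- 0L
    for (x in nu) if (x %in% nv) cn <- cn + 1L
    (cn + 1) / min(length(nu), length(nv))
  }, numeric(1L))
}

adjacency_of <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net))
}
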