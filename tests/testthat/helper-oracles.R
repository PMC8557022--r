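# Independent brute-force oracles used to check the implementation paths.
# These deliberately use different algorithms from the package code.

# Benjamini-Hochberg by literal step-up with monotonicity, from the largest
# rank downward.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, ps[i] * m / i)
    adj[i] <- cur
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# All-pairs shortest paths and path counts by exhaustive BFS.
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

shortest_path_counts <- function(A, D) {
  n <- nrow(A)
  N <- matrix(0, n, n); diag(N) <- 1
  for (s in seq_len(n)) {
    for (d in sort(unique(D[s, D[s, ] > 0 & is.finite(D[s, ])]))) {
      for (t in which(D[s, ] == d)) {
        pred <- which(A[t, ] > 0 & D[s, ] == d - 1)
        N[s, t] <- sum(N[s, pred])
      }
    }
  }
  N
}

# The seven topology metrics computed from first principles on a dense
# adjacency matrix (connected graph assumed).
centrality_oracle <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  nbdeg <- vapply(seq_len(n), function(i) mean(deg[A[i, ] > 0]), numeric(1))
  D <- bfs_distances(A)
  clo <- (n - 1) / rowSums(D)
  # eigenvector by long power iteration on A + I (same eigenvector, but the
  # shift makes the principal eigenvalue strictly dominant so the iteration
  # converges on bipartite graphs too)
  M <- A + diag(n)
  v <- rep(1, n)
  for (k in 1:2000) v <- drop(M %*% v) / sqrt(sum((M %*% v)^2))
  v <- abs(v)
  lmax <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  alpha <- 0.9 / lmax
  # katz by truncated series sum_{k>=0} (alpha A)^k 1
  x <- rep(1, n); term <- rep(1, n)
  for (k in 1:500) { term <- alpha * drop(A %*% term); x <- x + term }
  x <- x / sqrt(sum(x^2))
  Np <- shortest_path_counts(A, D)
  btw <- numeric(n)
  for (v_ in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s < t && s != v_ && t != v_ &&
          is.finite(D[s, t]) &&
          D[s, v_] + D[v_, t] == D[s, t]) {
        btw[v_] <- btw[v_] + Np[s, v_] * Np[v_, t] / Np[s, t]
      }
    }
  }
  btw <- btw * 2 / ((n - 1) * (n - 2))
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  list(degree = deg, neighbor_degree = nbdeg, closeness = clo,
       eigenvector = v, katz = x, betweenness = btw, clustering_coeff = cc)
}

# Exact two-sided Fisher p by enumerating all tables with the observed
# margins; point-probability rule with relative tolerance.
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; N <- a + b + c + d
  xs <- max(0, col1 - (N - row1)):min(row1, col1)
  probs <- dhyper(xs, col1, N - col1, row1)
  p_obs <- dhyper(a, col1, N - col1, row1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating assignments and computing U
# from pairwise comparisons (ties count one half).
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xi, yi) {
    sum(outer(xi, yi, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hypergeometric upper tail by summing the exact overlap distribution.
hyper_oracle <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# O(n*m) interval scan, half-open semantics, both inputs 0-based.
overlap_oracle <- function(dmrs0, clusters0, min_overlap = 1) {
  hits <- list()
  for (i in seq_len(nrow(dmrs0))) {
    for (j in seq_len(nrow(clusters0))) {
      if (dmrs0$chrom[i] != clusters0$chrom[j]) next
      ov <- min(dmrs0$end0[i], clusters0$end0[j]) -
        max(dmrs0$start0[i], clusters0$start0[j])
      if (ov >= min_overlap) {
        hits[[length(hits) + 1]] <- data.frame(
          tf = clusters0$tf[j], region_id = dmrs0$region_id[i],
          overlap_bp = ov)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(tf = character(), region_id = character(),
                      overlap_bp = integer()))
  }
  do.call(rbind, hits)
}

# Small random connected graph as an edge tibble (retries until connected).
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p)
    A <- A + t(A)
    D <- bfs_distances(A)
    if (all(is.finite(D))) return(A)
  }
}

graph_tbl_from_adj <- function(A) {
  nodes <- sprintf("n%02d", seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  tibble::tibble(gene_a = nodes[idx[, 1]], gene_b = nodes[idx[, 2]],
                 confidence = 1)
}
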