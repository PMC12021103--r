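# Independent brute-force oracles.  These deliberately share no code with
# the package implementation: dense loops, Floyd-Warshall, exhaustive path
# enumeration, textbook metric formulas.

# All-pairs shortest hop counts by Floyd-Warshall on an undirected edge list
# of integer node indices 1..n.
fw_distances <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    D[i, j] <- 1; D[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Enumerate every shortest path between two nodes (list of index vectors).
enumerate_shortest_paths <- function(adj, s, t) {
  n <- nrow(adj)
  # BFS distances from s
  d <- rep(Inf, n); d[s] <- 0
  q <- s
  while (length(q)) {
    u <- q[1]; q <- q[-1]
    for (v in which(adj[u, ] > 0)) if (d[v] == Inf) { d[v] <- d[u] + 1; q <- c(q, v) }
  }
  if (!is.finite(d[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- which(adj[v, ] > 0 & d == d[v] - 1)
    out <- list()
    for (p in preds) for (pp in walk(p)) out <- c(out, list(c(pp, v)))
    out
  }
  walk(t)
}

# Unnormalized betweenness over unordered pairs via path enumeration.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  g <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_shortest_paths(adj, s, t)
    if (!length(paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p[-c(1, length(p))], logical(1)))
      g[v] <- g[v] + through / length(paths)
    }
  }
  g
}

# Dense per-node GraphSAGE oracle (row convention as the implementation
# documents: act(cbind(h_self, agg) %*% t(W))).
naive_sage <- function(H_dst, H_src, A, W, act = identity, aggregator = "mean") {
  out <- matrix(NA_real_, nrow(H_dst), nrow(W))
  for (i in seq_len(nrow(H_dst))) {
    nb <- which(A[i, ] > 0)
    agg <- if (!length(nb)) rep(0, ncol(H_src)) else {
      block <- H_src[nb, , drop = FALSE]
      switch(aggregator,
             mean = colMeans(block), sum = colSums(block),
             pool = apply(block, 2, max))
    }
    out[i, ] <- act(as.numeric(W %*% c(H_dst[i, ], agg)))
  }
  out
}

# Dense per-node GCN oracle with symmetric degree normalization.
naive_gcn <- function(H_src, A, W, act = identity) {
  dd <- rowSums(A); ds <- colSums(A)
  out <- matrix(0, nrow(A), nrow(W))
  for (i in seq_len(nrow(A))) {
    acc <- rep(0, ncol(H_src))
    for (j in which(A[i, ] > 0)) {
      acc <- acc + H_src[j, ] / sqrt(dd[i] * ds[j])
    }
    out[i, ] <- act(as.numeric(W %*% acc))
  }
  out
}

# Textbook metric formulas.
naive_rmse <- function(p, o) sqrt(sum((p - o)^2) / length(p))
naive_pcc <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}
avg_rank <- function(x) {
  # average ranks for ties, from first principles
  sapply(seq_along(x), function(i) {
    less <- sum(x < x[i]); eq <- sum(x == x[i])
    less + (eq + 1) / 2
  })
}
naive_scc <- function(a, b) naive_pcc(avg_rank(a), avg_rank(b))

# Random connected-ish undirected graph as an edge list of indices.
random_edge_list <- function(n, p = 0.2) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  rbind(pairs[keep, , drop = FALSE],
        cbind(1:(n - 1), 2:n)[runif(n - 1) < 0.5, , drop = FALSE])
}
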