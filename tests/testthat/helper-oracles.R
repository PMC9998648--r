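# Brute-force graph-metric oracles, written independently of the package
# internals (and of igraph): Floyd-Warshall distances and literal
# enumeration of simple paths. Only meant for graphs with <= 8 nodes.

oracle_distances <- function(b) {
  n <- nrow(b)
  d <- ifelse(b == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all simple paths from s to t, as lists of vertex sequences
enumerate_paths <- function(b, s, t) {
  n <- nrow(b)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in which(b[v, ] == 1))
      if (!w %in% path) walk(c(path, w))
  }
  walk(s)
  out
}

# betweenness as unnormalized sum over unordered pairs s < t (s,t != i) of
# the fraction of shortest s-t paths passing through i
oracle_betweenness <- function(b) {
  n <- nrow(b)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_paths(b, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    short <- paths[lens == min(lens)]
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      through <- sum(vapply(short, function(p) i %in% p, logical(1)))
      btw[i] <- btw[i] + through / length(short)
    }
  }
  btw
}

oracle_clustering <- function(b) {
  n <- nrow(b)
  vapply(seq_len(n), function(i) {
    nb <- which(b[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- sum(b[nb, nb]) / 2
    2 * t_i / (k * (k - 1))
  }, numeric(1))
}

oracle_global_efficiency <- function(b) {
  d <- oracle_distances(b)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  if (nrow(b) < 2) 0 else mean(inv)
}

oracle_path_length <- function(b) {
  d <- oracle_distances(b)[upper.tri(matrix(0, nrow(b), nrow(b)))]
  d <- d[is.finite(d)]
  if (length(d)) mean(d) else NA_real_
}

oracle_local_efficiency <- function(b) {
  n <- nrow(b)
  vapply(seq_len(n), function(i) {
    nb <- which(b[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(b[nb, nb, drop = FALSE])
  }, numeric(1))
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  parts <- list()
  grow <- function(assign, maxg) {
    i <- length(assign) + 1L
    if (i > n) { parts[[length(parts) + 1L]] <<- assign; return(invisible()) }
    for (g in seq_len(maxg + 1L))
      grow(c(assign, g), max(maxg, g))
  }
  grow(integer(0), 0L)
  parts
}

# exhaustive-search optimum of Newman modularity at gamma = 1
oracle_best_modularity <- function(b) {
  m <- sum(b) / 2
  deg <- rowSums(b)
  best <- -Inf
  for (memb in all_partitions(nrow(b))) {
    q <- 0
    for (g in unique(memb)) {
      idx <- which(memb == g)
      q <- q + sum(b[idx, idx]) / 2 / m - (sum(deg[idx]) / (2 * m))^2
    }
    if (q > best) best <- q
  }
  best
}

# adjacency matrix from an integer index over the upper triangle
graph_from_index <- function(idx, n) {
  n_edges <- n * (n - 1) / 2
  bits <- as.integer(intToBits(idx))[seq_len(n_edges)]
  b <- matrix(0, n, n)
  b[upper.tri(b)] <- bits
  b <- b + t(b)
  rownames(b) <- colnames(b) <- paste0("v", seq_len(n))
  b
}

is_connected_adj <- function(b) {
  all(is.finite(oracle_distances(b)))
}
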