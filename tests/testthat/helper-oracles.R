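# Brute-force graph-metric oracles, written independently of the package
# implementation (and of igraph): explicit BFS for distances, exhaustive
# simple-path enumeration for betweenness, direct neighbor-pair counting for
# clustering. Only feasible for small graphs; used to verify the fast paths.

oracle_bfs <- function(a, s) {
  n <- nrow(a)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(a[v, ] != 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_distances <- function(a) {
  t(vapply(seq_len(nrow(a)), function(s) oracle_bfs(a, s), numeric(nrow(a))))
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        if (a[nb[p], nb[q]] != 0) links <- links + 1
      }
    }
    nodal[i] <- 2 * links / (k * (k - 1))
  }
  list(c_p = mean(nodal), nodal = nodal)
}

# enumerate all shortest paths between i and j by depth-limited DFS
oracle_shortest_paths <- function(a, i, j, dij) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) {
      if (length(path) - 1 == dij) paths[[length(paths) + 1]] <<- path
      return()
    }
    if (length(path) - 1 >= dij) return()
    for (w in which(a[v, ] != 0)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(i)
  paths
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  b <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.finite(d[i, j]) || d[i, j] < 2) next
      paths <- oracle_shortest_paths(a, i, j, d[i, j])
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b
}

oracle_efficiencies <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  e_glob <- sum(inv) / (n * (n - 1))
  nodal <- rowSums(inv) / (n - 1)
  e_loc_parts <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_efficiencies(a[nb, nb, drop = FALSE])$e_glob
  }, numeric(1))
  list(e_glob = e_glob, e_loc = mean(e_loc_parts), nodal_efficiency = nodal,
       l_p = if (e_glob == 0) Inf else 1 / e_glob)
}

# small named graphs used across tests
graph_complete <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0; a
}
graph_path <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}
graph_star <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- as.numeric(stats::runif(length(ut)) < p)
  a + t(a)
}

# rank-based AUROC of score against binary labels
auroc <- function(score, label) {
  r <- rank(score)
  (mean(r[label == 1]) - (sum(label == 1) + 1) / 2) / sum(label == 0)
}
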