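# Global and nodal graph metrics on binary undirected networks, degree-
# preserving null models, and AUC integration over the sparsity grid.
# Standard algorithms (BFS distances, Brandes betweenness, Latora-Marchiori
# efficiencies, Maslov-Sneppen rewiring) are delegated to igraph.

as_adj <- function(a) {
  m <- unclass(as.matrix(a))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("adjacency matrix must be square")
  m
}

adj_graph <- function(a) {
  igraph::graph_from_adjacency_matrix(as_adj(a), mode = "undirected", diag = FALSE)
}

#' Clustering coefficient (global and nodal)
#'
#' Nodal value is `2 * triangles_i / (k_i * (k_i - 1))`, defined as 0 for
#' nodes of degree < 2; the global value `c_p` is the mean over all nodes.
#'
#' @param a Binary symmetric adjacency matrix (zero diagonal).
#' @return List with `c_p` and `nodal`.
#' @export
clustering_coefficient <- function(a) {
  m <- as_adj(a)
  k <- colSums(m)
  tri <- diag(m %*% m %*% m) / 2
  nodal <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  list(c_p = mean(nodal), nodal = as.numeric(nodal))
}

#' Global/local/nodal efficiency
#'
#' Global efficiency is the mean over ordered node pairs of the inverse
#' shortest-path distance (1/Inf = 0 for disconnected pairs); nodal
#' efficiency is the per-node mean; local efficiency is the mean over nodes
#' of the global efficiency of each node's neighborhood subgraph (0 for
#' degree < 2).
#'
#' @param a Binary symmetric adjacency matrix.
#' @return List with `e_glob`, `e_loc`, `nodal_efficiency`.
#' @export
efficiencies <- function(a) {
  m <- as_adj(a)
  st <- inv_distance_stats(adj_graph(m))
  # local efficiency: global efficiency of each node's neighborhood subgraph
  # (paths restricted to the subgraph), 0 for degree < 2
  loc <- vapply(seq_len(nrow(m)), function(i) {
    nb <- which(m[i, ] != 0)
    if (length(nb) < 2L) return(0)
    dense_subgraph_eglob(m[nb, nb, drop = FALSE])
  }, numeric(1))
  list(e_glob = st$e_glob, e_loc = mean(loc), nodal_efficiency = st$nodal)
}

# global efficiency of a small dense subgraph via matrix-power BFS: the first
# power s with a length-s walk between a pair equals their shortest-path
# distance, and realized distances have no gaps, so stopping when no new
# pair appears is exact
dense_subgraph_eglob <- function(sub) {
  k <- nrow(sub)
  dist <- sub
  frontier <- sub
  s <- 1
  repeat {
    s <- s + 1
    frontier <- (frontier %*% sub > 0) * 1
    new <- frontier > 0 & dist == 0
    diag(new) <- FALSE
    if (!any(new)) break
    dist[new] <- s
  }
  inv <- 1 / dist
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (k * (k - 1))
}

# global + nodal efficiency from BFS distances (no neighborhood subgraphs)
inv_distance_stats <- function(g) {
  n <- igraph::vcount(g)
  inv <- 1 / igraph::distances(g)
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  list(e_glob = sum(inv) / (n * (n - 1)), nodal = as.numeric(rowSums(inv) / (n - 1)))
}

#' Characteristic path length (harmonic mean)
#'
#' `l_p` is the inverse of the mean inverse shortest-path distance over all
#' unordered pairs, i.e. `1 / e_glob`; this stays finite on disconnected
#' graphs (disconnected pairs contribute 0). A graph with no finite-distance
#' pair returns `Inf`.
#'
#' @param a Binary symmetric adjacency matrix.
#' @return Scalar `l_p` (>= 1 for any graph with at least one edge).
#' @export
characteristic_path_length_harmonic <- function(a) {
  e <- inv_distance_stats(adj_graph(a))$e_glob
  if (e == 0) Inf else 1 / e
}

#' Nodal degree and betweenness centrality
#'
#' Degree is the adjacency row sum; betweenness is unnormalized
#' shortest-path betweenness (Brandes accumulation, endpoints excluded).
#'
#' @param a Binary symmetric adjacency matrix.
#' @return List with `degree` and `betweenness` vectors.
#' @export
nodal_degree_betweenness <- function(a) {
  m <- as_adj(a)
  list(
    degree = as.numeric(colSums(m)),
    betweenness = as.numeric(igraph::betweenness(adj_graph(m), directed = FALSE,
                                                 normalized = FALSE))
  )
}

#' Degree-preserving random null ensemble
#'
#' Generates `m` rewired copies of the graph by Maslov-Sneppen double-edge
#' swaps (10 x |edges| rewiring trials each), preserving every node's degree.
#' Graphs that admit no swap (fewer than 2 edges, or e.g. a star) are
#' returned as unchanged copies with a warning.
#'
#' @param a Binary symmetric adjacency matrix.
#' @param m Ensemble size (>= 1).
#' @param seed Seed for the rewiring randomness.
#' @return List of `m` adjacency matrices with the same degree sequence.
#' @export
random_null_ensemble <- function(a, m = 100L, seed = 1L) {
  mat <- as_adj(a)
  m <- as.integer(m)
  if (m < 1L) stop("ensemble size m must be >= 1")
  g <- adj_graph(mat)
  ne <- igraph::ecount(g)
  if (ne < 2L) {
    warning("graph has fewer than 2 edges; returning unchanged copies")
    return(replicate(m, mat, simplify = FALSE))
  }
  nulls <- with_seed(seed, {
    lapply(seq_len(m), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
      out <- as.matrix(igraph::as_adjacency_matrix(r, sparse = FALSE))
      dimnames(out) <- dimnames(mat)
      out
    })
  })
  if (all(vapply(nulls, function(x) identical(x, mat), logical(1)))) {
    warning("graph admits no degree-preserving swap; nulls are copies of the input")
  }
  nulls
}

#' Small-world indices against a null ensemble
#'
#' `gamma = C_p / mean(C_p of nulls)`, `lambda = L_p / mean(L_p of nulls)`,
#' `sigma = gamma / lambda`. A null ensemble with zero mean clustering yields
#' `gamma = Inf`.
#'
#' @param a Binary symmetric adjacency matrix.
#' @param nulls List of null adjacency matrices (e.g. from
#'   [random_null_ensemble()]).
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
small_world_indices <- function(a, nulls) {
  if (length(nulls) < 1L) stop("null ensemble must be non-empty")
  cp <- clustering_coefficient(a)$c_p
  lp <- characteristic_path_length_harmonic(a)
  cp0 <- mean(vapply(nulls, function(x) clustering_coefficient(x)$c_p, numeric(1)))
  lp0 <- mean(vapply(nulls, characteristic_path_length_harmonic, numeric(1)))
  gamma <- if (cp0 == 0) Inf else cp / cp0
  lambda <- lp / lp0
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Trapezoidal area under a metric curve over the sparsity grid
#'
#' Integrates one metric's per-threshold values over the grid by the
#' trapezoidal rule, giving a single threshold-independent scalar. Any
#' non-finite value propagates as `Inf`.
#'
#' @param values Numeric vector, one value per grid point.
#' @param grid A [sparsity_grid()] (or its numeric `values`).
#' @return Scalar integral.
#' @export
auc_over_grid <- function(values, grid) {
  s <- if (inherits(grid, "sparsity_grid")) grid$values else as.numeric(grid)
  if (length(values) != length(s)) stop("one value per grid point required")
  if (length(s) < 2L) stop("grid must have at least 2 points")
  if (any(!is.finite(values))) return(Inf)
  sum(diff(s) * (values[-1] + values[-length(values)]) / 2)
}

#' Global and nodal metric curves over the sparsity grid
#'
#' Binarizes a partial-correlation matrix at every sparsity in the grid and
#' computes the seven global metrics (Cp, Lp, gamma, lambda, sigma, Eloc,
#' Eglob) plus the three nodal metrics (degree, betweenness, efficiency) per
#' region; gamma/lambda/sigma are normalized by `null_m` degree-preserving
#' rewired nulls per threshold, seeded per threshold from `seed`.
#'
#' @param pc A [partial_corr()].
#' @param grid A [sparsity_grid()].
#' @param null_m Null-ensemble size per threshold (default 100).
#' @param seed Master seed for the null ensembles.
#' @return An object of class `metric_curves`: list with `grid`, `global`
#'   (data frame, one row per threshold), `nodal` (list of three
#'   thresholds x regions matrices), `region_labels`, `null_m`, `seed`.
#' @export
compute_metric_curves <- function(pc, grid = sparsity_grid(), null_m = 100L,
                                  seed = 1L) {
  stopifnot(inherits(pc, "partial_corr"), inherits(grid, "sparsity_grid"))
  n <- length(pc$region_labels)
  ns <- length(grid$values)
  glob <- matrix(NA_real_, ns, 7,
                 dimnames = list(NULL, c("Cp", "Lp", "Gamma", "Lambda", "Sigma",
                                         "Eloc", "Eglob")))
  nodal <- list(
    degree = matrix(NA_real_, ns, n, dimnames = list(NULL, pc$region_labels)),
    betweenness = matrix(NA_real_, ns, n, dimnames = list(NULL, pc$region_labels)),
    efficiency = matrix(NA_real_, ns, n, dimnames = list(NULL, pc$region_labels))
  )
  for (i in seq_len(ns)) {
    a <- binarize_at_sparsity(pc, grid$values[i])
    cc <- clustering_coefficient(a)
    ef <- efficiencies(a)
    db <- nodal_degree_betweenness(a)
    lp <- if (ef$e_glob == 0) Inf else 1 / ef$e_glob
    nulls <- random_null_ensemble(a, m = null_m, seed = derive_seed(seed, i))
    sw <- small_world_indices(a, nulls)
    glob[i, ] <- c(cc$c_p, lp, sw$gamma, sw$lambda, sw$sigma, ef$e_loc, ef$e_glob)
    nodal$degree[i, ] <- db$degree
    nodal$betweenness[i, ] <- db$betweenness
    nodal$efficiency[i, ] <- ef$nodal_efficiency
  }
  structure(
    list(grid = grid, global = as.data.frame(glob), nodal = nodal,
         region_labels = pc$region_labels, null_m = as.integer(null_m),
         seed = seed),
    class = "metric_curves"
  )
}
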