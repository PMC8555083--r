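test_that("clustering coefficient matches hand-enumerable cases", {
  expect_equal(clustering_coefficient(graph_complete(4))$c_p, 1.0)
  expect_equal(clustering_coefficient(graph_path(4))$c_p, 0.0)
  # K4 minus one edge: oracle by exhaustive triangle counting
  a <- graph_complete(4); a[1, 2] <- a[2, 1] <- 0
  o <- oracle_clustering(a)
  r <- clustering_coefficient(a)
  expect_equal(r$nodal, o$nodal)
  expect_equal(r$c_p, o$c_p)
})

test_that("harmonic path length handles connected and disconnected graphs", {
  expect_equal(characteristic_path_length_harmonic(graph_complete(6)), 1.0)
  # P3: pair distances 1, 1, 2 -> Lp = 3 / (1 + 1 + 0.5) = 1.2
  expect_equal(characteristic_path_length_harmonic(graph_path(3)), 1.2)
  # two disjoint edges on 4 nodes: finite despite disconnection
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1
  expect_equal(characteristic_path_length_harmonic(a), 3.0)
  # edgeless graph: no finite pair
  expect_identical(characteristic_path_length_harmonic(matrix(0, 4, 4)), Inf)
})

test_that("efficiencies match hand-enumerable cases", {
  e <- efficiencies(graph_complete(5))
  expect_equal(e$e_glob, 1.0)
  expect_equal(e$e_loc, 1.0)
  expect_equal(efficiencies(matrix(0, 4, 4))$e_glob, 0)
  # P3: mean of (1 + 1 + 0.5)/3 over unordered pairs
  expect_equal(efficiencies(graph_path(3))$e_glob, (1 + 1 + 0.5) / 3)
})

test_that("degree and betweenness match brute-force enumeration", {
  # star: center lies on all leaf-pair shortest paths
  s4 <- graph_star(4)
  db <- nodal_degree_betweenness(s4)
  expect_equal(db$betweenness, c(3, 0, 0, 0))
  expect_equal(db$degree, c(3, 1, 1, 1))
  # complete graph: no intermediate vertices
  expect_equal(nodal_degree_betweenness(graph_complete(5))$betweenness, rep(0, 5))
  # handshake lemma on a random graph
  a <- random_adjacency(12, 0.3, seed = 7)
  db <- nodal_degree_betweenness(a)
  expect_equal(sum(db$degree), sum(a))
  expect_equal(db$betweenness, oracle_betweenness(a), tolerance = 1e-10)
})

test_that("all metrics agree with brute-force oracles on random small graphs", {
  cases <- expand.grid(n = 5:7, p = c(0.3, 0.5, 0.8), rep = 1:3)
  for (i in seq_len(nrow(cases))) {
    a <- random_adjacency(cases$n[i], cases$p[i], seed = 100 + i)
    oc <- oracle_clustering(a)
    oe <- oracle_efficiencies(a)
    cc <- clustering_coefficient(a)
    ef <- efficiencies(a)
    db <- nodal_degree_betweenness(a)
    expect_equal(cc$nodal, oc$nodal, tolerance = 1e-12)
    expect_equal(ef$e_glob, oe$e_glob, tolerance = 1e-12)
    expect_equal(ef$e_loc, oe$e_loc, tolerance = 1e-12)
    expect_equal(ef$nodal_efficiency, oe$nodal_efficiency, tolerance = 1e-12)
    expect_equal(db$betweenness, oracle_betweenness(a), tolerance = 1e-10)
    expect_equal(characteristic_path_length_harmonic(a), oe$l_p, tolerance = 1e-12)
  }
})

test_that("null ensemble preserves degrees, is seeded, and destroys clustering", {
  g <- igraph::sample_smallworld(1, 40, 3, 0)  # pure ring lattice
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  nulls <- random_null_ensemble(a, m = 20, seed = 4)
  expect_length(nulls, 20)
  for (x in nulls) {
    expect_equal(colSums(x), colSums(a))
    expect_true(all(x == t(x)))
    expect_true(all(diag(x) == 0))
  }
  nulls2 <- random_null_ensemble(a, m = 20, seed = 4)
  expect_identical(nulls, nulls2)
  # lattice clustering collapses under rewiring
  cp_null <- mean(vapply(nulls, function(x) clustering_coefficient(x)$c_p,
                         numeric(1)))
  expect_lt(cp_null, clustering_coefficient(a)$c_p / 2)
})

test_that("graphs without swaps fall back to copies with a warning", {
  expect_warning(nulls <- random_null_ensemble(graph_star(5), m = 3, seed = 1),
                 "swap|copies")
  expect_equal(unname(nulls[[1]]), graph_star(5))
})

test_that("small-world indices are 1 against an identity null", {
  a <- random_adjacency(15, 0.4, seed = 9)
  sw <- small_world_indices(a, list(a))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("Erdos-Renyi graphs score sigma near 1 against rewired nulls", {
  set.seed(77)
  g <- igraph::sample_gnp(90, 0.11)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  sw <- small_world_indices(a, random_null_ensemble(a, m = 50, seed = 5))
  expect_gt(sw$sigma, 0.8)
  expect_lt(sw$sigma, 1.2)
})

test_that("AUC over the grid matches closed-form integrals", {
  grid <- sparsity_grid()
  # constant integrand over [0.05, 0.40]
  expect_equal(auc_over_grid(rep(2, 36), grid), 2 * 0.35, tolerance = 1e-12)
  # linear integrand: trapezoid is exact
  vals <- 3 * grid$values + 1
  expect_equal(auc_over_grid(vals, grid),
               1.5 * (0.40^2 - 0.05^2) + 0.35, tolerance = 1e-12)
  # single trapezoid
  expect_equal(auc_over_grid(c(1, 3), c(0.1, 0.2)), 0.2)
  # non-finite values propagate as Inf
  expect_identical(auc_over_grid(c(1, Inf, 1), c(0.1, 0.2, 0.3)), Inf)
})

test_that("path-length/global-efficiency identity holds on computed graphs", {
  for (seed in 1:5) {
    a <- random_adjacency(25, 0.2, seed = seed)
    e <- efficiencies(a)$e_glob
    if (e > 0) {
      expect_equal(characteristic_path_length_harmonic(a) * e, 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never decreases efficiency or degree", {
  a <- random_adjacency(15, 0.15, seed = 13)
  missing <- which(upper.tri(a) & a == 0)
  before <- efficiencies(a)
  db_before <- nodal_degree_betweenness(a)$degree
  for (idx in missing[c(1, 5, 9)]) {
    b <- a
    b[idx] <- 1
    b <- pmax(b, t(b))
    after <- efficiencies(b)
    expect_gte(after$e_glob, before$e_glob)
    expect_true(all(after$nodal_efficiency >= before$nodal_efficiency - 1e-12))
    expect_true(all(nodal_degree_betweenness(b)$degree >= db_before))
  }
})

test_that("metric curves cover the grid with consistent dimensions", {
  cfg <- cohort_config(n_regions = 20, seed = 40)
  sp <- make_group_precision(cfg, "A")
  ts <- simulate_subject_timeseries(sp, 150, seed = 41)
  pc <- partial_correlation(ts)
  grid <- sparsity_grid(0.1, 0.3, 0.05)
  curves <- compute_metric_curves(pc, grid, null_m = 5, seed = 2)
  expect_equal(nrow(curves$global), length(grid$values))
  expect_equal(dim(curves$nodal$degree), c(length(grid$values), 20))
  expect_equal(colnames(curves$global),
               c("Cp", "Lp", "Gamma", "Lambda", "Sigma", "Eloc", "Eglob"))
  # sigma = gamma/lambda and Lp = 1/Eglob at every threshold
  expect_equal(curves$global$Sigma, curves$global$Gamma / curves$global$Lambda,
               tolerance = 1e-12)
  expect_equal(curves$global$Lp, 1 / curves$global$Eglob, tolerance = 1e-12)
  # determinism
  curves2 <- compute_metric_curves(pc, grid, null_m = 5, seed = 2)
  expect_identical(curves$global, curves2$global)
})
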