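# Metric-curve fixture with known constant values: exercises feature
# assembly without the cost of a real connectome computation.
constant_curves <- function(labels, grid = sparsity_grid(), value = 2) {
  ns <- length(grid$values)
  n <- length(labels)
  glob <- as.data.frame(matrix(value, ns, 7))
  colnames(glob) <- c("Cp", "Lp", "Gamma", "Lambda", "Sigma", "Eloc", "Eglob")
  nodal <- lapply(1:3, function(i) matrix(value, ns, n,
                                          dimnames = list(NULL, labels)))
  names(nodal) <- c("degree", "betweenness", "efficiency")
  structure(list(grid = grid, global = glob, nodal = nodal,
                 region_labels = labels, null_m = 1L, seed = 1L),
            class = "metric_curves")
}
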