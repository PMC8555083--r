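#' Assemble the threshold-integrated topological feature vector
#'
#' Applies [auc_over_grid()] to each metric curve and lays the results out in
#' the fixed order: 7 global features (Cp, Lp, Gamma, Lambda, Sigma, Eloc,
#' Eglob), then one block per nodal metric (degree, betweenness, efficiency),
#' each block in atlas region order. For a 90-region atlas this is the
#' 7 + 3*90 = 277-dimensional feature vector.
#'
#' @param curves A [compute_metric_curves()] result.
#' @param subject_id Subject identifier.
#' @param group Group label.
#' @return An object of class `topo_features`: named numeric vector of length
#'   `7 + 3 * n_regions` with attributes `subject_id` and `group`. Names are
#'   `"global:<metric>"`, `"degree:<region>"`, `"betweenness:<region>"`,
#'   `"efficiency:<region>"`.
#' @export
assemble_features <- function(curves, subject_id = "sub", group = NA_character_) {
  stopifnot(inherits(curves, "metric_curves"))
  grid <- curves$grid
  glob <- vapply(curves$global, auc_over_grid, numeric(1), grid = grid)
  nodal <- lapply(curves$nodal, function(m) apply(m, 2, auc_over_grid, grid = grid))
  values <- c(glob, nodal$degree, nodal$betweenness, nodal$efficiency)
  names(values) <- feature_names(curves$region_labels)
  structure(values, class = "topo_features", subject_id = subject_id, group = group)
}

#' Canonical feature-name vector for an atlas
#'
#' @param region_labels Character vector of region labels in atlas order.
#' @return Character vector of length `7 + 3 * length(region_labels)`.
#' @export
feature_names <- function(region_labels) {
  c(paste0("global:", c("Cp", "Lp", "Gamma", "Lambda", "Sigma", "Eloc", "Eglob")),
    paste0("degree:", region_labels),
    paste0("betweenness:", region_labels),
    paste0("efficiency:", region_labels))
}

#' Cohort feature table
#'
#' Stacks per-subject feature vectors into a subjects x features matrix with
#' subject ids and group labels. All vectors must share the identical name
#' order; any mismatch is a hard error to prevent silent column
#' misalignment.
#'
#' @param features List of [assemble_features()] vectors.
#' @return An object of class `feature_table`: data frame with columns
#'   `subject_id`, `group`, then one column per feature.
#' @export
feature_table <- function(features) {
  if (length(features) == 0L) stop("empty cohort: no feature vectors")
  ref <- names(features[[1]])
  for (f in features) {
    if (!identical(names(f), ref)) {
      stop("feature name order mismatch between subjects")
    }
  }
  mat <- do.call(rbind, lapply(features, as.numeric))
  colnames(mat) <- ref
  df <- data.frame(
    subject_id = vapply(features, function(f) attr(f, "subject_id"), character(1)),
    group = vapply(features, function(f) as.character(attr(f, "group")), character(1)),
    mat, check.names = FALSE, stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

# numeric feature matrix / labels of a feature_table
ft_matrix <- function(ft) {
  as.matrix(ft[, setdiff(colnames(ft), c("subject_id", "group")), drop = FALSE])
}

ft_labels <- function(ft) factor(ft$group)

#' Write / read a feature table as TSV
#'
#' Plain UTF-8 tab-delimited round trip: first column `subject_id`, second
#' `group`, remaining columns the named features at full double precision.
#'
#' @param ft A [feature_table()].
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  out <- ft
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% colnames(df)[1:2])) {
    stop("feature table must start with subject_id and group columns")
  }
  class(df) <- c("feature_table", "data.frame")
  df
}
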