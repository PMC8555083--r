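# Backward weight-propagation attribution: starting from the deepest hidden
# layer, retain the nodes carrying > 50% of the layer's contribution and
# propagate through the restricted weight matrices back to the raw features.

#' Per-node contributions of a layer from its outgoing weight matrix
#'
#' Contribution of node `j` in layer `i` is the sum over the retained
#' downstream nodes `k` of `|w[k, j]|` (or squared weights), normalized to
#' sum to 1 across the layer.
#'
#' @param w Weight matrix, rows = downstream-layer nodes, columns =
#'   this-layer nodes.
#' @param kept_next Indices of retained downstream nodes (default: all rows).
#' @param type `"abs"` (default) or `"square"` weight magnitudes.
#' @return Numeric contribution vector over the layer's nodes, summing to 1.
#' @export
layer_contributions <- function(w, kept_next = seq_len(nrow(w)),
                                type = c("abs", "square")) {
  type <- match.arg(type)
  w <- as.matrix(w)
  if (length(kept_next) < 1L || any(kept_next < 1L | kept_next > nrow(w))) {
    stop("kept_next must index rows of w")
  }
  mag <- if (type == "abs") abs(w) else w^2
  contrib <- colSums(mag[kept_next, , drop = FALSE])
  total <- sum(contrib)
  if (total == 0) stop("all-zero restricted weight matrix: degenerate model")
  contrib / total
}

#' Minimal node set carrying more than half the contribution
#'
#' Sorts contributions in descending order (ties broken by node index) and
#' returns the smallest prefix whose sum strictly exceeds 0.5.
#'
#' @param contributions Normalized contribution vector.
#' @return Integer vector of retained node indices.
#' @export
select_over_half <- function(contributions) {
  ord <- order(-contributions, seq_along(contributions))
  cum <- cumsum(contributions[ord])
  n_keep <- which(cum > 0.5)[1]
  if (is.na(n_keep)) n_keep <- length(contributions)
  sort(ord[seq_len(n_keep)])
}

#' Backward weight-propagation contribution report
#'
#' Seeds the pass at the deepest hidden layer using its outgoing weight
#' matrix (all downstream nodes retained), then alternates
#' [select_over_half()] and [layer_contributions()] through the earlier
#' weight matrices. At the input layer all raw features are scored against
#' the retained second-layer set (no > 50% cut), yielding a normalized
#' contribution per raw feature.
#'
#' @param model A fine-tuned `sae_model`.
#' @param feature_names Names of the raw input features (default: stored
#'   training names when present).
#' @param type `"abs"` or `"square"` weight magnitudes.
#' @param top_k Number of top features to rank (default 10).
#' @return An object of class `contribution_report`: `kept` (retained node
#'   sets per hidden layer, deepest first), `contributions` (named, length =
#'   input width, sums to 1), `top` (data frame of the `top_k` best features,
#'   descending).
#' @export
backward_propagate_contributions <- function(model, feature_names = NULL,
                                             type = c("abs", "square"),
                                             top_k = 10L) {
  stopifnot(inherits(model, "sae_model"))
  type <- match.arg(type)
  nl <- length(model$W)
  feature_names <- feature_names %||% colnames(model$W[[1]]) %||%
    sprintf("f%03d", seq_len(model$layer_sizes[1]))
  if (length(feature_names) != model$layer_sizes[1]) {
    stop("feature_names length must equal the input width")
  }
  kept <- vector("list", nl)
  # deepest hidden layer: scored from its outgoing weights, all rows kept
  contrib <- layer_contributions(model$W[[nl]], type = type)
  kept[[1]] <- select_over_half(contrib)
  if (nl > 1) {
    for (i in (nl - 1):1) {
      contrib <- layer_contributions(model$W[[i]], kept[[nl - i]], type = type)
      if (i > 1) kept[[nl - i + 1]] <- select_over_half(contrib)
    }
  }
  names(contrib) <- feature_names
  ord <- order(-contrib, seq_along(contrib))
  top <- data.frame(
    feature = feature_names[ord[seq_len(min(top_k, length(contrib)))]],
    contribution = unname(contrib[ord[seq_len(min(top_k, length(contrib)))]]),
    stringsAsFactors = FALSE
  )
  structure(
    list(kept = kept[seq_len(max(1, nl - 1))], contributions = contrib, top = top),
    class = "contribution_report"
  )
}

#' Human-readable top-feature table
#'
#' Formats the ranked features as a three-column table: metric class
#' ("Global", "Nodal degree", "Nodal betweenness", "Nodal efficiency"), the
#' full region name with hemisphere (or "-" for global metrics), and the
#' contribution rounded to 4 decimals.
#'
#' @param report A [backward_propagate_contributions()] result.
#' @param atlas Atlas label table with columns `code` and `name` (default
#'   [aal_labels()]).
#' @return Data frame with columns `topological_property`, `brain_region`,
#'   `contribution` (formatted character).
#' @export
format_report <- function(report, atlas = aal_labels()) {
  stopifnot(inherits(report, "contribution_report"))
  parts <- strsplit(report$top$feature, ":", fixed = TRUE)
  metric <- vapply(parts, `[`, character(1), 1)
  region <- vapply(parts, `[`, character(1), 2)
  prop <- c(global = "Global", degree = "Nodal degree",
            betweenness = "Nodal betweenness",
            efficiency = "Nodal efficiency")[metric]
  region_name <- ifelse(
    metric == "global", "-",
    ifelse(region %in% atlas$code,
           atlas$name[match(region, atlas$code)], region)
  )
  data.frame(
    topological_property = unname(prop),
    brain_region = region_name,
    contribution = sprintf("%.4f", report$top$contribution),
    stringsAsFactors = FALSE
  )
}

#' AAL 90-region label table
#'
#' The 90 cortical and subcortical regions of the automated anatomical
#' labeling atlas in standard index order (left/right pairs), with the
#' conventional short codes (`.L`/`.R` suffix) and full names including
#' hemisphere.
#'
#' @return Data frame with columns `index`, `code`, `name`.
#' @export
aal_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "topoconn",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
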