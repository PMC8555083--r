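#' Partial-correlation connectome of an ROI time series
#'
#' Column-standardizes the data, estimates the covariance (with optional
#' Ledoit-Wolf shrinkage towards a scaled identity, the default and the only
#' stable choice when timepoints do not greatly exceed regions), inverts it to
#' the precision matrix `Theta`, and returns the partial correlations
#' `p_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`: the conditional dependence
#' of every region pair given all remaining regions.
#'
#' @param ts A [roi_timeseries()].
#' @param shrinkage `"auto"` (Ledoit-Wolf intensity estimated from the data),
#'   `"none"` (plain inverse; errors when the sample covariance is not safely
#'   invertible), or a numeric intensity in \[0, 1\].
#' @return An object of class `partial_corr`: list with `values` (symmetric
#'   N x N, zero diagonal, entries in \[-1, 1\]), `region_labels`, and
#'   `shrinkage_intensity` actually used.
#' @export
partial_correlation <- function(ts, shrinkage = "auto") {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  tt <- nrow(x)
  n <- ncol(x)
  if (tt <= 2L) stop("need more than 2 timepoints")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(ts$region_labels[sds == 0], collapse = ", "))
  }
  xs <- scale(x)
  s <- crossprod(xs) / tt
  if (identical(shrinkage, "none")) {
    rho <- 0
  } else if (is.numeric(shrinkage)) {
    if (shrinkage < 0 || shrinkage > 1) stop("numeric shrinkage must be in [0, 1]")
    rho <- shrinkage
  } else if (identical(shrinkage, "auto")) {
    rho <- ledoit_wolf_intensity(xs, s)
  } else {
    stop("shrinkage must be \"auto\", \"none\", or a numeric intensity")
  }
  mu <- mean(diag(s))
  sig <- (1 - rho) * s + rho * mu * diag(n)
  theta <- tryCatch(chol2inv(chol(sig)), error = function(e) NULL)
  if (is.null(theta) || kappa(sig, exact = FALSE) > 1e12) {
    stop("covariance is not stably invertible; use shrinkage = \"auto\"")
  }
  d <- 1 / sqrt(diag(theta))
  p <- -theta * tcrossprod(d)
  p <- (p + t(p)) / 2
  p[p > 1] <- 1
  p[p < -1] <- -1
  diag(p) <- 0
  dimnames(p) <- list(ts$region_labels, ts$region_labels)
  structure(
    list(values = p, region_labels = ts$region_labels, shrinkage_intensity = rho),
    class = "partial_corr"
  )
}

# Ledoit-Wolf (2004) optimal shrinkage intensity towards mu*I, computed from
# the standardized data xs (T x N) and its covariance s = xs'xs/T.
ledoit_wolf_intensity <- function(xs, s) {
  tt <- nrow(xs)
  mu <- mean(diag(s))
  d2 <- sum((s - mu * diag(ncol(s)))^2)
  if (d2 == 0) return(0)
  # b2 = (1/T^2) sum_t || x_t x_t' - S ||_F^2
  x2 <- xs^2
  b2 <- (sum(crossprod(x2)) - tt * sum(s^2)) / tt^2
  min(1, max(0, b2 / d2))
}

#' Sparsity grid for network thresholding
#'
#' Inclusive arithmetic grid of sparsity (edge-density) values; the defaults
#' give the 36 values 0.05, 0.06, ..., 0.40.
#'
#' @param s_min,s_max Grid endpoints, `0 < s_min <= s_max < 1`.
#' @param step Positive increment.
#' @return An object of class `sparsity_grid`: list with `values`, `s_min`,
#'   `s_max`, `step`.
#' @export
sparsity_grid <- function(s_min = 0.05, s_max = 0.40, step = 0.01) {
  if (!(s_min > 0 && s_min <= s_max && s_max < 1)) {
    stop("require 0 < s_min <= s_max < 1")
  }
  if (step <= 0) stop("step must be positive")
  k <- floor((s_max - s_min) / step + 1e-9)
  values <- round(s_min + step * (0:k), 10)
  if (length(values) == 0L) stop("empty sparsity grid")
  structure(
    list(values = values, s_min = s_min, s_max = s_max, step = step),
    class = "sparsity_grid"
  )
}

#' Binarize a partial-correlation matrix at a fixed sparsity
#'
#' Ranks the `N(N-1)/2` upper-triangle entries by absolute value and keeps the
#' top `round(s * N(N-1)/2)` as edges (rounding half away from zero), so every
#' subject's network has the same edge density. Ties at the cut are broken by
#' (row, column) index for determinism.
#'
#' @param pc A [partial_corr()] or a symmetric numeric matrix.
#' @param s Target sparsity (edge density) in (0, 1).
#' @return An `adjacency_matrix`: binary symmetric matrix with zero diagonal,
#'   with attributes `sparsity` and `region_labels`.
#' @export
binarize_at_sparsity <- function(pc, s) {
  vals <- if (inherits(pc, "partial_corr")) pc$values else as.matrix(pc)
  labels <- if (inherits(pc, "partial_corr")) pc$region_labels else colnames(vals)
  n <- nrow(vals)
  if (!(s > 0 && s < 1)) stop("sparsity must be in (0, 1)")
  m_total <- n * (n - 1) / 2
  k <- as.integer(round_half_up(s * m_total))
  if (k < 1L) stop("requested edge count is zero; increase sparsity")
  k <- min(k, m_total)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  ord <- order(-abs(vals[upper.tri(vals)]), ut[, 1], ut[, 2])
  keep <- ut[ord[seq_len(k)], , drop = FALSE]
  a <- matrix(0L, n, n)
  a[keep] <- 1L
  a <- a + t(a)
  dimnames(a) <- dimnames(vals)
  structure(a, class = c("adjacency_matrix", class(a)),
            sparsity = s, region_labels = labels)
}
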