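#' Synthetic two-group cohort configuration
#'
#' Describes a seeded cohort of two groups of subjects whose ROI time series
#' are drawn from group-specific Gaussian graphical models. The group
#' difference is planted in the precision matrix: off-diagonal entries whose
#' two endpoints both lie in `effect_regions` are scaled by
#' `(1 + effect_size)` for group B, so the planted regions change their
#' conditional-dependence strength and, downstream, their nodal topology.
#'
#' Defaults emulate a two-group resting-state study: 33 patients (group A)
#' versus 53 controls (group B), 90 atlas regions, 200 volumes at TR = 2 s.
#'
#' @param n_group_a,n_group_b Subjects per group (defaults 33 and 53).
#' @param n_regions Number of atlas regions / network nodes (default 90).
#' @param n_timepoints Volumes acquired per subject (default 200).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param effect_regions 1-based indices of the regions carrying the planted
#'   group difference (default the five consecutive regions 1:5, which are
#'   mutually linked in the small-world support lattice).
#' @param effect_size Non-negative multiplicative perturbation of the
#'   effect-block precision entries (default 1.5; 0 means no group
#'   difference).
#' @param noise_sd Standard deviation of additive white measurement noise on
#'   top of the model-implied signal (default 0).
#' @param motion_severity Scale of the simulated head-motion random walk
#'   (default 0.5; see [simulate_motion()]).
#' @param seed Master seed; every random quantity in the cohort derives from
#'   it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 33L, n_group_b = 53L, n_regions = 90L,
                          n_timepoints = 200L, tr_seconds = 2,
                          effect_regions = 1:5, effect_size = 1.5,
                          noise_sd = 0, motion_severity = 0.5, seed = 1L) {
  cfg <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    tr_seconds = as.numeric(tr_seconds),
    effect_regions = as.integer(effect_regions),
    effect_size = as.numeric(effect_size), noise_sd = as.numeric(noise_sd),
    motion_severity = as.numeric(motion_severity), seed = as.integer(seed)
  )
  if (cfg$n_group_a < 1L || cfg$n_group_b < 1L) stop("group sizes must be positive")
  if (cfg$n_regions < 3L) stop("need at least 3 regions")
  if (cfg$n_timepoints < 2L) stop("need at least 2 timepoints")
  if (cfg$tr_seconds <= 0) stop("tr_seconds must be positive")
  if (length(cfg$effect_regions) &&
      (min(cfg$effect_regions) < 1L || max(cfg$effect_regions) > cfg$n_regions)) {
    stop("effect_regions must lie in [1, n_regions]")
  }
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$motion_severity < 0) stop("motion_severity must be >= 0")
  structure(cfg, class = "cohort_config")
}

# Build a symmetric diagonally-dominant precision matrix on a given binary
# support with given edge weights; diagonal = abs row sum + 0.5.
precision_from_support <- function(support, weights) {
  n <- nrow(support)
  theta <- matrix(0, n, n)
  ut <- which(upper.tri(support) & support != 0)
  if (length(ut) != length(weights)) stop("one weight per support edge required")
  theta[ut] <- weights
  theta <- theta + t(theta)
  diag(theta) <- rowSums(abs(theta)) + 0.5
  theta
}

#' Precision-matrix specification for one group
#'
#' Wraps a symmetric positive-definite precision matrix together with the
#' binary support of its off-diagonal structure (the ground-truth network that
#' partial-correlation estimation should recover).
#'
#' @param matrix Symmetric positive-definite precision matrix.
#' @param ground_truth_adjacency Binary support of the off-diagonal entries;
#'   derived from `matrix` when omitted.
#' @return An object of class `precision_spec`.
#' @export
precision_spec <- function(matrix, ground_truth_adjacency = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("precision matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("precision matrix must be symmetric")
  if (any(diag(m) <= 0)) stop("precision diagonal must be positive")
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("precision matrix must be positive definite")
  if (is.null(ground_truth_adjacency)) {
    ground_truth_adjacency <- (abs(m) > 1e-12) * 1
    diag(ground_truth_adjacency) <- 0
  }
  structure(
    list(matrix = m, ground_truth_adjacency = ground_truth_adjacency),
    class = "precision_spec"
  )
}

#' Group precision matrix on a small-world support
#'
#' Both groups share a Watts-Strogatz support graph (ring lattice of mean
#' degree 10, rewiring probability 0.1) with edge weights of random sign and
#' magnitude in \[0.15, 0.4\], made positive definite by diagonal dominance
#' (diagonal = absolute row sum + 0.5).
#'
#' For group B the effect regions are reorganized into connector hubs, the
#' kind of topological alteration the nodal metrics are designed to detect:
#' their lattice couplings are weakened by `1/(1 + effect_size)`, each
#' acquires strong conditional dependencies (partial correlation
#' `0.16 * e/(e + 0.25)`, alternating sign) with up to 10 deterministically
#' spaced distant satellite regions, and the effect regions are mutually
#' coupled at partial correlation `0.12 * e/(e + 0.25)`. The saturating
#' coupling strengths keep the matrix safely positive definite for every
#' effect size while changing the degree, betweenness, and efficiency of the
#' effect regions. All changes are confined to the rows and columns of the
#' effect regions; `effect_size = 0` leaves the groups identical.
#'
#' @param config A [cohort_config()].
#' @param group `"A"` (reference) or `"B"` (perturbed).
#' @return A [precision_spec()].
#' @export
make_group_precision <- function(config, group = c("A", "B")) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  n <- config$n_regions
  nei <- min(5L, max(1L, (n - 1L) %/% 2L))
  base <- with_seed(derive_seed(config$seed, 1), {
    g <- igraph::simplify(igraph::sample_smallworld(1, n, nei, 0.1))
    support <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    ne <- sum(support[upper.tri(support)])
    w <- stats::runif(ne, 0.15, 0.4) * sample(c(-1, 1), ne, replace = TRUE)
    list(support = support, weights = w)
  })
  theta <- precision_from_support(base$support, base$weights)
  e <- config$effect_size
  eff <- config$effect_regions
  if (group == "B" && e > 0 && length(eff)) {
    gain <- e / (e + 0.25)
    rho_hub <- 0.16 * gain
    rho_block <- 0.12 * gain
    detach <- 1 / (1 + e)
    base_diag <- diag(theta)
    # satellite pool: away from the effect block on the ring
    win <- if (n >= 40) 6 else 2
    near <- unique(unlist(lapply(eff, function(r) ((r + (-win:win) - 1) %% n) + 1)))
    pool <- setdiff(seq_len(n), union(eff, near))
    n_sat <- min(10L, length(pool) %/% length(eff))
    d <- theta
    diag(d) <- 0
    if (n_sat > 0) {
      picks <- pool[round(seq(1, length(pool), length.out = length(eff) * n_sat))]
      sats <- split(picks, rep(seq_along(eff), each = n_sat))
      for (i in seq_along(eff)) {
        r <- eff[i]
        d[r, ] <- d[r, ] * detach
        d[, r] <- d[, r] * detach
        s <- sats[[i]]
        hubw <- -rho_hub * sqrt(base_diag[r] * base_diag[s]) *
          rep_len(c(1, -1), length(s))
        d[r, s] <- hubw
        d[s, r] <- hubw
      }
    }
    for (i in seq_along(eff)) {
      for (j in seq_along(eff)) {
        if (i != j) {
          d[eff[i], eff[j]] <- -rho_block * sqrt(base_diag[eff[i]] * base_diag[eff[j]])
        }
      }
    }
    diag(d) <- base_diag
    theta <- d
  }
  ch <- tryCatch(chol(theta), error = function(err) NULL)
  if (is.null(ch)) stop("internal error: constructed precision is not positive definite")
  gt <- (abs(theta) > 1e-12) * 1
  diag(gt) <- 0
  precision_spec(theta, gt)
}

#' Simulate one subject's ROI time series from a precision matrix
#'
#' Draws i.i.d. multivariate-normal rows with covariance equal to the inverse
#' of the precision matrix (plus optional additive white noise), so the
#' planted conditional-dependence structure is exactly the partial-correlation
#' structure of the generated signal.
#'
#' @param spec A [precision_spec()].
#' @param n_timepoints Number of rows to draw (>= 2).
#' @param seed Seed for this subject's draw.
#' @param noise_sd Additive white-noise standard deviation (default 0).
#' @param tr_seconds Repetition time recorded on the output (default 2).
#' @param region_labels Optional region names.
#' @return A [roi_timeseries()].
#' @export
simulate_subject_timeseries <- function(spec, n_timepoints, seed, noise_sd = 0,
                                        tr_seconds = 2, region_labels = NULL) {
  stopifnot(inherits(spec, "precision_spec"))
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  n <- nrow(spec$matrix)
  sigma <- chol2inv(chol(spec$matrix))
  r <- chol(sigma)
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
    out <- z %*% r
    if (noise_sd > 0) out <- out + noise_sd * matrix(stats::rnorm(length(out)), nrow(out))
    out
  })
  roi_timeseries(x, region_labels %||% sprintf("R%03d", seq_len(n)), tr_seconds)
}

#' Simulate a six-parameter head-motion trace
#'
#' Random-walk realignment parameters: three translations (mm) and three
#' rotations (degrees) with per-frame increments of standard deviation
#' `0.02 * severity`. `severity = 0` gives an all-zero trace; large values
#' produce traces exceeding the 1 mm / 1 degree exclusion limits.
#'
#' @param n_timepoints Number of frames.
#' @param severity Non-negative scale of the walk.
#' @param seed Seed for the draw.
#' @return A [motion_params()].
#' @export
simulate_motion <- function(n_timepoints, severity, seed) {
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (severity < 0) stop("severity must be >= 0")
  steps <- with_seed(seed, matrix(stats::rnorm(n_timepoints * 6, sd = 0.02 * severity),
                                  n_timepoints, 6))
  motion_params(apply(steps, 2, cumsum))
}

#' Simulate a full two-group cohort
#'
#' Generates `n_group_a + n_group_b` subject records (group label, ROI time
#' series, motion trace), all randomness derived from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: a list of subject records, each with
#'   `subject_id`, `group` (`"A"` or `"B"`), `timeseries`, `motion`; the
#'   config and the two [precision_spec()]s are attached as attributes.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- list(A = make_group_precision(config, "A"),
                B = make_group_precision(config, "B"))
  labels <- if (config$n_regions == 90L) aal_labels()$code else
    sprintf("R%03d", seq_len(config$n_regions))
  groups <- rep(c("A", "B"), c(config$n_group_a, config$n_group_b))
  records <- lapply(seq_along(groups), function(i) {
    list(
      subject_id = sprintf("sub%03d", i),
      group = groups[i],
      timeseries = simulate_subject_timeseries(
        specs[[groups[i]]], config$n_timepoints,
        seed = derive_seed(config$seed, 100 + i),
        noise_sd = config$noise_sd, tr_seconds = config$tr_seconds,
        region_labels = labels
      ),
      motion = simulate_motion(config$n_timepoints, config$motion_severity,
                               seed = derive_seed(config$seed, 5000 + i))
    )
  })
  structure(records, class = "cohort", config = config, specs = specs)
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cohort> %d subjects (%d A / %d B), %d regions, %d timepoints\n",
              length(x), cfg$n_group_a, cfg$n_group_b, cfg$n_regions,
              cfg$n_timepoints))
  invisible(x)
}
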