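# File formats and the end-to-end pipeline driver. All tabular artifacts are
# UTF-8 tab-delimited text with headers; nested results are JSON.

#' Write / read an ROI time series as TSV
#'
#' Rows = timepoints, columns = region labels (header row). TR is not stored
#' in the file and must be supplied on read.
#'
#' @param ts A [roi_timeseries()].
#' @param path File path.
#' @param tr_seconds Repetition time to attach on read.
#' @return `write_timeseries_tsv` returns `path` invisibly;
#'   `read_timeseries_tsv` returns a [roi_timeseries()].
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = ts$region_labels)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path, tr_seconds = 2) {
  df <- utils::read.delim(path, check.names = FALSE)
  roi_timeseries(as.matrix(df), colnames(df), tr_seconds)
}

#' Write / read a motion trace as 6-column whitespace-delimited text
#'
#' The SPM `rp_*.txt` dialect: no header, three translations (mm) then three
#' rotations (degrees) per frame.
#'
#' @param mp A [motion_params()].
#' @param path File path.
#' @return `write_motion_txt` returns `path` invisibly; `read_motion_txt`
#'   returns a [motion_params()].
#' @export
write_motion_txt <- function(mp, path) {
  stopifnot(inherits(mp, "motion_params"))
  utils::write.table(mp$data, path, sep = "  ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_txt
#' @export
read_motion_txt <- function(path) {
  motion_params(as.matrix(utils::read.table(path)))
}

#' Write a simulated cohort to disk
#'
#' Per-subject time-series TSVs and `rp_<id>.txt` motion traces plus a
#' manifest CSV (`subject_id`, `group`, `timeseries_path`, `motion_path`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    ts_path <- file.path(dir, paste0(rec$subject_id, "_timeseries.tsv"))
    mo_path <- file.path(dir, paste0("rp_", rec$subject_id, ".txt"))
    write_timeseries_tsv(rec$timeseries, ts_path)
    write_motion_txt(rec$motion, mo_path)
    data.frame(subject_id = rec$subject_id, group = rec$group,
               timeseries_path = ts_path, motion_path = mo_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Validate a cohort manifest
#'
#' Parses a manifest CSV (`subject_id`, `group`, `timeseries_path`, optional
#' `motion_path`), aggregates all schema problems into a single error, and
#' flags (never silently drops) subjects whose motion trace violates the
#' exclusion rule.
#'
#' @param path Manifest CSV path, or a data frame with the same columns.
#' @param max_translation_mm,max_rotation_deg Motion-exclusion thresholds
#'   (see [motion_exclusion()]).
#' @param check_files Verify that referenced files exist (default TRUE).
#' @return Data frame of subject records with an added logical
#'   `excluded_motion` column (`NA` when no motion file is given).
#' @export
validate_manifest <- function(path, max_translation_mm = 1.0,
                              max_rotation_deg = 1.0, check_files = TRUE) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- character(0)
  required <- c("subject_id", "group", "timeseries_path")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols)) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup)) {
    problems <- c(problems, paste("duplicate subject id(s):",
                                  paste(dup, collapse = ", ")))
  }
  bad_group <- unique(df$group[!df$group %in% c("A", "B")])
  if (length(bad_group)) {
    problems <- c(problems, paste("unknown group label(s):",
                                  paste(bad_group, collapse = ", ")))
  }
  if (check_files) {
    missing_ts <- df$timeseries_path[!file.exists(df$timeseries_path)]
    if (length(missing_ts)) {
      problems <- c(problems, paste("missing time-series file(s):",
                                    paste(missing_ts, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid manifest:\n  - ", paste(problems, collapse = "\n  - "))
  }
  has_motion <- "motion_path" %in% colnames(df) & !is.na(df[["motion_path"]] %||% NA)
  df$excluded_motion <- NA
  if (any(has_motion)) {
    for (i in which(has_motion)) {
      if (!file.exists(df$motion_path[i])) {
        if (check_files) stop("missing motion file: ", df$motion_path[i])
        next
      }
      df$excluded_motion[i] <- motion_exclusion(
        read_motion_txt(df$motion_path[i]), max_translation_mm, max_rotation_deg
      )
    }
  }
  df
}

#' Run the full analysis chain on a synthetic or file-backed cohort
#'
#' Simulates (or accepts) a cohort, applies the temporal preprocessing
#' requested in `prep`, flags motion-excluded subjects, estimates each
#' subject's partial-correlation connectome, computes the thresholded metric
#' curves and threshold-integrated features, cross-validates the two-stage
#' classifier, optionally runs the permutation test, and fits the
#' interpretation model for the contribution report.
#'
#' @param cohort A [simulate_cohort()] result or a [cohort_config()]
#'   (simulated on the fly).
#' @param grid A [sparsity_grid()].
#' @param null_m Null-ensemble size per threshold.
#' @param prep List of preprocessing switches: `n_discard` (initial volumes
#'   to drop), `bandpass` (logical; 0.01-0.08 Hz), `regress_motion`,
#'   `regress_global` (logical).
#' @param k_outer,layer_sizes,hyper,c_grid,k_inner Classifier settings (see
#'   [cross_validate_pipeline()]).
#' @param interp_hyper Training settings for the interpretation model that
#'   feeds the contribution report; attribution reads trained weight
#'   magnitudes, so this model is trained to convergence (default
#'   `sae_hyper(100, 500, 3e-3)`), unlike the cross-validation models whose
#'   codes only need to be predictive.
#' @param n_perm Permutations for the significance test (0 = skip).
#' @param seed Master seed for folds, SAE training, nulls, and permutations.
#' @param out_dir Optional directory; when given, the feature table,
#'   results JSON, permutation null TSV, and attribution report are written
#'   there.
#' @return List with `features` ([feature_table()]), `cv` ([cross_validate_pipeline()]
#'   result), `perm` (optional [permutation_test()] result), `attribution`
#'   ([backward_propagate_contributions()] report of the interpretation model
#'   fine-tuned on the full cohort), `excluded`, and `provenance`.
#' @export
run_pipeline <- function(cohort, grid = sparsity_grid(), null_m = 100L,
                         prep = list(n_discard = 10L, bandpass = FALSE,
                                     regress_motion = FALSE,
                                     regress_global = FALSE),
                         k_outer = 10L, layer_sizes = c(128L, 64L, 32L, 10L),
                         hyper = sae_hyper(), c_grid = 10^(-3:4),
                         k_inner = 5L, n_perm = 0L, seed = 1L,
                         interp_hyper = sae_hyper(100L, 500L, 3e-3),
                         out_dir = NULL) {
  if (inherits(cohort, "cohort_config")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"))
  excluded <- vapply(cohort, function(rec) motion_exclusion(rec$motion), logical(1))
  names(excluded) <- vapply(cohort, `[[`, character(1), "subject_id")
  kept <- cohort[!excluded]
  feats <- lapply(seq_along(kept), function(i) {
    rec <- kept[[i]]
    ts <- rec$timeseries
    if ((prep$n_discard %||% 0L) > 0L) {
      ts <- discard_initial_volumes(ts, prep$n_discard)
    }
    if (isTRUE(prep$bandpass)) ts <- detrend_bandpass(ts)
    conf <- NULL
    if (isTRUE(prep$regress_motion)) {
      mo <- rec$motion$data
      if ((prep$n_discard %||% 0L) > 0L) {
        mo <- mo[-seq_len(prep$n_discard), , drop = FALSE]
      }
      conf <- cbind(conf, mo)
    }
    if (isTRUE(prep$regress_global)) conf <- cbind(conf, global_signal(ts))
    if (!is.null(conf)) ts <- nuisance_regression(ts, conf)
    pc <- partial_correlation(ts)
    curves <- compute_metric_curves(pc, grid, null_m = null_m,
                                    seed = derive_seed(seed, 40000 + i))
    assemble_features(curves, rec$subject_id, rec$group)
  })
  ft <- feature_table(feats)
  cv <- cross_validate_pipeline(ft, k_outer = k_outer,
                                layer_sizes = layer_sizes, hyper = hyper,
                                c_grid = c_grid, k_inner = k_inner, seed = seed)
  perm <- NULL
  if (n_perm > 0L) {
    perm <- permutation_test(ft, n_perm = n_perm, seed = seed,
                             k_outer = k_outer, layer_sizes = layer_sizes,
                             hyper = hyper, c_grid = c_grid, k_inner = k_inner)
  }
  # interpretation model: one SAE fine-tuned on the full (standardized) cohort
  x <- ft_matrix(ft); y <- ft_labels(ft)
  st <- fit_standardizer(x)
  xs <- apply_standardizer(st, x)
  pre <- pretrain_autoencoders(xs, layer_sizes, interp_hyper,
                               seed = derive_seed(seed, 90001))
  interp <- fine_tune_supervised(pre, xs, y, interp_hyper,
                                 seed = derive_seed(seed, 90002))
  attribution <- backward_propagate_contributions(interp, colnames(x))
  provenance <- list(
    package_version = as.character(utils::packageVersion("topoconn")),
    seed = seed, n_subjects = length(cohort), n_excluded = sum(excluded),
    n_features = ncol(x), grid = grid$values, null_m = null_m,
    layer_sizes = layer_sizes, hyper = unclass(hyper),
    interp_hyper = unclass(interp_hyper), k_outer = k_outer,
    k_inner = k_inner, c_grid = c_grid, n_perm = n_perm, prep = prep
  )
  result <- list(features = ft, cv = cv, perm = perm,
                 attribution = attribution, interpretation_model = interp,
                 excluded = excluded, provenance = provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(ft, file.path(out_dir, "features.tsv"))
    res_json <- list(
      provenance = provenance,
      per_fold = cv$per_fold, mean = as.list(cv$mean), sd = as.list(cv$sd)
    )
    if (!is.null(perm)) {
      res_json$permutation <- list(observed = perm$observed,
                                   p_value = perm$p_value,
                                   p_label = perm$p_label, n_perm = perm$n_perm)
      utils::write.table(data.frame(balanced_accuracy = perm$null),
                         file.path(out_dir, "permutation_null.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(res_json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(format_report(attribution),
                       file.path(out_dir, "attribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    checks <- tools::md5sum(files)
    jsonlite::write_json(as.list(checks), file.path(out_dir, "checksums.json"),
                         auto_unbox = TRUE)
  }
  result
}
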