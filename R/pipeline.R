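# The three named pipelines — unimodal IMS, unimodal microscopy,
# multimodal — share one modeling code path and one patient-level split;
# only the feature block fed to the classifier differs.

#' Pipeline configuration
#'
#' @param n_axis_bins Bins of the common m/z axis (default 600 for
#'   synthetic runs; real profile data typically warrants several
#'   thousand).
#' @param mz_min,mz_max Axis range in Daltons (defaults 700 and 3500).
#' @param baseline_window Odd rolling window for baseline subtraction, in
#'   bins (default 51).
#' @param max_shift Realignment search half-range in bins (default 5).
#' @param snr_min Peak-picking SNR threshold (default 3).
#' @param window_halfwidth Peak integration half-width in bins
#'   (default 1).
#' @param embedder An `embedder_spec` (default: the built-in texture
#'   encoder at 512 dimensions).
#' @param encoder Encoder function (default [texture_encoder()]).
#' @param fusion_weights Length-2 weights `(w_ims, w_morph)` for the
#'   multimodal block (default `c(1, 1)`).
#' @param grid Regularization grid (default [default_grid()]).
#' @param k_outer,k_inner Outer and inner fold counts (defaults 5 and 5).
#' @param heldout_fraction Fraction of patients held out (default 0.2).
#' @param seed Seed driving the split, fold assignment and grid search.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_axis_bins = 600, mz_min = 700, mz_max = 3500,
                            baseline_window = 51, max_shift = 5,
                            snr_min = 3, window_halfwidth = 1,
                            embedder = embedder_spec(),
                            encoder = texture_encoder,
                            fusion_weights = c(1, 1),
                            grid = default_grid(),
                            k_outer = 5, k_inner = 5,
                            heldout_fraction = 0.2, seed = 1L) {
  structure(list(n_axis_bins = assert_count(n_axis_bins, "n_axis_bins",
                                            min = 2),
                 mz_min = mz_min, mz_max = mz_max,
                 baseline_window = baseline_window, max_shift = max_shift,
                 snr_min = snr_min, window_halfwidth = window_halfwidth,
                 embedder = embedder, encoder = encoder,
                 fusion_weights = fusion_weights, grid = grid,
                 k_outer = assert_count(k_outer, "k_outer", min = 2),
                 k_inner = assert_count(k_inner, "k_inner", min = 2),
                 heldout_fraction = assert_fraction(heldout_fraction,
                                                    "heldout_fraction",
                                                    open = TRUE),
                 seed = assert_count(seed, "seed", min = 0)),
            class = "pipeline_config")
}

# Shared per-cohort computations: spectral preprocessing referenced on the
# training spots, and (deterministic) patch embeddings.  `modes` limits
# the work to what the requested pipelines need.
prepare_inputs <- function(cohort, config, plan,
                           modes = c("ims", "microscopy", "multimodal")) {
  records <- cohort$records
  train_spots <- records$spot_id[records$patient_id %in%
                                   plan$train_patients]
  out <- list(records = records, train_spots = train_spots)
  need_ims <- any(modes %in% c("ims", "multimodal"))
  need_morph <- any(modes %in% c("microscopy", "multimodal"))
  if (need_ims) {
    axis <- axis_spec(config$mz_min, config$mz_max, config$n_axis_bins)
    prep <- preprocess_spectra(cohort$spectra, axis,
                               baseline_window = config$baseline_window,
                               max_shift = config$max_shift,
                               reference_ids = train_spots)
    if (length(prep$dropped)) {
      keep <- !(records$spot_id %in% prep$dropped)
      records <- records[keep, , drop = FALSE]
      out$records <- records
      out$train_spots <- intersect(train_spots, records$spot_id)
    }
    out$axis <- axis
    out$spectra <- prep$spectra[records$spot_id]
    out$shifts <- prep$shifts
  }
  if (need_morph) {
    out$embeddings <- embed_patches(cohort$patches[records$spot_id],
                                    config$embedder, config$encoder)
  }
  out
}

# Feature builder for one mode: returns function(fit_idx) -> matrix over
# the given spot ids, with peak picking and scaling fitted on fit_idx
# rows only.  Also records the last fit artifacts for inspection.
make_builder <- function(mode, inputs, config, spot_ids, artifacts) {
  force(spot_ids)
  function(fit_idx) {
    fit_ids <- spot_ids[fit_idx]
    blocks <- list()
    if (mode %in% c("ims", "multimodal")) {
      peaks <- detect_peaks(mean_spectrum(inputs$spectra[fit_ids]),
                            snr_min = config$snr_min,
                            window_halfwidth = config$window_halfwidth)
      pm <- build_peak_matrix(inputs$spectra[spot_ids], peaks)
      sc <- fit_scaler(pm, fit_idx)
      blocks$ims <- scale_block(sc, pm)
      artifacts$peaks <- peaks
      artifacts$ims_scaler <- sc
    }
    if (mode %in% c("microscopy", "multimodal")) {
      em <- inputs$embeddings[spot_ids, , drop = FALSE]
      sc <- fit_scaler(em, fit_idx)
      blocks$morph <- scale_block(sc, em)
      artifacts$morph_scaler <- sc
    }
    X <- if (mode == "multimodal") {
      fuse(blocks$ims, blocks$morph, config$fusion_weights)
    } else {
      blocks[[1L]]
    }
    rownames(X) <- spot_ids
    X
  }
}

#' Run one classification pipeline end to end
#'
#' Splits patients (unless a `plan` is supplied), preprocesses the
#' modalities the mode needs with every data-dependent fit restricted to
#' training spots, runs patient-grouped nested cross-validation on the
#' training patients, refits the final model at the modal selected `C` on
#' all training spots, and scores the held-out spots.
#'
#' @param cohort An `msi_cohort` (or a compatible list with `records`,
#'   `spectra`, `patches`).
#' @param mode `"ims"`, `"microscopy"` or `"multimodal"`.
#' @param config A `pipeline_config`.
#' @param plan Optional `split_plan` shared across pipelines; default: a
#'   fresh split from `config$seed`.
#' @param inputs Optional preprocessed inputs from a previous pipeline on
#'   the same cohort/plan (an internal cache used by [run_experiment()] to
#'   avoid re-embedding patches for every mode).
#' @return A `pipeline_result`: list with `mode`, `cv` (a `cv_result`),
#'   `heldout` (`scores` + `metrics`), `fitted` (final peak list, scaler
#'   statistics and `C`), and `plan`.
#' @export
run_pipeline <- function(cohort, mode = c("ims", "microscopy",
                                          "multimodal"),
                         config = pipeline_config(), plan = NULL,
                         inputs = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("ims", "multimodal") && is.null(cohort$spectra)) {
    stop(sprintf("mode '%s' requires spectra", mode), call. = FALSE)
  }
  if (mode %in% c("microscopy", "multimodal") && is.null(cohort$patches)) {
    stop(sprintf("mode '%s' requires patches", mode), call. = FALSE)
  }
  if (is.null(plan)) {
    plan <- split_patients(cohort$records, config$heldout_fraction,
                           seed = config$seed)
    plan <- assign_outer_folds(plan, config$k_outer)
  }
  if (is.null(inputs)) {
    inputs <- prepare_inputs(cohort, config, plan, modes = mode)
  }
  records <- inputs$records
  train_mask <- records$patient_id %in% plan$train_patients
  train_records <- records[train_mask, , drop = FALSE]

  artifacts <- new.env(parent = emptyenv())
  # nested CV over training spots only
  cv_builder_ids <- train_records$spot_id
  builder_cv <- make_builder(mode, inputs, config, cv_builder_ids,
                             artifacts)
  cv <- nested_cv(train_records$label, train_records$patient_id, plan,
                  grid = config$grid, k_inner = config$k_inner,
                  seed = config$seed, builder = builder_cv,
                  spot_ids = cv_builder_ids)

  # final fit on all training spots, evaluated on the held-out spots
  all_ids <- records$spot_id
  builder_all <- make_builder(mode, inputs, config, all_ids, artifacts)
  X_all <- builder_all(which(train_mask))
  final <- train_linear_svm(X_all[train_mask, , drop = FALSE],
                            train_records$label, cv$selected_C)
  heldout_mask <- !train_mask
  heldout <- evaluate_heldout(final,
                              X_all[heldout_mask, , drop = FALSE],
                              records$label[heldout_mask],
                              spot_ids = records$spot_id[heldout_mask],
                              train_spot_ids = train_records$spot_id)
  fitted <- list(C = cv$selected_C,
                 fold_C = cv$folds$C,
                 peaks = artifacts$peaks %||% NULL,
                 ims_scaler = artifacts$ims_scaler %||% NULL,
                 morph_scaler = artifacts$morph_scaler %||% NULL,
                 model = final)
  structure(list(mode = mode, cv = cv, heldout = heldout, fitted = fitted,
                 plan = plan, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %s>\n", x$mode))
  cat(sprintf("  CV ROC-AUC %.3f +/- %.3f | held-out ROC-AUC %.3f\n",
              x$cv$summary$mean[x$cv$summary$metric == "roc_auc"],
              x$cv$summary$sd[x$cv$summary$metric == "roc_auc"],
              x$heldout$metrics$roc_auc))
  invisible(x)
}

#' Compare fitted pipelines on their shared held-out spots
#'
#' Builds the cross-pipeline metrics table (CV mean +/- sd and held-out
#' point metrics) and runs the DeLong test on every requested pair of
#' held-out score sets.
#'
#' @param results Named list of `pipeline_result` objects that share the
#'   same split plan.
#' @param pairs List of length-2 character vectors naming the pairs to
#'   test (default: all pairs).
#' @return A `pipeline_report`: list with `metrics` (data.frame), `delong`
#'   (named list of `delong_result`), `heldout_scores` and `plan`.
#' @export
compare_pipelines <- function(results, pairs = NULL) {
  stopifnot(length(results) >= 2L, !is.null(names(results)))
  ids0 <- results[[1L]]$heldout$scores$spot_ids
  for (r in results) {
    if (!identical(r$heldout$scores$spot_ids, ids0)) {
      stop("pipelines were evaluated on different held-out spots",
           call. = FALSE)
    }
  }
  metrics <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    s <- r$cv$summary
    data.frame(pipeline = nm,
               metric = s$metric, cv_mean = s$mean, cv_sd = s$sd,
               heldout = vapply(s$metric, function(m)
                 r$heldout$metrics[[m]], numeric(1)),
               row.names = NULL)
  }))
  if (is.null(pairs)) {
    nms <- names(results)
    pairs <- utils::combn(nms, 2L, simplify = FALSE)
  }
  delong <- lapply(pairs, function(p) {
    delong_paired(results[[p[1]]]$heldout$scores,
                  results[[p[2]]]$heldout$scores)
  })
  names(delong) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  structure(list(metrics = metrics, delong = delong,
                 heldout_scores = lapply(results, function(r)
                   r$heldout$scores),
                 plan = results[[1L]]$plan),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  wide <- x$metrics[x$metrics$metric == "roc_auc", ]
  cat("Pipeline comparison (ROC-AUC):\n")
  print(wide, row.names = FALSE)
  for (nm in names(x$delong)) {
    d <- x$delong[[nm]]
    cat(sprintf("  DeLong %s: dAUC = %+.4f, p = %.3g\n", nm,
                d$auc_a - d$auc_b, d$p_value))
  }
  invisible(x)
}

#' Run the full three-pipeline comparison on one cohort
#'
#' All three pipelines share the same patient-level split and the same
#' held-out spots; only the classifier input differs.
#'
#' @param cohort An `msi_cohort`.
#' @param config A `pipeline_config`.
#' @param modes Pipelines to run (default all three).
#' @return A `pipeline_report` with a `results` attribute holding the
#'   individual `pipeline_result` objects.
#' @export
run_experiment <- function(cohort, config = pipeline_config(),
                           modes = c("ims", "microscopy", "multimodal")) {
  plan <- split_patients(cohort$records, config$heldout_fraction,
                         seed = config$seed)
  plan <- assign_outer_folds(plan, config$k_outer)
  inputs <- prepare_inputs(cohort, config, plan, modes = modes)
  results <- lapply(modes, function(m)
    run_pipeline(cohort, m, config, plan = plan, inputs = inputs))
  names(results) <- modes
  report <- compare_pipelines(results)
  attr(report, "results") <- results
  report
}
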