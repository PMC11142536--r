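fake_records <- function(n_patients, labels = NULL, spots = 3) {
  labels <- labels %||% rep(c("melanoma", "nevus"),
                            length.out = n_patients)
  data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(n_patients)), each = spots),
    spot_id = sprintf("S%03d", seq_len(n_patients * spots)),
    label = rep(labels, each = spots),
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("patient splitting meets the rounding and stratification contracts", {
  rec <- fake_records(10)
  plan <- split_patients(rec, heldout_fraction = 0.3, seed = 5)
  expect_length(plan$heldout_patients, 3L)
  expect_length(plan$train_patients, 7L)
  expect_length(intersect(plan$train_patients, plan$heldout_patients), 0L)
  # at least one patient per class on each side
  for (side in list(plan$train_patients, plan$heldout_patients)) {
    expect_setequal(unique(plan$patient_labels[side]),
                    c("melanoma", "nevus"))
  }
  # spots follow their patient wholesale
  expect_true(all(rec$patient_id %in%
                    c(plan$train_patients, plan$heldout_patients)))
  # determinism
  expect_identical(plan, split_patients(rec, 0.3, seed = 5))
  expect_false(identical(plan$heldout_patients,
                         split_patients(rec, 0.3, seed = 6)$heldout_patients))

  expect_error(split_patients(fake_records(3, c("melanoma", "melanoma",
                                                "nevus")), 0.3, 1),
               "2 patients per class")
})

test_that("outer folds partition training patients with balanced strata", {
  rec <- fake_records(21)
  plan <- split_patients(rec, heldout_fraction = 1 / 21, seed = 2)
  plan <- assign_outer_folds(plan, k_outer = 5, seed = 3)
  expect_length(plan$outer_folds, 19L)
  expect_setequal(names(plan$outer_folds), plan$train_patients)
  sizes <- table(plan$outer_folds)
  expect_true(max(sizes) - min(sizes) <= 1)
  # label proportions within one patient of balance in every fold
  for (k in 1:5) {
    in_fold <- names(plan$outer_folds)[plan$outer_folds == k]
    tab <- table(factor(plan$patient_labels[in_fold],
                        levels = c("melanoma", "nevus")))
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
  # 20 training patients with k = 5 gives folds of exactly 4
  plan2 <- split_patients(fake_records(25), 0.2, seed = 1)
  plan2 <- assign_outer_folds(plan2, 5)
  expect_true(all(table(plan2$outer_folds) == 4))

  expect_error(assign_outer_folds(split_patients(fake_records(6), 0.34, 1),
                                  k_outer = 7), "exceeds")
})

test_that("the linear SVM separates what is separable and scores by margin sign", {
  X <- matrix(c(0, 1, 0, 1), 2, 2)
  m <- train_linear_svm(X, c("nevus", "melanoma"), C = 1)
  sc <- decision_score(m, X)
  expect_lt(sc[1], 0)
  expect_gt(sc[2], 0)

  X4 <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y4 <- c("nevus", "nevus", "melanoma", "melanoma")
  m4 <- train_linear_svm(X4, y4, C = 1000)
  expect_equal(sign(decision_score(m4, X4)), c(-1, -1, 1, 1))

  expect_error(train_linear_svm(X4, rep("nevus", 4), 1), "both classes")
})

test_that("the 1-D decision boundary lands between the class extremes", {
  set.seed(12)
  xn <- stats::runif(10, 0, 1)
  xm <- stats::runif(10, 2, 3)
  X <- matrix(c(xn, xm), ncol = 1)
  y <- rep(c("nevus", "melanoma"), each = 10)
  m <- train_linear_svm(X, y, C = 10)
  boundary <- -m$b / m$w   # score zero crossing
  # exhaustive threshold-scan oracle: the max-margin threshold is the one
  # maximizing the distance to the nearest point of either class
  grid <- seq(-1, 4, by = 0.001)
  margin <- vapply(grid, function(t) min(min(xm) - t, t - max(xn)),
                   numeric(1))
  best <- mean(range(grid[margin == max(margin)]))
  expect_gte(boundary, max(xn))
  expect_lte(boundary, min(xm))
  expect_equal(boundary, best, tolerance = 0.01)
})

test_that("grouped inner folds partition patients without class collapse", {
  ids <- sprintf("P%02d", 1:11)
  labels <- stats::setNames(rep(c("melanoma", "nevus"), c(6, 5)), ids)
  asg <- msifuse:::group_kfold(ids, labels, k = 3, seed = 4)
  expect_setequal(names(asg), ids)
  expect_true(all(asg %in% 1:3))
  for (k in 1:3) {
    expect_true(length(unique(labels[names(asg)[asg != k]])) == 2L)
  }
})

test_that("nested CV is perfect on separable data and never mixes patients", {
  set.seed(8)
  rec <- fake_records(15, spots = 4)
  y <- rec$label
  X <- matrix(stats::rnorm(nrow(rec) * 3), ncol = 3)
  X[, 1] <- X[, 1] + ifelse(y == "melanoma", 8, -8)   # separable
  rownames(X) <- rec$spot_id
  plan <- split_patients(rec, 0.2, seed = 8)
  plan <- assign_outer_folds(plan, 3, seed = 8)
  tr <- rec$patient_id %in% plan$train_patients

  seen <- list()
  builder <- function(fit_idx) {
    seen[[length(seen) + 1L]] <<- fit_idx
    Xt <- X[tr, , drop = FALSE]
    scale_block(fit_scaler(Xt, fit_idx), Xt)
  }
  cv <- nested_cv(y[tr], rec$patient_id[tr], plan, grid = c(0.1, 1),
                  k_inner = 2, seed = 8, builder = builder)
  expect_equal(cv$summary$mean[cv$summary$metric == "roc_auc"], 1)
  expect_equal(nrow(cv$folds), 3L)
  expect_true(all(cv$folds$C %in% c(0.1, 1)))

  # grouping contract: the builder's fit rows never include a patient of
  # the corresponding outer fold
  pid_tr <- rec$patient_id[tr]
  for (o in seq_along(seen)) {
    fit_patients <- unique(pid_tr[seen[[o]]])
    fold_patients <- names(plan$outer_folds)[plan$outer_folds == o]
    expect_length(intersect(fit_patients, fold_patients), 0L)
  }

  expect_error(nested_cv(y, rec$patient_id, plan, grid = c(1),
                         k_inner = 2, X = X),
               "non-training")
})

test_that("nested CV without a builder scales on fold-training rows only", {
  set.seed(14)
  rec <- fake_records(12, spots = 3)
  X <- matrix(stats::rnorm(nrow(rec) * 4), ncol = 4)
  X[, 2] <- X[, 2] + ifelse(rec$label == "melanoma", 3, -3)
  rownames(X) <- rec$spot_id
  plan <- split_patients(rec, 0.25, seed = 14)
  plan <- assign_outer_folds(plan, 3, seed = 14)
  tr <- rec$patient_id %in% plan$train_patients
  cv <- nested_cv(rec$label[tr], rec$patient_id[tr], plan,
                  grid = c(0.1, 1), k_inner = 2, seed = 14,
                  X = X[tr, , drop = FALSE])
  expect_s3_class(cv, "cv_result")
  expect_gt(cv$summary$mean[cv$summary$metric == "roc_auc"], 0.9)
  expect_true(all(cv$summary$sd >= 0))
})

test_that("held-out evaluation rejects spots seen during fitting", {
  set.seed(5)
  X <- matrix(stats::rnorm(20), 10, 2)
  m <- train_linear_svm(X, rep(c("nevus", "melanoma"), 5), 1)
  expect_error(
    evaluate_heldout(m, X, rep(c(0, 1), 5), sprintf("S%d", 1:10),
                     train_spot_ids = sprintf("S%d", c(3, 20))),
    "leakage")
  out <- evaluate_heldout(m, X, rep(c(0, 1), 5), sprintf("S%d", 1:10),
                          train_spot_ids = sprintf("T%d", 1:10))
  expect_length(out$scores$scores, 10L)
  expect_named(out$metrics, c("roc_auc", "pr_auc", "f1", "precision",
                              "recall"))
})

test_that("patient-permuted labels drive cross-validated AUC to chance", {
  aucs <- vapply(1:10, function(seed) {
    cfg <- cohort_config(n_patients = 16, spots_per_patient_mean = 5,
                         n_axis_bins = 100, n_signal_peaks = 6,
                         patch_px = 16, seed = seed)
    co <- generate_cohort(cfg)
    rec <- co$records
    # permute labels at the patient level
    pt <- unique(rec[, c("patient_id", "label")])
    set.seed(seed + 1000)
    pt$label <- sample(pt$label)
    rec$label <- pt$label[match(rec$patient_id, pt$patient_id)]
    prep <- preprocess_spectra(co$spectra, co$axis, baseline_window = 21)
    peaks <- detect_peaks(mean_spectrum(prep$spectra))
    pm <- build_peak_matrix(prep$spectra[rec$spot_id], peaks)
    plan <- split_patients(rec, 0.2, seed = seed)
    plan <- assign_outer_folds(plan, 3, seed = seed)
    tr <- rec$patient_id %in% plan$train_patients
    cv <- nested_cv(rec$label[tr], rec$patient_id[tr], plan,
                    grid = c(0.1, 1), k_inner = 2, seed = seed,
                    X = pm[tr, , drop = FALSE])
    cv$summary$mean[cv$summary$metric == "roc_auc"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
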