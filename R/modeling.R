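# Patient-level held-out splitting, patient-grouped nested CV with grid
# search, and the linear SVM shared by all pipelines.

patient_table <- function(records) {
  stopifnot(all(c("patient_id", "label") %in% names(records)))
  agg <- unique(records[, c("patient_id", "label")])
  if (anyDuplicated(agg$patient_id)) {
    stop("a patient carries more than one label", call. = FALSE)
  }
  agg
}

# per-class held-out counts by largest remainder, total fixed, >= 1 and
# <= n_class - 1 per class
allocate_stratified <- function(n_by_class, total) {
  raw <- total * n_by_class / sum(n_by_class)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  pmin(pmax(base, 1L), n_by_class - 1L)
}

#' Split patients into training and held-out sets
#'
#' Stratified by patient label, sampled without replacement; the held-out
#' count is `round(heldout_fraction * n_patients)` with at least one
#' patient per class on each side.  All of a patient's spots follow the
#' patient.
#'
#' @param records Spot-level data.frame with `patient_id` and `label`.
#' @param heldout_fraction Fraction of patients held out, in (0, 1)
#'   (default 0.2).
#' @param seed RNG seed.
#' @return A `split_plan`: list with `train_patients`,
#'   `heldout_patients`, `outer_folds` (empty until
#'   [assign_outer_folds()]) and `seed`.
#' @export
split_patients <- function(records, heldout_fraction = 0.2, seed = 1L) {
  heldout_fraction <- assert_fraction(heldout_fraction, "heldout_fraction",
                                      open = TRUE)
  pt <- patient_table(records)
  n_by_class <- table(pt$label)
  if (any(n_by_class < 2L) || length(n_by_class) < 2L) {
    stop("need at least 2 patients per class to stratify", call. = FALSE)
  }
  total <- round(heldout_fraction * nrow(pt))
  total <- min(max(total, length(n_by_class)), nrow(pt) - length(n_by_class))
  alloc <- allocate_stratified(as.integer(n_by_class), total)
  names(alloc) <- names(n_by_class)
  heldout <- with_seed(seed, {
    unlist(lapply(names(alloc), function(cl) {
      ids <- pt$patient_id[pt$label == cl]
      ids[sample.int(length(ids), alloc[[cl]])]
    }), use.names = FALSE)
  })
  structure(list(train_patients = setdiff(pt$patient_id, heldout),
                 heldout_patients = heldout,
                 outer_folds = integer(0),
                 patient_labels = stats::setNames(pt$label, pt$patient_id),
                 seed = seed),
            class = "split_plan")
}

#' Assign training patients to outer cross-validation folds
#'
#' Label-stratified partition of the training patients into `k_outer`
#' folds; the partition is by patient, never by spot.
#'
#' @param plan A `split_plan` from [split_patients()].
#' @param k_outer Number of outer folds (>= 2).
#' @param seed RNG seed (default: the plan's seed + 1).
#' @return The plan with `outer_folds` filled in (named integer vector,
#'   patient_id -> fold).
#' @export
assign_outer_folds <- function(plan, k_outer = 5, seed = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  k_outer <- assert_count(k_outer, "k_outer", min = 2)
  ids <- plan$train_patients
  if (length(ids) < k_outer) {
    stop("k_outer exceeds the number of training patients", call. = FALSE)
  }
  labels <- plan$patient_labels[ids]
  folds <- with_seed(seed %||% (plan$seed + 1L), {
    out <- integer(length(ids))
    names(out) <- ids
    offset <- 0L
    for (cl in sort(unique(labels))) {
      cl_ids <- sample(ids[labels == cl])
      # round-robin with a rotating offset so class remainders spread out
      out[cl_ids] <- ((seq_along(cl_ids) - 1L + offset) %% k_outer) + 1L
      offset <- offset + length(cl_ids) %% k_outer
    }
    out
  })
  plan$outer_folds <- folds
  plan$k_outer <- k_outer
  plan
}

#' Train a linear support-vector machine
#'
#' Thin wrapper around a linear-kernel C-classification SVM.  The fitted
#' model exposes a real-valued decision score `w . x + b`, oriented so
#' that higher scores mean melanoma.
#'
#' @param X Feature matrix (finite values).
#' @param y Labels: 0/1 or `"nevus"`/`"melanoma"` (1 = melanoma).
#' @param C Regularization parameter (> 0).
#' @return A `linear_svm` with elements `w`, `b`, `C`.
#' @export
train_linear_svm <- function(X, y, C = 1) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  C <- assert_number(C, "C", min = 0, open_min = TRUE)
  s <- score_set(numeric(nrow(X)), y)    # reuse label coercion
  y01 <- s$labels
  if (length(unique(y01)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  fac <- factor(ifelse(y01 == 1L, "melanoma", "nevus"),
                levels = c("melanoma", "nevus"))
  fit <- e1071::svm(x = X, y = fac, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients its decision value toward the first class it encounters
  # in the data; normalize so positive = melanoma.
  first_level <- fit$levels[fit$labels[1]]
  if (first_level != "melanoma") {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, C = C), class = "linear_svm")
}

#' Decision scores of a fitted linear SVM
#'
#' @param model A `linear_svm`.
#' @param X Feature matrix with the same columns used at training.
#' @return Numeric vector `X %*% w + b` (higher = melanoma).
#' @export
decision_score <- function(model, X) {
  stopifnot(inherits(model, "linear_svm"), ncol(X) == length(model$w))
  as.vector(X %*% model$w + model$b)
}

#' Default regularization grid
#' @return `10^(-3:3)`.
#' @export
default_grid <- function() 10^(-3:3)

# stratified grouped partition of patient ids into k folds; deterministic
group_kfold <- function(ids, labels, k, seed) {
  with_seed(seed, {
    out <- integer(length(ids))
    names(out) <- ids
    offset <- 0L
    for (cl in sort(unique(labels))) {
      cl_ids <- sample(ids[labels == cl])
      out[cl_ids] <- ((seq_along(cl_ids) - 1L + offset) %% k) + 1L
      offset <- offset + length(cl_ids) %% k
    }
    out
  })
}

#' Patient-grouped nested cross-validation with grid search
#'
#' For each outer fold, an inner patient-grouped `k_inner`-fold grid
#' search over `grid` selects the `C` maximizing mean inner ROC-AUC (ties
#' broken toward the smallest `C`, i.e. the strongest regularization); a
#' model with the selected `C` is refit on all non-fold data and scored
#' on the fold.  When a `builder` is supplied, the feature matrix itself
#' is refit per outer fold from that fold's training rows (e.g. peak
#' picking and scaling), so no held-out-fold information leaks into
#' feature construction.
#'
#' @param y Spot labels (0/1 or nevus/melanoma).
#' @param patient_ids Patient id per spot.
#' @param plan A `split_plan` with outer folds assigned; only spots of
#'   training patients may be passed.
#' @param grid Vector of candidate `C` values (default [default_grid()]).
#' @param k_inner Inner folds (default 5).
#' @param seed Seed for the inner fold assignments.
#' @param X Feature matrix (used when `builder` is absent; scaling on the
#'   fit rows is then applied internally per fold).
#' @param builder Optional function `(fit_row_idx) -> matrix` returning
#'   features for all rows, fitted using only `fit_row_idx`.
#' @param spot_ids Optional spot ids (default rownames of `X`).
#' @return A `cv_result`: `folds` data.frame (fold, C, n_spots, roc_auc,
#'   pr_auc, f1, precision, recall), `summary` (mean/sd per metric) and
#'   `selected_C` (the modal fold choice, ties toward the smallest).
#' @export
nested_cv <- function(y, patient_ids, plan, grid = default_grid(),
                      k_inner = 5, seed = 1L, X = NULL, builder = NULL,
                      spot_ids = NULL) {
  stopifnot(inherits(plan, "split_plan"), length(plan$outer_folds) > 0)
  k_inner <- assert_count(k_inner, "k_inner", min = 2)
  grid <- sort(as.numeric(grid))
  if (!length(grid) || any(grid <= 0)) {
    stop_field("grid", "must be positive regularization values")
  }
  y01 <- score_set(numeric(length(patient_ids)), y)$labels
  if (is.null(builder)) {
    stopifnot(is.matrix(X), nrow(X) == length(y01))
    builder <- function(fit_idx) {
      scale_block(fit_scaler(X, fit_idx), X)
    }
  }
  if (any(!patient_ids %in% plan$train_patients)) {
    stop("nested_cv received spots of non-training patients", call. = FALSE)
  }
  spot_fold <- plan$outer_folds[patient_ids]
  k_outer <- plan$k_outer
  metrics <- c("roc_auc", "pr_auc", "f1", "precision", "recall")
  fold_rows <- vector("list", k_outer)
  for (o in seq_len(k_outer)) {
    test_idx <- which(spot_fold == o)
    fit_idx <- which(spot_fold != o)
    Xo <- builder(fit_idx)
    fit_patients <- unique(patient_ids[fit_idx])
    fit_labels <- plan$patient_labels[fit_patients]
    inner <- group_kfold(fit_patients, fit_labels, k_inner,
                         seed = seed * 1009L + o)
    # guard: every inner training side must contain both classes; one
    # reshuffle is attempted before giving up
    ok <- function(asg) all(vapply(seq_len(k_inner), function(i) {
      tr <- fit_labels[names(asg)[asg != i]]
      length(unique(tr)) == 2L && length(unique(fit_labels[names(asg)[asg == i]])) >= 1L
    }, logical(1)))
    if (!ok(inner)) {
      inner <- group_kfold(fit_patients, fit_labels, k_inner,
                           seed = seed * 1009L + o + 1L)
      if (!ok(inner)) {
        stop("an inner fold is single-class even after resampling",
             call. = FALSE)
      }
    }
    spot_inner <- inner[patient_ids[fit_idx]]
    mean_auc <- vapply(grid, function(C) {
      aucs <- vapply(seq_len(k_inner), function(i) {
        tr <- fit_idx[spot_inner != i]
        va <- fit_idx[spot_inner == i]
        if (length(unique(y01[va])) < 2L) return(NA_real_)
        m <- train_linear_svm(Xo[tr, , drop = FALSE], y01[tr], C)
        roc_auc(score_set(decision_score(m, Xo[va, , drop = FALSE]),
                          y01[va]))
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best_C <- grid[which.max(mean_auc)]   # ties: first = smallest C
    m <- train_linear_svm(Xo[fit_idx, , drop = FALSE], y01[fit_idx], best_C)
    sc <- score_set(decision_score(m, Xo[test_idx, , drop = FALSE]),
                    y01[test_idx],
                    spot_ids = (spot_ids %||% rownames(Xo))[test_idx])
    sm <- score_metrics(sc)
    fold_rows[[o]] <- data.frame(fold = o, C = best_C,
                                 n_spots = length(test_idx),
                                 roc_auc = sm$roc_auc, pr_auc = sm$pr_auc,
                                 f1 = sm$f1, precision = sm$precision,
                                 recall = sm$recall)
  }
  folds <- do.call(rbind, fold_rows)
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]]), numeric(1)),
    row.names = NULL
  )
  tabC <- table(folds$C)
  modal <- as.numeric(names(tabC)[tabC == max(tabC)])
  structure(list(folds = folds, summary = summ,
                 selected_C = min(modal)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Patient-grouped nested cross-validation\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("selected C (modal across folds): %g\n", x$selected_C))
  invisible(x)
}

#' Score a fitted pipeline on the held-out spots
#'
#' Refuses to score any spot that was seen during fitting: passing a
#' training spot id raises a leakage error.
#'
#' @param model A `linear_svm` fitted on training spots only.
#' @param X Feature matrix of the spots to score.
#' @param y Their labels.
#' @param spot_ids Their spot ids.
#' @param train_spot_ids Spot ids used anywhere during fitting.
#' @param threshold Decision threshold for the point metrics (default 0).
#' @return List with `scores` (a `score_set`) and `metrics`.
#' @export
evaluate_heldout <- function(model, X, y, spot_ids, train_spot_ids,
                             threshold = 0) {
  overlap <- intersect(spot_ids, train_spot_ids)
  if (length(overlap)) {
    stop(sprintf("leakage: spot(s) %s were seen during fitting",
                 paste(utils::head(overlap, 5), collapse = ", ")),
         call. = FALSE)
  }
  sc <- score_set(decision_score(model, X), y, spot_ids = spot_ids)
  list(scores = sc, metrics = score_metrics(sc, threshold))
}
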