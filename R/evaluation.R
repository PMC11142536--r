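# ROC / PR curves and areas, thresholded metrics, and the DeLong test for
# two correlated AUCs measured on the same spots.

#' Bundle decision scores with labels and spot ids
#'
#' @param scores Real-valued decision scores (higher = more melanoma-like).
#' @param labels Class labels: 0/1, logical, or `"nevus"`/`"melanoma"`
#'   (melanoma is the positive class).
#' @param spot_ids Optional identifiers (default `s1..sn`).
#' @return A `score_set`.
#' @export
score_set <- function(scores, labels, spot_ids = NULL) {
  scores <- as.numeric(scores)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("nevus", "melanoma")))
    labels <- as.integer(labels == "melanoma")
  }
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)),
            length(scores) == length(labels), all(is.finite(scores)))
  spot_ids <- spot_ids %||% sprintf("s%d", seq_along(scores))
  stopifnot(length(spot_ids) == length(scores))
  structure(list(scores = scores, labels = labels,
                 spot_ids = as.character(spot_ids)),
            class = "score_set")
}

check_both_classes <- function(s) {
  if (!any(s$labels == 1L) || !any(s$labels == 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
}

#' ROC curve and area
#'
#' The curve is the (FPR, TPR) staircase over all distinct score
#' thresholds; the area (trapezoidal, which under tie-grouping equals the
#' Mann-Whitney pair-counting statistic) is returned alongside.
#'
#' @param s A `score_set` containing both classes.
#' @return List with `fpr`, `tpr`, `thresholds` (distinct scores,
#'   descending, with a leading `Inf`) and `auc`.
#' @export
roc_curve <- function(s) {
  stopifnot(inherits(s, "score_set"))
  check_both_classes(s)
  np <- sum(s$labels == 1L)
  nn <- sum(s$labels == 0L)
  ord <- order(s$scores, decreasing = TRUE)
  sc <- s$scores[ord]
  lb <- s$labels[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lb)
  fp <- cumsum(1L - lb)
  last <- which(!duplicated(grp, fromLast = TRUE))   # last index of each tie group
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, sc[last]), auc = auc)
}

#' Area under the ROC curve
#' @param s A `score_set`.
#' @return The ROC-AUC in [0, 1].
#' @export
roc_auc <- function(s) roc_curve(s)$auc

#' Precision-recall curve and area
#'
#' Staircase over distinct thresholds (descending), anchored at
#' (recall 0, precision 1); area by the trapezoidal rule.
#'
#' @param s A `score_set` containing both classes.
#' @return List with `recall`, `precision`, `thresholds` and `auc`.
#' @export
pr_curve <- function(s) {
  stopifnot(inherits(s, "score_set"))
  check_both_classes(s)
  np <- sum(s$labels == 1L)
  ord <- order(s$scores, decreasing = TRUE)
  sc <- s$scores[ord]
  lb <- s$labels[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lb)
  pred <- seq_along(lb)
  last <- which(!duplicated(grp, fromLast = TRUE))
  recall <- c(0, tp[last] / np)
  precision <- c(1, tp[last] / pred[last])
  auc <- sum(diff(recall) *
               (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
  list(recall = recall, precision = precision,
       thresholds = c(Inf, sc[last]), auc = auc)
}

#' Area under the precision-recall curve
#' @param s A `score_set`.
#' @return The PR-AUC in [0, 1].
#' @export
pr_auc <- function(s) pr_curve(s)$auc

#' Precision, recall and F1 at a fixed decision threshold
#'
#' A spot is predicted melanoma when `score >= threshold`.  With zero
#' predicted positives, precision is reported as 0 with a warning; F1 is 0
#' whenever precision + recall is 0.
#'
#' @param s A `score_set`.
#' @param threshold Decision threshold (default 0, the SVM margin).
#' @return Named list `precision`, `recall`, `f1`.
#' @export
thresholded_metrics <- function(s, threshold = 0) {
  stopifnot(inherits(s, "score_set"))
  pred <- s$scores >= threshold
  tp <- sum(pred & s$labels == 1L)
  fp <- sum(pred & s$labels == 0L)
  fn <- sum(!pred & s$labels == 1L)
  if (tp + fp == 0L) {
    warning("no predicted positives at this threshold; precision set to 0",
            call. = FALSE)
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# midranks of x (average ranks for ties), the workhorse of fast DeLong
midranks <- function(x) rank(x, ties.method = "average")

# structural components of one modality: list(auc, v10 (per positive),
# v01 (per negative))
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  rall <- midranks(c(pos, neg))
  rpos <- midranks(pos)
  rneg <- midranks(neg)
  v10 <- (rall[seq_len(m)] - rpos) / n
  v01 <- 1 - (rall[m + seq_len(n)] - rneg) / m
  auc <- (sum(rall[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score sets measured on the same spots (paired
#' design) using the structural-components (midrank) formulation; the
#' variance of the AUC difference accounts for the correlation between
#' the two score vectors.  Two-sided normal p-value; no flooring is
#' applied, so very small p-values are reported as computed.
#'
#' @param a,b `score_set` objects with identical `labels` and `spot_ids`.
#' @return A `delong_result`: list with `auc_a`, `auc_b`, `var_diff`, `z`
#'   and `p_value`.
#' @export
delong_paired <- function(a, b) {
  stopifnot(inherits(a, "score_set"), inherits(b, "score_set"))
  if (!identical(a$spot_ids, b$spot_ids) || !identical(a$labels, b$labels)) {
    stop("score sets are not paired (labels/spot_ids differ)", call. = FALSE)
  }
  check_both_classes(a)
  ca <- delong_components(a$scores, a$labels)
  cb <- delong_components(b$scores, b$labels)
  m <- length(ca$v10)
  n <- length(ca$v01)
  s10 <- stats::var(ca$v10 - cb$v10)
  s01 <- stats::var(ca$v01 - cb$v01)
  var_diff <- s10 / m + s01 / n
  dauc <- ca$auc - cb$auc
  if (var_diff <= 0) {
    if (abs(dauc) > 1e-12) {
      stop("degenerate DeLong variance with unequal AUCs", call. = FALSE)
    }
    z <- 0
    p <- 1
  } else {
    z <- dauc / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff,
                 z = z, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong test: AUC_a = %.4f, AUC_b = %.4f, z = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

#' All spot-level metrics of one score set
#'
#' @param s A `score_set`.
#' @param threshold Threshold for the point metrics (default 0).
#' @return Named list `roc_auc`, `pr_auc`, `f1`, `precision`, `recall`.
#' @export
score_metrics <- function(s, threshold = 0) {
  tm <- thresholded_metrics(s, threshold)
  list(roc_auc = roc_auc(s), pr_auc = pr_auc(s),
       f1 = tm$f1, precision = tm$precision, recall = tm$recall)
}
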