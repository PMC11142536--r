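# Block standardization on training statistics, then weighted
# concatenation of the IMS and morphology feature blocks.

#' Fit a per-feature scaler on training rows only
#'
#' Means and (population) standard deviations are computed exclusively
#' over the rows flagged as training; zero-variance features are masked
#' and transformed to 0.
#'
#' @param block Numeric matrix (spots x features).
#' @param train_rows Integer/logical index or rownames of the training
#'   rows (>= 2 rows).
#' @return A `block_scaler` with `means`, `sds` and the logical `mask` of
#'   retained (non-constant) features.
#' @export
fit_scaler <- function(block, train_rows) {
  stopifnot(is.matrix(block))
  tr <- block[train_rows, , drop = FALSE]
  if (nrow(tr) < 2L) stop("need at least 2 training rows", call. = FALSE)
  means <- colMeans(tr)
  sds <- sqrt(colMeans(sweep(tr, 2, means)^2))
  mask <- sds > 0
  structure(list(means = means, sds = sds, mask = mask,
                 n_train = nrow(tr)),
            class = "block_scaler")
}

#' Apply a fitted scaler to a feature block
#'
#' @param scaler A `block_scaler` from [fit_scaler()].
#' @param block Matrix with the same columns the scaler was fitted on.
#' @return The standardized matrix; masked (zero-variance) columns are 0.
#' @export
scale_block <- function(scaler, block) {
  stopifnot(inherits(scaler, "block_scaler"),
            ncol(block) == length(scaler$means))
  out <- sweep(block, 2, scaler$means)
  sds <- ifelse(scaler$mask, scaler$sds, 1)
  out <- sweep(out, 2, sds, "/")
  if (any(!scaler$mask)) out[, !scaler$mask] <- 0
  out
}

#' Fuse two standardized feature blocks by weighted concatenation
#'
#' Output is `[w_ims * ims_block | w_morph * morph_block]`; with the
#' default weights (1, 1) this is the plain equal-weight concatenation, so
#' a 5558-peak IMS block and a 512-dimensional morphology block fuse into
#' 6070 columns.
#'
#' @param ims_block,morph_block Row-aligned standardized matrices with
#'   identical rownames (spot ids).
#' @param weights Numeric length-2 vector `(w_ims, w_morph)`,
#'   default `c(1, 1)`.
#' @return A `fused_matrix`: numeric matrix with a `provenance` attribute
#'   (`"ims"`/`"morph"` per column).
#' @export
fuse <- function(ims_block, morph_block, weights = c(1, 1)) {
  stopifnot(is.matrix(ims_block), is.matrix(morph_block),
            length(weights) == 2L, all(is.finite(weights)))
  if (nrow(ims_block) != nrow(morph_block) ||
      !identical(rownames(ims_block), rownames(morph_block))) {
    bad <- union(setdiff(rownames(ims_block), rownames(morph_block)),
                 setdiff(rownames(morph_block), rownames(ims_block)))
    stop(sprintf("blocks are not row-aligned by spot_id (offending: %s)",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out <- cbind(weights[1] * ims_block, weights[2] * morph_block)
  attr(out, "provenance") <- c(rep("ims", ncol(ims_block)),
                               rep("morph", ncol(morph_block)))
  class(out) <- c("fused_matrix", class(out))
  out
}

#' Recover one modality's (weighted) columns from a fused matrix
#'
#' @param fused A `fused_matrix`.
#' @param which `"ims"` or `"morph"`.
#' @return The weighted sub-block.
#' @export
fused_slice <- function(fused, which = c("ims", "morph")) {
  which <- match.arg(which)
  prov <- attr(fused, "provenance")
  stopifnot(!is.null(prov))
  out <- fused[, prov == which, drop = FALSE]
  attr(out, "provenance") <- NULL
  class(out) <- "matrix"
  unclass(out)[, , drop = FALSE]
}
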