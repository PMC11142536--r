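# Patch -> fixed-length morphology vector.  The encoder is a pluggable
# interface: any function (tensor, spec) -> numeric vector of length
# `embed_dim` can stand behind it (e.g. an adapter around an external
# pre-trained network); the package ships a deterministic hand-crafted
# texture encoder as the default so the pipeline is testable offline.

#' Embedder configuration
#'
#' @param name Encoder name (default `"texture"`, the built-in).
#' @param embed_dim Output dimensionality (default 512).
#' @param input_side Side of the resized input tensor in pixels
#'   (default 224).
#' @param channel_means,channel_sds Per-channel normalization constants
#'   applied after scaling pixels to [0, 1] (defaults 0.5 / 0.5 per
#'   channel).
#' @param seed Seed of the fixed random projection used by the built-in
#'   encoder.
#' @return An `embedder_spec` object.
#' @export
embedder_spec <- function(name = "texture", embed_dim = 512,
                          input_side = 224,
                          channel_means = rep(0.5, 3),
                          channel_sds = rep(0.5, 3),
                          seed = 1L) {
  stopifnot(length(channel_means) == 3L, length(channel_sds) == 3L,
            all(channel_sds > 0))
  structure(list(name = name,
                 embed_dim = assert_count(embed_dim, "embed_dim"),
                 input_side = assert_count(input_side, "input_side", min = 8),
                 channel_means = as.numeric(channel_means),
                 channel_sds = as.numeric(channel_sds),
                 seed = assert_count(seed, "seed", min = 0)),
            class = "embedder_spec")
}

#' Extract a square patch of fixed physical size from an image
#'
#' The patch side in pixels is `round(physical_side / pixel_size)`; the
#' patch is the half-open square of that side centered at `center_xy`
#' (0-based, center floored onto the pixel grid).  At 0.5 um/px (20x) a
#' 48 um spot gives a 96 px patch; at 0.25 um/px (40x), 192 px.
#'
#' @param image Numeric or integer array H x W x 3 with values in
#'   [0, 255].
#' @param center_xy Length-2 vector (x, y) of 0-based pixel coordinates.
#' @param physical_side Patch side in microns (default 48).
#' @param pixel_size Microns per pixel.
#' @param spot_id Optional identifier (used in error messages).
#' @return An `he_patch`.
#' @export
extract_patch <- function(image, center_xy, physical_side = 48, pixel_size,
                          spot_id = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            length(center_xy) == 2L)
  side <- round(physical_side / pixel_size)
  if (side < 1) stop_field("physical_side", "patch collapses to < 1 px")
  cx <- floor(center_xy[1])
  cy <- floor(center_xy[2])
  x0 <- cx - side %/% 2          # 0-based first column
  y0 <- cy - side %/% 2
  H <- dim(image)[1]
  W <- dim(image)[2]
  if (x0 < 0 || y0 < 0 || x0 + side > W || y0 + side > H) {
    stop(sprintf("patch for spot %s crosses the image boundary",
                 spot_id %||% "<unnamed>"), call. = FALSE)
  }
  px <- image[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side), , drop = FALSE]
  structure(array(as.integer(round(px)), dim = dim(px)),
            class = "he_patch", pixel_size = pixel_size, spot_id = spot_id)
}

#' Resize and normalize a patch into the encoder's input tensor
#'
#' Bilinear resize to `input_side`, then each channel is mapped to
#' `(value / 255 - channel_mean) / channel_sd`.
#'
#' @param patch A square `he_patch`.
#' @param spec An `embedder_spec`.
#' @return Real-valued array `input_side x input_side x 3`.
#' @export
preprocess_patch <- function(patch, spec = embedder_spec()) {
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L) stop_field("patch", "must be H x W x 3")
  if (d[1] != d[2]) stop_field("patch", "must be square")
  x <- unclass(patch) / 255
  if (d[1] != spec$input_side) {
    x <- EBImage::resize(EBImage::Image(x, colormode = "Color"),
                         w = spec$input_side, h = spec$input_side)
    x <- EBImage::imageData(x)
  }
  for (c in 1:3) {
    x[, , c] <- (x[, , c] - spec$channel_means[c]) / spec$channel_sds[c]
  }
  if (any(!is.finite(x))) stop("non-finite values after normalization",
                               call. = FALSE)
  x
}

# Fixed Gaussian random projection, memoized: it depends only on
# (embed_dim, n_features, seed), and recomputing it per patch would
# dominate the embedding cost.
.proj_cache <- new.env(parent = emptyenv())
projection_matrix <- function(embed_dim, n_features, seed) {
  key <- sprintf("%d_%d_%d", embed_dim, n_features, seed)
  if (is.null(.proj_cache[[key]])) {
    .proj_cache[[key]] <- with_seed(seed, {
      matrix(stats::rnorm(embed_dim * n_features) / sqrt(n_features),
             embed_dim, n_features)
    })
  }
  .proj_cache[[key]]
}

# histogram proportions over fixed breaks (first/last bin open-ended)
hist_props <- function(v, breaks) {
  cuts <- findInterval(v, breaks, all.inside = TRUE)
  tabulate(cuts, nbins = length(breaks) - 1L) / length(v)
}

#' Deterministic texture encoder
#'
#' A desk-scale morphology descriptor: per-channel intensity histograms,
#' gradient-magnitude histograms, multi-scale local mean/variance
#' summaries and global moments, projected to `embed_dim` through a fixed
#' Gaussian random projection seeded by `spec$seed`, then normalized to
#' unit length.  A constant input maps to the unit vector
#' `(1, 0, ..., 0)`.
#'
#' @param tensor Preprocessed tensor from [preprocess_patch()].
#' @param spec An `embedder_spec`.
#' @return Numeric vector of length `spec$embed_dim` with unit norm.
#' @export
texture_encoder <- function(tensor, spec = embedder_spec()) {
  d <- dim(tensor)
  if (max(tensor) - min(tensor) < 1e-12) {
    out <- numeric(spec$embed_dim)
    out[1L] <- 1
    return(out)
  }
  feats <- c()
  ibreaks <- seq(-2.5, 2.5, length.out = 17)
  gbreaks <- c(seq(0, 0.6, length.out = 12), Inf)
  for (c in 1:3) {
    ch <- tensor[, , c]
    feats <- c(feats, hist_props(as.vector(ch), ibreaks))
    gx <- ch[, -1] - ch[, -ncol(ch)]
    gy <- ch[-1, ] - ch[-nrow(ch), ]
    gm <- sqrt(gx[-nrow(gx), ]^2 + gy[, -ncol(gy)]^2)
    feats <- c(feats, hist_props(as.vector(gm), gbreaks))
    # multi-scale block statistics: grids of 4x4, 8x8, 16x16 blocks
    for (g in c(4L, 8L, 16L)) {
      idx <- split(seq_len(nrow(ch)),
                   cut(seq_len(nrow(ch)), g, labels = FALSE))
      bm <- matrix(0, g, g)
      bv <- matrix(0, g, g)
      for (i in seq_len(g)) for (j in seq_len(g)) {
        blk <- ch[idx[[i]], idx[[j]]]
        m1 <- mean(blk)
        bm[i, j] <- m1
        bv[i, j] <- mean(blk * blk) - m1 * m1
      }
      feats <- c(feats, mean(bv), stats::sd(as.vector(bv)),
                 stats::sd(as.vector(bm)))
    }
    feats <- c(feats, mean(ch), stats::sd(as.vector(ch)))
  }
  proj <- projection_matrix(spec$embed_dim, length(feats), spec$seed)
  v <- as.vector(proj %*% feats)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) {
    out <- numeric(spec$embed_dim)
    out[1L] <- 1
    return(out)
  }
  v / nrm
}

#' Embed one patch through an encoder
#'
#' @param patch An `he_patch`.
#' @param spec An `embedder_spec`.
#' @param encoder Function `(tensor, spec) -> numeric(embed_dim)`;
#'   defaults to [texture_encoder()].
#' @return Numeric vector of length `spec$embed_dim`.
#' @export
embed_patch <- function(patch, spec = embedder_spec(),
                        encoder = texture_encoder) {
  v <- encoder(preprocess_patch(patch, spec), spec)
  if (!is.numeric(v) || length(v) != spec$embed_dim || any(!is.finite(v))) {
    stop(sprintf(
      "encoder violated its interface: expected a finite numeric vector of length %d",
      spec$embed_dim), call. = FALSE)
  }
  as.numeric(v)
}

#' Embed a list of patches into a spots-by-dimensions matrix
#'
#' @param patches Named list of `he_patch` objects (names = spot ids).
#' @param spec An `embedder_spec`.
#' @param encoder Encoder function, as in [embed_patch()].
#' @return Numeric matrix with one row per patch (rownames = spot ids) and
#'   `spec$embed_dim` columns.
#' @export
embed_patches <- function(patches, spec = embedder_spec(),
                          encoder = texture_encoder) {
  stopifnot(length(patches) >= 1L)
  out <- t(vapply(patches, function(p) embed_patch(p, spec, encoder),
                  numeric(spec$embed_dim)))
  rownames(out) <- unname(names(patches) %||%
    vapply(patches, function(p) as.character(attr(p, "spot_id") %||% ""),
           character(1)))
  colnames(out) <- sprintf("emb_%03d", seq_len(spec$embed_dim))
  out
}
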