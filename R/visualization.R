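# Low-dimensional projection of feature blocks, hyperspectral RGB mapping
# of 3-D coordinates, and rendering of colored spot maps.

#' Projection configuration
#'
#' @param n_components 2 or 3.
#' @param metric Distance metric: `"cosine"` (default) or `"euclidean"`.
#' @param n_neighbors Neighborhood size (default 15); inputs with fewer
#'   rows are rejected with guidance.
#' @param min_dist Minimum embedding distance, used by the `umap` backend
#'   (default 0.1).
#' @param seed Seed recorded with the projection.
#' @return A `projection_spec`.
#' @export
projection_spec <- function(n_components = 2, metric = c("cosine",
                                                         "euclidean"),
                            n_neighbors = 15, min_dist = 0.1, seed = 1L) {
  n_components <- assert_count(n_components, "n_components", min = 2)
  if (!n_components %in% c(2L, 3L)) {
    stop_field("n_components", "must be 2 or 3")
  }
  structure(list(n_components = n_components, metric = match.arg(metric),
                 n_neighbors = assert_count(n_neighbors, "n_neighbors",
                                            min = 2),
                 min_dist = assert_number(min_dist, "min_dist", min = 0),
                 seed = assert_count(seed, "seed", min = 0)),
            class = "projection_spec")
}

cosine_dist <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  xn <- x / nrm
  d <- 1 - tcrossprod(xn)
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Project a feature block to 2 or 3 dimensions
#'
#' The default backend is principal-coordinates analysis (classical
#' multidimensional scaling) of the chosen distance — deterministic,
#' dependency-free and adequate for cluster-structure inspection.  The
#' `"umap"` backend shells out to a Python `umap-learn` installation when
#' one is available and follows `spec` (cosine metric, `n_neighbors`,
#' `min_dist`, fixed random state).
#'
#' @param features Numeric matrix with at least 10 rows.
#' @param spec A `projection_spec`.
#' @param method `"pcoa"` (default) or `"umap"`.
#' @param python Python executable for the `"umap"` backend.
#' @return Coordinate matrix (rows x `n_components`), rownames preserved.
#' @export
project <- function(features, spec = projection_spec(),
                    method = c("pcoa", "umap"), python = "python") {
  method <- match.arg(method)
  stopifnot(is.matrix(features), all(is.finite(features)))
  if (nrow(features) < 10L) {
    stop("projection needs at least 10 rows", call. = FALSE)
  }
  if (nrow(features) <= spec$n_neighbors) {
    stop(sprintf(
      "fewer rows (%d) than the neighborhood size (%d); lower `n_neighbors` in the projection_spec",
      nrow(features), spec$n_neighbors), call. = FALSE)
  }
  if (method == "pcoa") {
    d <- if (spec$metric == "cosine") cosine_dist(features) else
      stats::dist(features)
    coords <- stats::cmdscale(d, k = spec$n_components)
    # canonical sign: make each axis positively correlated with its
    # largest-magnitude loading so the output is reproducible
    for (j in seq_len(ncol(coords))) {
      i <- which.max(abs(coords[, j]))
      if (coords[i, j] < 0) coords[, j] <- -coords[, j]
    }
  } else {
    coords <- project_umap_python(features, spec, python)
  }
  rownames(coords) <- rownames(features)
  colnames(coords) <- sprintf("dim%d", seq_len(ncol(coords)))
  coords
}

# UMAP via an external Python interpreter with umap-learn installed.
project_umap_python <- function(features, spec, python = "python") {
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  utils::write.table(features, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy, umap; X = numpy.loadtxt(%s, delimiter=',');",
    "E = umap.UMAP(n_components=%d, metric='%s', n_neighbors=%d,",
    " min_dist=%g, random_state=%d).fit_transform(X);",
    "numpy.savetxt(%s, E, delimiter=',')"),
    deparse(infile), spec$n_components, spec$metric, spec$n_neighbors,
    spec$min_dist, spec$seed, deparse(outfile))
  status <- system2(python, c("-c", shQuote(code)), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0 || !file.exists(outfile)) {
    stop("the umap backend requires a Python interpreter with umap-learn",
         call. = FALSE)
  }
  as.matrix(utils::read.table(outfile, sep = ","))
}

#' Map 3-D coordinates to RGB colors ("hyperspectral" scheme)
#'
#' Each coordinate column is clipped to its `[low, high]` percentiles,
#' min-max scaled to [0, 255] and rounded; columns map to (R, G, B) in
#' order.  A constant column is set to 128 with a warning.
#'
#' @param coords3 Numeric matrix with exactly 3 columns.
#' @param clip_percentiles Length-2 percentile pair (default `c(1, 99)`).
#' @return Integer matrix (rows x 3) of RGB values in [0, 255].
#' @export
hyperspectral_rgb <- function(coords3, clip_percentiles = c(1, 99)) {
  stopifnot(is.matrix(coords3), ncol(coords3) == 3L,
            length(clip_percentiles) == 2L)
  out <- matrix(0L, nrow(coords3), 3L,
                dimnames = list(rownames(coords3), c("R", "G", "B")))
  for (j in 1:3) {
    v <- coords3[, j]
    q <- stats::quantile(v, clip_percentiles / 100, names = FALSE)
    v <- pmin(pmax(v, q[1]), q[2])
    if (q[2] - q[1] <= 0) {
      warning(sprintf("coordinate column %d is constant; channel set to 128",
                      j), call. = FALSE)
      out[, j] <- 128L
    } else {
      out[, j] <- as.integer(round(255 * (v - q[1]) / (q[2] - q[1])))
    }
  }
  out
}

#' Render colored spots at their slide positions
#'
#' Draws each spot as a filled disc of its RGB color on a white canvas
#' covering the bounding box of the spot centers, and writes the canvas
#' as a PNG.  Spots without coordinates are skipped with a logged count.
#'
#' @param records Data.frame with `spot_id`, `center_x`, `center_y`.
#' @param colors Integer matrix (spots x 3) of RGB values in [0, 255],
#'   row order matching `records`.
#' @param path Output PNG path.
#' @param radius Disc radius in canvas pixels (default 4).
#' @param margin Margin around the bounding box in pixels (default 10).
#' @return Invisibly, a list with the `path` and the canvas `dim`.
#' @export
render_spot_map <- function(records, colors, path, radius = 4,
                            margin = 10) {
  stopifnot(nrow(records) == nrow(colors), ncol(colors) == 3L)
  has_xy <- is.finite(records$center_x) & is.finite(records$center_y)
  if (sum(!has_xy) > 0) {
    warning(sprintf("%d spot(s) lack coordinates and were skipped",
                    sum(!has_xy)), call. = FALSE)
  }
  if (!any(has_xy)) {
    canvas <- array(1, dim = c(2L * margin, 2L * margin, 3L))
    png::writePNG(canvas, path)
    return(invisible(list(path = path, dim = dim(canvas))))
  }
  x <- records$center_x[has_xy]
  y <- records$center_y[has_xy]
  cols <- colors[has_xy, , drop = FALSE]
  px <- round(x - min(x)) + margin + 1L
  py <- round(y - min(y)) + margin + 1L
  W <- max(px) + margin
  H <- max(py) + margin
  canvas <- array(1, dim = c(H, W, 3L))
  disc <- which(outer(seq(-radius, radius)^2,
                      seq(-radius, radius)^2, "+") <= radius^2,
                arr.ind = TRUE) - radius - 1L
  for (i in seq_along(px)) {
    rows <- py[i] + disc[, 1]
    colsx <- px[i] + disc[, 2]
    keep <- rows >= 1 & rows <= H & colsx >= 1 & colsx <= W
    for (c in 1:3) {
      canvas[cbind(rows[keep], colsx[keep], c)] <- cols[i, c] / 255
    }
  }
  png::writePNG(canvas, path)
  invisible(list(path = path, dim = dim(canvas)))
}
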