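#' Construct a profile mass spectrum
#'
#' A spectrum holds one spot's profile trace: an m/z axis (Da, strictly
#' increasing) and non-negative intensities of the same length.
#'
#' @param mz Numeric vector of m/z values in Daltons, strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param spot_id Optional spot identifier carried through preprocessing.
#' @return An object of class `ims_spectrum`: a list with elements `mz`,
#'   `intensity` and `spot_id`.
#' @export
ims_spectrum <- function(mz, intensity, spot_id = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) < 2L) stop_field("mz", "needs at least 2 points")
  if (length(mz) != length(intensity)) {
    stop_field("intensity", "must have the same length as `mz`")
  }
  if (any(diff(mz) <= 0)) stop_field("mz", "must be strictly increasing")
  if (any(!is.finite(intensity))) {
    stop_field("intensity", "must be finite")
  }
  structure(list(mz = mz, intensity = intensity, spot_id = spot_id),
            class = "ims_spectrum")
}

#' @export
print.ims_spectrum <- function(x, ...) {
  cat(sprintf("<ims_spectrum%s: %d points, m/z %.1f-%.1f, TIC %.4g>\n",
              if (is.null(x$spot_id)) "" else paste0(" ", x$spot_id),
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Define a common m/z axis
#'
#' The axis is the uniform grid every spectrum is resampled onto before any
#' further preprocessing; bin centers span `[mz_min, mz_max]` inclusive.
#'
#' @param mz_min,mz_max Axis range in Daltons (defaults 700 and 3500, the
#'   tryptic-peptide window of the acquisition).
#' @param n_bins Number of bin centers (>= 2).
#' @return An `axis_spec` object with elements `mz_min`, `mz_max`, `n_bins`,
#'   `centers` and `bin_width`.
#' @export
axis_spec <- function(mz_min = 700, mz_max = 3500, n_bins) {
  mz_min <- assert_number(mz_min, "mz_min")
  mz_max <- assert_number(mz_max, "mz_max")
  if (mz_min >= mz_max) stop_field("mz_min", "must be < mz_max")
  n_bins <- assert_count(n_bins, "n_bins", min = 2)
  centers <- seq(mz_min, mz_max, length.out = n_bins)
  structure(list(mz_min = mz_min, mz_max = mz_max, n_bins = n_bins,
                 centers = centers,
                 bin_width = (mz_max - mz_min) / (n_bins - 1)),
            class = "axis_spec")
}

#' Define a peak list
#'
#' Picked peak centers plus the half-width (in bins) of the integration
#' window used when assembling the peak matrix.
#'
#' @param centers Peak centers in Daltons, strictly increasing.
#' @param window_halfwidth Integration half-width in bins (>= 0).
#' @param axis The `axis_spec` the centers live on; centers outside the axis
#'   range are an error here, not later.
#' @return A `peak_list` object.
#' @export
peak_list <- function(centers, window_halfwidth = 1, axis = NULL) {
  centers <- as.numeric(centers)
  if (length(centers) && any(diff(centers) <= 0)) {
    stop_field("centers", "must be strictly increasing")
  }
  window_halfwidth <- assert_count(window_halfwidth, "window_halfwidth",
                                   min = 0)
  if (!is.null(axis)) {
    stopifnot(inherits(axis, "axis_spec"))
    if (length(centers) &&
        (min(centers) < axis$mz_min || max(centers) > axis$mz_max)) {
      stop_field("centers", "must lie within the axis range")
    }
  }
  structure(list(centers = centers, window_halfwidth = window_halfwidth),
            class = "peak_list")
}

#' Mean spectrum of a set of spectra on a common axis
#'
#' @param spectra List of `ims_spectrum` objects sharing one m/z axis.
#' @return An `ims_spectrum` whose intensity is the pointwise mean.
#' @export
mean_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  mz <- spectra[[1L]]$mz
  for (s in spectra) {
    if (length(s$mz) != length(mz) || any(s$mz != mz)) {
      stop("all spectra must share one common m/z axis", call. = FALSE)
    }
  }
  acc <- rowMeans(vapply(spectra, function(s) s$intensity,
                         numeric(length(mz))))
  ims_spectrum(mz, acc, spot_id = "mean")
}
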