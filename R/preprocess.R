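# IMS preprocessing: resample -> baseline -> TIC -> realign -> peak picking
# -> peak matrix.  Each step is a named function so any one of them can be
# swapped without touching the orchestration.

#' Resample a spectrum onto a common m/z axis
#'
#' Linear interpolation at the axis bin centers; bins outside the support of
#' the input spectrum are set to 0.
#'
#' @param spectrum An `ims_spectrum`.
#' @param axis An `axis_spec`.
#' @return An `ims_spectrum` sampled exactly at `axis$centers`.
#' @export
resample_to_axis <- function(spectrum, axis) {
  stopifnot(inherits(spectrum, "ims_spectrum"), inherits(axis, "axis_spec"))
  if (max(spectrum$mz) < axis$mz_min || min(spectrum$mz) > axis$mz_max) {
    stop(sprintf("spectrum %s does not overlap the axis [%g, %g]",
                 spectrum$spot_id %||% "<unnamed>", axis$mz_min, axis$mz_max),
         call. = FALSE)
  }
  y <- stats::approx(spectrum$mz, spectrum$intensity, xout = axis$centers,
                     method = "linear", yleft = 0, yright = 0)$y
  ims_spectrum(axis$centers, y, spot_id = spectrum$spot_id)
}

# Rolling minimum over a centered window of `window` bins; out-of-range
# positions do not contribute (edges take the min over what is available).
rolling_min <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (k in seq_len(h)) {
    out <- pmin(out,
                c(x[-seq_len(k)], rep(Inf, k)),        # lead by k
                c(rep(Inf, k), x[seq_len(n - k)]))     # lag by k
  }
  out
}

# Rolling mean over a centered window, edges averaged over available bins.
rolling_mean <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  acc <- x
  cnt <- rep(1, n)
  for (k in seq_len(h)) {
    acc <- acc + c(x[-seq_len(k)], rep(0, k)) + c(rep(0, k), x[seq_len(n - k)])
    cnt <- cnt + c(rep(1, n - k), rep(0, k)) + c(rep(0, k), rep(1, n - k))
  }
  acc / cnt
}

#' Subtract a rolling-minimum baseline
#'
#' The baseline estimate is a rolling minimum over `window` bins followed by
#' a rolling mean over the same window (a simple morphological-opening
#' analogue); the result is clamped at zero.
#'
#' @param spectrum An `ims_spectrum` on a common axis.
#' @param window Odd window width in bins, `1 <= window <= length(spectrum)`.
#' @return Baseline-subtracted `ims_spectrum` (non-negative).
#' @export
subtract_baseline <- function(spectrum, window = 51) {
  stopifnot(inherits(spectrum, "ims_spectrum"))
  window <- assert_count(window, "window", min = 1)
  if (window %% 2L == 0L) stop_field("window", "must be odd")
  n <- length(spectrum$intensity)
  if (window > n) stop_field("window", "must not exceed the spectrum length")
  baseline <- rolling_mean(rolling_min(spectrum$intensity, window), window)
  ims_spectrum(spectrum$mz, pmax(spectrum$intensity - baseline, 0),
               spot_id = spectrum$spot_id)
}

#' Total-ion-current normalization
#'
#' Scales a spectrum so that its intensity sum equals `target_sum`.
#'
#' @param spectrum An `ims_spectrum` with a positive intensity sum.
#' @param target_sum Positive target for the total ion current (default 1).
#' @return Normalized `ims_spectrum`.
#' @export
tic_normalize <- function(spectrum, target_sum = 1) {
  stopifnot(inherits(spectrum, "ims_spectrum"))
  target_sum <- assert_number(target_sum, "target_sum", min = 0,
                              open_min = TRUE)
  tic <- sum(spectrum$intensity)
  if (tic <= 0) {
    stop(sprintf("spot %s has zero total ion current",
                 spectrum$spot_id %||% "<unnamed>"), call. = FALSE)
  }
  ims_spectrum(spectrum$mz, spectrum$intensity * (target_sum / tic),
               spot_id = spectrum$spot_id)
}

#' Realign a spectrum against a reference by an integer bin shift
#'
#' Scans integer lags in `[-max_shift, max_shift]`, picks the lag maximizing
#' the cross-correlation with the reference (ties broken toward lag 0) and
#' undoes it; bins vacated by the shift are set to 0.
#'
#' @param spectrum,reference `ims_spectrum` objects on the same axis.
#' @param max_shift Maximum absolute lag in bins (>= 0).
#' @return A list with the realigned `spectrum` and the detected integer
#'   `shift` (positive = the input was shifted towards higher m/z).
#' @export
realign_spectrum <- function(spectrum, reference, max_shift = 5) {
  stopifnot(inherits(spectrum, "ims_spectrum"),
            inherits(reference, "ims_spectrum"))
  if (length(spectrum$mz) != length(reference$mz) ||
      any(spectrum$mz != reference$mz)) {
    stop("spectrum and reference must share one axis", call. = FALSE)
  }
  max_shift <- assert_count(max_shift, "max_shift", min = 0)
  x <- spectrum$intensity
  r <- reference$intensity
  n <- length(x)
  lags <- seq(-max_shift, max_shift)
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(x[seq_len(n - l) + l] * r[seq_len(n - l)])
    else        sum(x[seq_len(n + l)] * r[seq_len(n + l) - l])
  }, numeric(1))
  # ties toward lag 0: order candidates by |lag| then lag, take first argmax
  ord <- order(abs(lags), lags)
  best <- ord[which.max(cc[ord])]
  shift <- lags[best]
  if (max_shift > 0 && abs(shift) == max_shift) {
    warning(sprintf("spot %s: best lag %d is at the search boundary",
                    spectrum$spot_id %||% "<unnamed>", shift), call. = FALSE)
  }
  out <- numeric(n)
  if (shift >= 0) out[seq_len(n - shift)] <- x[seq_len(n - shift) + shift]
  else            out[seq_len(n + shift) - shift] <- x[seq_len(n + shift)]
  list(spectrum = ims_spectrum(spectrum$mz, out, spot_id = spectrum$spot_id),
       shift = shift)
}

#' Pick peaks from a mean spectrum by local maxima above an SNR threshold
#'
#' Peaks are strict local maxima (greater than both neighbors, endpoints
#' excluded) with height `>= snr_min * noise`, where the noise level is the
#' scaled median absolute deviation of the first difference of the
#' intensities divided by `sqrt(2)`.
#'
#' @param mean_spectrum A preprocessed (baseline-subtracted, normalized)
#'   `ims_spectrum`, typically the mean over the training spots.
#' @param snr_min Positive signal-to-noise threshold (default 3).
#' @param window_halfwidth Integration half-width recorded in the returned
#'   peak list (default 1).
#' @return A `peak_list` with the sorted peak centers in Daltons.
#' @export
detect_peaks <- function(mean_spectrum, snr_min = 3, window_halfwidth = 1) {
  stopifnot(inherits(mean_spectrum, "ims_spectrum"))
  if (!is.numeric(snr_min) || length(snr_min) != 1L || snr_min <= 0) {
    stop_field("snr_min", "must be a single positive number")
  }
  y <- mean_spectrum$intensity
  n <- length(y)
  noise <- stats::mad(diff(y)) / sqrt(2)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  idx <- idx[y[idx] >= snr_min * noise]
  peak_list(mean_spectrum$mz[idx], window_halfwidth = window_halfwidth)
}

#' Assemble the spots-by-peaks feature matrix
#'
#' Entry (i, j) is the sum of intensities of spectrum i over the bins within
#' `window_halfwidth` of peak center j.
#'
#' @param spectra List of `ims_spectrum` objects on one common axis.
#' @param peaks A `peak_list`.
#' @return Numeric matrix (spots x peaks) with `spot_id` rownames and the
#'   peak centers (Da) as column names.
#' @export
build_peak_matrix <- function(spectra, peaks) {
  stopifnot(length(spectra) >= 1L, inherits(peaks, "peak_list"))
  mz <- spectra[[1L]]$mz
  n <- length(mz)
  centers_idx <- vapply(peaks$centers,
                        function(ctr) which.min(abs(mz - ctr)), integer(1))
  h <- peaks$window_halfwidth
  windows <- lapply(centers_idx, function(i) {
    seq(max(1L, i - h), min(n, i + h))
  })
  out <- t(vapply(spectra, function(s) {
    if (length(s$mz) != n || any(s$mz != mz)) {
      stop("all spectra must share one common axis", call. = FALSE)
    }
    vapply(windows, function(w) sum(s$intensity[w]), numeric(1))
  }, numeric(length(windows))))
  if (length(windows) == 1L) out <- matrix(out, ncol = 1L)
  rownames(out) <- unname(vapply(spectra, function(s)
    as.character(s$spot_id %||% ""), character(1)))
  colnames(out) <- sprintf("mz_%.4f", peaks$centers)
  out
}

#' Run the full spectral preprocessing chain over a cohort
#'
#' Applies, in order: resampling onto `axis`, baseline subtraction, TIC
#' normalization, and integer-lag realignment against a reference (default:
#' the mean of the normalized spectra listed in `reference_ids`, so held-out
#' spots never shape the reference).  Spots whose total ion current is zero
#' are dropped with a warning.
#'
#' @param spectra Named list of `ims_spectrum` objects.
#' @param axis An `axis_spec`.
#' @param baseline_window Odd rolling window in bins (default 51).
#' @param max_shift Realignment search half-range in bins (default 5).
#' @param reference_ids Spot ids used to build the alignment reference;
#'   default all spots.
#' @param reference Optional explicit reference `ims_spectrum`; overrides
#'   `reference_ids`.
#' @return A list with `spectra` (processed, named by spot id), `shifts`
#'   (named integer vector), `reference` and `dropped` (ids of zero-TIC
#'   spots).
#' @export
preprocess_spectra <- function(spectra, axis, baseline_window = 51,
                               max_shift = 5, reference_ids = NULL,
                               reference = NULL) {
  ids <- names(spectra) %||% vapply(spectra, function(s)
    as.character(s$spot_id), character(1))
  names(spectra) <- ids
  res <- lapply(spectra, function(s) {
    subtract_baseline(resample_to_axis(s, axis), baseline_window)
  })
  tics <- vapply(res, function(s) sum(s$intensity), numeric(1))
  dropped <- ids[tics <= 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-TIC spot(s): %s", length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
    res <- res[tics > 0]
    ids <- ids[tics > 0]
  }
  res <- lapply(res, tic_normalize)
  if (is.null(reference)) {
    ref_ids <- intersect(reference_ids %||% ids, ids)
    if (!length(ref_ids)) stop("no reference spots available", call. = FALSE)
    reference <- mean_spectrum(res[ref_ids])
  }
  shifts <- integer(length(res))
  names(shifts) <- ids
  for (i in seq_along(res)) {
    al <- realign_spectrum(res[[i]], reference, max_shift)
    res[[i]] <- al$spectrum
    shifts[i] <- al$shift
  }
  list(spectra = res, shifts = shifts, reference = reference,
       dropped = dropped)
}
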