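test_that("resampling interpolates linearly and zero-fills outside the support", {
  ax <- axis_spec(700, 702, n_bins = 3)
  s <- ims_spectrum(c(700, 702), c(0, 2))
  out <- resample_to_axis(s, ax)
  expect_equal(out$mz, c(700, 701, 702))
  expect_equal(out$intensity, c(0, 1, 2))

  # input already on the axis centers is unchanged
  ax2 <- axis_spec(700, 800, n_bins = 26)
  s2 <- ims_spectrum(ax2$centers, seq_len(26))
  expect_equal(resample_to_axis(s2, ax2)$intensity, as.numeric(1:26))

  # all-zero input stays all-zero on any axis
  s3 <- ims_spectrum(c(710, 750, 790), c(0, 0, 0))
  expect_equal(resample_to_axis(s3, ax2)$intensity, rep(0, 26))

  # narrow input: bins outside its support are exactly 0
  s4 <- ims_spectrum(c(740, 760), c(5, 5))
  out4 <- resample_to_axis(s4, ax2)
  expect_true(all(out4$intensity[ax2$centers < 740 | ax2$centers > 760] == 0))

  expect_error(resample_to_axis(ims_spectrum(c(100, 200), c(1, 1),
                                             spot_id = "S1"), ax2), "S1")
})

test_that("baseline subtraction removes flat offsets and matches the windowed oracle", {
  expect_equal(subtract_baseline(flat_spectrum(7), window = 9)$intensity,
               rep(0, 50))

  # constant offset 5 + single-bin peak of height 10
  x <- rep(5, 101)
  x[51] <- 15
  s <- ims_spectrum(seq(700, 800, length.out = 101), x)
  out <- subtract_baseline(s, window = 21)
  expect_equal(out$intensity, pmax(x - oracle_baseline(x, 21), 0),
               tolerance = 1e-12)
  expect_equal(out$intensity[51], 10, tolerance = 1e-9)

  # random spectra: never negative, and oracle agreement
  for (seed in 1:5) {
    set.seed(seed)
    y <- stats::rnorm(80, mean = 3)
    s <- ims_spectrum(seq(700, 780, along.with = y), y)
    out <- subtract_baseline(s, window = 11)
    expect_true(all(out$intensity >= 0))
    expect_equal(out$intensity, pmax(y - oracle_baseline(y, 11), 0),
                 tolerance = 1e-12)
  }

  expect_error(subtract_baseline(flat_spectrum(1, n = 5), window = 9),
               "window")
  expect_error(subtract_baseline(flat_spectrum(1), window = 10), "odd")
})

test_that("TIC normalization is exact, idempotent and scale invariant", {
  s <- ims_spectrum(c(700, 701), c(1, 3))
  expect_equal(tic_normalize(s)$intensity, c(0.25, 0.75))

  # already at target: unchanged
  s2 <- ims_spectrum(c(700, 701, 702), c(0.2, 0.3, 0.5))
  expect_equal(tic_normalize(s2)$intensity, s2$intensity)

  # scaling input by any c > 0 gives identical output; sum hits target
  set.seed(1)
  y <- stats::runif(40)
  sa <- ims_spectrum(seq(700, 739), y)
  sb <- ims_spectrum(seq(700, 739), 17.3 * y)
  expect_equal(tic_normalize(sa)$intensity, tic_normalize(sb)$intensity,
               tolerance = 1e-12)
  expect_equal(sum(tic_normalize(sa, target_sum = 2.5)$intensity), 2.5,
               tolerance = 1e-9)
  expect_equal(tic_normalize(tic_normalize(sa))$intensity,
               tic_normalize(sa)$intensity, tolerance = 1e-9)

  expect_error(tic_normalize(flat_spectrum(0, id = "S77")), "S77")
})

test_that("realignment recovers integer shifts and honours its contracts", {
  n <- 200
  mz <- seq(700, 899, length.out = n)
  ref_y <- exp(-0.5 * ((seq_len(n) - 100) / 3)^2)
  ref <- ims_spectrum(mz, ref_y)

  # identity: zero shift, unchanged spectrum
  out <- realign_spectrum(ref, ref, max_shift = 5)
  expect_equal(out$shift, 0L)
  expect_equal(out$spectrum$intensity, ref_y)

  # peak moved to bin 102 (shift +2): detected and undone
  shifted <- ims_spectrum(mz, exp(-0.5 * ((seq_len(n) - 102) / 3)^2))
  out <- realign_spectrum(shifted, ref, max_shift = 5)
  expect_equal(out$shift, 2L)
  expect_equal(which.max(out$spectrum$intensity), 100L)
  expect_equal(out$shift, oracle_best_lag(shifted$intensity, ref_y, 5))

  # max_shift = 0 forces zero shift
  expect_equal(realign_spectrum(shifted, ref, max_shift = 0)$shift, 0L)

  # boundary lag warns
  far <- ims_spectrum(mz, exp(-0.5 * ((seq_len(n) - 104) / 3)^2))
  expect_warning(realign_spectrum(far, ref, max_shift = 4), "boundary")
})

test_that("all injected shifts within max_shift are recovered exactly on clean toys", {
  n <- 120
  mz <- seq(700, 819, length.out = n)
  base <- exp(-0.5 * ((seq_len(n) - 60) / 2)^2) +
    0.6 * exp(-0.5 * ((seq_len(n) - 30) / 2)^2)
  ref <- ims_spectrum(mz, base)
  for (shift in -3:3) {
    y <- numeric(n)
    src <- seq_len(n) - shift
    ok <- src >= 1 & src <= n
    y[ok] <- base[src[ok]]    # peaks displaced by +shift bins
    out <- realign_spectrum(ims_spectrum(mz, y), ref, max_shift = 5)
    expect_equal(out$shift, shift)
    expect_equal(which.max(out$spectrum$intensity), 60L)
  }
})

test_that("peak picking finds exactly the planted bumps and nothing on flat/ramp input", {
  expect_length(detect_peaks(flat_spectrum(1))$centers, 0L)
  ramp <- ims_spectrum(seq(700, 799), seq(0, 99) / 10)
  expect_length(detect_peaks(ramp)$centers, 0L)
  expect_error(detect_peaks(flat_spectrum(1), snr_min = 0), "snr_min")

  # brute-force oracle: strict interior local maxima above the threshold
  oracle_peaks <- function(y, snr_min) {
    noise <- stats::mad(diff(y)) / sqrt(2)
    keep <- integer(0)
    for (i in 2:(length(y) - 1)) {
      if (y[i] > y[i - 1] && y[i] > y[i + 1] && y[i] >= snr_min * noise) {
        keep <- c(keep, i)
      }
    }
    keep
  }
  n <- 300
  mz <- seq(700, 999, length.out = n)
  for (seed in 1:20) {
    set.seed(seed)
    y <- stats::rnorm(n, 0, 0.01)
    noise_level <- stats::mad(diff(y)) / sqrt(2)
    y <- y + 50 * noise_level * exp(-0.5 * ((seq_len(n) - 80) / 3)^2) +
      50 * noise_level * exp(-0.5 * ((seq_len(n) - 220) / 3)^2)
    pk <- detect_peaks(ims_spectrum(mz, y), snr_min = 3)
    idx <- vapply(pk$centers, function(ctr) which.min(abs(mz - ctr)),
                  integer(1))
    # exact agreement with the brute scan
    expect_equal(idx, oracle_peaks(y, 3))
    # both planted bumps recovered within one bin of truth
    expect_true(any(abs(idx - 80) <= 1))
    expect_true(any(abs(idx - 220) <= 1))
    # at a decisive prominence, the planted bumps are the only peaks:
    # noise-floor maxima hover at the 3-sigma threshold, the bumps at 50
    strong <- idx[y[idx] >= 10 * noise_level]
    expect_length(strong, 2L)
    expect_true(all(pmin(abs(strong - 80), abs(strong - 220)) <= 1))
  }
})

test_that("the peak matrix integrates window sums with the documented shape", {
  ax <- axis_spec(700, 709, n_bins = 10)
  mk <- function(y, id) ims_spectrum(ax$centers, y, spot_id = id)
  pk <- peak_list(ax$centers[c(2, 5, 7, 9)], window_halfwidth = 1,
                  axis = ax)
  sp <- list(mk(rep(1, 10), "a"), mk(seq(0.1, 1, by = 0.1), "b"),
             mk(rep(0, 10), "c"))
  pm <- build_peak_matrix(sp, pk)
  expect_equal(dim(pm), c(3L, 4L))
  expect_equal(rownames(pm), c("a", "b", "c"))
  # hand-computed 3-bin sums for the ramp spectrum
  expect_equal(unname(pm["b", ]), c(0.1 + 0.2 + 0.3, 0.4 + 0.5 + 0.6,
                                    0.6 + 0.7 + 0.8, 0.8 + 0.9 + 1.0))
  expect_equal(unname(pm["a", ]), rep(3, 4))
  expect_equal(unname(pm["c", ]), rep(0, 4))

  # indicator case: unit intensity inside exactly one window
  y <- numeric(10)
  y[5] <- 1
  expect_equal(unname(build_peak_matrix(list(mk(y, "i")), pk)[1, ]),
               c(0, 1, 0, 0))

  expect_error(peak_list(c(500, 800), axis = ax), "within the axis")
  expect_error(peak_list(c(703, 702)), "increasing")
})

test_that("the preprocessing chain drops zero-TIC spots with a warning and stays non-negative", {
  co <- generate_cohort(tiny_cohort_config(seed = 13, n_patients = 4))
  spectra <- co$spectra
  dead <- spectra[[2]]
  dead$intensity[] <- 0
  spectra[[2]] <- dead
  expect_warning(
    prep <- preprocess_spectra(spectra, co$axis, baseline_window = 21),
    "zero-TIC")
  expect_equal(prep$dropped, names(spectra)[2])
  sums <- vapply(prep$spectra, function(s) sum(s$intensity), numeric(1))
  # realignment zero-fills vacated bins, so sums stay within one bin of 1
  expect_true(all(abs(sums - 1) < 0.05))
  expect_true(all(vapply(prep$spectra, function(s)
    all(s$intensity >= 0), logical(1))))
})
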