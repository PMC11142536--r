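# Paired-modality synthetic cohort: per-spot profile spectra and H&E-like
# RGB patches with a patient-grouped class signal in either, both, or
# neither modality.  The generator exists so the whole comparison can be
# exercised end-to-end without patient data; it aims for analytic
# transparency (Gaussian peaks, lognormal TIC, filtered-noise textures),
# not histological realism.

#' Configuration of a synthetic paired-modality cohort
#'
#' @param n_patients Number of patients.
#' @param spots_per_patient_mean Mean spots per patient; actual counts are
#'   Poisson draws truncated at 1 (default 21, matching the annotated-spot
#'   density of the dermatopathology cohort the generator emulates).
#' @param class_prevalence Fraction of melanoma patients, in (0, 1)
#'   (default 0.5; per-class counts are not dictated by the cohort design,
#'   so a balanced split is the neutral choice).
#' @param mz_min,mz_max m/z range in Daltons (defaults 700 and 3500).
#' @param n_axis_bins Bins of the generation axis (default 600; a coarse
#'   grid keeps simulated cohorts fast while leaving peaks several bins
#'   wide).
#' @param n_signal_peaks Number of class-bearing Gaussian peaks (default
#'   40).
#' @param ims_effect_size Separation of the class mean peak heights along
#'   the signed peak pattern, in absolute intensity units (default 0.3,
#'   i.e. two patient-level standard deviations — a moderate, unsaturated
#'   signal; `noise_sd` and `patient_sd` set the scale it competes
#'   against).
#' @param morph_effect_size Separation of the class texture/color
#'   statistics on the same dimensionless scale (default 0.3).
#' @param frac_ims_uninformative_patients,frac_morph_uninformative_patients
#'   Fractions of patients whose spectra (respectively patches) are drawn
#'   from the class-neutral distribution.  The two patient sets are kept
#'   disjoint whenever the fractions sum to at most 1 — the
#'   complementary-signal regime.
#' @param noise_sd SD of i.i.d. bin noise and of per-spot peak-height
#'   jitter (default 0.1).
#' @param baseline_amplitude Amplitude of the smooth decaying baseline
#'   (default 0.5).
#' @param mz_jitter_bins Maximum absolute integer m/z shift applied to a
#'   whole spectrum (default 1).
#' @param tic_scale_sd SD of the lognormal per-spot total-ion-current
#'   factor (default 0.2).
#' @param patient_sd SD of the patient-level random shift along each
#'   modality's class-discriminant direction (default 0.15).  This shared
#'   within-patient component is what makes patient-grouped validation
#'   honest: spots from one patient are not independent replicates.
#' @param patch_px Side of the square RGB patch in pixels (default 96,
#'   i.e. a 48 um spot at 0.5 um/px).
#' @param pixel_size_um Microns per pixel of the patches (default 0.5).
#' @param seed Integer master seed; a fixed seed reproduces the cohort
#'   bit-identically.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          spots_per_patient_mean = 21,
                          class_prevalence = 0.5,
                          mz_min = 700, mz_max = 3500,
                          n_axis_bins = 600,
                          n_signal_peaks = 40,
                          ims_effect_size = 0.3,
                          morph_effect_size = 0.3,
                          frac_ims_uninformative_patients = 0,
                          frac_morph_uninformative_patients = 0,
                          noise_sd = 0.1,
                          baseline_amplitude = 0.5,
                          mz_jitter_bins = 1,
                          tic_scale_sd = 0.2,
                          patient_sd = 0.15,
                          patch_px = 96,
                          pixel_size_um = 0.5,
                          seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    spots_per_patient_mean = assert_number(spots_per_patient_mean,
                                           "spots_per_patient_mean",
                                           min = 1),
    class_prevalence = assert_fraction(class_prevalence, "class_prevalence",
                                       open = TRUE),
    mz_min = assert_number(mz_min, "mz_min"),
    mz_max = assert_number(mz_max, "mz_max"),
    n_axis_bins = assert_count(n_axis_bins, "n_axis_bins", min = 2),
    n_signal_peaks = assert_count(n_signal_peaks, "n_signal_peaks"),
    ims_effect_size = assert_number(ims_effect_size, "ims_effect_size",
                                    min = 0),
    morph_effect_size = assert_number(morph_effect_size, "morph_effect_size",
                                      min = 0),
    frac_ims_uninformative_patients =
      assert_fraction(frac_ims_uninformative_patients,
                      "frac_ims_uninformative_patients"),
    frac_morph_uninformative_patients =
      assert_fraction(frac_morph_uninformative_patients,
                      "frac_morph_uninformative_patients"),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0),
    baseline_amplitude = assert_number(baseline_amplitude,
                                       "baseline_amplitude", min = 0),
    mz_jitter_bins = assert_count(mz_jitter_bins, "mz_jitter_bins", min = 0),
    tic_scale_sd = assert_number(tic_scale_sd, "tic_scale_sd", min = 0),
    patient_sd = assert_number(patient_sd, "patient_sd", min = 0),
    patch_px = assert_count(patch_px, "patch_px", min = 8),
    pixel_size_um = assert_number(pixel_size_um, "pixel_size_um", min = 0,
                                  open_min = TRUE),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (cfg$mz_min >= cfg$mz_max) stop_field("mz_min", "must be < mz_max")
  structure(cfg, class = "cohort_config")
}

# Cohort-level deterministic signal template: peak centers (bin indices),
# base heights, signed class pattern.  Depends only on the config.
cohort_template <- function(config) {
  n <- config$n_signal_peaks
  # evenly spaced centers in the middle 80% of the axis
  centers_bin <- unique(round(seq(0.1, 0.9, length.out = n) *
                                (config$n_axis_bins - 1)) + 1L)
  h0 <- with_seed(config$seed * 7L + 13L, stats::runif(length(centers_bin),
                                                       1.0, 2.0))
  sign <- rep(c(1, -1), length.out = length(centers_bin))
  list(centers_bin = centers_bin, h0 = h0, sign = sign,
       peak_sd_bins = 1.5,
       axis = axis_spec(config$mz_min, config$mz_max, config$n_axis_bins))
}

# Banded Gaussian smoothing operator for the texture field, memoized per
# patch side (it is deterministic and reused for every patch).
.blur_cache <- new.env(parent = emptyenv())
blur_operator <- function(px) {
  key <- as.character(px)
  if (is.null(.blur_cache[[key]])) {
    k <- stats::dnorm(seq(-6, 6), sd = 2)
    k <- k / sum(k)
    K <- matrix(0, px, px)
    d <- abs(outer(seq_len(px), seq_len(px), "-"))
    K[d <= 6] <- k[d[d <= 6] + 7L]
    .blur_cache[[key]] <- K
  }
  .blur_cache[[key]]
}

# Smooth decaying baseline on [0, 1] of the axis.
baseline_shape <- function(t, amplitude) {
  amplitude * (exp(-3 * t) + 0.2 * (1 + cos(2 * pi * t)) / 2)
}

#' Generate one synthetic profile spectrum
#'
#' Intensities are a smooth decaying baseline plus Gaussian peaks at the
#' cohort's fixed m/z centers plus i.i.d. bin noise, scaled by a lognormal
#' TIC factor, with the whole trace shifted by a random integer of at most
#' `mz_jitter_bins` bins and clipped at zero.  Melanoma and nevus differ in
#' the mean peak heights by `ims_effect_size` along the signed peak
#' pattern; for an IMS-uninformative patient the class term is zero.
#'
#' @param label `"melanoma"` or `"nevus"`.
#' @param config A `cohort_config`.
#' @param patient_effects Optional list with `ims_informative` (logical)
#'   and `ims_shift` (patient-level shift along the discriminant);
#'   defaults to an informative patient with zero shift.
#' @param seed RNG seed for this spot.
#' @param spot_id Optional identifier.
#' @return An `ims_spectrum` on the cohort generation axis.
#' @export
generate_spectrum <- function(label, config, patient_effects = NULL,
                              seed = 1L, spot_id = NULL) {
  stopifnot(label %in% c("melanoma", "nevus"))
  tmpl <- cohort_template(config)
  informative <- patient_effects$ims_informative %||% TRUE
  # class-neutral distribution for uninformative patients: no class term
  # and no patient shift along the discriminant (one fixed neutral law)
  shift <- if (informative) patient_effects$ims_shift %||% 0 else 0
  cls <- if (!informative) 0 else if (label == "melanoma") 1 else -1
  n_bins <- config$n_axis_bins
  with_seed(seed, {
    heights <- pmax(0, tmpl$h0 +
                      tmpl$sign * (cls * config$ims_effect_size / 2 + shift) +
                      stats::rnorm(length(tmpl$h0), 0, config$noise_sd))
    jitter <- if (config$mz_jitter_bins > 0) {
      sample(seq(-config$mz_jitter_bins, config$mz_jitter_bins), 1L)
    } else 0L
    bins <- seq_len(n_bins)
    clean <- baseline_shape((bins - 1) / (n_bins - 1),
                            config$baseline_amplitude)
    for (j in seq_along(tmpl$centers_bin)) {
      ctr <- tmpl$centers_bin[j] + jitter
      clean <- clean + heights[j] *
        exp(-0.5 * ((bins - ctr) / tmpl$peak_sd_bins)^2)
    }
    noise <- stats::rnorm(n_bins, 0, config$noise_sd)
    tic <- if (config$tic_scale_sd > 0) {
      stats::rlnorm(1, 0, config$tic_scale_sd)
    } else 1
    ims_spectrum(tmpl$axis$centers, pmax(0, tic * (clean + noise)),
                 spot_id = spot_id)
  })
}

#' Generate one synthetic H&E-like patch
#'
#' An RGB image whose channel means and dark-blob (nucleus-like) density
#' are modulated by the class along a fixed color/texture direction, on top
#' of a smooth filtered-noise background.  For a morphology-uninformative
#' patient the class term is zero.  Pixel values are integers in [0, 255].
#'
#' @param label `"melanoma"` or `"nevus"`.
#' @param config A `cohort_config`.
#' @param patient_effects Optional list with `morph_informative` (logical)
#'   and `morph_shift` (patient-level shift along the discriminant).
#' @param seed RNG seed for this spot.
#' @param spot_id Optional identifier.
#' @return An `he_patch`: integer array `patch_px x patch_px x 3` with
#'   attributes `pixel_size` (um/px) and `spot_id`.
#' @export
generate_patch <- function(label, config, patient_effects = NULL,
                           seed = 1L, spot_id = NULL) {
  stopifnot(label %in% c("melanoma", "nevus"))
  informative <- patient_effects$morph_informative %||% TRUE
  shift <- if (informative) patient_effects$morph_shift %||% 0 else 0
  cls <- if (!informative) 0 else if (label == "melanoma") 1 else -1
  a <- cls * config$morph_effect_size / 2 + shift
  px <- config$patch_px
  u <- c(-1, -1.2, 0.6)
  u <- u / sqrt(sum(u^2))        # melanoma: darker, shifted toward blue
  with_seed(seed, {
    base <- c(0.72, 0.58, 0.66) + 0.30 * a * u + stats::rnorm(3, 0, 0.015)
    # smooth background texture: blurred white noise, shared across channels
    field <- matrix(stats::rnorm(px * px), px, px)
    K <- blur_operator(px)
    field <- K %*% field %*% K
    field <- field / max(stats::sd(field), 1e-12) * 0.04
    # nucleus-like dark blobs; density carries part of the class signal
    lambda <- max(0, 10 * (1 + a))
    n_blobs <- stats::rpois(1, lambda)
    blob <- matrix(0, px, px)
    if (n_blobs > 0) {
      cx <- stats::runif(n_blobs, 1, px)
      cy <- stats::runif(n_blobs, 1, px)
      rr <- stats::runif(n_blobs, 2.5, 5)
      dd <- stats::runif(n_blobs, 0.15, 0.30)
      xs <- seq_len(px)
      for (b in seq_len(n_blobs)) {
        w <- which(abs(xs - cx[b]) <= 3 * rr[b])
        h <- which(abs(xs - cy[b]) <= 3 * rr[b])
        d2 <- outer((xs[w] - cx[b])^2, (xs[h] - cy[b])^2, "+")
        blob[w, h] <- blob[w, h] + dd[b] * exp(-d2 / (2 * (rr[b] / 2)^2))
      }
    }
    gch <- c(0.8, 1.0, 0.9)      # field weight per channel
    wch <- c(0.55, 0.75, 0.35)   # blob absorption per channel (purple-ish)
    img <- array(0L, dim = c(px, px, 3L))
    for (c in 1:3) {
      img[, , c] <- as.integer(round(
        255 * clamp01(base[c] + gch[c] * field - wch[c] * blob)))
    }
    structure(img, class = "he_patch",
              pixel_size = config$pixel_size_um, spot_id = spot_id)
  })
}

#' Generate a full paired-modality cohort
#'
#' Draws patient labels, per-patient spot counts (Poisson truncated at 1),
#' per-patient informativeness flags and random modality shifts, and one
#' spectrum plus one patch per spot.  All of a patient's spots share that
#' patient's label.  When the uninformative fractions sum to at most 1 the
#' IMS- and morphology-uninformative patient sets are disjoint.
#'
#' @param config A `cohort_config`.
#' @return An `msi_cohort`: list with `records` (data.frame patient_id,
#'   spot_id, label, center_x, center_y, pixel_size_um), `spectra` and
#'   `patches` (lists named by spot id), `truth` (per-patient effect
#'   annotations), `config`, and `axis` (the generation `axis_spec`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tmpl <- cohort_template(config)
  with_seed(config$seed, {
    n <- config$n_patients
    n_mel <- round(config$class_prevalence * n)
    if (n > 1L) n_mel <- min(max(n_mel, 1L), n - 1L)
    labels <- rep("nevus", n)
    labels[sample.int(n, n_mel)] <- "melanoma"

    ord <- sample.int(n)
    n_ims_unf <- round(config$frac_ims_uninformative_patients * n)
    n_mor_unf <- round(config$frac_morph_uninformative_patients * n)
    ims_unf <- ord[seq_len(n_ims_unf)]
    rest <- setdiff(ord, ims_unf)
    if (n_mor_unf <= length(rest)) {
      mor_unf <- rest[seq_len(n_mor_unf)]
    } else {
      mor_unf <- c(rest, ims_unf[seq_len(n_mor_unf - length(rest))])
    }

    n_spots <- pmax(1L, stats::rpois(n, config$spots_per_patient_mean))
    truth <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      label = labels,
      n_spots = n_spots,
      ims_informative = !(seq_len(n) %in% ims_unf),
      morph_informative = !(seq_len(n) %in% mor_unf),
      ims_shift = stats::rnorm(n, 0, config$patient_sd),
      morph_shift = stats::rnorm(n, 0, config$patient_sd),
      stringsAsFactors = FALSE
    )

    total <- sum(n_spots)
    spot_seeds <- derive_seeds(2L * total)
    centers <- matrix(stats::runif(2L * total, 64, 960), ncol = 2)

    records <- data.frame(
      patient_id = rep(truth$patient_id, n_spots),
      spot_id = sprintf("S%05d", seq_len(total)),
      label = rep(truth$label, n_spots),
      center_x = round(centers[, 1]),
      center_y = round(centers[, 2]),
      pixel_size_um = config$pixel_size_um,
      stringsAsFactors = FALSE
    )
    patient_idx <- rep(seq_len(n), n_spots)

    spectra <- vector("list", total)
    patches <- vector("list", total)
    for (i in seq_len(total)) {
      p <- patient_idx[i]
      eff <- list(ims_informative = truth$ims_informative[p],
                  ims_shift = truth$ims_shift[p],
                  morph_informative = truth$morph_informative[p],
                  morph_shift = truth$morph_shift[p])
      spectra[[i]] <- generate_spectrum(records$label[i], config, eff,
                                        seed = spot_seeds[2L * i - 1L],
                                        spot_id = records$spot_id[i])
      patches[[i]] <- generate_patch(records$label[i], config, eff,
                                     seed = spot_seeds[2L * i],
                                     spot_id = records$spot_id[i])
    }
    names(spectra) <- records$spot_id
    names(patches) <- records$spot_id
    structure(list(records = records, spectra = spectra, patches = patches,
                   truth = truth, config = config, axis = tmpl$axis),
              class = "msi_cohort")
  })
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat(sprintf(
    "<msi_cohort: %d patients, %d spots (%d melanoma / %d nevus), %d-bin axis>\n",
    nrow(x$truth), nrow(x$records),
    sum(x$records$label == "melanoma"), sum(x$records$label == "nevus"),
    x$config$n_axis_bins))
  invisible(x)
}

#' Write a cohort to disk as plain-text/PNG files
#'
#' Writes `manifest.csv` (patient_id, spot_id, label, pixel_size_um,
#' center_x, center_y), one `<spot_id>.csv` per spectrum (columns
#' mz,intensity) under `spectra/`, and one `<spot_id>.png` per patch under
#' `patches/`.
#'
#' @param cohort An `msi_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "msi_cohort"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "patches"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(cohort$records, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (id in cohort$records$spot_id) {
    s <- cohort$spectra[[id]]
    utils::write.csv(data.frame(mz = s$mz, intensity = s$intensity),
                     file.path(dir, "spectra", paste0(id, ".csv")),
                     row.names = FALSE)
    png::writePNG(unclass(cohort$patches[[id]]) / 255,
                  file.path(dir, "patches", paste0(id, ".png")))
  }
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a per-spot spectrum CSV (columns mz, intensity)
#' @param path CSV path.
#' @param spot_id Optional identifier (default: file name without extension).
#' @return An `ims_spectrum`.
#' @export
read_spectrum_csv <- function(path, spot_id = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("mz", "intensity") %in% names(d)))
  ims_spectrum(d$mz, d$intensity,
               spot_id = spot_id %||% sub("\\.csv$", "", basename(path)))
}

#' Read a patch PNG back as an `he_patch`
#' @param path PNG path.
#' @param pixel_size Microns per pixel recorded on the patch.
#' @param spot_id Optional identifier.
#' @return An `he_patch` integer array in [0, 255].
#' @export
read_patch_png <- function(path, pixel_size = 0.5, spot_id = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]
  structure(array(as.integer(round(img * 255)), dim = dim(img)),
            class = "he_patch", pixel_size = pixel_size,
            spot_id = spot_id %||% sub("\\.png$", "", basename(path)))
}
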