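#' Configuration for synthetic ROI cohorts
#'
#' Builds the parameter set for [generate_cohort()]. The generator emulates a
#' two-class tumor-texture study: a "regular" (adenocarcinoma-like, smooth)
#' class and an "irregular" (squamous-like, noise-dominated) class, with
#' several images per patient sharing a per-patient latent texture so that
#' patient-grouped cross-validation is meaningful. The default cohort layout
#' (12 vs 19 patients) mirrors the class imbalance of a typical NSCLC
#' subtype study.
#'
#' Presets:
#' * `"strong"` — widely separated classes: a smooth correlated field
#'   (`corr_len_regular = 12` px) versus i.i.d. noise (SD 8) riding on a
#'   rougher smooth background; both classes receive Gaussian and
#'   salt-and-pepper noise so both filtrations have work to do. The noise
#'   and background widths are calibrated so that the irregular class has
#'   higher sample/fuzzy/dispersion entropy at every scale while template
#'   matches (and hence sample entropy) remain defined.
#' * `"weak"` — the same construction with the class contrast reduced
#'   (irregular noise SD 3, heavier injected noise), giving intermediate
#'   classification difficulty.
#' * `"null"` — both classes are drawn from the *same* (regular) texture
#'   model; any detected class difference is a false positive.
#'
#' @param preset One of `"strong"`, `"weak"`, `"null"`.
#' @param n_patients_regular,n_patients_irregular Patients per class.
#' @param images_per_patient Images (ROIs) per patient.
#' @param image_size Side length of the square ROI in pixels (>= 8).
#' @param corr_len_regular Smoothing length (pixels) of the regular class.
#' @param noise_sd_irregular SD of the i.i.d. intensity noise of the
#'   irregular class.
#' @param bg_corr_len_irregular,bg_amplitude_irregular Smoothing length and
#'   amplitude of the weak smooth background under the irregular class.
#' @param gaussian_sd SD of Gaussian noise injected into every image.
#' @param sp_fraction Expected fraction of pixels replaced by salt/pepper.
#' @param intensity_range Length-2 numeric, on-disk intensity range.
#' @param patient_weight Weight of the shared per-patient latent field in
#'   each image (0 = no patient structure).
#' @param patient_jitter Relative half-width of the per-patient jitter of
#'   the texture parameters (smoothing length, noise SD, background
#'   amplitude). Each patient draws one multiplier per parameter from
#'   `1 +/- patient_jitter`, shared by all of that patient's images, so
#'   patients differ in texture, not only in the latent field realization.
#' @param seed Integer seed; the same configuration reproduces the cohort
#'   bit for bit.
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config("strong", n_patients_regular = 2,
#'                         n_patients_irregular = 2, images_per_patient = 2,
#'                         image_size = 32)
#' cohort <- generate_cohort(cfg)
synthetic_config <- function(preset = c("strong", "weak", "null"),
                             n_patients_regular = 12,
                             n_patients_irregular = 19,
                             images_per_patient = 5,
                             image_size = 128,
                             corr_len_regular = NULL,
                             noise_sd_irregular = NULL,
                             bg_corr_len_irregular = NULL,
                             bg_amplitude_irregular = NULL,
                             gaussian_sd = NULL,
                             sp_fraction = NULL,
                             intensity_range = c(0, 255),
                             patient_weight = 0.5,
                             patient_jitter = 0.25,
                             seed = 42) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    strong = list(corr_len_regular = 16, noise_sd_irregular = 11,
                  bg_corr_len_irregular = 10, bg_amplitude_irregular = 32,
                  gaussian_sd = 2, sp_fraction = 0.01),
    weak   = list(corr_len_regular = 14, noise_sd_irregular = 4,
                  bg_corr_len_irregular = 12, bg_amplitude_irregular = 36,
                  gaussian_sd = 3, sp_fraction = 0.02),
    null   = list(corr_len_regular = 16, noise_sd_irregular = 11,
                  bg_corr_len_irregular = 10, bg_amplitude_irregular = 32,
                  gaussian_sd = 2, sp_fraction = 0.01))
  cfg <- list(
    preset = preset,
    null_classes = identical(preset, "null"),
    n_patients_regular = n_patients_regular,
    n_patients_irregular = n_patients_irregular,
    images_per_patient = images_per_patient,
    image_size = image_size,
    corr_len_regular = corr_len_regular %||% defaults$corr_len_regular,
    noise_sd_irregular = noise_sd_irregular %||% defaults$noise_sd_irregular,
    bg_corr_len_irregular =
      bg_corr_len_irregular %||% defaults$bg_corr_len_irregular,
    bg_amplitude_irregular =
      bg_amplitude_irregular %||% defaults$bg_amplitude_irregular,
    gaussian_sd = gaussian_sd %||% defaults$gaussian_sd,
    sp_fraction = sp_fraction %||% defaults$sp_fraction,
    intensity_range = as.numeric(intensity_range),
    patient_weight = patient_weight,
    patient_jitter = patient_jitter,
    seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_patients_regular, cfg$n_patients_irregular,
              cfg$images_per_patient)
  if (any(counts < 0)) stop("patient/image counts must be >= 0", call. = FALSE)
  if (cfg$image_size < 8) stop("image_size must be >= 8", call. = FALSE)
  if (cfg$sp_fraction < 0 || cfg$sp_fraction > 1) {
    stop("sp_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$intensity_range) != 2 ||
      cfg$intensity_range[1] >= cfg$intensity_range[2]) {
    stop("intensity_range must be (min, max) with min < max", call. = FALSE)
  }
  if (cfg$patient_weight < 0 || cfg$patient_weight > 1) {
    stop("patient_weight must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$patient_jitter < 0 || cfg$patient_jitter >= 1) {
    stop("patient_jitter must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> preset:", x$preset, "\n")
  cat(sprintf("  %d regular + %d irregular patients x %d images, %dx%d px\n",
              x$n_patients_regular, x$n_patients_irregular,
              x$images_per_patient, x$image_size, x$image_size))
  cat(sprintf("  corr_len %g | noise_sd %g | gaussian_sd %g | sp %g | seed %d\n",
              x$corr_len_regular, x$noise_sd_irregular, x$gaussian_sd,
              x$sp_fraction, x$seed))
  invisible(x)
}

# Row-smoothing matrix with truncated Gaussian weights (rows sum to 1).
gauss_smooth_matrix <- function(n, corr_len) {
  d <- outer(seq_len(n), seq_len(n), "-")
  S <- exp(-0.5 * (d / corr_len)^2)
  S / rowSums(S)
}

# Spatially correlated standard-normal field: white noise smoothed with an
# isotropic Gaussian low-pass of width corr_len, renormalized pixelwise to
# exact unit marginal variance. With corr_len on the order of the image size
# the whole field collapses to (nearly) a single constant draw.
smooth_field <- function(size, corr_len) {
  S <- gauss_smooth_matrix(size, corr_len)
  z <- S %*% matrix(rnorm(size * size), size, size) %*% t(S)
  a <- rowSums(S^2)
  z / sqrt(outer(a, a))
}

#' Generate one smooth ("regular") synthetic ROI
#'
#' White noise convolved with an isotropic Gaussian low-pass kernel of width
#' `corr_len`, scaled so the mid-intensity +/- 3 SD of the field spans the
#' intensity range, clipped and rounded to integer gray levels.
#'
#' @param size Side length in pixels (>= 8).
#' @param corr_len Smoothing length in pixels (>= 1).
#' @param intensity_range Length-2 numeric (min, max).
#' @param seed Integer seed; identical arguments give identical pixels.
#' @return A `size` x `size` numeric matrix of integer-valued intensities.
#' @export
make_regular_roi <- function(size, corr_len, intensity_range = c(0, 255),
                             seed = 1) {
  if (size < 8) stop("size must be >= 8", call. = FALSE)
  if (corr_len < 1) stop("corr_len must be >= 1", call. = FALSE)
  lo <- intensity_range[1]; hi <- intensity_range[2]
  set.seed(seed)
  z <- smooth_field(size, corr_len)
  round(clip((lo + hi) / 2 + (hi - lo) / 6 * z, lo, hi))
}

#' Generate one noise-dominated ("irregular") synthetic ROI
#'
#' A weak smooth background plus i.i.d. Gaussian intensity noise of SD
#' `noise_sd`, clipped into the intensity range and rounded.
#'
#' @inheritParams make_regular_roi
#' @param noise_sd SD of the i.i.d. noise component (>= 0).
#' @param bg_corr_len Smoothing length of the weak background.
#' @param bg_amplitude Amplitude (intensity units) of the background;
#'   0 gives a flat background.
#' @return A `size` x `size` numeric matrix of integer-valued intensities.
#' @export
make_irregular_roi <- function(size, noise_sd, intensity_range = c(0, 255),
                               seed = 1, bg_corr_len = max(2, size / 4),
                               bg_amplitude = diff(intensity_range) / 8) {
  if (size < 8) stop("size must be >= 8", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  lo <- intensity_range[1]; hi <- intensity_range[2]
  set.seed(seed)
  bg <- if (bg_amplitude > 0) bg_amplitude * smooth_field(size, bg_corr_len)
        else matrix(0, size, size)
  noise <- if (noise_sd > 0) matrix(rnorm(size * size, 0, noise_sd), size, size)
           else 0
  round(clip((lo + hi) / 2 + bg + noise, lo, hi))
}

#' Inject Gaussian and salt-and-pepper noise into an image
#'
#' Adds zero-mean Gaussian noise, then replaces a seeded random subset of
#' pixels (each pixel independently with probability `sp_fraction`) with the
#' intensity minimum or maximum, with equal probability. The result is
#' clipped to the range and rounded. With both noise levels at zero the
#' input is returned untouched.
#'
#' @param image Numeric matrix.
#' @param gaussian_sd SD of the additive Gaussian component (>= 0).
#' @param sp_fraction Expected fraction of salt/pepper pixels, in \[0, 1\].
#' @param seed Integer seed.
#' @param intensity_range Length-2 numeric (min, max).
#' @return A numeric matrix of the same shape.
#' @export
inject_noise <- function(image, gaussian_sd, sp_fraction, seed = 1,
                         intensity_range = c(0, 255)) {
  check_image(image)
  if (gaussian_sd < 0) stop("gaussian_sd must be >= 0", call. = FALSE)
  if (sp_fraction < 0 || sp_fraction > 1) {
    stop("sp_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (gaussian_sd == 0 && sp_fraction == 0) return(image)
  lo <- intensity_range[1]; hi <- intensity_range[2]
  set.seed(seed)
  y <- image + matrix(rnorm(length(image), 0, gaussian_sd),
                      nrow(image), ncol(image))
  hit <- runif(length(image)) < sp_fraction
  if (any(hit)) {
    y[hit] <- ifelse(runif(sum(hit)) < 0.5, lo, hi)
  }
  round(clip(y, lo, hi))
}

#' Generate a labeled synthetic ROI cohort
#'
#' Draws `images_per_patient` images for every patient of both classes. Each
#' image is a convex combination of a per-patient latent texture field and an
#' image-specific field from the same class model (weight
#' `patient_weight`), followed by Gaussian and salt-and-pepper noise
#' injection; all randomness derives deterministically from `config$seed`.
#' Under the `"null"` preset both classes use the regular texture model with
#' identical parameters.
#'
#' @param config A [synthetic_config()].
#' @return A cohort tibble with columns `image_id`, `patient_id`,
#'   `class_label` (`"regular"`/`"irregular"`), `image_type` (`"raw"`) and a
#'   `pixels` list-column of numeric matrices.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- list(
    list(label = "regular", n = config$n_patients_regular, prefix = "R"),
    list(label = "irregular", n = config$n_patients_irregular, prefix = "I"))
  rows <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    if (cl$n == 0 || config$images_per_patient == 0) next
    for (p in seq_len(cl$n)) {
      pid <- sprintf("%s%02d", cl$prefix, p)
      pidx <- ci * 1000L + p
      pcfg <- jitter_config(config, derive_seed(config$seed, pidx, 999L))
      latent <- class_field(pcfg, cl$label, derive_seed(config$seed, pidx, 0L))
      for (img in seq_len(config$images_per_patient)) {
        own <- class_field(pcfg, cl$label,
                           derive_seed(config$seed, pidx, img))
        pix <- config$patient_weight * latent +
          (1 - config$patient_weight) * own
        pix <- inject_noise(round(pix), config$gaussian_sd, config$sp_fraction,
                            seed = derive_seed(config$seed, pidx, img + 500L),
                            intensity_range = config$intensity_range)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image_id = sprintf("%s_%02d", pid, img),
          patient_id = pid,
          class_label = cl$label,
          image_type = "raw",
          pixels = list(pix))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(image_id = character(), patient_id = character(),
                          class_label = character(), image_type = character(),
                          pixels = list()))
  }
  dplyr::bind_rows(rows)
}

# Per-patient multiplicative jitter of the texture parameters: one factor
# per parameter, shared by all images of the patient.
jitter_config <- function(config, seed) {
  if (config$patient_jitter == 0) return(config)
  set.seed(seed)
  f <- 1 + config$patient_jitter * stats::runif(4, -1, 1)
  config$corr_len_regular <- max(1, config$corr_len_regular * f[1])
  config$noise_sd_irregular <- config$noise_sd_irregular * f[2]
  config$bg_corr_len_irregular <- max(1, config$bg_corr_len_irregular * f[3])
  config$bg_amplitude_irregular <- config$bg_amplitude_irregular * f[4]
  config
}

class_field <- function(config, label, seed) {
  if (label == "regular" || config$null_classes) {
    make_regular_roi(config$image_size, config$corr_len_regular,
                     config$intensity_range, seed)
  } else {
    make_irregular_roi(config$image_size, config$noise_sd_irregular,
                       config$intensity_range, seed,
                       bg_corr_len = config$bg_corr_len_irregular,
                       bg_amplitude = config$bg_amplitude_irregular)
  }
}
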