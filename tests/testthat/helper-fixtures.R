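# Shared, lazily built fixtures. Cohorts use 32x32 ROIs so the whole suite
# stays fast; the generator's texture parameters are the documented presets.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_cfg <- function(preset, n_reg = 5, n_irr = 5, ipp = 2, size = 32,
                      seed = 42) {
  synthetic_config(preset, n_patients_regular = n_reg,
                   n_patients_irregular = n_irr, images_per_patient = ipp,
                   image_size = size, seed = seed)
}

# strong-preset cohort + combined features (10 patients x 2 images, 96 px;
# 96 px keeps template matches well populated at the coarsest scale)
strong_features <- function() {
  fixture("strong_features", function() {
    co <- generate_cohort(small_cfg("strong", size = 96))
    suppressWarnings(extract_features(co, "combined"))
  })
}

# null-preset cohort (identical class models) with enough patients and
# images per patient for stable fold-level accuracy estimates
null_features <- function() {
  fixture("null_features", function() {
    co <- generate_cohort(small_cfg("null", n_reg = 8, n_irr = 8, ipp = 3))
    suppressWarnings(extract_features(co, "combined"))
  })
}
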