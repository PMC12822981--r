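# Cohort and feature-table I/O plus the one-call pipeline.

#' Write a cohort to disk
#'
#' Writes every image as an 8-bit grayscale PNG (lossless) together with a
#' manifest CSV (`path`, `patient_id`, `class_label`, `image_type`,
#' `image_id`). Images whose values are not already 8-bit gray levels
#' (e.g. normalize-filtered images) are rescaled min-max to 0..255 for
#' writing; pipelines operate on in-memory values.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble (invisibly), with the manifest written to
#'   `<dir>/manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    px <- cohort$pixels[[i]]
    if (min(px) < 0 || max(px) > 255 || any(px != round(px))) {
      rng <- range(px)
      px <- if (rng[1] == rng[2]) matrix(0, nrow(px), ncol(px))
            else round((px - rng[1]) / (rng[2] - rng[1]) * 255)
    }
    fname <- sprintf("%s_%s.png", cohort$image_id[i], cohort$image_type[i])
    paths[i] <- file.path(dir, fname)
    png::writePNG(px / 255, paths[i])
  }
  manifest <- tibble::tibble(path = paths,
                             patient_id = cohort$patient_id,
                             class_label = cohort$class_label,
                             image_type = cohort$image_type,
                             image_id = cohort$image_id)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF images",
             call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s' for %s", ext, path),
         call. = FALSE))
  if (length(dim(arr)) == 3) {
    ch <- arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE]
    if (dim(ch)[3] > 1 &&
        max(abs(ch[, , 1] - ch[, , 2])) > 0) {
      stop(sprintf("color image rejected (grayscale required): %s", path),
           call. = FALSE)
    }
    arr <- arr[, , 1]
  }
  round(arr * 255)
}

#' Load a cohort from a manifest
#'
#' Reads the images listed in a manifest CSV (columns `path`,
#' `patient_id`, `class_label`, optionally `image_type`, `image_id`) as
#' 8-bit grayscale arrays. PNG is the primary format; TIFF is accepted.
#' Color images and missing files are rejected with the offending path
#' named.
#'
#' @param manifest_path Path to the manifest CSV; relative image paths are
#'   resolved against its directory.
#' @return A cohort tibble.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  pixels <- lapply(man$path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, basename(p))
    if (!file.exists(full)) {
      stop(sprintf("image file missing: %s", p), call. = FALSE)
    }
    read_gray_image(full)
  })
  tibble::tibble(
    image_id = man$image_id %||%
      sub("\\.[^.]+$", "", basename(man$path)),
    patient_id = man$patient_id,
    class_label = man$class_label,
    image_type = man$image_type %||% "raw",
    pixels = pixels)
}

#' Save feature tables as CSV
#'
#' One CSV per image type x feature set, named
#' `features_<type>_<set>.csv`, with header `image_id`, `patient_id`,
#' `class_label`, `image_type`, then the feature columns at full floating
#' precision.
#'
#' @param features A feature tibble (its `image_type` column may mix
#'   types; one file is written per type).
#' @param dir Output directory.
#' @param feature_set Tag used in the file names.
#' @return Character vector of paths written (invisibly).
#' @export
save_features <- function(features, dir, feature_set = "combined") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (nrow(features) == 0) {
    path <- file.path(dir, sprintf("features_empty_%s.csv", feature_set))
    write.csv(features, path, row.names = FALSE)
    return(invisible(path))
  }
  for (tp in unique(features$image_type)) {
    sub <- dplyr::filter(features, .data$image_type == tp)
    path <- file.path(dir, sprintf("features_%s_%s.csv", tp, feature_set))
    write.csv(sub, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Run the whole pipeline on a synthetic cohort
#'
#' generate -> filter -> extract features -> group statistics -> selection
#' -> cross-validated classification, writing all tabular artifacts (and a
#' run manifest echoing the configuration and seeds) under `out_dir` when
#' given. Identical configurations produce byte-identical feature CSVs and
#' identical cross-validation reports.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory for CSV artifacts.
#' @param image_types,feature_sets,classifiers Factorial axes (defaults:
#'   the full 3 x 3 x 3 grid).
#' @param k,cv_seed,mode,select_k,n_trees,rf_seed Cross-validation and
#'   selection settings.
#' @param L,params Feature-extraction settings.
#' @return A list: `cohort`, `features` (named by image type, combined
#'   set), `stats` (significance tables per image type), `selection`
#'   (per image type, full table), `experiment` (the 27-cell grid +
#'   reports).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         image_types = c("raw", "normalize", "median"),
                         feature_sets = c("statistical", "entropy",
                                          "combined"),
                         classifiers = c("knn", "svm", "lr"),
                         k = 5, cv_seed = 42, mode = "safe", select_k = 25,
                         n_trees = 100, rf_seed = 42, L = 32,
                         params = entropy_params()) {
  cohort <- generate_cohort(config)
  filtered <- filter_cohort(cohort, image_types)
  features <- stats_tabs <- selections <- list()
  for (tp in image_types) {
    sub <- dplyr::filter(filtered, .data$image_type == tp)
    feats <- extract_features(sub, "combined", L = L, params = params)
    features[[tp]] <- feats
    stats_tabs[[tp]] <- significance_table(feats)
    std <- standardize_fit(feats)
    selections[[tp]] <- select_top_k(standardize_apply(std, feats),
                                     k = select_k, n_trees = n_trees,
                                     seed = rf_seed)
  }
  experiment <- run_experiment(cohort, image_types, feature_sets,
                               classifiers, k = k, seed = cv_seed,
                               mode = mode, select_k = select_k,
                               n_trees = n_trees, rf_seed = rf_seed,
                               L = L, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tp in image_types) {
      save_features(features[[tp]], out_dir)
      write.csv(stats_tabs[[tp]],
                file.path(out_dir, sprintf("stats_%s.csv", tp)),
                row.names = FALSE)
      write.csv(tidy(selections[[tp]]),
                file.path(out_dir, sprintf("selection_%s.csv", tp)),
                row.names = FALSE)
    }
    write.csv(experiment$grid, file.path(out_dir, "results_grid.csv"),
              row.names = FALSE)
    fold_rows <- purrr::imap(experiment$reports, function(rep, nm) {
      dplyr::mutate(rep$metrics, cell = nm)
    })
    write.csv(dplyr::bind_rows(fold_rows),
              file.path(out_dir, "per_fold_metrics.csv"), row.names = FALSE)
    manifest <- c(
      sprintf("package_version: %s",
              as.character(utils::packageVersion("texent"))),
      sprintf("preset: %s", config$preset),
      sprintf("generator_seed: %d", config$seed),
      sprintf("cv_seed: %d", cv_seed),
      sprintf("rf_seed: %d", rf_seed),
      sprintf("mode: %s", mode),
      sprintf("image_size: %d", config$image_size),
      sprintf("quantization_levels: %d", L))
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  list(cohort = cohort, features = features, stats = stats_tabs,
       selection = selections, experiment = experiment)
}
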