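#' Extract a feature table from a cohort
#'
#' Assembles one of the three study feature sets per image:
#' * `"statistical"` — 17 first-order + 73 gray-level-matrix features
#'   (90 columns);
#' * `"entropy"` — the 25 multiscale entropy features;
#' * `"combined"` — the union of both (115 columns).
#'
#' @param cohort A cohort tibble (any mix of image types; features are
#'   computed per row).
#' @param feature_set One of `"statistical"`, `"entropy"`, `"combined"`.
#' @param L Quantization levels for the gray-level matrices.
#' @param params An [entropy_params()].
#' @param gldm_alpha Dependence tolerance for GLDM.
#' @return A tibble with `image_id`, `patient_id`, `class_label`,
#'   `image_type`, then the feature columns; stable names across runs.
#' @export
extract_features <- function(cohort,
                             feature_set = c("combined", "statistical",
                                             "entropy"),
                             L = 32, params = entropy_params(),
                             gldm_alpha = 0) {
  feature_set <- match.arg(feature_set)
  meta <- c("image_id", "patient_id", "class_label", "image_type")
  if (feature_set == "statistical") {
    return(statistical_features(cohort, L, gldm_alpha))
  }
  if (feature_set == "entropy") {
    return(entropy_features(cohort, params))
  }
  stat <- statistical_features(cohort, L, gldm_alpha)
  ent <- entropy_features(cohort, params)
  dplyr::bind_cols(stat, dplyr::select(ent, -dplyr::all_of(meta)))
}

#' Names of the feature columns of a feature table
#'
#' @param features A feature tibble from [extract_features()].
#' @return Character vector of feature column names (metadata excluded).
#' @export
feature_names <- function(features) {
  setdiff(names(features),
          c("image_id", "patient_id", "class_label", "image_type"))
}

#' Feature group of each feature name
#'
#' Maps feature column names to their family tag: `FOS`, `GLCM`, `GLDM`,
#' `GLRLM`, `GLSZM`, `NGTDM` or the entropy method name.
#'
#' @param x Character vector of feature names.
#' @return Character vector of group tags.
#' @export
feature_group <- function(x) {
  dplyr::case_when(
    startsWith(x, "fos_") ~ "FOS",
    startsWith(x, "glcm_") ~ "GLCM",
    startsWith(x, "gldm_") ~ "GLDM",
    startsWith(x, "glrlm_") ~ "GLRLM",
    startsWith(x, "glszm_") ~ "GLSZM",
    startsWith(x, "ngtdm_") ~ "NGTDM",
    TRUE ~ sub("_s[0-9]+$", "", x))
}
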