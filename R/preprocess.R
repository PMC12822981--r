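#' Normalize filtration
#'
#' Linear rescaling of an ROI so the pixel population has zero mean and unit
#' variance (population, N-denominator). A constant image has no defined
#' rescaling and is returned as all zeros with a warning.
#'
#' @param image Numeric matrix with at least 2 pixels.
#' @return Numeric matrix of the same shape.
#' @export
normalize_filter <- function(image) {
  check_image(image)
  if (length(image) < 2) stop("image must have at least 2 pixels", call. = FALSE)
  s <- sd_pop(image)
  if (s == 0) {
    warning("constant image: normalize filtration returns all zeros",
            call. = FALSE)
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - mean(image)) / s
}

#' Median filtration
#'
#' Each output pixel is the median of its (2 * radius + 1)^2 neighborhood,
#' with replicate (clamp-to-edge) padding at the borders.
#'
#' @param image Numeric matrix.
#' @param radius Neighborhood radius in pixels (>= 1); the default 1 gives
#'   the common 3x3 window.
#' @return Numeric matrix of the same shape.
#' @export
median_filter <- function(image, radius = 1) {
  check_image(image)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  cpp_median_filter(image, as.integer(radius))
}

#' Apply the study filtrations across a cohort
#'
#' Expands a raw cohort into the requested image types: `"raw"` passes
#' images through, `"normalize"` applies [normalize_filter()], `"median"`
#' applies [median_filter()]. Returns the stacked cohort with `image_type`
#' set per row.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param types Character vector from `c("raw", "normalize", "median")`.
#' @param median_radius Radius for the median filtration.
#' @return A cohort tibble with one row per image x type.
#' @export
filter_cohort <- function(cohort, types = c("raw", "normalize", "median"),
                          median_radius = 1) {
  types <- match.arg(types, several.ok = TRUE)
  raw <- dplyr::filter(cohort, .data$image_type == "raw")
  out <- lapply(types, function(tp) {
    filtered <- switch(tp,
      raw = raw$pixels,
      normalize = lapply(raw$pixels, normalize_filter),
      median = lapply(raw$pixels, median_filter, radius = median_radius))
    dplyr::mutate(raw, image_type = tp, pixels = filtered)
  })
  dplyr::bind_rows(out)
}
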