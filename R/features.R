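# Lesion feature vectors.
#
# 15 microcalcification descriptors, 26 mass descriptors and their
# 41-element combination, computed from a grayscale image plus binary
# masks. The canonical name orders below are fixed by the package; every
# feature is invariant to integer translation and to 90-degree rotation of
# the image and masks.

#' Canonical feature names
#'
#' The fixed column orders of the microcalcification (15), mass (26) and
#' combined (41 = 15 + 26) feature schemas.
#'
#' @return character vector of feature names.
#' @export
calc_feature_names <- function() {
  c("calc_number", "calc_total_area", "calc_mean_diameter",
    "calc_max_diameter", "calc_density", "calc_mean_circularity",
    "calc_circularity_proportion", "calc_mean_solidity",
    "calc_sandy_proportion", "calc_linear_proportion",
    "calc_mean_spiculation", "calc_volume_ratio", "calc_mean_gray",
    "calc_gray_sd", "calc_cluster_eccentricity")
}

#' @rdname calc_feature_names
#' @export
mass_feature_names <- function() {
  c("mass_area", "mass_perimeter", "mass_solidity", "mass_elongation",
    "mass_axis_ratio", "mass_eccentricity", "mass_convexity",
    "mass_spiculation", "mass_heterogeneity", "mass_volume_ratio",
    "mass_mean_gray", "mass_max_gray", "mass_min_gray", "mass_gray_sd",
    "mass_gray_relativity", "mass_entropy",
    "mass_inverse_difference_moment", "mass_difference_entropy",
    "mass_correlation", "mass_difference_variance", "mass_sum_average",
    "mass_sum_variance", "mass_energy", "mass_mutual_information",
    "mass_contrast", "mass_sum_entropy")
}

#' @rdname calc_feature_names
#' @export
combined_feature_names <- function() {
  c(calc_feature_names(), mass_feature_names())
}

feature_vector <- function(values, group) {
  nms <- switch(group, calc = calc_feature_names(),
                mass = mass_feature_names(),
                combined = combined_feature_names())
  stopifnot(length(values) == length(nms))
  if (any(!is.finite(values))) stop_input("feature values must be finite")
  structure(stats::setNames(as.numeric(values), nms), group = group,
            class = c("feature_vector", "numeric"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector (%s, %d features)\n", attr(x, "group"),
              length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Microcalcification feature vector (15 features)
#'
#' Characterizes a cluster of segmented microcalcifications: count, size
#' (total area, mean/max equivalent diameter), spatial density (count per
#' convex-hull area of the pooled calcification pixels), shape (mean
#' circularity, proportion of round components, mean solidity, proportion
#' of "sandy" components with equivalent diameter < 3 px, proportion of
#' linear components with axis ratio >= 3, mean spiculation
#' `perimeter/convex_perimeter - 1`), the calcified fraction of the region
#' of interest, intensity statistics over the calcification pixels, and
#' the eccentricity of the ellipse fitted to all pooled pixels.
#'
#' An empty `calc_mask` yields the documented degenerate vector of zeros.
#'
#' @param image grayscale matrix (0--255).
#' @param calc_mask binary microcalcification mask, subset of `roi_mask`.
#' @param roi_mask binary region-of-interest mask; defaults to the whole
#'   image.
#' @return a `feature_vector` of length 15 (group `"calc"`).
#' @export
microcalc_features <- function(image, calc_mask, roi_mask = NULL) {
  check_image(image)
  calc_mask <- check_mask(calc_mask, image, "calc_mask")
  if (is.null(roi_mask)) roi_mask <- matrix(1L, nrow(image), ncol(image))
  roi_mask <- check_mask(roi_mask, image, "roi_mask")
  if (!any(roi_mask == 1)) stop_input("roi_mask is empty")
  if (any(calc_mask == 1 & roi_mask == 0))
    stop_input("calc_mask must lie inside roi_mask")
  comps <- label_components(calc_mask)
  n <- length(comps)
  if (n == 0) return(feature_vector(rep(0, 15), "calc"))
  geos <- lapply(comps, component_geometry)
  areas <- vapply(geos, `[[`, numeric(1), "area")
  eqd <- vapply(geos, `[[`, numeric(1), "equivalent_diameter")
  circ <- vapply(geos, shape_circularity, numeric(1))
  sol <- vapply(geos, function(g) g$area / g$convex_area, numeric(1))
  ratio <- vapply(geos, function(g) g$major_axis / g$minor_axis, numeric(1))
  spic <- vapply(geos, function(g)
    max(g$perimeter / max(g$convex_perimeter, 1e-12) - 1, 0), numeric(1))
  px_all <- which(calc_mask == 1, arr.ind = TRUE)
  hull_all <- pixel_hull(px_all)
  ax_all <- moment_axes(px_all)
  ecc <- sqrt(max(0, 1 - (ax_all$minor / ax_all$major)^2))
  gv <- image[calc_mask == 1]
  gsd <- if (length(gv) > 1) sd(gv) else 0
  feature_vector(c(
    n,
    sum(areas),
    mean(eqd),
    max(eqd),
    n / max(hull_all$area, 1),
    mean(circ),
    mean(circ >= 0.8),
    mean(sol),
    mean(eqd < 3),
    mean(ratio >= 3),
    mean(spic),
    sum(areas) / sum(roi_mask == 1),
    mean(gv),
    gsd,
    ecc), "calc")
}

# Radial boundary-distance signature: distances from the component
# centroid to its boundary pixels (pixels with an exposed 4-edge).
radial_signature <- function(mask, centroid) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)] == 1
  exposed <- inner & (pad[1:h, 2:(w + 1)] == 0 | pad[3:(h + 2), 2:(w + 1)] == 0 |
                        pad[2:(h + 1), 1:w] == 0 | pad[2:(h + 1), 3:(w + 2)] == 0)
  px <- which(exposed, arr.ind = TRUE)
  sqrt((px[, 1] - centroid[1])^2 + (px[, 2] - centroid[2])^2)
}

#' Mass feature vector (26 features)
#'
#' Shape descriptors of the (single-component) mass mask — area, crack
#' perimeter, solidity, elongation `1 - minor/major`, axis ratio,
#' eccentricity, convexity `convex_perimeter/perimeter`, spiculation (the
#' coefficient of variation of the radial boundary-distance signature) —
#' plus intensity statistics inside the mask (heterogeneity = SD/mean,
#' mean/max/min/SD gray, gray relativity = mean inside divided by the mean
#' of a 5-pixel dilation band outside) and the Haralick texture statistics
#' of the masked gray-level co-occurrence matrix.
#'
#' An empty `mass_mask` yields the documented degenerate vector of zeros;
#' a multi-component mask is an error (largest-component selection is the
#' detector's job).
#'
#' @inheritParams microcalc_features
#' @param mass_mask binary mass mask with at most one 8-connected
#'   component.
#' @param glcm_levels,glcm_distance co-occurrence quantization levels and
#'   offset distance.
#' @return a `feature_vector` of length 26 (group `"mass"`).
#' @export
mass_features <- function(image, mass_mask, roi_mask = NULL,
                          glcm_levels = 16, glcm_distance = 1) {
  check_image(image)
  mass_mask <- check_mask(mass_mask, image, "mass_mask")
  if (is.null(roi_mask)) roi_mask <- matrix(1L, nrow(image), ncol(image))
  roi_mask <- check_mask(roi_mask, image, "roi_mask")
  if (!any(roi_mask == 1)) stop_input("roi_mask is empty")
  if (any(mass_mask == 1 & roi_mask == 0))
    stop_input("mass_mask must lie inside roi_mask")
  lab <- label_matrix(mass_mask)
  ncomp <- max(lab)
  if (ncomp == 0) return(feature_vector(rep(0, 26), "mass"))
  if (ncomp > 1)
    stop_input("mass_mask must have a single connected component")
  g <- component_geometry(mass_mask)
  sol <- g$area / g$convex_area
  elong <- 1 - g$minor_axis / g$major_axis
  ratio <- g$major_axis / g$minor_axis
  ecc <- sqrt(max(0, 1 - (g$minor_axis / g$major_axis)^2))
  convexity <- min(g$convex_perimeter / max(g$perimeter, 1e-12), 1)
  rs <- radial_signature(mass_mask, g$centroid)
  spic <- if (length(rs) > 1 && mean(rs) > 0) sd(rs) / mean(rs) else 0
  gv <- image[mass_mask == 1]
  mg <- mean(gv)
  gsd <- if (length(gv) > 1) sd(gv) else 0
  het <- if (mg > 0) gsd / mg else 0
  band <- EBImage::dilate(mass_mask, EBImage::makeBrush(11, "disc")) == 1 &
    mass_mask == 0
  relat <- if (any(band) && mean(image[band]) > 0) {
    mg / mean(image[band])
  } else 0
  tex <- if (g$area >= 2) {
    tryCatch(glcm_features(compute_glcm(image, mass_mask,
                                        levels = glcm_levels,
                                        distance = glcm_distance)),
             mammocad_input_error = function(e)
               stats::setNames(rep(0, 11), names(glcm_features(diag(1)))))
  } else stats::setNames(rep(0, 11), c("energy", "entropy", "correlation",
                                       "inverse_difference_moment",
                                       "sum_average", "sum_variance",
                                       "difference_variance",
                                       "difference_entropy", "sum_entropy",
                                       "contrast", "mutual_information"))
  feature_vector(c(
    g$area, g$perimeter, sol, elong, ratio, ecc, convexity, spic, het,
    g$area / sum(roi_mask == 1), mg, max(gv), min(gv), gsd, relat,
    tex[["entropy"]], tex[["inverse_difference_moment"]],
    tex[["difference_entropy"]], tex[["correlation"]],
    tex[["difference_variance"]], tex[["sum_average"]],
    tex[["sum_variance"]], tex[["energy"]], tex[["mutual_information"]],
    tex[["contrast"]], tex[["sum_entropy"]]), "mass")
}

#' Combine microcalcification and mass feature vectors
#'
#' @param calc_fv a length-15 `feature_vector` of group `"calc"`.
#' @param mass_fv a length-26 `feature_vector` of group `"mass"`.
#' @return the concatenated length-41 `feature_vector` (group
#'   `"combined"`), calc features first.
#' @export
combined_features <- function(calc_fv, mass_fv) {
  if (!inherits(calc_fv, "feature_vector") ||
      !identical(attr(calc_fv, "group"), "calc"))
    stop_input("calc_fv must be a calc feature_vector")
  if (!inherits(mass_fv, "feature_vector") ||
      !identical(attr(mass_fv, "group"), "mass"))
    stop_input("mass_fv must be a mass feature_vector")
  feature_vector(c(as.numeric(calc_fv), as.numeric(mass_fv)), "combined")
}

#' Extract features for a generated or loaded case
#'
#' Convenience wrapper computing the scenario-appropriate feature vector
#' from a `lesion_case` (or an image plus masks).
#'
#' @param case a [generate_case()] result.
#' @param scenario `"calc"`, `"mass"` or `"combined"`.
#' @param ... passed to [mass_features()] (GLCM settings).
#' @return a `feature_vector`.
#' @export
case_features <- function(case, scenario = c("combined", "calc", "mass"),
                          ...) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(case, "lesion_case"))
  if (scenario == "calc")
    return(microcalc_features(case$image, case$calc_mask))
  if (scenario == "mass")
    return(mass_features(case$image, case$mass_mask, ...))
  combined_features(microcalc_features(case$image, case$calc_mask),
                    mass_features(case$image, case$mass_mask, ...))
}
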