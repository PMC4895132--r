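# Plumbing detectors for phantom images.
#
# Deliberately simple, transparent stand-ins for a full segmentation
# pipeline: a white-top-hat bright-spot detector for microcalcifications
# and a blur + Otsu largest-component detector for masses. Both are pure
# functions of (image, parameters).

#' Detect microcalcifications by white top-hat filtering
#'
#' Enhances bright spots with a white top-hat transform (disc structuring
#' element), thresholds the response at `mean + k_sigma * SD`, restricts
#' candidates to pixels at least as bright as the global image mean (this
#' gate suppresses false positives in dark tissue), and removes connected
#' components outside the \[`min_area`, `max_area`\] range.
#'
#' @param image grayscale matrix (0--255).
#' @param top_hat_radius structuring-element radius in pixels (>= 1).
#' @param k_sigma threshold multiplier (>= 0).
#' @param min_area,max_area component area bounds in pixels.
#' @return binary 0/1 mask (possibly empty).
#' @export
detect_microcalcifications <- function(image, top_hat_radius = 7,
                                       k_sigma = 3, min_area = 2,
                                       max_area = 400) {
  check_image(image)
  if (top_hat_radius < 1) stop_input("top_hat_radius must be >= 1")
  if (k_sigma < 0) stop_input("k_sigma must be >= 0")
  if (min_area <= 0 || min_area > max_area)
    stop_input("need 0 < min_area <= max_area")
  brush <- EBImage::makeBrush(2 * as.integer(top_hat_radius) + 1, "disc")
  th <- EBImage::whiteTopHat(image / 255, brush)
  thr <- mean(th) + k_sigma * sd(as.vector(th))
  cand <- (th > thr & image >= mean(image)) * 1L
  lab <- label_matrix(cand)
  if (max(lab) == 0) return(matrix(0L, nrow(image), ncol(image)))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_area & sizes <= max_area)
  out <- matrix(0L, nrow(image), ncol(image))
  out[lab %in% keep] <- 1L
  out
}

#' Detect a mass by Gaussian blur and Otsu thresholding
#'
#' Blurs the image, applies Otsu's threshold and keeps the largest
#' 8-connected component if its area reaches `min_area`; otherwise returns
#' an empty mask.
#'
#' @param image grayscale matrix (0--255).
#' @param blur_sigma Gaussian sigma in pixels (>= 0; 0 skips blurring).
#' @param min_area minimum component area in pixels.
#' @return binary 0/1 mask that is a single connected component or empty.
#' @export
detect_mass <- function(image, blur_sigma = 12, min_area = 200) {
  check_image(image)
  if (blur_sigma < 0) stop_input("blur_sigma must be >= 0")
  b <- image / 255
  # cap sigma so the Gaussian kernel (~6 sigma wide) fits in the image
  blur_sigma <- min(blur_sigma, (min(dim(image)) - 1) %/% 7)
  if (blur_sigma > 0) b <- EBImage::gblur(b, sigma = blur_sigma)
  if (max(b) - min(b) < 1e-9)
    return(matrix(0L, nrow(image), ncol(image)))
  thr <- EBImage::otsu(b, range = range(b))
  lab <- label_matrix((b > thr) * 1L)
  out <- matrix(0L, nrow(image), ncol(image))
  if (max(lab) == 0) return(out)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  best <- which.max(sizes)
  if (sizes[best] < min_area) return(out)
  out[lab == best] <- 1L
  out
}

#' Dice overlap between two binary masks
#'
#' @param a,b binary matrices of equal dimensions.
#' @return `2|A∩B| / (|A|+|B|)`, or 0 when both masks are empty.
#' @export
dice_overlap <- function(a, b) {
  a <- check_mask(a); b <- check_mask(b, a)
  denom <- sum(a == 1) + sum(b == 1)
  if (denom == 0) return(0)
  2 * sum(a == 1 & b == 1) / denom
}
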