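# Gray-level co-occurrence matrix (GLCM) texture engine.
#
# Haralick-style statistics over a symmetric, normalized co-occurrence
# matrix accumulated at four offsets (0, 45, 90, 135 degrees) at a fixed
# pixel distance, restricted to pixel pairs that both lie inside the mask.
# Intensities are quantized per-mask (linear min-max) to G levels; all
# logarithms are base 2 with the 0*log(0) := 0 convention.

glcm_offsets <- function(distance) {
  d <- as.integer(distance)
  list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
}

#' Gray-level co-occurrence matrix over a masked region
#'
#' @param image grayscale matrix.
#' @param mask binary matrix, same dimensions; pairs are counted only when
#'   both pixels are inside the mask.
#' @param levels number of quantization levels G (>= 2).
#' @param distance pixel offset distance (>= 1).
#' @param offsets optional list of `c(drow, dcol)` offsets overriding the
#'   default symmetric 4-direction set (useful for hand-checked examples).
#' @return an object of class `glcm`: list with `matrix` (G x G, symmetric,
#'   summing to 1), `levels` and `offsets`.
#' @export
compute_glcm <- function(image, mask, levels = 16, distance = 1,
                         offsets = NULL) {
  check_image(image)
  mask <- check_mask(mask, image)
  G <- as.integer(levels)
  if (G < 2) stop_input("levels must be >= 2")
  if (distance < 1) stop_input("distance must be >= 1")
  if (is.null(offsets)) offsets <- glcm_offsets(distance)
  inside <- mask == 1
  if (sum(inside) < 2) stop_input("mask must cover at least 2 pixels")
  v <- image[inside]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi - lo < .Machine$double.eps) {
    q[inside] <- 0L
  } else {
    q[inside] <- pmin(G - 1L, as.integer(floor((image[inside] - lo) /
                                                 (hi - lo) * G)))
  }
  counts <- matrix(0, G, G)
  h <- nrow(image); w <- ncol(image)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    if (length(r1) == 0 || length(c1) == 0) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    idx <- a[keep] * G + b[keep] + 1L
    tab <- tabulate(idx, nbins = G * G)
    counts <- counts + matrix(tab, G, G, byrow = TRUE)
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0) stop_input("no valid in-mask pixel pair at this offset")
  structure(list(matrix = counts / tot, levels = G, offsets = offsets),
            class = "glcm")
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

#' Haralick texture statistics of a co-occurrence matrix
#'
#' Computes the classical statistics with logarithms in base 2. The
#' `correlation` of a degenerate (zero-variance) matrix is defined as 0,
#' and `mutual_information` is `H(row) + H(col) - H(joint)`.
#'
#' @param g a [compute_glcm()] result (or a bare normalized symmetric
#'   matrix).
#' @return named numeric vector with `energy`, `entropy`, `correlation`,
#'   `inverse_difference_moment`, `sum_average`, `sum_variance`,
#'   `difference_variance`, `difference_entropy`, `sum_entropy`,
#'   `contrast` and `mutual_information`.
#' @export
glcm_features <- function(g) {
  P <- if (inherits(g, "glcm")) g$matrix else g
  if (!is.matrix(P) || abs(sum(P) - 1) > 1e-6)
    stop_input("g must be a normalized co-occurrence matrix")
  G <- nrow(P)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_i <- sum((0:(G - 1)) * px); mu_j <- sum((0:(G - 1)) * py)
  sd_i <- sqrt(sum(((0:(G - 1)) - mu_i)^2 * px))
  sd_j <- sqrt(sum(((0:(G - 1)) - mu_j)^2 * py))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  } else 0
  # distributions of i+j (0..2G-2) and |i-j| (0..G-1)
  psum <- vapply(0:(2 * G - 2), function(k) sum(P[i + j == k]), numeric(1))
  pdif <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  sa <- sum((0:(2 * G - 2)) * psum)
  dmean <- sum((0:(G - 1)) * pdif)
  c(energy = sum(P^2),
    entropy = entropy_bits(P),
    correlation = corr,
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    sum_average = sa,
    sum_variance = sum(((0:(2 * G - 2)) - sa)^2 * psum),
    difference_variance = sum(((0:(G - 1)) - dmean)^2 * pdif),
    difference_entropy = entropy_bits(pdif),
    sum_entropy = entropy_bits(psum),
    contrast = sum((i - j)^2 * P),
    mutual_information = entropy_bits(px) + entropy_bits(py) -
      entropy_bits(P))
}
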