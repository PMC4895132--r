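# Connected components and per-component geometry.
#
# All geometry follows the pixel-square model: a component is the union of
# unit squares centered on its pixels. The perimeter is the crack-boundary
# length (count of exposed pixel edges), the convex hull is taken over the
# pixel-square corners (so a filled rectangle has solidity exactly 1), and
# the axes come from second central moments with the 1/12 per-pixel
# variance term, matching the ellipse-of-equal-moments convention.

# 8-connectivity label matrix. EBImage::bwlabel provides 4-connected
# labels; diagonally adjacent labels are merged with a union-find pass.
label_matrix <- function(mask) {
  mask <- check_mask(mask)
  if (!any(mask == 1)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab > 1L) {
    # pairs of distinct labels touching diagonally
    h <- nrow(lab); w <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nrow(pairs) > 0) {
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    lab[] <- c(0L, root)[lab + 1L]
  }
  # renumber deterministically by (top row, then left column) of bbox
  ids <- sort(unique(lab[lab > 0]))
  idx <- which(lab > 0, arr.ind = TRUE)
  v <- lab[lab > 0]
  top <- tapply(idx[, 1], v, min)
  left <- tapply(idx[, 2], v, min)
  ord <- order(top, left)
  remap <- integer(max(ids))
  remap[as.integer(names(top))[ord]] <- seq_along(ord)
  lab[lab > 0] <- remap[v]
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

#' Label 8-connected components of a binary mask
#'
#' @param mask binary matrix.
#' @return a list of binary component masks (same dimensions as `mask`),
#'   ordered by the top row, then left column, of each component's bounding
#'   box. An empty mask yields an empty list.
#' @export
label_components <- function(mask) {
  lab <- label_matrix(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) (lab == i) * 1L)
}

# Crack-boundary perimeter: 4*area minus twice the 4-adjacent pairs.
crack_perimeter <- function(mask) {
  a <- sum(mask == 1)
  horiz <- sum(mask[, -ncol(mask), drop = FALSE] == 1 &
                 mask[, -1, drop = FALSE] == 1)
  vert <- sum(mask[-nrow(mask), , drop = FALSE] == 1 &
                mask[-1, , drop = FALSE] == 1)
  4 * a - 2 * (horiz + vert)
}

# Convex hull quantities from a pixel index matrix (row, col).
# The convex PERIMETER is the perimeter of the hull polygon over the
# pixel-square corners (consistent with the crack-boundary perimeter, so
# convexity <= 1). The convex AREA is the pixel count of the rasterized
# hull of pixel CENTERS (the standard "convex image" convention): a
# filled rectangle then has solidity exactly 1 and a smooth digital
# ellipse is not penalized for boundary staircasing or the half-pixel
# corner band. Returns list(area, perimeter).
pixel_hull <- function(px) {
  corners <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] - 0.5, px[, 2] + 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  corners <- unique(corners)
  chc <- grDevices::chull(corners[, 2], corners[, 1])
  polyc <- corners[chc, , drop = FALSE]
  per <- sum(sqrt(rowSums((polyc[c(seq_len(nrow(polyc))[-1], 1), ,
                                 drop = FALSE] - polyc)^2)))
  area <- rasterized_hull_area(px)
  list(area = area, perimeter = per)
}

# Pixel count of the rasterized convex hull of pixel centers.
rasterized_hull_area <- function(px) {
  px <- unique(px)
  ch <- grDevices::chull(px[, 2], px[, 1])
  poly <- px[ch, , drop = FALSE]
  k <- nrow(poly)
  if (k < 3) return(nrow(px))            # point or collinear run
  y <- poly[, 1]; x <- poly[, 2]
  rr <- min(px[, 1]):max(px[, 1])
  cc <- min(px[, 2]):max(px[, 2])
  gy <- rep(rr, times = length(cc))
  gx <- rep(cc, each = length(rr))
  sgn <- sign(sum(x * y[c(2:k, 1)] - x[c(2:k, 1)] * y))  # orientation
  inside <- rep(TRUE, length(gy))
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cross <- (x[j] - x[i]) * (gy - y[i]) - (y[j] - y[i]) * (gx - x[i])
    inside <- inside & (sgn * cross >= -1e-9)
    if (!any(inside)) break
  }
  sum(inside)
}

# Moment-based axes: eigenvalues of the pixel-coordinate covariance plus
# the 1/12 pixel-extent term; axis length = 4*sqrt(eigenvalue).
moment_axes <- function(px) {
  n <- nrow(px)
  mu <- colMeans(px)
  d <- sweep(px, 2, mu)
  cc <- crossprod(d) / n + diag(1 / 12, 2)
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  list(major = 4 * sqrt(max(ev[1], 0)), minor = 4 * sqrt(max(ev[2], 1e-12)),
       centroid = mu)
}

#' Geometric descriptors of a single component
#'
#' @param mask binary matrix containing one non-empty component.
#' @return an object of class `component_geometry`: list with `area`,
#'   `perimeter` (crack-boundary length), `convex_area`,
#'   `convex_perimeter` (pixel-corner hull), `major_axis`, `minor_axis`
#'   (ellipse of equal second moments), `centroid` (row, col) and
#'   `equivalent_diameter` (`sqrt(4 area / pi)`).
#' @export
component_geometry <- function(mask) {
  mask <- check_mask(mask)
  px <- which(mask == 1, arr.ind = TRUE)
  if (nrow(px) == 0) stop_input("component is empty")
  area <- nrow(px)
  hull <- pixel_hull(px)
  ax <- moment_axes(px)
  structure(list(area = area,
                 perimeter = crack_perimeter(mask),
                 convex_area = max(hull$area, area),
                 convex_perimeter = hull$perimeter,
                 major_axis = ax$major, minor_axis = ax$minor,
                 centroid = ax$centroid,
                 equivalent_diameter = sqrt(4 * area / pi)),
            class = "component_geometry")
}

#' @export
print.component_geometry <- function(x, ...) {
  cat(sprintf(paste0("component: area=%d perim=%.1f solidity=%.3f ",
                     "axes=%.2f/%.2f eqd=%.2f\n"),
              x$area, x$perimeter, x$area / x$convex_area,
              x$major_axis, x$minor_axis, x$equivalent_diameter))
  invisible(x)
}

# Circularity 4*pi*A/P^2 with the standard 4/pi crack-length bias
# correction (an axis-aligned digital disc has crack perimeter 8r, not
# 2*pi*r), clamped to [0, 1] so compact convex shapes score ~1.
shape_circularity <- function(geom) {
  p <- geom$perimeter * pi / 4
  if (p <= 0) return(0)
  min(4 * pi * geom$area / p^2, 1)
}
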