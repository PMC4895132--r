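# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Co-occurrence by explicit enumeration of all in-mask pixel pairs.
glcm_bruteforce <- function(image, mask, levels, offsets) {
  inside <- mask == 1
  v <- image[inside]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi - lo < .Machine$double.eps) {
    q[inside] <- 0L
  } else {
    q[inside] <- pmin(levels - 1L,
                      as.integer(floor((image[inside] - lo) / (hi - lo) *
                                         levels)))
  }
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(image))) for (cc in seq_len(ncol(image))) {
    if (!inside[r, cc]) next
    for (off in offsets) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(image) && c2 >= 1 && c2 <= ncol(image) &&
          inside[r2, c2]) {
        counts[q[r, cc] + 1L, q[r2, c2] + 1L] <-
          counts[q[r, cc] + 1L, q[r2, c2] + 1L] + 1
      }
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

# AUC as the Mann-Whitney pair-counting statistic (ties count one half).
auc_pair_counting <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Central finite differences of a scalar function of one parameter block.
finite_diff <- function(f, v, eps = 1e-6) {
  g <- v
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    g[i] <- (f(vp) - f(vm)) / (2 * eps)
  }
  g
}

# 90-degree rotation of a matrix (counter-clockwise).
rot90m <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
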