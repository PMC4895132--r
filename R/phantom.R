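# Synthetic lesion phantom generator.
#
# Produces mammogram-like 8-bit grayscale rasters with ground-truth
# microcalcification and mass masks, plus simulated feature tables with a
# known (linear or XOR) class structure. These phantoms emulate the
# statistical setting of a clinical benign/malignant discrimination study
# without any patient data: benign cases draw sparse, round calcifications
# and smooth masses; malignant cases draw numerous, elongated/irregular
# calcifications and spiculated masses.

#' Phantom specification
#'
#' Describes one synthetic case: image geometry, background texture, the
#' class-conditional morphology of the inserted microcalcification cluster
#' and mass, and the class label.
#'
#' @param width,height image size in pixels (>= 32).
#' @param background_smoothness standard deviation (pixels) of the Gaussian
#'   low-pass filter applied to the white-noise background; 0 gives i.i.d.
#'   per-pixel noise.
#' @param calc_count_range integer interval `c(lo, hi)` for the number of
#'   microcalcifications (lo <= hi, both >= 0).
#' @param calc_diameter_range diameter interval in pixels, within \[1, 20\]
#'   (emulating the 0.1--1 mm scale of clinical microcalcifications).
#' @param calc_shape_mix proportions of round/elongated/irregular primitives,
#'   non-negative, summing to 1.
#' @param mass_present logical; insert a mass?
#' @param mass_axes semi-axes `c(a, b)` of the mass ellipse in pixels.
#' @param mass_spiculation_level non-negative; 0 gives a smooth filled
#'   ellipse, larger values add more/larger radial spicules.
#' @param contrast_boost peak added intensity (gray levels) of a
#'   microcalcification; the mass uses 60\% of it.
#' @param label 0 (benign) or 1 (malignant).
#' @return an object of class `phantom_spec`.
#' @seealso [generate_case()] for class-conditional defaults.
#' @export
phantom_spec <- function(width = 256, height = 256,
                         background_smoothness = 2,
                         calc_count_range = c(3, 8),
                         calc_diameter_range = c(2, 9),
                         calc_shape_mix = c(round = 0.8, elongated = 0.1,
                                            irregular = 0.1),
                         mass_present = TRUE,
                         mass_axes = c(40, 25),
                         mass_spiculation_level = 0,
                         contrast_boost = 230,
                         label = 0L) {
  if (width < 32 || height < 32)
    stop_input("image dimensions must be at least 32 pixels")
  if (background_smoothness < 0)
    stop_input("background_smoothness must be >= 0")
  if (length(calc_count_range) != 2 || any(calc_count_range < 0) ||
      calc_count_range[1] > calc_count_range[2])
    stop_input("calc_count_range must be a non-degenerate interval >= 0")
  if (length(calc_diameter_range) != 2 ||
      calc_diameter_range[1] < 1 || calc_diameter_range[2] > 20 ||
      calc_diameter_range[1] > calc_diameter_range[2])
    stop_input("calc_diameter_range must lie within [1, 20] with lo <= hi")
  if (length(calc_shape_mix) != 3 || any(calc_shape_mix < 0) ||
      abs(sum(calc_shape_mix) - 1) > 1e-9)
    stop_input("calc_shape_mix must be 3 proportions summing to 1")
  if (length(mass_axes) != 2 || any(mass_axes <= 0))
    stop_input("mass_axes must be two positive semi-axes")
  if (mass_spiculation_level < 0)
    stop_input("mass_spiculation_level must be >= 0")
  if (contrast_boost <= 0 || contrast_boost > 255)
    stop_input("contrast_boost must be in (0, 255]")
  label <- check_labels(label, "label")
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_smoothness = background_smoothness,
                 calc_count_range = as.integer(calc_count_range),
                 calc_diameter_range = calc_diameter_range,
                 calc_shape_mix = stats::setNames(as.numeric(calc_shape_mix),
                                                  c("round", "elongated",
                                                    "irregular")),
                 mass_present = isTRUE(mass_present),
                 mass_axes = as.numeric(mass_axes),
                 mass_spiculation_level = mass_spiculation_level,
                 contrast_boost = contrast_boost,
                 label = label),
            class = "phantom_spec")
}

#' Class-conditional default phantom specification
#'
#' Benign cases: 3--8 mostly round calcifications and a smooth mass.
#' Malignant cases: 8--25 calcifications with a 60\% elongated/irregular
#' shape mix and a spiculated mass (level 4). These defaults produce the
#' qualitative benign/malignant morphology contrast that the lesion
#' features are designed to capture.
#'
#' @param label 0 (benign) or 1 (malignant).
#' @param ... overrides passed on to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
phantom_spec_default <- function(label, ...) {
  label <- check_labels(label, "label")
  args <- if (label == 1L) {
    list(calc_count_range = c(8, 25),
         calc_shape_mix = c(round = 0.4, elongated = 0.3, irregular = 0.3),
         mass_spiculation_level = 4, label = 1L)
  } else {
    list(calc_count_range = c(3, 8),
         calc_shape_mix = c(round = 0.8, elongated = 0.1, irregular = 0.1),
         mass_spiculation_level = 0, label = 0L)
  }
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

#' Generate a smooth random background
#'
#' White Gaussian noise low-passed with a Gaussian kernel and affinely
#' rescaled to the 8-bit range. The smoothing parameter controls the spatial
#' autocorrelation of the background, which in turn drives the co-occurrence
#' texture of overlaid lesions. The rescaled range is \[0, 250\], leaving
#' headroom so inserted lesions remain strictly brighter than the tissue
#' they cover.
#'
#' @param width,height image size in pixels (>= 32).
#' @param smoothness Gaussian sigma in pixels (>= 0; 0 skips smoothing).
#' @param seed integer seed; the output is bit-reproducible.
#' @return a `height` x `width` numeric matrix with integer values in
#'   \[0, 250\].
#' @export
generate_background <- function(width, height, smoothness = 8, seed = 1) {
  if (length(width) != 1 || length(height) != 1 || width < 32 || height < 32)
    stop_input("width and height must be >= 32")
  if (smoothness < 0) stop_input("smoothness must be >= 0")
  with_seed(seed, {
    z <- matrix(rnorm(width * height), nrow = height, ncol = width)
    # cap sigma so the Gaussian kernel (~6 sigma wide) fits in the image
    smoothness <- min(smoothness, (min(width, height) - 1) %/% 7)
    if (smoothness > 0) z <- EBImage::gblur(z, sigma = smoothness)
    rng <- range(z)
    if (rng[2] - rng[1] < .Machine$double.eps)
      return(matrix(125, nrow = height, ncol = width))
    round((z - rng[1]) / (rng[2] - rng[1]) * 250)
  })
}

# Add a soft intensity bump to an image. Calcifications are additive with
# a hard 255 clip (they saturate, as clinical microcalcifications do);
# masses use a multiplicative ceiling out = in + (255-in)*stamp*boost/255
# that compresses smoothly and never reaches 255. Either way the output
# strictly exceeds the input wherever stamp > 0, provided the input is
# below 255 there (generated backgrounds are capped at 250 for this
# reason, and the mass ceiling keeps its pixels below 255).
add_bump <- function(image, stamp, boost, row0, col0,
                     mode = c("additive", "ceiling")) {
  mode <- match.arg(mode)
  h <- nrow(stamp); w <- ncol(stamp)
  rows <- row0:(row0 + h - 1L); cols <- col0:(col0 + w - 1L)
  sub <- image[rows, cols]
  image[rows, cols] <- if (mode == "additive") {
    pmin(sub + stamp * boost, 255)
  } else {
    sub + (255 - sub) * clamp(stamp * boost / 255, 0, 1)
  }
  image
}

# Soft (anti-aliased) stamps on a patch grid centered at the patch middle.
# Values in [0,1]; the truth mask is stamp >= 0.5. All are star-shaped about
# the center so their binarization is connected.
stamp_grid <- function(half) {
  n <- 2L * half + 1L
  dy <- matrix(rep(-half:half, n), nrow = n)
  dx <- t(dy)
  list(n = n, dy = dy, dx = dx, rho = sqrt(dy^2 + dx^2),
       theta = atan2(dy, dx))
}

stamp_round <- function(diameter) {
  r <- diameter / 2
  g <- stamp_grid(as.integer(ceiling(r)) + 2L)
  clamp(r - g$rho + 0.5, 0, 1)
}

stamp_elongated <- function(diameter, axis_ratio, phi) {
  a <- max(diameter / 2, 3)           # major semi-axis; floor keeps thin
  b <- max(a / axis_ratio, 0.45)      # stamps measurable after binarization
  # redraw the orientation until the binarized stamp measures as
  # elongated; discretization can shorten thin stamps at some angles
  for (try in 1:25) {
    g <- stamp_grid(as.integer(ceiling(a)) + 2L)
    xr <- g$dx * cos(phi) + g$dy * sin(phi)
    yr <- -g$dx * sin(phi) + g$dy * cos(phi)
    rho_e <- sqrt((xr / a)^2 + (yr / b)^2)
    v <- clamp((1 - rho_e) * b + 0.5, 0, 1)
    px <- which(v >= 0.5, arr.ind = TRUE)
    if (nrow(px) >= 2) {
      ax <- moment_axes(px)
      if (ax$major / ax$minor >= 2.05) return(v)
    }
    phi <- runif(1, 0, pi)
    a <- a + 0.35                      # gently lengthen if still stubby
  }
  v
}

stamp_irregular <- function(diameter, harmonics) {
  r <- max(diameter / 2, 1.2)
  g <- stamp_grid(as.integer(ceiling(r * 1.6)) + 2L)
  pert <- rep(0, length(g$theta))
  for (k in seq_along(harmonics$amp)) {
    pert <- pert + harmonics$amp[k] *
      cos((k + 1) * g$theta + harmonics$phase[k])
  }
  rb <- r * clamp(1 + pert, 0.45, 1.6)
  clamp(rb - g$rho + 0.5, 0, 1)
}

# Grow a logical patch by one pixel in 8-connectivity.
grow1 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(FALSE, n + 2L, p + 2L)
  out <- matrix(FALSE, n + 2L, p + 2L)
  pad[2:(n + 1), 2:(p + 1)] <- m
  for (dr in -1:1) for (dc in -1:1) {
    out[(2 + dr):(n + 1 + dr), (2 + dc):(p + 1 + dc)] <-
      out[(2 + dr):(n + 1 + dr), (2 + dc):(p + 1 + dc)] | pad[2:(n + 1), 2:(p + 1)]
  }
  out
}

#' Insert clustered microcalcifications into an image
#'
#' Draws a calcification count from `spec$calc_count_range`, then places
#' that many anti-aliased primitives (discs, elongated ellipses with axis
#' ratio in \[2, 5\], or irregular radially perturbed blobs, mixed per
#' `spec$calc_shape_mix`) inside a cluster disc of radius 1/6 of the image
#' min-dimension around a random center. Placement is non-overlapping by
#' rejection sampling (at most 1000 attempts per calcification); accepted
#' primitives are kept at least one pixel apart so the truth mask has
#' exactly the drawn number of 8-connected components.
#'
#' @param image grayscale matrix (values in \[0, 255\]).
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return `list(image =, mask =)`: the image with added intensity bumps
#'   (every mask pixel strictly brighter than before) and the binary truth
#'   mask.
#' @export
insert_microcalcifications <- function(image, spec, seed = 1) {
  check_image(image)
  stopifnot(inherits(spec, "phantom_spec"))
  dmax <- spec$calc_diameter_range[2]
  half_max <- as.integer(ceiling(max(dmax / 2, 2.2) * 1.6)) + 2L
  if (2L * half_max + 1L > min(dim(image)))
    stop_input("requested calcification diameter does not fit in the image")
  mask <- matrix(0L, nrow(image), ncol(image))
  with_seed(seed, {
    lo <- spec$calc_count_range[1]; hi <- spec$calc_count_range[2]
    n <- lo + floor(runif(1) * (hi - lo + 1))
    n <- min(n, hi)
    if (n == 0) return(list(image = image, mask = mask))
    h <- nrow(image); w <- ncol(image)
    rad <- min(h, w) / 6
    m <- half_max + 1L
    cy <- runif(1, min = m + rad, max = h - m - rad)
    cx <- runif(1, min = m + rad, max = w - m - rad)
    occ <- matrix(FALSE, h, w)
    placed <- 0L
    while (placed < n) {
      ok <- FALSE
      for (attempt in seq_len(1000)) {
        ang <- runif(1, 0, 2 * pi); rr <- rad * sqrt(runif(1))
        py <- as.integer(round(cy + rr * sin(ang)))
        px <- as.integer(round(cx + rr * cos(ang)))
        d <- runif(1, spec$calc_diameter_range[1], spec$calc_diameter_range[2])
        u <- runif(1); cum <- cumsum(spec$calc_shape_mix)
        stamp <- if (u <= cum[1]) {
          stamp_round(d)
        } else if (u <= cum[2]) {
          stamp_elongated(d, runif(1, 2, 5), runif(1, 0, pi))
        } else {
          stamp_irregular(d, list(amp = runif(4, 0.05, 0.18),
                                  phase = runif(4, 0, 2 * pi)))
        }
        half <- (nrow(stamp) - 1L) %/% 2L
        r0 <- py - half; c0 <- px - half
        if (r0 < 1L || c0 < 1L || r0 + 2L * half > h || c0 + 2L * half > w)
          next
        sel <- stamp >= 0.5
        if (!any(sel)) next
        rows <- r0:(r0 + 2L * half); cols <- c0:(c0 + 2L * half)
        if (any(occ[rows, cols] & sel)) next
        image <- add_bump(image, stamp, spec$contrast_boost, r0, c0)
        mask[rows, cols][sel] <- 1L
        gr <- grow1(sel)
        rows2 <- max(1L, r0 - 1L):min(h, r0 + 2L * half + 1L)
        cols2 <- max(1L, c0 - 1L):min(w, c0 + 2L * half + 1L)
        occ[rows2, cols2] <- occ[rows2, cols2] |
          gr[rows2 - (r0 - 2L), cols2 - (c0 - 2L)]
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok)
        stop_input("could not place calcification without overlap after ",
                   "1000 attempts")
    }
    list(image = image, mask = mask)
  })
}

#' Insert a (possibly spiculated) mass into an image
#'
#' The mass is a filled ellipse with semi-axes `spec$mass_axes` at a random
#' center and orientation. For `mass_spiculation_level > 0`, narrow radial
#' spicules (3 per level, with amplitude proportional to the level) are
#' added to the boundary radius, lowering the solidity of the truth mask; a
#' level of 0 yields a smooth ellipse with solidity >= 0.98. Intensity is
#' added as a soft dome (brightest at the center) with peak contrast 60\%
#' of `spec$contrast_boost`.
#'
#' @inheritParams insert_microcalcifications
#' @return `list(image =, mask =)` with a single-component binary mask
#'   (empty if `spec$mass_present` is `FALSE`).
#' @export
insert_mass <- function(image, spec, seed = 1) {
  check_image(image)
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- matrix(0L, nrow(image), ncol(image))
  if (!spec$mass_present) return(list(image = image, mask = mask))
  a <- max(spec$mass_axes); b <- min(spec$mass_axes)
  lvl <- spec$mass_spiculation_level
  half <- as.integer(ceiling(a * (1 + 0.12 * lvl))) + 3L
  h <- nrow(image); w <- ncol(image)
  if (2L * half + 1L > min(h, w))
    stop_input("mass axes too large for the image")
  with_seed(seed, {
    phi <- runif(1, 0, pi)
    py <- as.integer(round(runif(1, half + 1, h - half)))
    px <- as.integer(round(runif(1, half + 1, w - half)))
    g <- stamp_grid(half)
    xr <- g$dx * cos(phi) + g$dy * sin(phi)
    yr <- -g$dx * sin(phi) + g$dy * cos(phi)
    th <- atan2(yr, xr)
    re <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    spic <- 0
    n_spic <- round(3 * lvl)
    if (n_spic > 0) {
      centers <- runif(n_spic, -pi, pi)
      amps <- 0.08 * lvl * runif(n_spic, 0.7, 1.3)
      widths <- runif(n_spic, 0.035, 0.06)
      spic <- rep(0, length(th))
      for (k in seq_len(n_spic)) {
        dth <- (th - centers[k] + pi) %% (2 * pi) - pi
        spic <- spic + amps[k] * exp(-0.5 * (dth / widths[k])^2)
      }
    }
    rb <- re * (1 + spic)
    edge <- clamp(rb - g$rho + 0.5, 0, 1)
    dome <- 0.35 + 0.65 * clamp(1 - (g$rho / rb)^2, 0, 1)
    stamp <- edge * dome
    sel <- edge >= 0.5
    # keep the largest 8-connected component; spicule tips can pinch off
    # isolated pixels under discretization
    lab <- label_matrix(sel * 1L)
    if (max(lab) > 1L) {
      sizes <- tabulate(lab[lab > 0L])
      sel <- lab == which.max(sizes)
    }
    image <- add_bump(image, stamp, 0.6 * spec$contrast_boost,
                      py - half, px - half, mode = "ceiling")
    rows <- (py - half):(py + half); cols <- (px - half):(px + half)
    mask[rows, cols][sel] <- 1L
    list(image = image, mask = mask)
  })
}

#' Generate a complete synthetic lesion case
#'
#' Builds a background, inserts a microcalcification cluster and a mass
#' using the class-conditional defaults of [phantom_spec_default()] (or a
#' supplied specification), and returns the case with its ground truth.
#'
#' @param label 0 (benign) or 1 (malignant).
#' @param seed integer seed; the case is fully reproducible.
#' @param spec optional [phantom_spec()] overriding the class defaults.
#' @return an object of class `lesion_case`: list with `image`,
#'   `calc_mask`, `mass_mask`, `label`, `truth` (the spec) and `n_calcs`
#'   (the drawn calcification count).
#' @export
generate_case <- function(label, seed = 1, spec = NULL) {
  label <- check_labels(label, "label")
  if (is.null(spec)) spec <- phantom_spec_default(label)
  stopifnot(inherits(spec, "phantom_spec"))
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  img <- generate_background(spec$width, spec$height,
                             spec$background_smoothness, sub[1])
  ms <- insert_mass(img, spec, sub[2])
  cs <- insert_microcalcifications(ms$image, spec, sub[3])
  cs$image <- round(cs$image)   # 8-bit quantization for lossless file IO
  structure(list(image = cs$image, calc_mask = cs$mask,
                 mass_mask = ms$mask, label = label, truth = spec,
                 n_calcs = max(label_matrix(cs$mask)), seed = seed),
            class = "lesion_case")
}

#' @export
print.lesion_case <- function(x, ...) {
  cat(sprintf("lesion_case: %dx%d, label=%d, %d calcifications, mass=%s\n",
              nrow(x$image), ncol(x$image), x$label, x$n_calcs,
              if (any(x$mass_mask == 1)) "yes" else "no"))
  invisible(x)
}

#' Simulate a feature table with known class structure
#'
#' Draws a case-by-feature matrix with the canonical 15/26/41 feature names
#' and a binary label vector. Two informative dimensions (the first two
#' columns) carry the class signal; the remaining columns are uninformative
#' Gaussian noise with half the informative standard deviation, so that
#' distance-based classifiers retain the signal among many noise axes.
#'
#' \describe{
#'   \item{`linear`}{class means on the informative dimensions differ by
#'     `effect` times their (unit) standard deviation; linearly separable
#'     for large `effect`.}
#'   \item{`xor`}{each case draws signs `s1, s2` with the class equal to
#'     the XOR of the signs; cluster centers sit at `±effect/2`. The two
#'     classes have identical means, so the problem is linearly
#'     inseparable by construction.}
#' }
#'
#' @param n number of cases (>= 20, even).
#' @param dims 15, 26 or 41 (the calc / mass / combined schemas).
#' @param structure `"linear"` or `"xor"`.
#' @param effect non-negative class separation in units of the informative
#'   standard deviation; 0 gives no signal.
#' @param seed integer seed.
#' @param malignant_fraction fraction of cases with label 1 (default 0.5,
#'   i.e. balanced classes).
#' @return `list(x =, y =)`: an `n` x `dims` named matrix and an integer
#'   0/1 label vector.
#' @export
simulate_feature_table <- function(n, dims, structure = c("linear", "xor"),
                                   effect = 1, seed = 1,
                                   malignant_fraction = 0.5) {
  structure <- match.arg(structure)
  if (n < 20 || n %% 2 != 0) stop_input("n must be even and >= 20")
  if (effect < 0) stop_input("effect must be >= 0")
  if (!dims %in% c(15, 26, 41))
    stop_input("dims must be one of 15 (calc), 26 (mass), 41 (combined)")
  nms <- switch(as.character(dims),
                "15" = calc_feature_names(),
                "26" = mass_feature_names(),
                "41" = combined_feature_names())
  with_seed(seed, {
    n1 <- round(n * malignant_fraction)
    y <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    x <- matrix(rnorm(n * dims, sd = 0.5), nrow = n, ncol = dims)
    x[, 1:2] <- rnorm(n * 2)
    if (structure == "linear") {
      x[y == 1L, 1:2] <- x[y == 1L, 1:2] + effect
    } else {
      s1 <- sample(c(-1, 1), n, replace = TRUE)
      s2 <- ifelse(y == 1L, s1, -s1)
      x[, 1] <- x[, 1] + s1 * effect / 2
      x[, 2] <- x[, 2] + s2 * effect / 2
    }
    colnames(x) <- nms
    list(x = x, y = y)
  })
}
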