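# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) {
  stop(structure(class = c("mammocad_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("mammocad_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("mammocad_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Validate a grayscale image matrix (numeric, values in [0, 255]).
check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_input(arg, " must be a numeric matrix")
  if (anyNA(image) || any(!is.finite(image)))
    stop_input(arg, " contains non-finite values")
  invisible(image)
}

# Validate and coerce a binary mask to an integer 0/1 matrix.
check_mask <- function(mask, dim_ref = NULL, arg = "mask") {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || !is.numeric(mask))
    stop_input(arg, " must be a binary matrix")
  if (!all(mask %in% c(0, 1)))
    stop_input(arg, " values must be 0 or 1")
  if (!is.null(dim_ref) && !identical(dim(mask), dim(dim_ref)))
    stop_input(arg, " dimensions must match the image")
  mask
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stable binary 0/1 coercion for labels.
check_labels <- function(y, arg = "y") {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop_input(arg, " must contain only 0 (benign) and 1 (malignant)")
  y
}
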