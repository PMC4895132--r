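# Readers/writers for images, masks, feature tables, case manifests and
# serialized classifiers.
#
# Images are 8-bit grayscale PNG or TIFF; masks are 0/255 single-channel
# PNG (loaded back to 0/1) so they are viewable in any image tool; feature
# tables are UTF-8 CSV with a mandatory header; models are a versioned
# JSON container (arrays as nested lists) rather than a language-native
# serialization, so they are portable and tamper-checkable.

image_writer <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG,
         tif = tiff::writeTIFF, tiff = tiff::writeTIFF,
         stop_format("unsupported image extension: ", ext))
}

#' Write / read an 8-bit grayscale image
#'
#' @param image numeric matrix with values in \[0, 255\] (rounded to
#'   integers on write).
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_gray_image` returns a numeric matrix of integers in
#'   \[0, 255\]; `write_gray_image` returns `path` invisibly.
#' @export
write_gray_image <- function(image, path) {
  check_image(image)
  if (min(image) < 0 || max(image) > 255)
    stop_input("image values must lie in [0, 255]")
  image_writer(path)(round(image) / 255, path)
  invisible(path)
}

#' @rdname write_gray_image
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_io("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = tiff::readTIFF(path), tiff = tiff::readTIFF(path),
                stop_format("unsupported image extension: ", ext))
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    chans <- lapply(seq_len(min(ch, 3)), function(k) arr[, , k])
    if (!all(vapply(chans[-1], function(m)
      isTRUE(all.equal(m, chans[[1]])), logical(1))))
      stop_format("multi-channel image with unequal channels: ", path)
    arr <- chans[[1]]
  }
  round(arr * 255)
}

#' Write / read a binary mask as a 0/255 grayscale PNG
#'
#' @param mask binary matrix.
#' @param path file path.
#' @return `read_mask` returns an integer 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- check_mask(mask)
  write_gray_image(mask * 255, path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  matrix(as.integer(img > 127), nrow(img), ncol(img))
}

#' Write generated cases and their manifest
#'
#' Saves each case as `<stem>_img.png`, `<stem>_calc.png` and
#' `<stem>_mass.png` under `dir` and writes `manifest.csv` with columns
#' `case_id, label, image_path, calc_mask_path, mass_mask_path, seed`.
#'
#' @param cases list of `lesion_case` objects.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly; also written as
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_cases <- function(cases, dir) {
  stopifnot(all(vapply(cases, inherits, logical(1), "lesion_case")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    stem <- sprintf("case_%04d", i)
    paths <- file.path(dir, paste0(stem, c("_img.png", "_calc.png",
                                           "_mass.png")))
    write_gray_image(cs$image, paths[1])
    write_mask(cs$calc_mask, paths[2])
    write_mask(cs$mass_mask, paths[3])
    data.frame(case_id = stem, label = cs$label, image_path = paths[1],
               calc_mask_path = paths[2], mass_mask_path = paths[3],
               seed = cs$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read and validate a case manifest
#'
#' @param path path to a manifest CSV written by [write_cases()].
#' @return data frame with unique `case_id`, binary `label` and existing
#'   file paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "label", "image_path", "calc_mask_path",
            "mass_mask_path", "seed")
  if (!all(need %in% names(m)))
    stop_format("manifest is missing columns: ",
                paste(setdiff(need, names(m)), collapse = ", "))
  if (anyDuplicated(m$case_id)) stop_format("duplicate case_id in manifest")
  m$label <- check_labels(m$label, "label")
  for (col in c("image_path", "calc_mask_path", "mass_mask_path")) {
    missing <- !file.exists(m[[col]])
    if (any(missing))
      stop_io("missing file referenced by manifest: ",
              m[[col]][which(missing)[1]])
  }
  m
}

#' Write / read a feature table CSV
#'
#' The CSV has a header `case_id, label, <feature names...>`; labels must
#' be 0/1 and every feature cell numeric.
#'
#' @param x numeric feature matrix with column names.
#' @param y binary labels, one per row.
#' @param path output CSV path.
#' @param case_id optional case identifiers (default `case_0001`, ...).
#' @return `read_feature_table` returns `list(x =, y =, names =)` with
#'   column order preserved.
#' @export
write_feature_table <- function(x, y, path, case_id = NULL) {
  if (is.null(colnames(x))) stop_input("feature matrix must have colnames")
  y <- check_labels(y)
  if (length(y) != nrow(x)) stop_input("labels must match rows")
  if (is.null(case_id)) case_id <- sprintf("case_%04d", seq_len(nrow(x)))
  df <- data.frame(case_id = case_id, label = y, x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_io("feature table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  if (!all(c("case_id", "label") %in% names(df)))
    stop_format("feature table must have case_id and label columns")
  feat_cols <- setdiff(names(df), c("case_id", "label"))
  if (length(feat_cols) == 0)
    stop_format("feature table has no feature columns")
  lab <- suppressWarnings(as.numeric(df$label))
  if (anyNA(lab) || !all(lab %in% c(0, 1)))
    stop_format("label column must contain only 0 and 1")
  x <- matrix(NA_real_, nrow(df), length(feat_cols),
              dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(df[[feat_cols[j]]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_format("non-numeric feature value at row ", bad, ", column '",
                  feat_cols[j], "'")
    }
    x[, j] <- v
  }
  list(x = x, y = as.integer(lab), names = feat_cols)
}

#' Save / load a trained stacked-autoencoder classifier
#'
#' Serializes all layer weights, biases, the softmax parameters, the
#' feature-name order, the input scaler, the training configuration and
#' the seed into a versioned JSON file. The roundtrip is lossless (weights
#' are written at full double precision).
#'
#' @param model an `sae_classifier` from [sae_train()].
#' @param path JSON file path.
#' @return `load_model` returns the restored `sae_classifier`;
#'   `save_model` returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sae_classifier"))
  obj <- list(
    version = "1.0",
    layer_sizes = model$layer_sizes,
    weights = lapply(model$layers, function(p)
      list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2)),
    softmax = list(W = model$softmax_W, b = model$softmax_b),
    scaler = list(min = model$scaler$min, range = model$scaler$range),
    feature_names = model$feature_names,
    config = unclass(model$train_config),
    seed = model$train_config$seed)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop_format("corrupted model file: ",
                                                  conditionMessage(e)))
  if (is.null(obj$version) || !identical(obj$version, "1.0"))
    stop_format("unsupported model file version")
  sizes <- as.integer(obj$layer_sizes)
  layers <- lapply(obj$weights, function(p) {
    list(W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
         W2 = as.matrix(p$W2), b2 = as.numeric(p$b2))
  })
  for (k in seq_along(layers)) {
    p <- layers[[k]]
    if (!identical(dim(p$W1), c(sizes[k + 1L], sizes[k])) ||
        length(p$b1) != sizes[k + 1L] ||
        !identical(dim(p$W2), c(sizes[k], sizes[k + 1L])) ||
        length(p$b2) != sizes[k])
      stop_format("model file dimensions are inconsistent at layer ", k)
  }
  W <- as.matrix(obj$softmax$W)
  if (!identical(dim(W), c(2L, sizes[length(sizes)])) ||
      length(obj$softmax$b) != 2)
    stop_format("model file softmax dimensions are inconsistent")
  cfg <- do.call(train_config, obj$config[names(obj$config) %in%
                                            names(formals(train_config))])
  structure(list(layers = layers, softmax_W = W,
                 softmax_b = as.numeric(obj$softmax$b),
                 layer_sizes = sizes,
                 scaler = list(min = as.numeric(obj$scaler$min),
                               range = as.numeric(obj$scaler$range)),
                 feature_names = as.character(obj$feature_names),
                 train_config = cfg),
            class = "sae_classifier")
}
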