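# Image and mask I/O plus the benchmark manifest.
#
# Canonical in-memory form: a plain numeric matrix (H x W) with values in
# [0, 1], carrying attributes "source_path" and "bit_depth_origin"
# ("8", "16" or "float"). All package functions accept plain matrices.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop_autoqc("unsupported image format for '", path, "' (use TIFF or PNG)")
}

collapse_gray <- function(x) {
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    if (nc == 2L || nc == 4L) nc <- nc - 1L  # drop alpha channel
    x <- apply(x[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  x
}

#' Load a grayscale microscopy image
#'
#' Reads an 8/16-bit or float TIFF, or an 8/16-bit PNG, converts
#' multi-channel data to grayscale by the channel mean, and normalizes
#' intensities to the canonical \[0, 1\] range: integer images are divided by
#' the dtype maximum (255 or 65535); float images are min-max scaled per
#' image (which discards absolute-intensity information — see the methods
#' vignette).
#'
#' @param path Path to a TIFF or PNG file.
#' @param normalize If `FALSE`, raw stored values are returned instead of
#'   the canonical \[0, 1\] frame.
#' @return A numeric matrix (H x W) with attributes `source_path` and
#'   `bit_depth_origin` (one of `"8"`, `"16"`, `"float"`).
#' @export
load_image <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop_autoqc("cannot read image: '", path, "'")
  fmt <- img_format(path)
  if (fmt == "tiff") {
    x <- tryCatch(tiff::readTIFF(path), error = function(e)
      stop_autoqc("failed to read TIFF '", path, "': ", conditionMessage(e)))
    meta <- tiff::readTIFF(path, payload = FALSE)
    bps <- meta$bits.per.sample %||% 8L
    is_float <- identical(meta$sample.format, "float") || bps > 16L
    depth <- if (is_float) "float" else as.character(bps)
  } else {
    x <- tryCatch(png::readPNG(path, info = TRUE), error = function(e)
      stop_autoqc("failed to read PNG '", path, "': ", conditionMessage(e)))
    info <- attr(x, "info")
    depth <- as.character(info$bit.depth %||% 8L)
    is_float <- FALSE
    bps <- info$bit.depth %||% 8L
  }
  x <- collapse_gray(unclass(x))
  attributes(x) <- list(dim = dim(x))
  if (is_float) {
    if (normalize) {
      rng <- range(x)
      if (diff(rng) == 0)
        stop_autoqc("degenerate float image (zero dynamic range): '", path, "'")
      x <- (x - rng[1]) / diff(rng)
    }
  } else if (!normalize) {
    # readers return value / (2^bps - 1); undo to recover stored integers
    x <- round(x * (2^bps - 1))
  }
  attr(x, "source_path") <- path
  attr(x, "bit_depth_origin") <- depth
  x
}

#' Save an image in the canonical \[0, 1\] frame
#'
#' @param pixels Numeric matrix with values in \[0, 1\] (clipped on write).
#' @param path Output TIFF or PNG path.
#' @param bits Bit depth: 8 or 16 for integer output; 32 writes a float TIFF
#'   (TIFF only), used for score maps.
#' @export
save_image <- function(pixels, path, bits = 8L) {
  fmt <- img_format(path)
  x <- clip01(unname(as.matrix(pixels)))
  if (fmt == "tiff") {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  } else {
    if (bits > 16L) stop_autoqc("PNG output supports 8 or 16 bits only")
    png::writePNG(x, path)
  }
  invisible(path)
}

#' Save a binary anomaly mask
#'
#' Writes an 8-bit single-channel image with anomalous pixels stored as 255
#' and background as 0. A saved mask round-trips bit-exactly through
#' [load_mask()].
#'
#' @param mask Binary (0/1) matrix.
#' @param path Output TIFF or PNG path.
#' @export
save_mask <- function(mask, path) {
  m <- unname(as.matrix(mask))
  if (!all(m %in% c(0, 1))) stop_autoqc("mask values must be 0/1")
  save_image(m, path, bits = 8L)
}

#' Load a binary anomaly mask
#'
#' Reads an image written with 0/255 mask semantics and returns a 0/1
#' matrix (any pixel above half intensity counts as anomalous).
#'
#' @param path Mask image path.
#' @export
load_mask <- function(path) {
  x <- load_image(path)
  m <- (unclass(x) > 0.5) * 1
  attributes(m) <- list(dim = dim(m))
  attr(m, "source_path") <- path
  m
}

## ---- manifest ---------------------------------------------------------

list_images <- function(dir) {
  if (!dir.exists(dir)) return(character(0))
  sort(list.files(dir, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                  full.names = TRUE))
}

match_masks <- function(images, mask_dir, context) {
  if (length(images) == 0) return(character(0))
  masks <- list_images(mask_dir)
  stems <- tools::file_path_sans_ext(basename(masks))
  idx <- match(tools::file_path_sans_ext(basename(images)), stems)
  if (anyNA(idx))
    stop_autoqc("missing mask for ", context, " sample(s): ",
                paste(basename(images)[is.na(idx)], collapse = ", "))
  masks[idx]
}

new_manifest <- function(train_normal, test_positive, test_negative,
                         validation, root = NULL) {
  structure(list(train_normal = train_normal, test_positive = test_positive,
                 test_negative = test_negative, validation = validation,
                 root = root),
            class = "autoqc_manifest")
}

#' Read a benchmark dataset manifest
#'
#' Accepts either a root directory with the documented layout
#' (`train_normal/`, `test_positive/`, `test_negative/images/` +
#' `test_negative/masks/` with identical file stems, and optionally
#' `validation/normal/` and `validation/abnormal/images/` + `masks/`), or a
#' YAML manifest file with sections `train_normal`, `test_positive`,
#' `test_negative` (entries `image` + `mask`) and `validation` (entries
#' `image`, `label`, optional `mask`). Relative paths in a YAML manifest are
#' resolved against its location.
#'
#' @param path Directory or YAML manifest file.
#' @param check_shapes Verify that every negative-sample mask matches its
#'   image shape (loads each pair once).
#' @return An `autoqc_manifest` object.
#' @export
read_manifest <- function(path, check_shapes = TRUE) {
  if (dir.exists(path)) m <- manifest_from_dir(path)
  else if (file.exists(path)) m <- manifest_from_yaml(path)
  else stop_autoqc("manifest path does not exist: '", path, "'")
  validate_manifest(m, check_shapes = check_shapes)
  m
}

manifest_from_dir <- function(root) {
  neg_imgs <- list_images(file.path(root, "test_negative", "images"))
  neg <- data.frame(
    image = neg_imgs,
    mask = match_masks(neg_imgs, file.path(root, "test_negative", "masks"),
                       "test_negative"),
    stringsAsFactors = FALSE)
  val_norm <- list_images(file.path(root, "validation", "normal"))
  val_abn <- list_images(file.path(root, "validation", "abnormal", "images"))
  val <- data.frame(
    image = c(val_norm, val_abn),
    label = rep(c("normal", "abnormal"), c(length(val_norm), length(val_abn))),
    mask = c(rep(NA_character_, length(val_norm)),
             if (length(val_abn)) match_masks(
               val_abn, file.path(root, "validation", "abnormal", "masks"),
               "validation abnormal") else character(0)),
    stringsAsFactors = FALSE)
  new_manifest(list_images(file.path(root, "train_normal")),
               list_images(file.path(root, "test_positive")),
               neg, val, root = root)
}

manifest_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  for (sec in c("train_normal", "test_positive", "test_negative"))
    if (is.null(y[[sec]]))
      stop_autoqc("manifest is missing required section '", sec, "'")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  neg <- y$test_negative
  neg <- if (length(neg) == 0) {
    data.frame(image = character(0), mask = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(image = resolve(vapply(neg, `[[`, "", "image")),
               mask = resolve(vapply(neg, function(e) e$mask %||%
                 stop_autoqc("test_negative entry for '", e$image,
                             "' has no mask"), "")),
               stringsAsFactors = FALSE)
  }
  val <- y$validation
  val <- if (length(val) == 0) {
    data.frame(image = character(0), label = character(0),
               mask = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(image = resolve(vapply(val, `[[`, "", "image")),
               label = vapply(val, `[[`, "", "label"),
               mask = resolve(vapply(val, function(e)
                 e$mask %||% NA_character_, "")),
               stringsAsFactors = FALSE)
  }
  new_manifest(resolve(unlist(y$train_normal)),
               resolve(unlist(y$test_positive)), neg, val,
               root = base)
}

validate_manifest <- function(m, check_shapes = TRUE) {
  paths <- c(m$train_normal, m$test_positive, m$test_negative$image,
             m$test_negative$mask, m$validation$image,
             m$validation$mask[!is.na(m$validation$mask)])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_autoqc("manifest references nonexistent file(s): ",
                paste(basename(missing), collapse = ", "))
  bad <- m$validation$label[!m$validation$label %in% c("normal", "abnormal")]
  if (length(bad))
    stop_autoqc("validation labels must be 'normal' or 'abnormal'")
  if (check_shapes && nrow(m$test_negative)) {
    for (i in seq_len(nrow(m$test_negative))) {
      di <- dim(load_image(m$test_negative$image[i]))
      dm <- dim(load_mask(m$test_negative$mask[i]))
      if (!identical(di, dm))
        stop_autoqc("mask shape mismatch for '",
                    basename(m$test_negative$image[i]), "'")
    }
  }
  invisible(m)
}

#' @export
print.autoqc_manifest <- function(x, ...) {
  cat("autoqc benchmark manifest\n")
  if (!is.null(x$root)) cat("  root:          ", x$root, "\n")
  cat("  train_normal:  ", length(x$train_normal), "images\n")
  cat("  test_positive: ", length(x$test_positive), "images\n")
  cat("  test_negative: ", nrow(x$test_negative), "images (with masks)\n")
  cat("  validation:    ", nrow(x$validation), "images (",
      sum(x$validation$label == "normal"), "normal /",
      sum(x$validation$label == "abnormal"), "abnormal )\n")
  invisible(x)
}

write_manifest_yaml <- function(m, path) {
  rel <- function(p) {
    out <- p
    ok <- !is.na(p)
    root <- normalizePath(dirname(path))
    out[ok] <- sub(paste0("^", root, "/"), "", normalizePath(p[ok]))
    out
  }
  y <- list(
    train_normal = as.list(rel(m$train_normal)),
    test_positive = as.list(rel(m$test_positive)),
    test_negative = lapply(seq_len(nrow(m$test_negative)), function(i)
      list(image = rel(m$test_negative$image[i]),
           mask = rel(m$test_negative$mask[i]))),
    validation = lapply(seq_len(nrow(m$validation)), function(i) {
      e <- list(image = rel(m$validation$image[i]),
                label = m$validation$label[i])
      if (!is.na(m$validation$mask[i])) e$mask <- rel(m$validation$mask[i])
      e
    }))
  yaml::write_yaml(y, path)
  invisible(path)
}
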