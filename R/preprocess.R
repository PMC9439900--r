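# Image loading and preprocessing: crop, min-max normalize, resize.
#
# All internal images are [0,1] floating point matrices; 8-bit conversion
# happens only at file boundaries.

#' Preprocessing configuration
#'
#' @param crop_mode One of `"none"`, `"center_square"`, `"fixed_margin"`.
#'   `center_square` keeps the largest centered square (the usual way to drop
#'   the lateral background bands of a radiograph); `fixed_margin` removes a
#'   fraction of each side.
#' @param margin_fraction Fraction in `[0, 0.45]` of each dimension removed
#'   from each side when `crop_mode = "fixed_margin"`.
#' @param target_size Integer pair `(height, width)`, each >= 8. Default
#'   `c(224, 224)`, the input size of the VGG-16 family.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(crop_mode = c("center_square", "none", "fixed_margin"),
                              margin_fraction = 0.1,
                              target_size = c(224L, 224L)) {
  crop_mode <- match.arg(crop_mode)
  stopifnot_scalar_number(margin_fraction, "margin_fraction")
  if (margin_fraction < 0 || margin_fraction > 0.45) {
    abort("`margin_fraction` must lie in [0, 0.45].")
  }
  target_size <- as.integer(target_size)
  if (length(target_size) != 2L || any(!is.finite(target_size)) || any(target_size < 8L)) {
    abort("`target_size` must be two integers, each >= 8.")
  }
  structure(
    list(crop_mode = crop_mode, margin_fraction = margin_fraction,
         target_size = target_size),
    class = "preprocess_config"
  )
}

#' Load an image file as a grayscale image
#'
#' PNG files are read with the png package; JPEG files require the EBImage
#' package. Color images are collapsed to a single channel with the standard
#' luminance weights (0.299 R + 0.587 G + 0.114 B). Values are scaled to
#' `[0, 1]`.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A [gray_image()].
#' @export
load_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort("`path` must be a single file path.")
  }
  if (!file.exists(path)) {
    abort(sprintf("cannot read image: file does not exist: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    {
      if (ext == "png") {
        png::readPNG(path)
      } else if (ext %in% c("jpg", "jpeg")) {
        if (!requireNamespace("EBImage", quietly = TRUE)) {
          abort("JPEG reading requires the EBImage package.")
        }
        a <- EBImage::imageData(EBImage::readImage(path))
        # EBImage stores x-major (width, height[, channels]); transpose to row = y.
        if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
      } else {
        abort(sprintf("unsupported image format '%s' for %s", ext, path))
      }
    },
    error = function(e) {
      abort(sprintf("failed to read image %s: %s", path, conditionMessage(e)))
    }
  )
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    m <- if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  } else {
    m <- arr
  }
  if (is.null(dim(m)) || any(dim(m) == 0L)) {
    abort(sprintf("zero-sized image: %s", path))
  }
  m <- pmin(pmax(m, 0), 1)
  gray_image(m, source_id = path)
}

#' Crop a grayscale image
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param cfg A [preprocess_config()].
#' @return The cropped [gray_image()].
#' @export
crop <- function(img, cfg = preprocess_config()) {
  m <- as_pixel_matrix(img)
  h <- nrow(m); w <- ncol(m)
  out <- switch(cfg$crop_mode,
    none = m,
    center_square = {
      s <- min(h, w)
      r0 <- floor((h - s) / 2)
      c0 <- floor((w - s) / 2)
      m[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
    },
    fixed_margin = {
      mr <- floor(h * cfg$margin_fraction)
      mc <- floor(w * cfg$margin_fraction)
      m[(mr + 1L):(h - mr), (mc + 1L):(w - mc), drop = FALSE]
    }
  )
  if (nrow(out) < 3L || ncol(out) < 3L) {
    abort(sprintf("crop result %dx%d is smaller than the 3x3 minimum.",
                  nrow(out), ncol(out)))
  }
  gray_image(out, source_id = attr(img, "source_id") %||% "<memory>")
}

#' Min-max normalize image intensities
#'
#' Maps intensities to `(x - min) / (max - min)`; a constant image maps to all
#' zeros. Idempotent, and invariant to affine rescaling `a * x + b` (a > 0) of
#' the input.
#'
#' @inheritParams crop
#' @return A [gray_image()] with min 0 and max 1 (or all zeros if constant).
#' @export
normalize_minmax <- function(img) {
  m <- as_pixel_matrix(img)
  lo <- min(m); hi <- max(m)
  out <- if (hi > lo) (m - lo) / (hi - lo) else array(0, dim = dim(m))
  dim(out) <- dim(m)
  gray_image(out, source_id = attr(img, "source_id") %||% "<memory>")
}

# Bilinear resample with corner-aligned grid mapping, so an identity-size
# resize reproduces the input exactly.
bilinear_resize <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  ys <- if (out_h == 1L) rep(1, 1) else 1 + (seq_len(out_h) - 1) * (in_h - 1) / (out_h - 1)
  xs <- if (out_w == 1L) rep(1, 1) else 1 + (seq_len(out_w) - 1) * (in_w - 1) / (out_w - 1)
  y0 <- pmin(floor(ys), in_h - 1L); y0[in_h == 1L] <- 1L
  x0 <- pmin(floor(xs), in_w - 1L); x0[in_w == 1L] <- 1L
  if (in_h == 1L) y0 <- rep(1L, out_h)
  if (in_w == 1L) x0 <- rep(1L, out_w)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1L, in_h); x1 <- pmin(x0 + 1L, in_w)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w)
  wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

#' Resize a grayscale image to the configured target size
#'
#' Bilinear interpolation on a corner-aligned grid; output values are clipped
#' to `[0, 1]`.
#'
#' @inheritParams crop
#' @return A [gray_image()] of dimensions `cfg$target_size`.
#' @export
resize <- function(img, cfg = preprocess_config()) {
  m <- as_pixel_matrix(img)
  out <- bilinear_resize(m, cfg$target_size[1], cfg$target_size[2])
  out <- pmin(pmax(out, 0), 1)
  gray_image(out, source_id = attr(img, "source_id") %||% "<memory>")
}

#' Full preprocessing pipeline
#'
#' Crop, min-max normalize, then resize — the canonical preparation of a
#' radiograph before texture extraction and classification.
#'
#' @param path Path to a PNG or JPEG file.
#' @param cfg A [preprocess_config()].
#' @return A [gray_image()] of dimensions `cfg$target_size`, in `[0, 1]`.
#' @export
preprocess_image <- function(path, cfg = preprocess_config()) {
  img <- load_gray(path)
  if (nrow(img) < 3L || ncol(img) < 3L) {
    abort(sprintf("image %s is smaller than the 3x3 minimum.", path))
  }
  resize(normalize_minmax(crop(img, cfg)), cfg)
}
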