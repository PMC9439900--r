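# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

#' Construct a grayscale image object
#'
#' A `gray_image` is a plain numeric matrix (rows = y, columns = x) carrying
#' intensities, nominally in `[0, 1]`, plus a `source_id` attribute recording
#' provenance. All texture operators and the network consume this type.
#'
#' @param pixels Numeric matrix of intensities.
#' @param source_id Opaque provenance string (e.g. a file path).
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, source_id = "<memory>") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("image must be non-empty.")
  }
  structure(pixels, source_id = source_id, class = c("gray_image", class(pixels)))
}

as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "source_id") <- NULL
  m
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, range [%.3f, %.3f], source: %s\n",
    nrow(x), ncol(x), min(x), max(x), attr(x, "source_id") %||% "<memory>"
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a grayscale image
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot object rendering the image as a raster.
#' @method autoplot gray_image
#' @export
autoplot.gray_image <- function(object, ...) {
  m <- as_pixel_matrix(object)
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$value <- as.vector(t(m))[(df$y - 1L) * ncol(m) + df$x]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
}

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}
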