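# Histogram of oriented gradients.
#
# Gradients are central differences (F_x = H(x+1,y) - H(x-1,y), F_y =
# H(x,y+1) - H(x,y-1)) on a replicate-padded image; magnitude is
# sqrt(Fx^2 + Fy^2). Each pixel votes its magnitude into the two nearest
# orientation bins with linear interpolation; per-cell histograms are left
# unnormalized (normalization happens once, at render time).

#' HOG configuration
#'
#' @param cell_size Side of the square cell in pixels; one of 2, 4, 8, 16, 32.
#'   Default 2, the finest cell in the supported sweep range.
#' @param n_bins Number of orientation bins (default 9).
#' @param signed_gradients If `FALSE` (default) orientations are folded to
#'   `[0, 180)` degrees; if `TRUE` the full `[0, 360)` circle is used.
#' @param render_mode `"dominant"` paints each cell with its maximum bin
#'   magnitude; `"glyph"` draws oriented line glyphs weighted by the bin
#'   magnitudes.
#' @param orientation_formula `"conventional"` uses the quadrant-aware angle
#'   of (F_y, F_x); `"as_printed"` uses the angle of (F_x, F_y), i.e. the
#'   same field reflected about 45 degrees.
#' @return A `hog_config` list.
#' @export
hog_config <- function(cell_size = 2L, n_bins = 9L, signed_gradients = FALSE,
                       render_mode = c("dominant", "glyph"),
                       orientation_formula = c("conventional", "as_printed")) {
  cell_size <- as.integer(cell_size)
  if (!cell_size %in% c(2L, 4L, 8L, 16L, 32L)) {
    abort("`cell_size` must be one of 2, 4, 8, 16, 32.")
  }
  n_bins <- as.integer(n_bins)
  stopifnot_scalar_number(n_bins, "n_bins", positive = TRUE)
  structure(
    list(cell_size = cell_size, n_bins = n_bins,
         signed_gradients = isTRUE(signed_gradients),
         render_mode = match.arg(render_mode),
         orientation_formula = match.arg(orientation_formula)),
    class = "hog_config"
  )
}

#' Image gradient field
#'
#' Central differences with replicate-padded borders, gradient magnitude, and
#' orientation in degrees.
#'
#' @param img A [gray_image()] or numeric matrix, at least 3x3.
#' @param cfg A [hog_config()] (controls the orientation convention and
#'   signed/unsigned folding).
#' @return A `gradient_field` list with matrices `fx`, `fy`, `magnitude`,
#'   `orientation` (degrees; `[0, 180)` unsigned, `[0, 360)` signed).
#' @export
gradients <- function(img, cfg = hog_config()) {
  m <- as_pixel_matrix(img)
  if (nrow(m) < 3L || ncol(m) < 3L) {
    abort("gradients need an image of at least 3x3.")
  }
  h <- nrow(m); w <- ncol(m)
  mp <- pad_replicate(m, 1L)
  # x is the horizontal (column) axis, y the vertical (row) axis.
  fx <- mp[1L + seq_len(h), 2L + seq_len(w), drop = FALSE] -
    mp[1L + seq_len(h), seq_len(w), drop = FALSE]
  fy <- mp[2L + seq_len(h), 1L + seq_len(w), drop = FALSE] -
    mp[seq_len(h), 1L + seq_len(w), drop = FALSE]
  mag <- sqrt(fx^2 + fy^2)
  ang <- if (cfg$orientation_formula == "conventional") {
    atan2(fy, fx)
  } else {
    atan2(fx, fy)
  }
  deg <- ang * 180 / pi
  deg <- if (cfg$signed_gradients) deg %% 360 else deg %% 180
  deg[mag == 0] <- 0
  structure(list(fx = fx, fy = fy, magnitude = mag, orientation = deg),
            class = "gradient_field")
}

#' Per-cell orientation histograms
#'
#' Partitions the image into non-overlapping `cell_size` x `cell_size` cells
#' (trailing partial cells are dropped). Each pixel votes its gradient
#' magnitude into the two nearest orientation bins by linear interpolation,
#' so the total vote of a cell equals the sum of its pixels' magnitudes.
#'
#' @param g A `gradient_field` from [gradients()].
#' @param cfg A [hog_config()].
#' @return A `hog_descriptor`: 3-D array `(cells_y, cells_x, n_bins)` of
#'   nonnegative vote mass, with the config attached.
#' @export
cell_histograms <- function(g, cfg = hog_config()) {
  cs <- cfg$cell_size
  h <- nrow(g$magnitude); w <- ncol(g$magnitude)
  if (h < cs || w < cs) {
    abort(sprintf("cell_size %d exceeds the %dx%d image.", cs, h, w))
  }
  cy <- h %/% cs; cx <- w %/% cs
  hh <- cy * cs; ww <- cx * cs
  mag <- g$magnitude[seq_len(hh), seq_len(ww), drop = FALSE]
  deg <- g$orientation[seq_len(hh), seq_len(ww), drop = FALSE]
  span <- if (cfg$signed_gradients) 360 else 180
  nb <- cfg$n_bins
  bw <- span / nb
  # Bin centers sit at i * bw (i = 0..nb-1) with wraparound.
  t_ <- as.vector(deg) / bw
  i0 <- floor(t_)
  frac <- t_ - i0
  b0 <- (as.integer(i0) %% nb)
  b1 <- (b0 + 1L) %% nb
  v <- as.vector(mag)
  cell_row <- (as.vector(row(mag)) - 1L) %/% cs
  cell_col <- (as.vector(col(mag)) - 1L) %/% cs
  cell_id <- cell_row + cy * cell_col  # column-major cell index
  idx0 <- cell_id + (cy * cx) * b0
  idx1 <- cell_id + (cy * cx) * b1
  acc <- numeric(cy * cx * nb)
  add0 <- rowsum(v * (1 - frac), idx0)
  acc[as.integer(rownames(add0)) + 1L] <- acc[as.integer(rownames(add0)) + 1L] + add0[, 1L]
  add1 <- rowsum(v * frac, idx1)
  acc[as.integer(rownames(add1)) + 1L] <- acc[as.integer(rownames(add1)) + 1L] + add1[, 1L]
  arr <- array(acc, dim = c(cy, cx, nb))
  structure(arr, config = cfg, class = c("hog_descriptor", "array"))
}

# Nearest-neighbor upsampling of a cells_y x cells_x matrix to out_h x out_w.
nn_upsample <- function(m, out_h, out_w) {
  ri <- pmin(nrow(m), 1L + ((seq_len(out_h) - 1L) * nrow(m)) %/% out_h)
  ci <- pmin(ncol(m), 1L + ((seq_len(out_w) - 1L) * ncol(m)) %/% out_w)
  m[ri, ci, drop = FALSE]
}

#' Render a HOG descriptor as a grayscale feature image
#'
#' `dominant` mode paints each cell with its maximum bin magnitude and
#' upsamples to `out_size` (nearest neighbor, so each cell keeps a uniform
#' footprint); `glyph` mode draws a line through each cell center per bin,
#' weighted by the bin magnitude. Both are min-max normalized per image
#' (an all-zero descriptor renders as zeros).
#'
#' @param d A `hog_descriptor` from [cell_histograms()].
#' @param out_size Integer pair `(height, width)` of the output image.
#' @return A [gray_image()] in `[0, 1]`.
#' @export
render_hog_image <- function(d, out_size) {
  cfg <- attr(d, "config")
  out_h <- as.integer(out_size[1]); out_w <- as.integer(out_size[2])
  arr <- unclass(d)
  attributes(arr) <- list(dim = dim(arr))
  cy <- dim(arr)[1]; cx <- dim(arr)[2]; nb <- dim(arr)[3]
  if (cfg$render_mode == "dominant") {
    dom <- apply(arr, c(1, 2), max)
    img <- nn_upsample(dom, out_h, out_w)
  } else {
    img <- matrix(0, out_h, out_w)
    sy <- out_h / cy; sx <- out_w / cx
    half <- max(1, min(sy, sx) / 2 - 0.5)
    span <- if (cfg$signed_gradients) 360 else 180
    for (b in seq_len(nb)) {
      ang <- (b - 1) * span / nb * pi / 180
      # Glyph line is perpendicular to the gradient direction (an edge glyph).
      dy <- cos(ang); dx <- -sin(ang)
      ts <- seq(-half, half, length.out = max(3L, ceiling(2 * half) + 1L))
      for (iy in seq_len(cy)) {
        for (ix in seq_len(cx)) {
          wgt <- arr[iy, ix, b]
          if (wgt <= 0) next
          cyc <- (iy - 0.5) * sy; cxc <- (ix - 0.5) * sx
          py <- pmin(pmax(round(cyc + ts * dy), 1), out_h)
          px <- pmin(pmax(round(cxc + ts * dx), 1), out_w)
          for (k in seq_along(ts)) {
            img[py[k], px[k]] <- img[py[k], px[k]] + wgt
          }
        }
      }
    }
  }
  lo <- min(img); hi <- max(img)
  out <- if (hi > lo) (img - lo) / (hi - lo) else matrix(0, out_h, out_w)
  gray_image(out, source_id = sprintf("hog_%s_cell%d", cfg$render_mode, cfg$cell_size))
}

#' HOG feature image in one call
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param cfg A [hog_config()].
#' @param out_size Output image size; defaults to the input extent.
#' @return A [gray_image()].
#' @export
hog_image <- function(img, cfg = hog_config(), out_size = dim(as_pixel_matrix(img))) {
  g <- gradients(img, cfg)
  d <- cell_histograms(g, cfg)
  render_hog_image(d, out_size)
}
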