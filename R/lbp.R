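# Local binary patterns.
#
# The code of a pixel thresholds its P circular neighbors against the center
# intensity q_c: code = sum_i 2^i * s(q_i - q_c), s(d) = 1 iff d >= 0 (ties
# count as 1). Neighbor enumeration (bit_order) starts at the east neighbor
# and proceeds counter-clockwise; bit i carries weight 2^i. Variants post-map
# the raw code (ror, uniform, nri_uniform) or replace it with the local
# variance of the neighbor intensities (var).

LBP_VARIANTS <- c("default", "ror", "uniform", "nri_uniform", "var", "circular")

#' LBP configuration
#'
#' @param variant One of `"default"` (raw 8-bit code), `"ror"`
#'   (rotation-invariant: minimum over circular bit rotations), `"uniform"`
#'   (rotation-invariant uniform, P + 2 labels), `"nri_uniform"`
#'   (non-rotation-invariant uniform, 59 labels at P = 8), `"var"` (local
#'   population variance of the neighbor intensities, a contrast measure), or
#'   `"circular"` (P bilinearly interpolated samples on a circle of radius R,
#'   raw code, no post-mapping).
#' @param neighbors_P Number of sampled neighbors (default 8). Grid variants
#'   (`default`, `ror`, `uniform`, `nri_uniform`, `var`) require `P = 8`,
#'   `R = 1` and use the exact 3x3 grid without interpolation.
#' @param radius_R Sampling radius in pixels (default 1).
#' @return An `lbp_config` list.
#' @export
lbp_config <- function(variant = c("var", "default", "ror", "uniform",
                                   "nri_uniform", "circular"),
                       neighbors_P = 8L, radius_R = 1) {
  variant <- match.arg(variant)
  neighbors_P <- as.integer(neighbors_P)
  stopifnot_scalar_number(neighbors_P, "neighbors_P", positive = TRUE)
  stopifnot_scalar_number(radius_R, "radius_R", positive = TRUE)
  if (variant != "circular" && (neighbors_P != 8L || radius_R != 1)) {
    abort("grid LBP variants require neighbors_P = 8 and radius_R = 1; use variant = \"circular\" for other samplings.")
  }
  structure(list(variant = variant, neighbors_P = neighbors_P,
                 radius_R = radius_R),
            class = "lbp_config")
}

# 3x3 grid neighbor offsets in bit order: east, then counter-clockwise.
# (dy, dx) with y increasing downward.
lbp_grid_offsets <- function() {
  list(dy = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
       dx = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))
}

# Circular sampling offsets for P points of radius R, same start/direction.
lbp_circle_offsets <- function(P, R) {
  theta <- 2 * pi * (seq_len(P) - 1) / P
  list(dy = -R * sin(theta), dx = R * cos(theta))
}

# Number of 0<->1 transitions around the circular bit string.
count_transitions <- function(bits) {
  sum(bits != bits[c(2:length(bits), 1L)])
}

code_bits <- function(code, P) {
  as.integer(bitwAnd(code, bitwShiftL(1L, 0:(P - 1L))) > 0L)
}

bits_to_code <- function(bits) {
  sum(bits * 2L^(seq_along(bits) - 1L))
}

# Lookup tables mapping raw 8-bit codes to variant labels. Uniform patterns
# (<= 2 transitions) for nri_uniform are labeled 0..57 in ascending code
# order; all non-uniform codes share label 58.
lbp_lut <- function(variant, P = 8L) {
  codes <- 0:(2L^P - 1L)
  bits <- lapply(codes, code_bits, P = P)
  switch(variant,
    ror = vapply(bits, function(b) {
      min(vapply(seq_len(P), function(r) {
        bits_to_code(b[c(r:P, seq_len(r - 1L))[seq_len(P)]])
      }, numeric(1)))
    }, numeric(1)),
    uniform = vapply(bits, function(b) {
      if (count_transitions(b) <= 2L) sum(b) else P + 1L
    }, numeric(1)),
    nri_uniform = {
      uni <- vapply(bits, function(b) count_transitions(b) <= 2L, logical(1))
      lut <- integer(length(codes))
      lut[uni] <- seq_len(sum(uni)) - 1L
      lut[!uni] <- sum(uni)
      lut
    },
    abort(sprintf("no lookup table for variant '%s'", variant))
  )
}

lut_cache <- new.env(parent = emptyenv())

lbp_lut_cached <- function(variant, P = 8L) {
  key <- paste(variant, P, sep = "_")
  if (is.null(lut_cache[[key]])) lut_cache[[key]] <- lbp_lut(variant, P)
  lut_cache[[key]]
}

#' Maximum possible code value for an LBP variant
#'
#' Used to scale integer code maps into `[0, 1]` images.
#' @param cfg An [lbp_config()].
#' @return Integer maximum code (NA for `var`, which is unbounded).
#' @export
lbp_max_code <- function(cfg) {
  P <- cfg$neighbors_P
  switch(cfg$variant,
    default = 2L^P - 1L,
    circular = 2L^P - 1L,
    ror = 2L^P - 1L,
    uniform = P + 1L,
    nri_uniform = if (P == 8L) 58L else NA_integer_,
    var = NA_integer_
  )
}

#' LBP code of a single 3x3 patch
#'
#' Scalar reference entry point for the grid variants (radius 1, P = 8).
#'
#' @param patch A 3x3 numeric matrix; the center pixel is the threshold.
#' @param cfg An [lbp_config()] with a grid variant.
#' @return A single nonnegative code (real-valued for `var`).
#' @export
lbp_code_at <- function(patch, cfg = lbp_config("default")) {
  if (!is.matrix(patch) || !all(dim(patch) == c(3L, 3L))) {
    abort("`patch` must be a 3x3 matrix.")
  }
  if (cfg$variant == "circular") {
    abort("lbp_code_at() is defined for the grid variants; use lbp_map() for variant = \"circular\".")
  }
  off <- lbp_grid_offsets()
  qc <- patch[2L, 2L]
  qp <- patch[cbind(2L + off$dy, 2L + off$dx)]
  if (cfg$variant == "var") {
    return(mean((qp - mean(qp))^2))
  }
  code <- sum((qp >= qc) * 2L^(0:7))
  switch(cfg$variant,
    default = code,
    ror = lbp_lut_cached("ror")[code + 1L],
    uniform = lbp_lut_cached("uniform")[code + 1L],
    nri_uniform = lbp_lut_cached("nri_uniform")[code + 1L]
  )
}

# Shifted-neighbor image stack: list of P matrices, each the neighbor value
# at every pixel, computed on a replicate-padded image so the output keeps
# the input extent.
neighbor_stack <- function(m, cfg) {
  h <- nrow(m); w <- ncol(m)
  if (cfg$variant == "circular") {
    R <- cfg$radius_R
    pad <- ceiling(R) + 1L
    mp <- pad_replicate(m, pad)
    off <- lbp_circle_offsets(cfg$neighbors_P, R)
    lapply(seq_len(cfg$neighbors_P), function(i) {
      yy <- pad + seq_len(h) + off$dy[i]
      xx <- pad + seq_len(w) + off$dx[i]
      y0 <- floor(yy); x0 <- floor(xx)
      fy <- yy - y0; fx <- xx - x0
      a <- mp[y0, x0, drop = FALSE]; b <- mp[y0, x0 + 1L, drop = FALSE]
      c_ <- mp[y0 + 1L, x0, drop = FALSE]; d <- mp[y0 + 1L, x0 + 1L, drop = FALSE]
      wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
      (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
    })
  } else {
    mp <- pad_replicate(m, 1L)
    off <- lbp_grid_offsets()
    lapply(seq_len(8L), function(i) {
      mp[1L + seq_len(h) + off$dy[i], 1L + seq_len(w) + off$dx[i], drop = FALSE]
    })
  }
}

#' LBP code map of an image
#'
#' Applies the configured LBP operator at every pixel. By default the image is
#' replicate-padded by the radius so the code map has the same extent as the
#' input (a map the network can consume at full resolution); `pad = FALSE`
#' returns only the valid interior.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param cfg An [lbp_config()].
#' @param pad Pad with replicated borders (default `TRUE`).
#' @return An `lbp_code_map`: a numeric matrix of codes with attributes
#'   `variant` and `config`.
#' @export
lbp_map <- function(img, cfg = lbp_config(), pad = TRUE) {
  m <- as_pixel_matrix(img)
  need <- 2 * ceiling(cfg$radius_R) + 1L
  if (nrow(m) < need || ncol(m) < need) {
    abort(sprintf("image %dx%d is smaller than the %dx%d neighborhood.",
                  nrow(m), ncol(m), need, need))
  }
  nb <- neighbor_stack(m, cfg)
  P <- cfg$neighbors_P
  codes <- if (cfg$variant == "var") {
    mu <- Reduce(`+`, nb) / P
    Reduce(`+`, lapply(nb, function(q) (q - mu)^2)) / P
  } else {
    raw <- Reduce(`+`, lapply(seq_len(P), function(i) {
      (nb[[i]] >= m) * 2^(i - 1)
    }))
    switch(cfg$variant,
      default = raw,
      circular = raw,
      {
        lut <- lbp_lut_cached(cfg$variant, P)
        out <- as.double(lut[as.integer(round(raw)) + 1L])
        dim(out) <- dim(raw)
        out
      }
    )
  }
  if (!pad) {
    r <- ceiling(cfg$radius_R)
    codes <- codes[(r + 1L):(nrow(codes) - r), (r + 1L):(ncol(codes) - r),
                   drop = FALSE]
  }
  structure(codes, variant = cfg$variant, config = cfg,
            class = c("lbp_code_map", "matrix", "array"))
}

#' Render an LBP code map as a grayscale feature image
#'
#' Integer-code variants are scaled by the maximum possible code so equal
#' codes always render identically across images; the unbounded `var` variant
#' is min-max normalized per image (constant maps render as zeros).
#'
#' @param map An `lbp_code_map` from [lbp_map()].
#' @return A [gray_image()] in `[0, 1]`.
#' @export
render_lbp_image <- function(map) {
  cfg <- attr(map, "config")
  m <- unclass(map)
  attributes(m) <- list(dim = dim(m))
  if (cfg$variant == "var") {
    lo <- min(m); hi <- max(m)
    out <- if (hi > lo) (m - lo) / (hi - lo) else array(0, dim = dim(m))
  } else {
    out <- m / lbp_max_code(cfg)
  }
  dim(out) <- dim(m)
  gray_image(out, source_id = sprintf("lbp_%s", cfg$variant))
}

#' LBP feature image in one call
#'
#' @inheritParams lbp_map
#' @return A [gray_image()] rendering of the code map.
#' @export
lbp_image <- function(img, cfg = lbp_config()) {
  render_lbp_image(lbp_map(img, cfg))
}
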