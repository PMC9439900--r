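# The fused texture-depth convolutional classifier.
#
# Backbone: the VGG-16 convolutional layout (stages of 2,2,3,3,3 conv layers
# of widths 64,128,256,512,512, each stage closed by a 2x2 max-pool), with
# the VGG head reduced to dropout -> FC -> ReLU -> dropout -> FC(2) (the
# first of VGG-16's three FC layers is removed and the output narrowed to two
# classes). A texture branch with the same stage layout runs on the stacked
# LBP/HOG feature images and joins the backbone by element-wise Add — with a
# learnable per-channel kernel, initialized to identity — after the last conv
# of the chosen block, before that block's max-pool. `*` in the fusion
# formula z_i = (x_i + y_i) * k_i is implemented as cross-correlation, the
# CNN convention.

VGG_WIDTHS <- c(64L, 128L, 256L, 512L, 512L)
VGG_DEPTHS <- c(2L, 2L, 3L, 3L, 3L)
FUSION_POSITIONS <- c("input", "block1", "block2", "block3", "block4", "block5")

scaled_width <- function(base, wm) max(1L, as.integer(round(base * wm)))

#' Declarative specification of the fusion network
#'
#' @param fusion_position Where the texture branch joins the backbone: one of
#'   `"input"`, `"block1"` ... `"block5"`. Block positions fuse after the
#'   block's last conv layer, before its max-pool. At `"input"` the single
#'   depth channel is broadcast across the texture channels and the Add
#'   happens in texture-channel space.
#' @param width_multiplier Fraction in `(0, 1]` scaling every layer width
#'   (1 reproduces the full-size architecture; small values give desk-scale
#'   variants with the same topology).
#' @param dropout_rate Dropout probability in `[0, 1)` applied before each of
#'   the two head FC layers. Default 0.5.
#' @param texture_mode `"stacked"` feeds the LBP and HOG images as two
#'   channels of one texture branch; `"separate_branches"` gives each texture
#'   channel its own branch (their outputs are summed before fusion);
#'   `"none"` builds the depth-only classifier (no texture branch, the
#'   ablation baseline).
#' @param share_weights If `TRUE`, texture branches reuse the backbone's
#'   filters; only shape-consistent with `texture_mode = "separate_branches"`.
#' @param n_texture_channels Number of texture feature channels (default 2:
#'   one LBP, one HOG image).
#' @param fusion_kernel_size Odd side of the learnable per-channel fusion
#'   kernel (default 1; identity-initialized so training starts from plain
#'   addition).
#' @return A `fusion_net_spec` list.
#' @export
fusion_net_spec <- function(fusion_position = "block3",
                            width_multiplier = 1,
                            dropout_rate = 0.5,
                            texture_mode = c("stacked", "separate_branches", "none"),
                            share_weights = FALSE,
                            n_texture_channels = 2L,
                            fusion_kernel_size = 1L) {
  if (!fusion_position %in% FUSION_POSITIONS) {
    abort(sprintf("`fusion_position` must be one of %s.",
                  paste(FUSION_POSITIONS, collapse = ", ")))
  }
  texture_mode <- match.arg(texture_mode)
  stopifnot_scalar_number(width_multiplier, "width_multiplier", positive = TRUE)
  if (width_multiplier > 1) abort("`width_multiplier` must lie in (0, 1].")
  stopifnot_scalar_number(dropout_rate, "dropout_rate")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must lie in [0, 1).")
  if (isTRUE(share_weights) && texture_mode != "separate_branches") {
    abort(paste0(
      "share_weights = TRUE requires texture_mode = \"separate_branches\": ",
      "the backbone's first filters take one channel, so a stacked ",
      "multi-channel texture input cannot reuse them."
    ))
  }
  fusion_kernel_size <- as.integer(fusion_kernel_size)
  if (fusion_kernel_size < 1L || fusion_kernel_size %% 2L == 0L) {
    abort("`fusion_kernel_size` must be a positive odd integer.")
  }
  n_texture_channels <- as.integer(n_texture_channels)
  if (texture_mode == "input" && n_texture_channels < 1L) {
    abort("`n_texture_channels` must be >= 1.")
  }
  structure(
    list(
      fusion_position = fusion_position,
      width_multiplier = width_multiplier,
      dropout_rate = dropout_rate,
      texture_mode = texture_mode,
      share_weights = isTRUE(share_weights),
      n_texture_channels = n_texture_channels,
      fusion_kernel_size = fusion_kernel_size,
      widths = vapply(VGG_WIDTHS, scaled_width, integer(1), wm = width_multiplier),
      depths = VGG_DEPTHS,
      fc_width = max(2L, as.integer(round(4096 * width_multiplier)))
    ),
    class = "fusion_net_spec"
  )
}

fusion_block_index <- function(position) {
  match(position, FUSION_POSITIONS) - 1L  # 0 = input, 1..5 = blocks
}

#' Activation shapes at every candidate fusion position
#'
#' For each of the six fusion positions, the `(channels, height, width)` at
#' which the Add would occur: before any pooling at `"input"`, and after the
#' last conv of the block (before its pool) for `"block1"` ... `"block5"`.
#' Used to size the texture branch and validate configurations.
#'
#' @param spec A [fusion_net_spec()].
#' @param input_size Integer pair `(height, width)`; must be divisible by 16
#'   so the block-5 position is reachable.
#' @return A tibble with columns `position`, `channels`, `height`, `width`.
#' @export
fusion_position_shapes <- function(spec, input_size = c(224L, 224L)) {
  h <- as.integer(input_size[1]); w <- as.integer(input_size[2])
  if (h %% 16L != 0L || w %% 16L != 0L) {
    abort(sprintf(
      "input size %dx%d is not divisible by 16: the deepest fusion position needs four 2x2 pools before it.",
      h, w))
  }
  tibble::tibble(
    position = FUSION_POSITIONS,
    channels = c(spec$n_texture_channels, spec$widths),
    height = c(h, h %/% 2L^(0:4)),
    width = c(w, w %/% 2L^(0:4))
  )
}

# ---- parameter initialization -------------------------------------------

he_uniform <- function(n_out, n_in_eff, nrow_, ncol_) {
  lim <- sqrt(6 / n_in_eff)
  matrix(runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}

init_conv_layer <- function(c_in, c_out, k = 3L) {
  list(w = he_uniform(c_out, k * k * c_in, c_out, k * k * c_in),
       b = numeric(c_out))
}

init_stage <- function(c_in, c_out, n_layers) {
  lapply(seq_len(n_layers), function(i) {
    init_conv_layer(if (i == 1L) c_in else c_out, c_out)
  })
}

init_branch <- function(c_in, widths, depths, n_stages) {
  lapply(seq_len(n_stages), function(b) {
    init_stage(if (b == 1L) c_in else widths[b - 1L], widths[b], depths[b])
  })
}

identity_fuse_kernels <- function(n_channels, k) {
  K <- matrix(0, n_channels, k * k)
  center <- (k * k + 1L) %/% 2L
  K[, center] <- 1
  K
}

#' Build a trainable fusion network
#'
#' Materializes a [fusion_net_spec()] into weights (He-uniform initialized,
#' seed-deterministic) for a given input size. The returned object is used by
#' [fit_network()] and [predict_network()].
#'
#' @param spec A [fusion_net_spec()].
#' @param input_size Integer pair `(height, width)`, divisible by 32 (five
#'   2x2 pools).
#' @param seed Integer seed for weight initialization.
#' @return A `fusion_net` object with elements `spec`, `input_size`, `params`
#'   and `n_parameters`.
#' @export
build_network <- function(spec, input_size = c(64L, 64L), seed = 1L) {
  h <- as.integer(input_size[1]); w <- as.integer(input_size[2])
  if (h %% 32L != 0L || w %% 32L != 0L) {
    abort(sprintf("input size %dx%d must be divisible by 32 (five 2x2 pools).", h, w))
  }
  fb <- fusion_block_index(spec$fusion_position)
  params <- with_seed(seed, {
    backbone_in <- if (spec$texture_mode != "none" && fb == 0L) {
      spec$n_texture_channels
    } else {
      1L
    }
    p <- list(backbone = init_branch(backbone_in, spec$widths, spec$depths, 5L))
    if (spec$texture_mode == "stacked" && fb > 0L) {
      p$texture <- list(init_branch(spec$n_texture_channels, spec$widths,
                                    spec$depths, fb))
    } else if (spec$texture_mode == "separate_branches" && fb > 0L) {
      p$texture <- if (spec$share_weights) {
        NULL  # reuse backbone weights at forward time
      } else {
        lapply(seq_len(spec$n_texture_channels), function(i) {
          init_branch(1L, spec$widths, spec$depths, fb)
        })
      }
    }
    if (spec$texture_mode != "none") {
      fuse_channels <- if (fb == 0L) spec$n_texture_channels else spec$widths[fb]
      p$fuse <- identity_fuse_kernels(fuse_channels, spec$fusion_kernel_size)
    }
    d_in <- (h %/% 32L) * (w %/% 32L) * spec$widths[5]
    d_h <- spec$fc_width
    p$head <- list(
      W1 = he_uniform(d_h, d_in, d_in, d_h),
      b1 = numeric(d_h),
      W2 = he_uniform(2L, d_h, d_h, 2L),
      b2 = numeric(2L)
    )
    p
  })
  net <- structure(
    list(spec = spec, input_size = c(h, w), params = params, seed = seed),
    class = "fusion_net"
  )
  net$n_parameters <- count_parameters(net)
  net
}

# Sum of leaf lengths of a nested parameter list.
tree_param_count <- function(p) {
  if (is.list(p)) sum(vapply(p, tree_param_count, numeric(1))) else length(p)
}

#' Number of trainable parameters
#'
#' @param x A `fusion_net` (counts its actual weights) or a
#'   [fusion_net_spec()] (counts symbolically from the layer algebra).
#' @param input_size Required for a spec: the input image size.
#' @return Parameter count (double, to avoid integer overflow at full scale).
#' @export
count_parameters <- function(x, input_size = NULL) {
  if (inherits(x, "fusion_net")) {
    return(tree_param_count(x$params))
  }
  spec <- x
  if (is.null(input_size)) abort("`input_size` is required for a spec.")
  h <- as.numeric(input_size[1]); w <- as.numeric(input_size[2])
  fb <- fusion_block_index(spec$fusion_position)
  widths <- as.numeric(spec$widths)
  conv_branch <- function(c_in, n_stages) {
    total <- 0
    for (b in seq_len(n_stages)) {
      cin <- if (b == 1L) c_in else widths[b - 1L]
      for (i in seq_len(spec$depths[b])) {
        total <- total + widths[b] * (9 * (if (i == 1L) cin else widths[b]) + 1)
      }
    }
    total
  }
  backbone_in <- if (spec$texture_mode != "none" && fb == 0L) spec$n_texture_channels else 1
  total <- conv_branch(backbone_in, 5L)
  if (spec$texture_mode == "stacked" && fb > 0L) {
    total <- total + conv_branch(spec$n_texture_channels, fb)
  } else if (spec$texture_mode == "separate_branches" && fb > 0L && !spec$share_weights) {
    total <- total + spec$n_texture_channels * conv_branch(1, fb)
  }
  if (spec$texture_mode != "none") {
    fuse_channels <- if (fb == 0L) spec$n_texture_channels else widths[fb]
    total <- total + fuse_channels * spec$fusion_kernel_size^2
  }
  d_in <- (h / 32) * (w / 32) * widths[5]
  total + head_parameter_count(d_in, spec$fc_width)
}

# Two-FC head: dropout -> FC(d_h) -> ReLU -> dropout -> FC(2).
head_parameter_count <- function(d_in, d_h) {
  d_in * d_h + d_h + d_h * 2 + 2
}

#' Parameter count of the original VGG-16 three-FC head
#'
#' Reference quantity: flatten -> FC(4096) -> FC(4096) -> FC(n_classes),
#' for comparison with the reduced two-FC head used here.
#'
#' @param input_size Input image size (default 224x224).
#' @param n_classes Output classes of the reference head (default 1000).
#' @return Parameter count (double).
#' @export
vgg16_head_parameter_count <- function(input_size = c(224L, 224L), n_classes = 1000L) {
  d_in <- (as.numeric(input_size[1]) / 32) * (as.numeric(input_size[2]) / 32) * 512
  d_in * 4096 + 4096 + 4096 * 4096 + 4096 + 4096 * n_classes + n_classes
}

#' Parameter count of the full original VGG-16
#'
#' @inheritParams vgg16_head_parameter_count
#' @return Parameter count (double).
#' @export
vgg16_parameter_count <- function(input_size = c(224L, 224L), n_classes = 1000L) {
  widths <- as.numeric(VGG_WIDTHS)
  total <- 0
  for (b in 1:5) {
    cin <- if (b == 1L) 1 else widths[b - 1L]
    for (i in seq_len(VGG_DEPTHS[b])) {
      total <- total + widths[b] * (9 * (if (i == 1L) cin else widths[b]) + 1)
    }
  }
  total + vgg16_head_parameter_count(input_size, n_classes)
}

#' @export
print.fusion_net <- function(x, ...) {
  cat(sprintf(
    "<fusion_net> %s fusion, width x%.3g, input %dx%d, %s texture mode, %s parameters\n",
    x$spec$fusion_position, x$spec$width_multiplier,
    x$input_size[1], x$input_size[2], x$spec$texture_mode,
    format(x$n_parameters, big.mark = ",")
  ))
  invisible(x)
}

#' Layer/shape/parameter summary of a network
#'
#' @param net A `fusion_net`.
#' @return A tibble with one row per layer: branch, stage, layer, output
#'   channels, spatial size, parameter count.
#' @export
network_summary <- function(net) {
  spec <- net$spec
  h <- net$input_size[1]; w <- net$input_size[2]
  fb <- fusion_block_index(spec$fusion_position)
  rows <- list()
  emit <- function(branch, stage, layer, cout, hh, ww, n) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      branch = branch, stage = stage, layer = layer,
      channels = cout, height = hh, width = ww, n_params = n)
  }
  walk_branch <- function(branch_name, c_in, n_stages) {
    hh <- h; ww <- w; cin <- c_in
    for (b in seq_len(n_stages)) {
      cout <- spec$widths[b]
      for (i in seq_len(spec$depths[b])) {
        ci <- if (i == 1L) cin else cout
        emit(branch_name, b, i, cout, hh, ww, cout * (9 * ci + 1))
      }
      if (!(branch_name != "backbone" && b == n_stages)) {
        hh <- hh %/% 2L; ww <- ww %/% 2L
      }
      cin <- cout
    }
  }
  backbone_in <- if (spec$texture_mode != "none" && fb == 0L) spec$n_texture_channels else 1L
  walk_branch("backbone", backbone_in, 5L)
  if (spec$texture_mode == "stacked" && fb > 0L) {
    walk_branch("texture", spec$n_texture_channels, fb)
  } else if (spec$texture_mode == "separate_branches" && fb > 0L && !spec$share_weights) {
    for (i in seq_len(spec$n_texture_channels)) {
      walk_branch(sprintf("texture_%d", i), 1L, fb)
    }
  }
  if (spec$texture_mode != "none") {
    fc_ <- if (fb == 0L) spec$n_texture_channels else spec$widths[fb]
    sh <- if (fb == 0L) c(h, w) else c(h %/% 2L^(fb - 1L), w %/% 2L^(fb - 1L))
    emit("fusion", fb, 1L, fc_, sh[1], sh[2], fc_ * spec$fusion_kernel_size^2)
  }
  d_in <- (h %/% 32L) * (w %/% 32L) * spec$widths[5]
  emit("head", 6L, 1L, spec$fc_width, 1L, 1L, d_in * spec$fc_width + spec$fc_width)
  emit("head", 6L, 2L, 2L, 1L, 1L, spec$fc_width * 2 + 2)
  dplyr::bind_rows(rows)
}

# ---- Add fusion ----------------------------------------------------------

#' Element-wise Add fusion with per-channel kernels
#'
#' Fuses two same-shaped activation tensors: per channel i,
#' `z_i = (x_i + y_i) * k_i`, where `*` is (cross-)correlation with the
#' channel's kernel. With identity kernels this is exactly `x + y`, keeping
#' the dimensionality unchanged (the cheap alternative to channel
#' concatenation).
#'
#' @param x,y Numeric arrays `(H, W, C)` (a matrix is treated as `C = 1`).
#' @param k Per-channel kernels: `NULL` for identity, a numeric vector of
#'   length C (1x1 kernels), or a matrix `(C, s^2)` of flattened odd-sided
#'   square kernels (column-major patch order).
#' @return An array of the same shape as `x`.
#' @export
add_fuse <- function(x, y, k = NULL) {
  xa <- if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
  ya <- if (is.matrix(y)) array(y, dim = c(dim(y), 1L)) else y
  if (!identical(dim(xa), dim(ya))) {
    abort(sprintf("add_fuse shape mismatch: x is (%s) but y is (%s).",
                  paste(dim(xa), collapse = "x"), paste(dim(ya), collapse = "x")))
  }
  C <- dim(xa)[3]
  s <- xa + ya
  if (is.null(k)) {
    out <- s
  } else {
    if (is.numeric(k) && is.null(dim(k))) k <- matrix(k, length(k), 1L)
    if (nrow(k) != C) {
      abort(sprintf("`k` must supply one kernel per channel (%d), got %d.", C, nrow(k)))
    }
    ks <- as.integer(sqrt(ncol(k)))
    if (ks * ks != ncol(k) || ks %% 2L == 0L) {
      abort("each fusion kernel must be an odd-sided square.")
    }
    out <- array(0, dim = dim(xa))
    for (c_ in seq_len(C)) {
      sc <- array(s[, , c_], dim = c(dim(xa)[1:2], 1L))
      out[, , c_] <- conv_fwd(sc, matrix(k[c_, ], 1L), 0, ks)[, , 1L]
    }
  }
  if (is.matrix(x)) out[, , 1L] else out
}
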