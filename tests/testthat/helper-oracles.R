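# Independent reference implementations (slow scalar loops) used to verify
# the vectorized/compiled production code.

# Neighbor order shared contract: east first, counter-clockwise, bit i -> 2^i.
oracle_offsets_grid <- function() {
  list(dy = c(0, -1, -1, -1, 0, 1, 1, 1),
       dx = c(1, 1, 0, -1, -1, -1, 0, 1))
}

oracle_replicate_pad <- function(m, r) {
  ri <- c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

oracle_rotations_min <- function(bits) {
  best <- Inf
  for (r in seq_along(bits)) {
    rot <- bits[c(r:length(bits), seq_len(r - 1))]
    val <- sum(rot * 2^(seq_along(rot) - 1))
    if (val < best) best <- val
  }
  best
}

oracle_transitions <- function(bits) {
  n <- length(bits)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (bits[i] != bits[j]) s <- s + 1
  }
  s
}

# Ascending-code labels for uniform patterns at P = 8; non-uniform -> 58.
oracle_nri_label <- function(code) {
  uniform_codes <- integer(0)
  for (cd in 0:255) {
    b <- as.integer(intToBits(cd)[1:8])
    if (oracle_transitions(b) <= 2) uniform_codes <- c(uniform_codes, cd)
  }
  if (code %in% uniform_codes) which(uniform_codes == code) - 1 else length(uniform_codes)
}

oracle_lbp_pixel <- function(qc, qp, variant) {
  if (variant == "var") {
    return(mean((qp - mean(qp))^2))
  }
  bits <- as.integer(qp >= qc)
  code <- sum(bits * 2^(seq_along(bits) - 1))
  switch(variant,
    default = code,
    circular = code,
    ror = oracle_rotations_min(bits),
    uniform = if (oracle_transitions(bits) <= 2) sum(bits) else length(bits) + 1,
    nri_uniform = oracle_nri_label(code)
  )
}

oracle_bilinear_at <- function(mp, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  (1 - fy) * ((1 - fx) * mp[y0, x0] + fx * mp[y0, x0 + 1]) +
    fy * ((1 - fx) * mp[y0 + 1, x0] + fx * mp[y0 + 1, x0 + 1])
}

# Full-image LBP by per-pixel double loop, replicate padding, same extent.
oracle_lbp_map <- function(m, variant, P = 8, R = 1) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  if (variant == "circular") {
    pad <- ceiling(R) + 1
    mp <- oracle_replicate_pad(m, pad)
    theta <- 2 * pi * (seq_len(P) - 1) / P
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        qp <- numeric(P)
        for (p_ in seq_len(P)) {
          qp[p_] <- oracle_bilinear_at(mp, pad + i - R * sin(theta[p_]),
                                       pad + j + R * cos(theta[p_]))
        }
        out[i, j] <- oracle_lbp_pixel(m[i, j], qp, "circular")
      }
    }
  } else {
    mp <- oracle_replicate_pad(m, 1)
    off <- oracle_offsets_grid()
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        qp <- numeric(8)
        for (p_ in 1:8) {
          qp[p_] <- mp[1 + i + off$dy[p_], 1 + j + off$dx[p_]]
        }
        out[i, j] <- oracle_lbp_pixel(m[i, j], qp, variant)
      }
    }
  }
  out
}

# Per-pixel HOG voting loop: own central differences, own angle folding,
# own two-bin linear interpolation.
oracle_hog_cells <- function(m, cell_size, n_bins = 9, signed = FALSE) {
  h <- nrow(m); w <- ncol(m)
  mp <- oracle_replicate_pad(m, 1)
  cy <- h %/% cell_size; cx <- w %/% cell_size
  hist <- array(0, c(cy, cx, n_bins))
  span <- if (signed) 360 else 180
  bw <- span / n_bins
  for (i in seq_len(cy * cell_size)) {
    for (j in seq_len(cx * cell_size)) {
      fx <- mp[1 + i, 1 + j + 1] - mp[1 + i, 1 + j - 1]
      fy <- mp[1 + i + 1, 1 + j] - mp[1 + i - 1, 1 + j]
      mag <- sqrt(fx^2 + fy^2)
      if (mag == 0) next
      ang <- atan2(fy, fx) * 180 / pi
      ang <- ang %% span
      t_ <- ang / bw
      b0 <- floor(t_) %% n_bins
      fr <- t_ - floor(t_)
      ci_ <- (i - 1) %/% cell_size + 1
      cj <- (j - 1) %/% cell_size + 1
      hist[ci_, cj, b0 + 1] <- hist[ci_, cj, b0 + 1] + mag * (1 - fr)
      hist[ci_, cj, ((b0 + 1) %% n_bins) + 1] <- hist[ci_, cj, ((b0 + 1) %% n_bins) + 1] + mag * fr
    }
  }
  hist
}

# Brute-force counting oracle for classification metrics.
oracle_metrics <- function(pred, truth, averaging) {
  classes <- sort(unique(c(pred, truth)))
  n <- length(truth)
  prec <- rec <- f1 <- supp <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- fp <- fn <- 0
    for (i in seq_len(n)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    supp[ci] <- tp + fn
    prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec[ci] + rec[ci] > 0) 2 * prec[ci] * rec[ci] / (prec[ci] + rec[ci]) else 0
  }
  wts <- if (averaging == "weighted") supp / sum(supp) else rep(1 / length(classes), length(classes))
  list(accuracy = mean(pred == truth),
       precision = sum(wts * prec), recall = sum(wts * rec), f1 = sum(wts * f1))
}

# Symbolic shape propagation through the backbone layer list, independent of
# the closed-form division in fusion_position_shapes().
oracle_fusion_shapes <- function(widths, depths, input_size, n_tex) {
  h <- input_size[1]; w <- input_size[2]
  shapes <- list(input = c(n_tex, h, w))
  for (b in seq_along(widths)) {
    for (l in seq_len(depths[b])) {
      ch <- widths[b]  # 3x3 same-pad conv: spatial unchanged
    }
    shapes[[paste0("block", b)]] <- c(ch, h, w)  # pre-pool, after last conv
    h <- h %/% 2; w <- w %/% 2                    # the block's 2x2 max-pool
  }
  shapes
}

# Drop class and metadata attributes, keeping only the dim.
strip_attrs <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# Tiny helpers for building fixture images in code.
random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

write_test_png <- function(m, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".png")
  png::writePNG(m, path)
  path
}
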