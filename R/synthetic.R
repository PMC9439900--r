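# Synthetic two-class radiograph-like images.
#
# Both classes share a smooth low-frequency background (Gaussian-filtered
# white noise plus a vertical brightness gradient, thorax-like) and optional
# horizontal sinusoidal "rib" bands. The "pneumonia" class additionally
# receives soft-edged blob opacities carrying a localized intensity delta and
# fine-grained texture noise, placed inside a central elliptical lung-field
# mask, so the class signal is carried by local second-order texture by
# construction.

#' Specification of the synthetic dataset
#'
#' @param n_per_class Images per class.
#' @param image_size Integer pair, default `c(64, 64)` (desk scale; the
#'   generator accepts 224 for full-architecture smoke tests).
#' @param background List with `amplitude` (intensity amplitude of the smooth
#'   field) and `correlation_length` (Gaussian sigma, pixels).
#' @param lesion_model List with `count_range` (min/max blobs per image),
#'   `radius_range` (pixels), `intensity_delta` (added brightness at blob
#'   center) and `texture_sd` (sd of the fine-grained noise inside blobs).
#'   Setting `intensity_delta = 0` and `texture_sd = 0` yields the null
#'   construction: the two classes are distributionally identical.
#' @param rib_model List with `amplitude` and `spacing` (pixels) of the
#'   horizontal sinusoidal bands, or `NULL` for none.
#' @param seed Integer seed; generation is bit-deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 100L,
                           image_size = c(64L, 64L),
                           background = list(amplitude = 0.15, correlation_length = 8),
                           lesion_model = list(count_range = c(3L, 7L),
                                               radius_range = c(3, 8),
                                               intensity_delta = 0.3,
                                               texture_sd = 0.12),
                           rib_model = list(amplitude = 0.05, spacing = 12),
                           seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  stopifnot_scalar_number(n_per_class, "n_per_class", positive = TRUE)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L)) {
    abort("`image_size` must be two integers >= 8.")
  }
  structure(
    list(n_per_class = n_per_class, image_size = image_size,
         background = background, lesion_model = lesion_model,
         rib_model = rib_model, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Separable Gaussian blur via banded row/column smoothing matrices whose rows
# are renormalized at the borders.
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  offs <- (-half):half
  kern <- exp(-offs^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    M[i, j[ok]] <- kern[ok] / sum(kern[ok])
  }
  M
}

gaussian_blur <- function(m, sigma) {
  R <- blur_matrix(nrow(m), sigma)
  C <- blur_matrix(ncol(m), sigma)
  R %*% m %*% t(C)
}

# One synthetic image; RNG state is the caller's responsibility.
synth_image <- function(spec, with_lesions) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  bg <- spec$background
  base <- matrix(0.45, h, w)
  base <- base + matrix(seq(-0.1, 0.1, length.out = h), h, w)  # vertical gradient
  noise <- matrix(rnorm(h * w), h, w)
  field <- gaussian_blur(noise, bg$correlation_length)
  if (max(abs(field)) > 0) field <- field / max(abs(field)) * bg$amplitude
  base <- base + field
  if (!is.null(spec$rib_model)) {
    rib <- spec$rib_model$amplitude * sin(2 * pi * seq_len(h) / spec$rib_model$spacing)
    base <- base + matrix(rib, h, w)
  }
  if (with_lesions) {
    lm <- spec$lesion_model
    n_lesions <- sample(lm$count_range[1]:lm$count_range[2], 1L)
    cy0 <- h / 2; cx0 <- w / 2
    ay <- 0.42 * h; ax <- 0.38 * w  # lung-field ellipse semi-axes
    for (i in seq_len(n_lesions)) {
      repeat {
        cy <- runif(1, 1, h); cx <- runif(1, 1, w)
        if (((cy - cy0) / ay)^2 + ((cx - cx0) / ax)^2 <= 1) break
      }
      r <- runif(1, lm$radius_range[1], lm$radius_range[2])
      d2 <- outer(seq_len(h), seq_len(w),
                  function(y, x) (y - cy)^2 + (x - cx)^2)
      g <- exp(-d2 / (2 * (r / 2)^2))
      base <- base + lm$intensity_delta * g
      if (lm$texture_sd > 0) {
        base <- base + matrix(rnorm(h * w, sd = lm$texture_sd), h, w) * (g > 0.2)
      }
    }
  }
  pmin(pmax(base, 0), 1)
}

#' Generate a synthetic two-class image dataset on disk
#'
#' Writes `out_dir/pneumonia/*.png` and `out_dir/normal/*.png` (8-bit
#' grayscale) plus `manifest.csv`. Both classes share the background and rib
#' models; only the pneumonia class receives blob opacities. Bit-identical
#' output for a fixed spec.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Writable output directory (created if missing).
#' @return The manifest as a tibble (`filename`, `class`, `n_lesions`,
#'   invisible attributes echoing the spec).
#' @export
generate_dataset <- function(spec, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory: %s", out_dir))
  }
  for (cl in c("normal", "pneumonia")) {
    dir.create(file.path(out_dir, cl), showWarnings = FALSE)
  }
  rows <- with_seed(spec$seed, {
    out <- vector("list", 2L * spec$n_per_class)
    i <- 0L
    for (cl in c("normal", "pneumonia")) {
      for (j in seq_len(spec$n_per_class)) {
        m <- synth_image(spec, with_lesions = (cl == "pneumonia"))
        fn <- sprintf("%s_%03d.png", cl, j)
        png::writePNG(m, file.path(out_dir, cl, fn))
        i <- i + 1L
        out[[i]] <- tibble::tibble(filename = file.path(cl, fn), class = cl)
      }
    }
    out
  })
  manifest <- dplyr::bind_rows(rows)
  manifest$image_height <- spec$image_size[1]
  manifest$image_width <- spec$image_size[2]
  manifest$seed <- spec$seed
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read the class-directory layout of an image dataset
#'
#' @param dir Root directory with one subdirectory per class containing PNG
#'   (or JPEG) files.
#' @return A tibble with `sample_id`, `path`, `class`.
#' @export
read_image_manifest <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no such dataset directory: %s", dir))
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  classes <- classes[classes != ""]
  if (length(classes) == 0L) abort(sprintf("no class subdirectories under %s", dir))
  rows <- lapply(classes, function(cl) {
    fs <- sort(list.files(file.path(dir, cl), pattern = "\\.(png|jpe?g)$",
                          ignore.case = TRUE))
    if (length(fs) == 0L) return(NULL)
    tibble::tibble(sample_id = file.path(cl, fs),
                   path = file.path(dir, cl, fs), class = cl)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort(sprintf("no images found under %s", dir))
  out
}

# Per-image separation features: normalized LBP code histogram plus mean
# gradient magnitude (HOG energy).
separation_features <- function(paths, lbp_cfg, hog_cfg) {
  imgs <- lapply(paths, function(p) as_pixel_matrix(load_gray(p)))
  int_variant <- lbp_cfg$variant != "var"
  if (int_variant) {
    nb <- lbp_max_code(lbp_cfg) + 1L
    breaks <- seq(-0.5, lbp_max_code(lbp_cfg) + 0.5, by = 1)
  } else {
    # var codes are continuous; bin on a pooled fixed grid (label-free).
    all_codes <- unlist(lapply(imgs, function(m) as.numeric(lbp_map(m, lbp_cfg))))
    top <- stats::quantile(all_codes, 0.99)
    if (top <= 0) top <- 1e-12
    breaks <- c(seq(0, top, length.out = 17L), Inf)
    nb <- length(breaks) - 1L
  }
  feats <- t(vapply(imgs, function(m) {
    codes <- as.numeric(lbp_map(m, lbp_cfg))
    hcounts <- hist(codes, breaks = breaks, plot = FALSE)$counts
    g <- gradients(m, hog_cfg)
    c(hcounts / length(codes), mean(g$magnitude))
  }, numeric(nb + 1L)))
  feats
}

#' Permutation test of texture separation between the two classes
#'
#' Summarizes each image by its LBP code histogram and mean gradient
#' magnitude, standardizes the features over the pooled sample, and measures
#' the Euclidean distance between class mean feature vectors. Significance is
#' assessed by permuting class labels.
#'
#' @param dataset_dir Dataset in the class-directory layout (two classes).
#' @param lbp_cfg An [lbp_config()].
#' @param hog_cfg A [hog_config()].
#' @param n_permutations At least 999 by default.
#' @param seed Integer seed for the permutations.
#' @return A `separation_check` list with `score`, `p_value`,
#'   `n_permutations`, `n_images`.
#' @export
texture_separation_check <- function(dataset_dir, lbp_cfg = lbp_config(),
                                     hog_cfg = hog_config(),
                                     n_permutations = 999L, seed = 1L) {
  manifest <- read_image_manifest(dataset_dir)
  classes <- unique(manifest$class)
  if (length(classes) < 2L) {
    abort(sprintf("separation check needs two classes; found only %s.",
                  paste(shQuote(classes), collapse = ", ")))
  }
  feats <- separation_features(manifest$path, lbp_cfg, hog_cfg)
  mu <- colMeans(feats)
  sdv <- apply(feats, 2L, stats::sd)
  keep <- sdv > 0
  z <- sweep(sweep(feats[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
  lab <- manifest$class == classes[1L]
  stat <- function(l) {
    sqrt(sum((colMeans(z[l, , drop = FALSE]) - colMeans(z[!l, , drop = FALSE]))^2))
  }
  obs <- stat(lab)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) stat(sample(lab)), numeric(1))
  })
  structure(
    list(score = obs,
         p_value = (1 + sum(perm >= obs)) / (n_permutations + 1),
         n_permutations = as.integer(n_permutations),
         n_images = nrow(manifest)),
    class = "separation_check"
  )
}

#' @export
print.separation_check <- function(x, ...) {
  cat(sprintf(
    "<separation_check> score %.3f, permutation p = %.4g (%d permutations, %d images)\n",
    x$score, x$p_value, x$n_permutations, x$n_images))
  invisible(x)
}
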