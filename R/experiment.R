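# End-to-end experiment harness: preprocess -> texture extraction -> k-fold
# training of the fused network -> evaluation.

#' Assemble a full experiment configuration
#'
#' @param data Either a [synthetic_spec()] (the dataset is generated into a
#'   temporary directory, or under `out_dir` if given) or a list
#'   `list(dir = "<path>")` pointing at a class-directory image layout.
#' @param input_size Network input size (height, width), divisible by 32.
#'   Also used as the preprocessing target size.
#' @param preprocess A [preprocess_config()]; its `target_size` is forced to
#'   `input_size`.
#' @param lbp An [lbp_config()].
#' @param hog A [hog_config()].
#' @param model A [fusion_net_spec()].
#' @param train A [train_config()].
#' @param k Number of cross-validation folds.
#' @param use_texture `FALSE` runs the depth-only ablation (the texture
#'   branch is dropped and only the preprocessed image enters the network).
#' @param averaging Metric averaging mode, `"weighted"` or `"macro"`.
#' @param seed Master seed; fold assignment and per-fold initialization /
#'   training seeds are derived from it.
#' @param out_dir Optional results directory.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(data = synthetic_spec(),
                              input_size = c(64L, 64L),
                              preprocess = preprocess_config(crop_mode = "none"),
                              lbp = lbp_config("var"),
                              hog = hog_config(cell_size = 2L),
                              model = fusion_net_spec(width_multiplier = 1 / 8),
                              train = train_config(learning_rate = 1e-3,
                                                   epochs = 10L, batch_size = 16L),
                              k = 2L, use_texture = TRUE,
                              averaging = "weighted",
                              seed = 1L, out_dir = NULL) {
  input_size <- as.integer(input_size)
  preprocess$target_size <- input_size
  structure(
    list(data = data, input_size = input_size, preprocess = preprocess,
         lbp = lbp, hog = hog, model = model, train = train,
         k = as.integer(k), use_texture = isTRUE(use_texture),
         averaging = averaging, seed = as.integer(seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Recognized blocks: `data` (either `dir:` or a `synthetic:` block),
#' `preprocessing`, `lbp`, `hog`, `model`, `train`, plus top-level
#' `input_size`, `k`, `use_texture`, `averaging`, `seed`, `out_dir`.
#' Missing entries fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, args) do.call(fun, args %||% list())
  data <- if (!is.null(y$data$dir)) {
    list(dir = y$data$dir)
  } else {
    build(synthetic_spec, y$data$synthetic)
  }
  experiment_config(
    data = data,
    input_size = y$input_size %||% c(64L, 64L),
    preprocess = build(preprocess_config, y$preprocessing),
    lbp = build(lbp_config, y$lbp),
    hog = build(hog_config, y$hog),
    model = build(fusion_net_spec, y$model),
    train = build(train_config, y$train),
    k = y$k %||% 2L,
    use_texture = y$use_texture %||% TRUE,
    averaging = y$averaging %||% "weighted",
    seed = y$seed %||% 1L,
    out_dir = y$out_dir
  )
}

# Load and featurize every image of a manifest: preprocessed depth image plus
# the stacked LBP/HOG texture image.
prepare_samples <- function(manifest, cfg) {
  depth <- vector("list", nrow(manifest))
  texture <- if (cfg$use_texture) vector("list", nrow(manifest)) else NULL
  for (i in seq_len(nrow(manifest))) {
    img <- preprocess_image(manifest$path[i], cfg$preprocess)
    m <- as_pixel_matrix(img)
    depth[[i]] <- m
    if (cfg$use_texture) {
      lb <- as_pixel_matrix(lbp_image(m, cfg$lbp))
      hg <- as_pixel_matrix(hog_image(m, cfg$hog, out_size = dim(m)))
      texture[[i]] <- array(c(lb, hg), dim = c(dim(m), 2L))
    }
  }
  list(depth = depth, texture = texture)
}

#' Run a k-fold cross-validated experiment
#'
#' For each fold: preprocess, extract texture feature images, train the
#' fused (or depth-only) network on the remaining folds, and evaluate on the
#' held-out fold. A failing fold is logged and skipped; the others continue.
#' When `out_dir` is set, writes `metrics.json`, `predictions.csv`,
#' `resolved_config.yaml` and `log.txt`.
#'
#' @param cfg An [experiment_config()].
#' @return A `texfuse_result` with per-fold and mean metrics, per-sample
#'   predictions, the resolved configuration and all seeds used.
#' @export
run_experiment <- function(cfg) {
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (inherits(cfg$data, "synthetic_spec")) {
    data_dir <- if (!is.null(cfg$out_dir)) file.path(cfg$out_dir, "data") else
      tempfile("texfuse_synth_")
    say("generating synthetic dataset (n_per_class = %d, %dx%d, seed %d)",
        cfg$data$n_per_class, cfg$data$image_size[1], cfg$data$image_size[2],
        cfg$data$seed)
    generate_dataset(cfg$data, data_dir)
  } else {
    data_dir <- cfg$data$dir
  }
  manifest <- read_image_manifest(data_dir)
  classes <- sort(unique(manifest$class))
  say("dataset: %d images, classes: %s", nrow(manifest),
      paste(classes, collapse = ", "))
  model_spec <- cfg$model
  if (!cfg$use_texture) {
    model_spec <- fusion_net_spec(
      fusion_position = cfg$model$fusion_position,
      width_multiplier = cfg$model$width_multiplier,
      dropout_rate = cfg$model$dropout_rate,
      texture_mode = "none"
    )
  }
  samples <- prepare_samples(manifest, cfg)
  truth <- manifest$class
  folds <- make_folds(manifest[, c("sample_id", "class")], k = cfg$k,
                      seed = derive_seed(cfg$seed, 0L))
  fold_ids <- sort(unique(folds$fold))
  fold_reports <- list()
  fold_seeds <- list()
  predictions <- list()
  for (f in fold_ids) {
    test_idx <- which(folds$fold == f)
    train_idx <- which(folds$fold != f)
    init_seed <- derive_seed(cfg$seed, f * 10L + 1L)
    train_seed <- derive_seed(cfg$seed, f * 10L + 2L)
    fold_seeds[[as.character(f)]] <- c(init = init_seed, train = train_seed)
    res <- tryCatch({
      net <- build_network(model_spec, input_size = cfg$input_size,
                           seed = init_seed)
      tcfg <- cfg$train
      tcfg$seed <- train_seed
      say("fold %d: training %s model (%d train / %d test, %d epochs)",
          f, if (cfg$use_texture) "fused" else "depth-only",
          length(train_idx), length(test_idx), tcfg$epochs)
      net <- fit_network(net, list(
        depth = samples$depth[train_idx],
        texture = if (cfg$use_texture) samples$texture[train_idx] else NULL,
        y = match(truth[train_idx], classes)
      ), tcfg)
      pr <- predict_network(net, list(
        depth = samples$depth[test_idx],
        texture = if (cfg$use_texture) samples$texture[test_idx] else NULL
      ))
      pred_class <- classes[pr$.pred_class]
      rep <- compute_metrics(pred_class, truth[test_idx],
                             averaging = cfg$averaging, classes = classes)
      say("fold %d: accuracy %.4f, precision %.4f, recall %.4f, F1 %.4f",
          f, rep$accuracy, rep$precision, rep$recall, rep$f1)
      list(report = rep,
           pred = tibble::tibble(sample_id = manifest$sample_id[test_idx],
                                 fold = f, truth = truth[test_idx],
                                 prediction = pred_class,
                                 score = pr$score_2))
    }, error = function(e) {
      say("fold %d FAILED: %s", f, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      fold_reports[[as.character(f)]] <- res$report
      predictions[[as.character(f)]] <- res$pred
    }
  }
  if (length(fold_reports) == 0L) abort("all folds failed; see the log.")
  fold_metrics <- dplyr::bind_rows(lapply(names(fold_reports), function(f) {
    dplyr::mutate(glance(fold_reports[[f]]), fold = as.integer(f),
                  .before = 1L)
  }))
  mean_metrics <- tibble::tibble(
    accuracy = mean(fold_metrics$accuracy),
    precision = mean(fold_metrics$precision),
    recall = mean(fold_metrics$recall),
    f1 = mean(fold_metrics$f1),
    n_folds = nrow(fold_metrics)
  )
  say("mean over %d folds: accuracy %.4f, precision %.4f, recall %.4f, F1 %.4f",
      mean_metrics$n_folds, mean_metrics$accuracy, mean_metrics$precision,
      mean_metrics$recall, mean_metrics$f1)
  result <- structure(
    list(fold_reports = fold_reports,
         fold_metrics = fold_metrics,
         mean_metrics = mean_metrics,
         predictions = dplyr::bind_rows(predictions),
         classes = classes,
         config = cfg,
         seeds = list(master = cfg$seed, folds = fold_seeds),
         log = log_lines),
    class = "texfuse_result"
  )
  if (!is.null(cfg$out_dir)) write_result(result, cfg$out_dir)
  result
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

write_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(per_fold = result$fold_metrics, mean = result$mean_metrics,
         seeds = result$seeds),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  utils::write.csv(result$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  cfg <- result$config
  cfg$out_dir <- NULL
  yaml::write_yaml(strip_classes(cfg), file.path(out_dir, "resolved_config.yaml"))
  writeLines(result$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.texfuse_result <- function(x, ...) {
  cat(sprintf("<texfuse_result> %d folds, classes: %s\n",
              nrow(x$fold_metrics), paste(x$classes, collapse = ", ")))
  print(x$fold_metrics)
  cat("mean:\n")
  print(x$mean_metrics)
  invisible(x)
}

#' @method tidy texfuse_result
#' @export
tidy.texfuse_result <- function(x, ...) {
  x$fold_metrics
}

#' @method glance texfuse_result
#' @export
glance.texfuse_result <- function(x, ...) {
  x$mean_metrics
}

#' Plot per-fold metrics of an experiment
#'
#' @param object A `texfuse_result`.
#' @param ... Unused.
#' @return A ggplot object: one point per fold and metric, with the mean
#'   marked.
#' @method autoplot texfuse_result
#' @export
autoplot.texfuse_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$fold_metrics,
                              c("accuracy", "precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  means <- tidyr::pivot_longer(object$mean_metrics[, 1:4],
                               dplyr::everything(),
                               names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$fold)), size = 2) +
    ggplot2::geom_point(data = means, shape = 95, size = 10) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, color = "fold",
                  title = "Cross-validated metrics (bar = mean)") +
    ggplot2::theme_minimal()
}

#' Sweep one experimental axis
#'
#' Re-runs [run_experiment()] for every value of the chosen axis and gathers
#' the mean metrics into one comparison table (the shape of the usual
#' variant / cell-size / fusion-position comparison tables).
#'
#' @param cfg An [experiment_config()] providing everything but the swept
#'   value.
#' @param axis One of `"lbp_variant"`, `"hog_cell_size"`, `"fusion_position"`.
#' @param values Optional subset of axis values; defaults to the full roster
#'   (six LBP variants, cell sizes 2-32, six fusion positions).
#' @return A tibble with columns `value`, `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
sweep_axis <- function(cfg, axis = c("lbp_variant", "hog_cell_size",
                                     "fusion_position"),
                       values = NULL) {
  axis <- match.arg(axis)
  values <- values %||% switch(axis,
    lbp_variant = c("default", "ror", "uniform", "nri_uniform", "var", "circular"),
    hog_cell_size = c(2L, 4L, 8L, 16L, 32L),
    fusion_position = FUSION_POSITIONS
  )
  rows <- lapply(values, function(v) {
    cfg2 <- cfg
    cfg2$out_dir <- NULL
    if (axis == "lbp_variant") {
      cfg2$lbp <- lbp_config(v, cfg$lbp$neighbors_P, cfg$lbp$radius_R)
    } else if (axis == "hog_cell_size") {
      cfg2$hog$cell_size <- as.integer(v)
    } else {
      cfg2$model$fusion_position <- v
    }
    res <- run_experiment(cfg2)
    dplyr::mutate(glance(res)[, c("accuracy", "precision", "recall", "f1")],
                  value = as.character(v), .before = 1L)
  })
  dplyr::bind_rows(rows)
}
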