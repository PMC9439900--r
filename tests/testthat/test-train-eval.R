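make_labels <- function(n_a, n_b) {
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n_a + n_b)),
    class = c(rep("a", n_a), rep("b", n_b))
  )
}

test_that("make_folds stratifies exactly, balances remainders, and is seed-deterministic", {
  f <- make_folds(make_labels(5, 5), k = 5, seed = 1)
  tab <- table(f$class, f$fold)
  expect_true(all(tab == 1))

  f2 <- make_folds(make_labels(5, 5), k = 5, seed = 1)
  expect_identical(f, f2)
  f3 <- make_folds(make_labels(5, 5), k = 5, seed = 2)
  expect_false(identical(f$fold, f3$fold))

  f13 <- make_folds(make_labels(13, 20), k = 5, seed = 3)
  sizes <- sort(as.integer(table(f13$fold[f13$class == "a"])), decreasing = TRUE)
  expect_identical(sizes, c(3L, 3L, 3L, 2L, 2L))

  # exhaustive and disjoint: every sample in exactly one fold
  expect_identical(sort(f13$sample_id), sort(make_labels(13, 20)$sample_id))
  expect_true(all(!is.na(f13$fold)))
})

test_that("make_folds rejects classes smaller than k", {
  expect_error(make_folds(make_labels(3, 10), k = 5), "fewer than k")
})

test_that("compute_metrics reproduces the worked confusion example and the perfect case", {
  # positive class 'p': tp=3 fp=1 fn=2, negative class 'n': tn=4
  truth <- c(rep("p", 5), rep("n", 5))
  pred <- c("p", "p", "p", "n", "n", "p", "n", "n", "n", "n")
  rep_ <- compute_metrics(pred, truth)
  pc <- rep_$per_class[rep_$per_class$class == "p", ]
  expect_equal(c(pc$tp, pc$fp, pc$tn, pc$fn), c(3, 1, 4, 2))
  expect_equal(rep_$accuracy, 0.7)
  expect_equal(pc$precision, 0.75)
  expect_equal(pc$recall, 0.6)
  expect_equal(pc$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)

  perfect <- compute_metrics(truth, truth, averaging = "macro")
  expect_equal(unlist(glance(perfect)[, 1:4]), c(accuracy = 1, precision = 1,
                                                 recall = 1, f1 = 1))
})

test_that("compute_metrics matches the brute-force counting oracle on random label pairs", {
  set.seed(33)
  for (rep_i in 1:25) {
    n <- sample(5:40, 1)
    truth <- sample(c("x", "y"), n, replace = TRUE)
    pred <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    for (avg in c("weighted", "macro")) {
      got <- suppressWarnings(compute_metrics(pred, truth, averaging = avg))
      want <- oracle_metrics(pred, truth, avg)
      expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
      expect_equal(got$precision, want$precision, tolerance = 1e-12)
      expect_equal(got$recall, want$recall, tolerance = 1e-12)
      expect_equal(got$f1, want$f1, tolerance = 1e-12)
    }
    # binary identity: weighted recall == accuracy, exactly
    got_w <- suppressWarnings(compute_metrics(pred, truth, averaging = "weighted"))
    expect_identical(got_w$recall, got_w$accuracy)
    # F1 lies between min and max of (precision, recall), per class
    per <- got_w$per_class
    expect_true(all(per$f1 >= pmin(per$precision, per$recall) - 1e-12))
    expect_true(all(per$f1 <= pmax(per$precision, per$recall) + 1e-12))
  }
})

test_that("degenerate predictions trigger the zero-division convention with a warning", {
  truth <- rep(c("a", "b"), each = 4)
  pred <- rep("a", 8)
  expect_warning(rep_ <- compute_metrics(pred, truth), "never predicted")
  expect_equal(rep_$accuracy, 0.5)
  expect_equal(rep_$recall, 0.5)  # weighted recall == accuracy
  expect_equal(rep_$per_class$precision[rep_$per_class$class == "b"], 0)
  expect_error(compute_metrics(c("a"), c("a", "b")), "differ in length")
})

tiny_cfg <- function(seed = 5L, use_texture = TRUE, epochs = 2L) {
  experiment_config(
    data = synthetic_spec(n_per_class = 6L, image_size = c(32L, 32L), seed = 71L),
    input_size = c(32L, 32L),
    model = fusion_net_spec(width_multiplier = 1 / 16),
    train = train_config(learning_rate = 1e-3, epochs = epochs, batch_size = 4L),
    k = 2L, use_texture = use_texture, seed = seed
  )
}

test_that("run_experiment emits the full results bundle and is run-to-run deterministic", {
  out_dir <- file.path(tempdir(), "texfuse_res")
  unlink(out_dir, recursive = TRUE)
  cfg <- tiny_cfg()
  cfg$out_dir <- out_dir
  res <- suppressWarnings(suppressMessages(run_experiment(cfg)))
  expect_s3_class(res, "texfuse_result")
  expect_equal(nrow(res$fold_metrics), 2L)
  expect_equal(nrow(res$predictions), 12L)
  expect_named(res$mean_metrics, c("accuracy", "precision", "recall", "f1", "n_folds"))
  expect_true(all(file.exists(file.path(out_dir,
    c("metrics.json", "predictions.csv", "resolved_config.yaml", "log.txt")))))
  expect_identical(sort(unique(res$predictions$fold)), c(0L, 1L))

  cfg2 <- tiny_cfg()
  res2 <- suppressWarnings(suppressMessages(run_experiment(cfg2)))
  expect_identical(res$fold_metrics, res2$fold_metrics)
  expect_identical(res$predictions$prediction, res2$predictions$prediction)

  g <- glance(res); t_ <- tidy(res)
  expect_identical(g, res$mean_metrics)
  expect_identical(t_, res$fold_metrics)
})

test_that("the depth-only ablation produces the same bundle shape", {
  res <- suppressWarnings(suppressMessages(run_experiment(tiny_cfg(use_texture = FALSE))))
  expect_equal(nrow(res$fold_metrics), 2L)
  expect_equal(nrow(res$predictions), 12L)
})

test_that("sweep_axis produces the full roster tables", {
  cfg <- tiny_cfg(epochs = 1L)
  # 1-epoch runs may collapse to one class; those warnings are expected here
  tab <- suppressWarnings(suppressMessages(
    sweep_axis(cfg, axis = "fusion_position",
               values = c("input", "block1", "block3"))))
  expect_equal(nrow(tab), 3L)
  expect_named(tab, c("value", "accuracy", "precision", "recall", "f1"))
  tab2 <- suppressWarnings(suppressMessages(
    sweep_axis(cfg, axis = "lbp_variant", values = c("default", "var"))))
  expect_equal(tab2$value, c("default", "var"))
})

test_that("training on texture-separable synthetic data reaches high training accuracy quickly", {
  # directional learning sanity: majority of 3 seeds exceed 0.9 train accuracy
  # within 10 epochs on a small separable set
  dir <- file.path(tempdir(), "texfuse_sanity")
  if (!dir.exists(dir)) {
    generate_dataset(synthetic_spec(n_per_class = 25L, image_size = c(32L, 32L),
                                    seed = 99L), dir)
  }
  manifest <- read_image_manifest(dir)
  cfg <- experiment_config(data = list(dir = dir), input_size = c(32L, 32L),
                           model = fusion_net_spec(width_multiplier = 1 / 8))
  samples <- texfuse:::prepare_samples(manifest, cfg)
  y <- match(manifest$class, sort(unique(manifest$class)))
  passes <- vapply(c(7L, 87L, 870L), function(s) {
    net <- build_network(cfg$model, input_size = c(32L, 32L), seed = s)
    fitted <- fit_network(net, list(depth = samples$depth,
                                    texture = samples$texture, y = y),
                          train_config(learning_rate = 1e-3, epochs = 10L,
                                       batch_size = 16L, seed = s + 1L))
    tail(fitted$history$train_accuracy, 1) > 0.9
  }, logical(1))
  expect_gte(sum(passes), 2L)
})
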