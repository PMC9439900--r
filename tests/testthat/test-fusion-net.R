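test_that("add_fuse with identity kernels is the exact elementwise sum, commutative, shape-preserving", {
  set.seed(5)
  for (C in c(1L, 2L, 64L)) {
    x <- array(rnorm(6 * 6 * C), c(6, 6, C))
    y <- array(rnorm(6 * 6 * C), c(6, 6, C))
    z <- add_fuse(x, y)
    expect_identical(dim(z), dim(x))
    expect_identical(z, x + y)
    expect_identical(add_fuse(y, x), z)
    zi <- add_fuse(x, y, k = rep(1, C))
    expect_equal(zi, x + y, tolerance = 1e-12)
  }
  # integer-valued tensors: identity fusion is bitwise exact
  xi <- array(as.double(sample.int(100, 32, replace = TRUE)), c(4, 4, 2))
  yi <- array(as.double(sample.int(100, 32, replace = TRUE)), c(4, 4, 2))
  expect_identical(add_fuse(xi, yi), xi + yi)
})

test_that("add_fuse applies per-channel kernels: 1x1 weight w gives w * (x + y)", {
  set.seed(6)
  x <- array(rnorm(9), c(3, 3, 1))
  y <- array(rnorm(9), c(3, 3, 1))
  w <- 0.37
  expect_equal(add_fuse(x, y, k = w), w * (x + y), tolerance = 1e-12)
  # x = zeros with identity kernel returns y
  expect_equal(add_fuse(array(0, dim(y)), y, k = 1), y, tolerance = 1e-12)
  # 3x3 kernel against a hand-rolled convolution at the center pixel
  k3 <- matrix(rnorm(9), 1, 9)
  z <- add_fuse(x, y, k = k3)
  s <- x[, , 1] + y[, , 1]
  manual <- sum(s * matrix(k3[1, ], 3, 3))  # center of a 3x3 image, zero pad
  expect_equal(z[2, 2, 1], manual, tolerance = 1e-12)
})

test_that("add_fuse rejects mismatched shapes, naming both", {
  x <- array(0, c(4, 4, 2)); y <- array(0, c(4, 5, 2))
  expect_error(add_fuse(x, y), "4x4x2.*4x5x2")
  expect_error(add_fuse(x, array(0, c(4, 4, 2)), k = rep(1, 3)), "per channel")
})

test_that("fusion_position_shapes matches independent symbolic shape propagation", {
  spec <- fusion_net_spec(width_multiplier = 1)
  tab <- fusion_position_shapes(spec, c(224L, 224L))
  want <- oracle_fusion_shapes(c(64, 128, 256, 512, 512), c(2, 2, 3, 3, 3),
                               c(224, 224), n_tex = 2)
  for (i in seq_len(nrow(tab))) {
    expect_equal(unname(unlist(tab[i, c("channels", "height", "width")])),
                 unname(want[[tab$position[i]]]))
  }
  expect_equal(unlist(tab[tab$position == "block3", c("channels", "height", "width")]),
               c(channels = 256, height = 56, width = 56))
  expect_equal(unlist(tab[tab$position == "block5", c("height", "width")]),
               c(height = 14, width = 14))
  expect_error(fusion_position_shapes(spec, c(100L, 100L)), "divisible")
})

test_that("parameter counts: symbolic equals built, scaled-down is tiny, counts grow with fusion depth", {
  spec8 <- fusion_net_spec(width_multiplier = 1 / 8)
  net <- build_network(spec8, input_size = c(64L, 64L), seed = 3L)
  expect_equal(net$n_parameters, count_parameters(spec8, c(64L, 64L)))
  expect_identical(sum(network_summary(net)$n_params), net$n_parameters)

  full <- count_parameters(fusion_net_spec(width_multiplier = 1), c(64L, 64L))
  expect_lt(net$n_parameters, full / 10)

  counts <- vapply(c("input", paste0("block", 1:5)), function(pos) {
    count_parameters(fusion_net_spec(fusion_position = pos,
                                     width_multiplier = 1 / 8), c(64L, 64L))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the two-FC head is strictly smaller than the original three-FC head, and the block3 fusion model undercuts plain VGG-16", {
  spec <- fusion_net_spec(fusion_position = "block3", width_multiplier = 1)
  ours_head <- texfuse:::head_parameter_count(7 * 7 * 512, 4096)
  expect_lt(ours_head, vgg16_head_parameter_count())
  expect_lt(count_parameters(spec, c(224L, 224L)), vgg16_parameter_count())
})

test_that("forward pass produces a 2-class score for full and scaled specs, all fusion positions", {
  for (pos in c("input", "block1", "block3", "block5")) {
    spec <- fusion_net_spec(fusion_position = pos, width_multiplier = 1 / 16)
    net <- build_network(spec, input_size = c(32L, 32L), seed = 2L)
    fw <- texfuse:::forward_sample(net$params, spec,
                                   matrix(runif(32 * 32), 32, 32),
                                   array(runif(32 * 32 * 2), c(32, 32, 2)))
    expect_length(fw$logits, 2L)
    expect_true(all(is.finite(fw$logits)))
  }
})

test_that("zeroing the texture branch with identity kernels reproduces the depth-only network", {
  spec_f <- fusion_net_spec(fusion_position = "block3", width_multiplier = 1 / 8)
  spec_d <- fusion_net_spec(fusion_position = "block3", width_multiplier = 1 / 8,
                            texture_mode = "none")
  net_f <- build_network(spec_f, input_size = c(32L, 32L), seed = 11L)
  net_d <- build_network(spec_d, input_size = c(32L, 32L), seed = 12L)
  # share backbone + head weights; zero every texture-branch parameter
  net_d$params$backbone <- net_f$params$backbone
  net_d$params$head <- net_f$params$head
  net_f$params$texture <- texfuse:::tree_zero(net_f$params$texture)
  depth <- matrix(runif(32 * 32), 32, 32)
  tex <- array(runif(32 * 32 * 2), c(32, 32, 2))
  lf <- texfuse:::forward_sample(net_f$params, spec_f, depth, tex)$logits
  ld <- texfuse:::forward_sample(net_d$params, spec_d, depth, NULL)$logits
  expect_equal(lf, ld, tolerance = 1e-5)
})

test_that("backpropagation matches finite differences across branches, fusion kernels and head", {
  spec <- fusion_net_spec(fusion_position = "block2", width_multiplier = 1 / 16,
                          dropout_rate = 0)
  net <- build_network(spec, input_size = c(32L, 32L), seed = 17L)
  set.seed(18)
  depth <- matrix(runif(32 * 32), 32, 32)
  tex <- array(runif(32 * 32 * 2), c(32, 32, 2))
  p <- net$params
  lossfn <- function(pp) {
    f <- texfuse:::forward_sample(pp, spec, depth, tex, FALSE)
    -log(texfuse:::softmax(f$logits)[1])
  }
  f0 <- texfuse:::forward_sample(p, spec, depth, tex, FALSE)
  dl <- texfuse:::softmax(f0$logits); dl[1] <- dl[1] - 1
  g <- texfuse:::backward_sample(p, spec, f0$cache, dl)
  eps <- 1e-5
  probe <- function(get, set, idx) {
    p1 <- set(p, idx, get(p)[idx] + eps)
    p2 <- set(p, idx, get(p)[idx] - eps)
    expect_equal(get(g)[idx], (lossfn(p1) - lossfn(p2)) / (2 * eps),
                 tolerance = 1e-4)
  }
  probe(function(q) q$backbone[[1]][[1]]$w,
        function(q, i, v) { q$backbone[[1]][[1]]$w[i] <- v; q }, 2L)
  probe(function(q) q$backbone[[4]][[2]]$b,
        function(q, i, v) { q$backbone[[4]][[2]]$b[i] <- v; q }, 1L)
  probe(function(q) q$texture[[1]][[2]][[1]]$w,
        function(q, i, v) { q$texture[[1]][[2]][[1]]$w[i] <- v; q }, 7L)
  probe(function(q) q$fuse,
        function(q, i, v) { q$fuse[i] <- v; q }, 3L)
  probe(function(q) q$head$W2,
        function(q, i, v) { q$head$W2[i] <- v; q }, 4L)
})

test_that("one training step moves parameters in both the backbone and the texture branch", {
  spec <- fusion_net_spec(width_multiplier = 1 / 16)
  net <- build_network(spec, input_size = c(32L, 32L), seed = 23L)
  set.seed(24)
  data <- list(
    depth = lapply(1:4, function(i) matrix(runif(32 * 32), 32, 32)),
    texture = lapply(1:4, function(i) array(runif(32 * 32 * 2), c(32, 32, 2))),
    y = c(1L, 2L, 1L, 2L)
  )
  fitted <- fit_network(net, data, train_config(learning_rate = 1e-3, epochs = 1L,
                                                batch_size = 4L, seed = 9L))
  delta <- function(a, b) max(abs(unlist(a) - unlist(b)))
  expect_gt(delta(fitted$params$backbone, net$params$backbone), 0)
  expect_gt(delta(fitted$params$texture, net$params$texture), 0)
})

test_that("spec validation rejects inconsistent configurations", {
  expect_error(fusion_net_spec(fusion_position = "block9"), "fusion_position")
  expect_error(fusion_net_spec(width_multiplier = 2), "width_multiplier")
  expect_error(fusion_net_spec(share_weights = TRUE), "separate_branches")
  expect_error(build_network(fusion_net_spec(), input_size = c(50L, 50L)),
               "divisible by 32")
})

test_that("separate texture branches and shared weights build and run", {
  for (share in c(FALSE, TRUE)) {
    spec <- fusion_net_spec(texture_mode = "separate_branches",
                            share_weights = share, width_multiplier = 1 / 16)
    net <- build_network(spec, input_size = c(32L, 32L), seed = 31L)
    fw <- texfuse:::forward_sample(net$params, spec,
                                   matrix(runif(32 * 32), 32, 32),
                                   array(runif(32 * 32 * 2), c(32, 32, 2)))
    expect_length(fw$logits, 2L)
  }
})
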