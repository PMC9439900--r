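# Forward/backward pass and optimization for the fusion network.
#
# Activations are (H, W, C) arrays; convolutions run through the compiled
# im2col kernels. Backpropagation is written out explicitly per layer and is
# checked against finite differences in the test suite.

relu <- function(a) {
  a[a < 0] <- 0
  a
}

as_cube <- function(m) {
  if (is.matrix(m)) array(m, dim = c(dim(m), 1L)) else m
}

stage_forward <- function(stage, x) {
  cache <- vector("list", length(stage))
  for (i in seq_along(stage)) {
    act <- relu(conv_fwd(x, stage[[i]]$w, stage[[i]]$b, 3L))
    cache[[i]] <- list(x = x, act = act)
    x <- act
  }
  list(out = x, cache = cache)
}

stage_backward <- function(stage, cache, dout) {
  grads <- vector("list", length(stage))
  for (i in rev(seq_along(stage))) {
    d <- dout * (cache[[i]]$act > 0)
    r <- conv_bwd(cache[[i]]$x, stage[[i]]$w, d, 3L)
    grads[[i]] <- list(w = r$dw, b = as.numeric(r$db))
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

# Per-channel fusion kernels applied to an already-summed tensor s.
fuse_forward <- function(s, K) {
  C <- dim(s)[3]
  if (ncol(K) == 1L) {
    return(s * rep(K[, 1L], each = dim(s)[1] * dim(s)[2]))
  }
  ks <- as.integer(sqrt(ncol(K)))
  out <- array(0, dim = dim(s))
  for (c_ in seq_len(C)) {
    sc <- array(s[, , c_], dim = c(dim(s)[1:2], 1L))
    out[, , c_] <- conv_fwd(sc, matrix(K[c_, ], 1L), 0, ks)[, , 1L]
  }
  out
}

fuse_backward <- function(s, K, dz) {
  C <- dim(s)[3]
  dK <- matrix(0, nrow(K), ncol(K))
  if (ncol(K) == 1L) {
    hw <- dim(s)[1] * dim(s)[2]
    ds <- dz * rep(K[, 1L], each = hw)
    for (c_ in seq_len(C)) dK[c_, 1L] <- sum(dz[, , c_] * s[, , c_])
    return(list(ds = ds, dK = dK))
  }
  ks <- as.integer(sqrt(ncol(K)))
  ds <- array(0, dim = dim(s))
  for (c_ in seq_len(C)) {
    sc <- array(s[, , c_], dim = c(dim(s)[1:2], 1L))
    dzc <- array(dz[, , c_], dim = c(dim(s)[1:2], 1L))
    r <- conv_bwd(sc, matrix(K[c_, ], 1L), dzc, ks)
    ds[, , c_] <- r$dx[, , 1L]
    dK[c_, ] <- as.numeric(r$dw)
  }
  list(ds = ds, dK = dK)
}

texture_branch_params <- function(params, spec, fb) {
  if (spec$texture_mode == "stacked") {
    list(params$texture[[1L]])
  } else if (spec$share_weights) {
    lapply(seq_len(spec$n_texture_channels), function(i) params$backbone[seq_len(fb)])
  } else {
    params$texture
  }
}

# Texture branch: stages 1..fb with pools between stages but none after the
# last (fusion is pre-pool). Returns per-branch caches for backprop.
texture_forward <- function(params, spec, tex, fb) {
  branches <- texture_branch_params(params, spec, fb)
  inputs <- if (spec$texture_mode == "stacked") {
    list(tex)
  } else {
    lapply(seq_len(dim(tex)[3]), function(c_) array(tex[, , c_], dim = c(dim(tex)[1:2], 1L)))
  }
  out <- NULL
  caches <- vector("list", length(branches))
  for (bi in seq_along(branches)) {
    t_ <- inputs[[bi]]
    scache <- vector("list", fb)
    pcache <- vector("list", fb)
    for (b in seq_len(fb)) {
      sf <- stage_forward(branches[[bi]][[b]], t_)
      scache[[b]] <- sf$cache
      t_ <- sf$out
      if (b < fb) {
        mp <- maxpool_fwd(t_)
        pcache[[b]] <- list(idx = mp$idx, h = dim(t_)[1], w = dim(t_)[2])
        t_ <- mp$y
      }
    }
    caches[[bi]] <- list(stages = scache, pools = pcache)
    out <- if (is.null(out)) t_ else out + t_
  }
  list(out = out, caches = caches)
}

texture_backward <- function(params, spec, fb, caches, dout) {
  branches <- texture_branch_params(params, spec, fb)
  branch_grads <- vector("list", length(branches))
  for (bi in seq_along(branches)) {
    d <- dout
    g <- vector("list", fb)
    for (b in rev(seq_len(fb))) {
      if (b < fb) {
        pc <- caches[[bi]]$pools[[b]]
        d <- maxpool_bwd(pc$idx, d, pc$h, pc$w)
      }
      sb <- stage_backward(branches[[bi]][[b]], caches[[bi]]$stages[[b]], d)
      g[[b]] <- sb$grads
      d <- sb$dx
    }
    branch_grads[[bi]] <- g
  }
  branch_grads
}

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (runif(n) >= rate) / (1 - rate)
}

forward_sample <- function(params, spec, depth, tex, training = FALSE) {
  fb <- fusion_block_index(spec$fusion_position)
  use_tex <- spec$texture_mode != "none"
  cache <- list()
  if (use_tex && fb == 0L) {
    tex <- as_cube(tex)
    s <- tex + as.numeric(depth)  # broadcast the depth channel
    cache$fuse_s <- s
    x <- fuse_forward(s, params$fuse)
  } else {
    x <- as_cube(depth)
  }
  cache$stages <- vector("list", 5L)
  cache$pools <- vector("list", 5L)
  for (b in 1:5) {
    sf <- stage_forward(params$backbone[[b]], x)
    cache$stages[[b]] <- sf$cache
    x <- sf$out
    if (use_tex && b == fb) {
      tf <- texture_forward(params, spec, as_cube(tex), fb)
      cache$texture <- tf$caches
      s <- x + tf$out
      cache$fuse_s <- s
      x <- fuse_forward(s, params$fuse)
    }
    mp <- maxpool_fwd(x)
    cache$pools[[b]] <- list(idx = mp$idx, h = dim(x)[1], w = dim(x)[2])
    x <- mp$y
  }
  cache$flat_dim <- dim(x)
  v <- as.numeric(x)
  m1 <- if (training) dropout_mask(length(v), spec$dropout_rate) else rep(1, length(v))
  v1 <- v * m1
  h_pre <- drop(crossprod(params$head$W1, v1)) + params$head$b1
  hr <- pmax(h_pre, 0)
  m2 <- if (training) dropout_mask(length(hr), spec$dropout_rate) else rep(1, length(hr))
  h2 <- hr * m2
  logits <- drop(crossprod(params$head$W2, h2)) + params$head$b2
  cache$head <- list(v = v, m1 = m1, v1 = v1, h_pre = h_pre, m2 = m2, h2 = h2)
  list(logits = logits, cache = cache)
}

backward_sample <- function(params, spec, cache, dlogits) {
  fb <- fusion_block_index(spec$fusion_position)
  use_tex <- spec$texture_mode != "none"
  hd <- cache$head
  grads <- list()
  dh2 <- drop(params$head$W2 %*% dlogits)
  dh <- dh2 * hd$m2 * (hd$h_pre > 0)
  # order must mirror params$head exactly (the optimizer pairs by position)
  grads$head <- list(
    W1 = hd$v1 %o% dh,
    b1 = dh,
    W2 = hd$h2 %o% dlogits,
    b2 = dlogits
  )
  dv <- drop(params$head$W1 %*% dh) * hd$m1
  d <- array(dv, dim = cache$flat_dim)
  for (b in 5:1) {
    pc <- cache$pools[[b]]
    d <- maxpool_bwd(pc$idx, d, pc$h, pc$w)
    if (use_tex && b == fb) {
      fbk <- fuse_backward(cache$fuse_s, params$fuse, d)
      grads$fuse <- fbk$dK
      d <- fbk$ds
      tex_grads <- texture_backward(params, spec, fb, cache$texture, d)
      if (spec$texture_mode == "stacked") {
        grads$texture <- tex_grads
      } else if (spec$share_weights) {
        grads$shared_texture <- tex_grads  # folded into backbone below
      } else {
        grads$texture <- tex_grads
      }
    }
    sb <- stage_backward(params$backbone[[b]], cache$stages[[b]], d)
    grads$backbone[[b]] <- sb$grads
    d <- sb$dx
  }
  grads$backbone <- grads$backbone[1:5]
  if (use_tex && fb == 0L) {
    fbk <- fuse_backward(cache$fuse_s, params$fuse, d)
    grads$fuse <- fbk$dK
  }
  if (!is.null(grads$shared_texture)) {
    for (g in grads$shared_texture) {
      for (b in seq_along(g)) {
        for (i in seq_along(g[[b]])) {
          grads$backbone[[b]][[i]]$w <- grads$backbone[[b]][[i]]$w + g[[b]][[i]]$w
          grads$backbone[[b]][[i]]$b <- grads$backbone[[b]][[i]]$b + g[[b]][[i]]$b
        }
      }
    }
    grads$shared_texture <- NULL
  }
  grads[names(params)]
}

softmax <- function(l) {
  e <- exp(l - max(l))
  e / sum(e)
}

# Mean cross-entropy loss and per-sample logit gradients for a batch.
loss_and_grads <- function(params, spec, depth_list, tex_list, y, training = TRUE) {
  n <- length(depth_list)
  total <- NULL
  loss <- 0
  correct <- 0L
  for (i in seq_len(n)) {
    fw <- forward_sample(params, spec, depth_list[[i]],
                         if (is.null(tex_list)) NULL else tex_list[[i]], training)
    p <- softmax(fw$logits)
    loss <- loss - log(max(p[y[i]], 1e-12))
    correct <- correct + as.integer(which.max(fw$logits) == y[i])
    dl <- p
    dl[y[i]] <- dl[y[i]] - 1
    g <- backward_sample(params, spec, fw$cache, dl)
    total <- if (is.null(total)) g else tree_add(total, g)
  }
  list(grads = tree_scale(total, 1 / n), loss = loss / n, acc = correct / n)
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else {
    a + b
  }
}

tree_scale <- function(a, s) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_scale(a[[i]], s)
    a
  } else {
    a * s
  }
}

tree_zero <- function(a) tree_scale(a, 0)

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

#' Training configuration
#'
#' Defaults are the full-scale training regime: Adam at learning rate 1e-4,
#' 50 epochs, batch size 64. Desk-scale experiments override these (see
#' [run_experiment()] and the methods vignette).
#'
#' @param learning_rate Positive learning rate.
#' @param epochs Positive integer number of epochs (no early stopping).
#' @param batch_size Positive integer batch size.
#' @param seed Integer seed controlling shuffling, dropout and (through
#'   [build_network()]) initialization.
#' @param optimizer_name `"adam"` or `"sgd"`.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 50L, batch_size = 64L,
                         seed = 1L, optimizer_name = c("adam", "sgd")) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  epochs <- as.integer(epochs)
  stopifnot_scalar_number(epochs, "epochs", positive = TRUE)
  batch_size <- as.integer(batch_size)
  stopifnot_scalar_number(batch_size, "batch_size", positive = TRUE)
  structure(
    list(learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, seed = as.integer(seed),
         optimizer_name = match.arg(optimizer_name)),
    class = "train_config"
  )
}

#' Fit a fusion network
#'
#' Plain minibatch training with cross-entropy loss. Deterministic for a
#' fixed seed on a single thread.
#'
#' @param net A `fusion_net` from [build_network()].
#' @param data A list with `depth` (list of H x W matrices), `texture` (list
#'   of H x W x C arrays, or `NULL` for the depth-only model) and `y`
#'   (integer class labels, 1 or 2).
#' @param cfg A [train_config()].
#' @return The fitted `fusion_net`, with a `history` tibble (epoch, mean
#'   loss, training accuracy) attached.
#' @export
fit_network <- function(net, data, cfg = train_config()) {
  spec <- net$spec
  params <- net$params
  n <- length(data$depth)
  state <- list(m = tree_zero(params), v = tree_zero(params))
  t_ <- 0L
  history <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_acc <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        lg <- loss_and_grads(params, spec,
                             data$depth[idx],
                             if (is.null(data$texture)) NULL else data$texture[idx],
                             data$y[idx], training = TRUE)
        t_ <- t_ + 1L
        if (cfg$optimizer_name == "adam") {
          au <- adam_update(params, lg$grads, state, cfg$learning_rate, t_)
          params <- au$params
          state <- au$state
        } else {
          params <- tree_add(params, tree_scale(lg$grads, -cfg$learning_rate))
        }
        ep_loss <- ep_loss + lg$loss; ep_acc <- ep_acc + lg$acc; nb <- nb + 1L
      }
      history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / nb,
                                      train_accuracy = ep_acc / nb)
    }
  })
  net$params <- params
  net$history <- dplyr::bind_rows(history)
  net
}

#' Predict with a fusion network
#'
#' @param net A (fitted) `fusion_net`.
#' @param data A list with `depth` and `texture` as in [fit_network()].
#' @return A tibble with columns `.pred_class` (integer 1/2), `score_1`,
#'   `score_2` (softmax probabilities).
#' @export
predict_network <- function(net, data) {
  n <- length(data$depth)
  out <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    fw <- forward_sample(net$params, net$spec, data$depth[[i]],
                         if (is.null(data$texture)) NULL else data$texture[[i]],
                         training = FALSE)
    out[i, ] <- softmax(fw$logits)
  }
  tibble::tibble(
    .pred_class = as.integer(apply(out, 1L, which.max)),
    score_1 = out[, 1L],
    score_2 = out[, 2L]
  )
}
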