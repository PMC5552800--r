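## The fully convolutional segmentation network.
##
## Encoder of Conv-Pool stages (feature maps double at every down-sampling,
## starting from `base_features`), a bottleneck of residual blocks
## (1x1 -> 3x3 -> 1x1 convolutions with an element-wise input sum followed by
## batch normalization), and a decoder of DeConv stages whose inputs receive
## the long skip connections from the encoder, element-wise summed and batch
## normalized. A final 1x1 convolution produces 2-class scores at the input
## resolution. Trained with a weighted softmax (cross-entropy) loss and
## RMSProp under a stepped learning-rate schedule.

#' Network architecture specification
#'
#' @param n_levels number of 2x down-samplings (and matching up-samplings).
#' @param base_features feature maps of the first stage; doubled at every
#'   down-sampling.
#' @param n_residual_blocks residual blocks at the bottleneck.
#' @param residual_features feature counts of the three convolutions inside
#'   a residual block.
#' @param residual_kernels kernel sizes of those convolutions.
#' @param input_size nominal square input size; must be divisible by
#'   `2^n_levels` (any such size is accepted at forward time).
#' @param in_channels data channels (3 for bright-field z-stacks, 4 for the
#'   non-nuclear channels of five-channel data).
#' @param n_classes output classes (2: background, cell).
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(n_levels = 3, base_features = 8,
                              n_residual_blocks = 2,
                              residual_features = c(16, 16, 64),
                              residual_kernels = c(1, 3, 1),
                              input_size = 480, in_channels = 3,
                              n_classes = 2) {
  if (base_features < 1) stopf("base_features must be >= 1")
  if (n_levels < 1) stopf("n_levels must be >= 1")
  if (input_size %% 2^n_levels != 0)
    stopf("input_size %d is not divisible by 2^%d", input_size, n_levels)
  structure(list(n_levels = as.integer(n_levels),
                 base_features = as.integer(base_features),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 residual_features = as.integer(residual_features),
                 residual_kernels = as.integer(residual_kernels),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes)),
            class = "architecture_spec")
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: initial learning rate 0.001,
#' 60000 iterations, rate divided by 10 every 5000 iterations, RMSProp.
#'
#' @param initial_lr initial learning rate.
#' @param total_iterations training iterations.
#' @param lr_drop_every iterations between learning-rate drops.
#' @param lr_drop_factor multiplicative drop (in `(0, 1)`).
#' @param batch_size samples per iteration (gradients averaged).
#' @param rng_seed seed for sample draws.
#' @param rmsprop_decay,rmsprop_eps RMSProp accumulator decay and epsilon.
#' @param checkpoint_every iterations between checkpoints (`Inf` disables).
#' @param checkpoint_dir directory for checkpoints and the loss trace.
#' @return a `training_config` list.
#' @export
training_config <- function(initial_lr = 0.001, total_iterations = 60000,
                            lr_drop_every = 5000, lr_drop_factor = 0.1,
                            batch_size = 1, rng_seed = 1L,
                            rmsprop_decay = 0.9, rmsprop_eps = 1e-8,
                            checkpoint_every = Inf, checkpoint_dir = NULL) {
  if (initial_lr <= 0 || total_iterations <= 0 || lr_drop_every <= 0 ||
      batch_size <= 0)
    stopf("learning rate, iteration counts and batch size must be positive")
  if (lr_drop_factor <= 0 || lr_drop_factor >= 1)
    stopf("lr_drop_factor must be in (0, 1)")
  structure(list(initial_lr = initial_lr,
                 total_iterations = as.integer(total_iterations),
                 lr_drop_every = as.integer(lr_drop_every),
                 lr_drop_factor = lr_drop_factor,
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed),
                 rmsprop_decay = rmsprop_decay, rmsprop_eps = rmsprop_eps,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "training_config")
}

#' Stepped learning-rate schedule
#'
#' `lr = initial_lr * lr_drop_factor^floor(iteration / lr_drop_every)` for a
#' 0-based iteration counter.
#'
#' @param iteration 0-based iteration index.
#' @param cfg a [training_config()].
#' @return learning rate at that iteration.
#' @export
lr_at <- function(iteration, cfg = training_config()) {
  if (any(iteration < 0)) stopf("iteration must be >= 0")
  cfg$initial_lr * cfg$lr_drop_factor^(iteration %/% cfg$lr_drop_every)
}

msra_weights <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

new_conv <- function(kh, cin, cout) {
  list(W = msra_weights(kh, kh, cin, cout), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

new_bn_state <- function(cout) list(mean = numeric(cout), var = rep(1, cout))

level_features <- function(arch) arch$base_features * 2^(seq_len(arch$n_levels) - 1L)

#' Build and initialize the network
#'
#' Weights use MSRA initialization (zero-mean Gaussian with variance
#' `2 / fan_in`), batch-norm scales start at 1 and shifts at 0, all drawn
#' deterministically from `init_seed`.
#'
#' @param arch an [architecture_spec()].
#' @param init_seed integer seed for the weight draws.
#' @return an object of class `brightseg_model`.
#' @export
build_network <- function(arch = architecture_spec(), init_seed = 1L) {
  rf <- arch$residual_features
  rk <- arch$residual_kernels
  feats <- level_features(arch)
  with_seed(init_seed, {
    params <- list()
    state <- list()
    cin <- arch$in_channels
    params$down <- list(); state$down <- list()
    for (i in seq_len(arch$n_levels)) {
      params$down[[i]] <- new_conv(3L, cin, feats[i])
      state$down[[i]] <- new_bn_state(feats[i])
      cin <- feats[i]
    }
    params$adapter <- new_conv(1L, cin, rf[3])
    state$adapter <- new_bn_state(rf[3])
    params$res <- list(); state$res <- list()
    for (j in seq_len(arch$n_residual_blocks)) {
      params$res[[j]] <- list(c1 = new_conv(rk[1], rf[3], rf[1]),
                              c2 = new_conv(rk[2], rf[1], rf[2]),
                              c3 = new_conv(rk[3], rf[2], rf[3]),
                              bn_out = list(gamma = rep(1, rf[3]),
                                            beta = numeric(rf[3])))
      state$res[[j]] <- list(c1 = new_bn_state(rf[1]),
                             c2 = new_bn_state(rf[2]),
                             c3 = new_bn_state(rf[3]),
                             bn_out = new_bn_state(rf[3]))
    }
    params$up <- list(); state$up <- list()
    cin <- rf[3]
    for (i in rev(seq_len(arch$n_levels))) {
      f <- feats[i]
      params$up[[i]] <- list(
        deconv = list(W = msra_weights(2L, 2L, cin, f), b = numeric(f)),
        skip_bn = list(gamma = rep(1, f), beta = numeric(f)),
        conv1 = new_conv(3L, f, f),
        conv2 = new_conv(3L, f, f))
      state$up[[i]] <- list(skip_bn = new_bn_state(f),
                            conv1 = new_bn_state(f),
                            conv2 = new_bn_state(f))
      cin <- f
    }
    params$final <- list(W = msra_weights(1L, 1L, feats[1], arch$n_classes),
                         b = numeric(arch$n_classes))
    structure(list(arch = arch, params = params, state = state,
                   init_seed = as.integer(init_seed)),
              class = "brightseg_model")
  })
}

#' @export
print.brightseg_model <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "list")))
  cat(sprintf(
    "brightseg_model: %d levels, base %d, %d residual blocks, %d -> %d channels, %d parameters\n",
    x$arch$n_levels, x$arch$base_features, x$arch$n_residual_blocks,
    x$arch$in_channels, x$arch$n_classes, np))
  invisible(x)
}

## Full forward pass. Returns scores plus (in training mode) the caches the
## backward pass needs and the updated batch-norm running state.
nn_forward_full <- function(model, x, training = FALSE) {
  arch <- model$arch
  p <- model$params; st <- model$state
  x <- as_channels(x)
  d <- dim(x)
  if (d[3] != arch$in_channels)
    stopf("expected %d data channels, got %d", arch$in_channels, d[3])
  if (d[1] %% 2^arch$n_levels != 0 || d[2] %% 2^arch$n_levels != 0)
    stopf("spatial size %dx%d not divisible by 2^%d", d[1], d[2],
          arch$n_levels)
  cache <- list(down = list(), res = list(), up = list())
  skips <- list()
  h <- x
  for (i in seq_len(arch$n_levels)) {
    cb <- convblock_forward(h, p$down[[i]], st$down[[i]], training)
    st$down[[i]] <- cb$rstate
    skips[[i]] <- cb$out
    pl <- pool_forward(cb$out)
    h <- pl$out
    cache$down[[i]] <- list(block = cb$cache, pool = pl)
  }
  ad <- convblock_forward(h, p$adapter, st$adapter, training)
  st$adapter <- ad$rstate
  h <- ad$out
  cache$adapter <- ad$cache
  for (j in seq_len(arch$n_residual_blocks)) {
    inp <- h
    c1 <- convblock_forward(inp, p$res[[j]]$c1, st$res[[j]]$c1, training)
    c2 <- convblock_forward(c1$out, p$res[[j]]$c2, st$res[[j]]$c2, training)
    c3 <- convblock_forward(c2$out, p$res[[j]]$c3, st$res[[j]]$c3, training)
    bo <- bn_forward(inp + c3$out, p$res[[j]]$bn_out$gamma,
                     p$res[[j]]$bn_out$beta, st$res[[j]]$bn_out, training)
    st$res[[j]] <- list(c1 = c1$rstate, c2 = c2$rstate, c3 = c3$rstate,
                        bn_out = bo$rstate)
    h <- bo$out
    cache$res[[j]] <- list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                           bn_out = bo)
  }
  for (i in rev(seq_len(arch$n_levels))) {
    dc <- deconv_forward(h, p$up[[i]]$deconv$W, p$up[[i]]$deconv$b)
    sb <- bn_forward(dc$out + skips[[i]], p$up[[i]]$skip_bn$gamma,
                     p$up[[i]]$skip_bn$beta, st$up[[i]]$skip_bn, training)
    c1 <- convblock_forward(sb$out, p$up[[i]]$conv1, st$up[[i]]$conv1, training)
    c2 <- convblock_forward(c1$out, p$up[[i]]$conv2, st$up[[i]]$conv2, training)
    st$up[[i]] <- list(skip_bn = sb$rstate, conv1 = c1$rstate,
                       conv2 = c2$rstate)
    h <- c2$out
    cache$up[[i]] <- list(deconv = dc, skip_bn = sb, conv1 = c1$cache,
                          conv2 = c2$cache)
  }
  fin <- conv_forward(h, p$final$W, p$final$b)
  cache$final <- fin
  list(scores = fin$out, cache = if (training) cache else NULL, state = st)
}

## Backward pass; dscores has the shape of the scores. Returns a gradient
## tree parallel to model$params.
nn_backward <- function(model, cache, dscores) {
  arch <- model$arch
  p <- model$params
  g <- list(down = vector("list", arch$n_levels),
            res = vector("list", arch$n_residual_blocks),
            up = vector("list", arch$n_levels))
  fin <- conv_backward(dscores, cache$final, p$final$W)
  g$final <- list(W = fin$dW, b = fin$db)
  dh <- fin$dx
  dskips <- vector("list", arch$n_levels)
  for (i in seq_len(arch$n_levels)) {
    cu <- cache$up[[i]]
    b2 <- convblock_backward(dh, cu$conv2, p$up[[i]]$conv2)
    b1 <- convblock_backward(b2$dx, cu$conv1, p$up[[i]]$conv1)
    sb <- bn_backward(b1$dx, cu$skip_bn, p$up[[i]]$skip_bn$gamma)
    dskips[[i]] <- sb$dx
    dcv <- deconv_backward(sb$dx, cu$deconv, p$up[[i]]$deconv$W)
    g$up[[i]] <- list(deconv = list(W = dcv$dW, b = dcv$db),
                      skip_bn = list(gamma = sb$dgamma, beta = sb$dbeta),
                      conv1 = b1$grads, conv2 = b2$grads)
    dh <- dcv$dx
  }
  for (j in rev(seq_len(arch$n_residual_blocks))) {
    cr <- cache$res[[j]]
    bo <- bn_backward(dh, cr$bn_out, p$res[[j]]$bn_out$gamma)
    b3 <- convblock_backward(bo$dx, cr$c3, p$res[[j]]$c3)
    b2 <- convblock_backward(b3$dx, cr$c2, p$res[[j]]$c2)
    b1 <- convblock_backward(b2$dx, cr$c1, p$res[[j]]$c1)
    g$res[[j]] <- list(c1 = b1$grads, c2 = b2$grads, c3 = b3$grads,
                       bn_out = list(gamma = bo$dgamma, beta = bo$dbeta))
    dh <- bo$dx + b1$dx   # residual: gradient flows through both paths
  }
  ad <- convblock_backward(dh, cache$adapter, p$adapter)
  g$adapter <- ad$grads
  dh <- ad$dx
  for (i in rev(seq_len(arch$n_levels))) {
    cd <- cache$down[[i]]
    dpool <- pool_backward(dh, cd$pool)
    dblock_out <- dpool + dskips[[i]]   # long skip into the decoder
    bb <- convblock_backward(dblock_out, cd$block, p$down[[i]])
    g$down[[i]] <- bb$grads
    dh <- bb$dx
  }
  g
}

## Stable per-pixel 2-class softmax from a scores array.
softmax2 <- function(scores) {
  s1 <- scores[, , 1]; s2 <- scores[, , 2]
  m <- pmax(s1, s2)
  e1 <- exp(s1 - m); e2 <- exp(s2 - m)
  z <- e1 + e2
  list(p1 = e1 / z, p2 = e2 / z, logz = m + log(z))
}

#' Forward pass: per-pixel class probabilities
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' returns the cell-class probability map.
#'
#' @param model a `brightseg_model`.
#' @param data H x W x C data array (C matching the architecture; H, W
#'   divisible by `2^n_levels`).
#' @return matrix of cell probabilities in `[0, 1]`, same spatial size.
#' @export
nn_predict <- function(model, data) {
  out <- nn_forward_full(model, data, training = FALSE)
  softmax2(out$scores)$p2
}

#' Weighted softmax (cross-entropy) loss
#'
#' `L = sum_p w_p * (-log softmax(scores_p)[label_p]) / sum_p w_p`. The
#' normalization by the total weight makes the loss invariant to a common
#' rescaling of the weights.
#'
#' @param scores H x W x 2 score array (channel 1 background, channel 2
#'   cell).
#' @param label H x W matrix of class indices in `{0, 1}`.
#' @param weight H x W matrix of positive per-pixel weights.
#' @param with_grad also return the gradient w.r.t. the scores.
#' @return scalar loss, or (with `with_grad`) a list `loss`, `grad`.
#' @export
weighted_softmax_loss <- function(scores, label, weight,
                                  with_grad = FALSE) {
  if (any(!is.finite(scores))) stopf("non-finite network scores")
  if (any(weight <= 0)) stopf("weights must be positive")
  assert_same_dim(scores, label, "scores and label")
  sm <- softmax2(scores)
  s_true <- scores[, , 1]
  is_fg <- label == 1
  s_true[is_fg] <- scores[, , 2][is_fg]
  sw <- sum(weight)
  loss <- sum(weight * (sm$logz - s_true)) / sw
  if (!with_grad) return(loss)
  wn <- weight / sw
  g1 <- wn * (sm$p1 - !is_fg)
  g2 <- wn * (sm$p2 - is_fg)
  grad <- array(0, dim(scores))
  grad[, , 1] <- g1; grad[, , 2] <- g2
  list(loss = loss, grad = grad)
}

## elementwise tree arithmetic over parameter/gradient structures
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    keys <- if (!is.null(names(a))) names(a) else seq_along(a)
    out <- a
    for (k in keys) out[[k]] <- tree_map2(f, a[[k]], b[[k]])
    out
  } else f(a, b)
}

tree_map1 <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- tree_map1(f, a[[k]])
    out
  } else f(a)
}

#' Train the network with RMSProp
#'
#' Iterates single (or small-batch) gradient steps on samples drawn
#' uniformly from the dataset, with the stepped learning-rate schedule of
#' [lr_at()]. Fully deterministic given `cfg$rng_seed`. Aborts with a
#' diagnostic checkpoint if the loss becomes non-finite.
#'
#' @param model a `brightseg_model` from [build_network()].
#' @param dataset a `training_set` (list of samples with `data`, `label`,
#'   `weight`).
#' @param cfg a [training_config()].
#' @param resume_from optional checkpoint file written by a previous run;
#'   training continues from its iteration counter.
#' @param verbose print the running loss every 100 iterations.
#' @return list with the trained `model` and the per-iteration `loss_trace`.
#' @export
train_network <- function(model, dataset, cfg = training_config(),
                          resume_from = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stopf("dataset is empty")
  msq <- tree_map1(function(x) x * 0, model$params)
  trace <- numeric(cfg$total_iterations)
  start_iter <- 0L
  if (!is.null(resume_from)) {
    ck <- readRDS(resume_from)
    model <- ck$model; msq <- ck$msq; start_iter <- ck$iteration
    trace[seq_len(start_iter)] <- ck$loss_trace
  }
  ckdir <- cfg$checkpoint_dir
  if (!is.null(ckdir)) dir.create(ckdir, recursive = TRUE, showWarnings = FALSE)
  with_seed(derive_seed(cfg$rng_seed, start_iter), {
    it <- start_iter
    while (it < cfg$total_iterations) {
      lr <- lr_at(it, cfg)
      idx <- sample.int(length(dataset), cfg$batch_size, replace = TRUE)
      grads <- NULL
      loss_acc <- 0
      for (s in idx) {
        smp <- dataset[[s]]
        fw <- nn_forward_full(model, smp$data, training = TRUE)
        model$state <- fw$state
        ls <- weighted_softmax_loss(fw$scores, smp$label, smp$weight,
                                    with_grad = TRUE)
        loss_acc <- loss_acc + ls$loss
        g <- nn_backward(model, fw$cache, ls$grad)
        grads <- if (is.null(grads)) g else tree_map2(`+`, grads, g)
      }
      loss <- loss_acc / length(idx)
      if (!is.finite(loss)) {
        if (!is.null(ckdir)) {
          saveRDS(list(model = model, msq = msq, iteration = it,
                       loss_trace = trace[seq_len(it)]),
                  file.path(ckdir, "checkpoint_diverged.rds"))
        }
        stopf("loss became non-finite at iteration %d", it)
      }
      if (length(idx) > 1)
        grads <- tree_map1(function(x) x / length(idx), grads)
      msq <- tree_map2(function(m, g)
        cfg$rmsprop_decay * m + (1 - cfg$rmsprop_decay) * g^2, msq, grads)
      step <- tree_map2(function(g, m) lr * g / (sqrt(m) + cfg$rmsprop_eps),
                        grads, msq)
      model$params <- tree_map2(`-`, model$params, step)
      it <- it + 1L
      trace[it] <- loss
      if (verbose && it %% 100L == 0L)
        message(sprintf("iter %d  lr %.2e  loss %.4f", it, lr, loss))
      if (!is.null(ckdir) && is.finite(cfg$checkpoint_every) &&
          it %% cfg$checkpoint_every == 0L) {
        saveRDS(list(model = model, msq = msq, iteration = it,
                     loss_trace = trace[seq_len(it)]),
                file.path(ckdir, "checkpoint_latest.rds"))
      }
    }
  })
  if (!is.null(ckdir)) {
    utils::write.csv(data.frame(iteration = seq_len(cfg$total_iterations),
                                loss = trace),
                     file.path(ckdir, "loss_trace.csv"), row.names = FALSE)
  }
  list(model = model, loss_trace = trace)
}

#' Save / load a model
#'
#' Checkpoints use R's native serialization; an accompanying plain-text
#' architecture description is written alongside.
#'
#' @param model a `brightseg_model`.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  arch <- model$arch; class(arch) <- NULL
  yaml::write_yaml(arch, paste0(path, ".arch.yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
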