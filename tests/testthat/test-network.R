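test_that("the learning-rate schedule steps by the drop factor", {
  cfg <- training_config()
  expect_identical(lr_at(0, cfg), 0.001)
  expect_identical(lr_at(4999, cfg), 0.001)
  expect_identical(lr_at(5000, cfg), 0.001 * 0.1)
  expect_identical(lr_at(59999, cfg), 0.001 * 0.1^11)
  cfg2 <- training_config(initial_lr = 0.5, lr_drop_every = 10,
                          lr_drop_factor = 0.5, total_iterations = 100)
  expect_identical(lr_at(c(0, 9, 10, 25), cfg2), 0.5 * 0.5^c(0, 0, 1, 2))
  expect_error(lr_at(-1, cfg), ">= 0")
})

test_that("network builds are deterministic in the init seed", {
  arch <- tiny_arch()
  m1 <- build_network(arch, init_seed = 3)
  m2 <- build_network(arch, init_seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(arch, init_seed = 4)
  expect_false(identical(m1$params, m3$params))
  ## feature plan doubles per level
  expect_identical(dim(m1$params$down[[1]]$W)[4], 4L)
  expect_identical(dim(m1$params$down[[2]]$W)[4], 8L)
})

test_that("forward pass preserves spatial size and normalizes probabilities", {
  m <- build_network(tiny_arch(), init_seed = 1)
  set.seed(2)
  x <- array(rnorm(64 * 96 * 3), c(64, 96, 3))   # any size divisible by 4
  fw <- brightseg:::nn_forward_full(m, x)
  expect_identical(dim(fw$scores), c(64L, 96L, 2L))
  sm <- brightseg:::softmax2(fw$scores)
  expect_lt(max(abs(sm$p1 + sm$p2 - 1)), 1e-6)
  p <- nn_predict(m, x)
  expect_identical(dim(p), c(64L, 96L))
  expect_true(all(p >= 0 & p <= 1))
  ## repeated evaluation-mode passes are identical
  expect_identical(nn_predict(m, x), p)
  ## a freshly initialized model is near-uninformative on average
  expect_lt(mean(abs(p - 0.5)), 0.25)
  expect_error(nn_predict(m, array(0, c(64, 96, 2))), "channels")
  expect_error(nn_predict(m, array(0, c(63, 96, 3))), "divisible")
})

test_that("the weighted softmax loss matches hand-computed cases", {
  ## 2 pixels, zero scores: -log(1/2) regardless of labels and weights
  scores <- array(0, c(1, 2, 2))
  label <- matrix(c(0L, 1L), 1, 2)
  weight <- matrix(c(1, 3), 1, 2)
  expect_equal(weighted_softmax_loss(scores, label, weight), log(2))
  ## uniform weights reduce to the mean cross-entropy
  set.seed(3)
  s <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  lab <- matrix(rbinom(64, 1, 0.5), 8, 8)
  w1 <- matrix(1, 8, 8)
  p <- brightseg:::softmax2(s)
  ptrue <- ifelse(lab == 1, p$p2, p$p1)
  expect_equal(weighted_softmax_loss(s, lab, w1), mean(-log(ptrue)))
  ## invariant to a common weight rescaling
  expect_equal(weighted_softmax_loss(s, lab, w1 * 7),
               weighted_softmax_loss(s, lab, w1))
  ## scores dominated by the true class drive the loss to zero
  s_good <- array(0, c(8, 8, 2))
  s_good[, , 1] <- ifelse(lab == 0, 50, -50)
  s_good[, , 2] <- -s_good[, , 1]
  expect_lt(weighted_softmax_loss(s_good, lab, w1), 1e-10)
  expect_error(weighted_softmax_loss(s * NA, lab, w1), "non-finite")
})

test_that("the loss gradient matches finite differences on a 2x2 toy", {
  set.seed(4)
  s <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  lab <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  w <- matrix(c(1, 3, 2, 0.5), 2, 2)
  g <- weighted_softmax_loss(s, lab, w, with_grad = TRUE)$grad
  eps <- 1e-6
  for (i in seq_len(8)) {
    sp <- s; sp[i] <- sp[i] + eps
    sm <- s; sm[i] <- sm[i] - eps
    num <- (weighted_softmax_loss(sp, lab, w) -
              weighted_softmax_loss(sm, lab, w)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("backpropagation matches finite differences through every block", {
  arch <- architecture_spec(n_levels = 1, base_features = 2,
                            n_residual_blocks = 1, input_size = 8,
                            in_channels = 2)
  m <- build_network(arch, init_seed = 3)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  lab <- matrix(rbinom(64, 1, 0.4), 8, 8)
  wt <- matrix(runif(64, 0.5, 2), 8, 8)
  fw <- brightseg:::nn_forward_full(m, x, training = TRUE)
  ls <- weighted_softmax_loss(fw$scores, lab, wt, with_grad = TRUE)
  g <- brightseg:::nn_backward(m, fw$cache, ls$grad)
  lossfn <- function(model) {
    f <- brightseg:::nn_forward_full(model, x, training = TRUE)
    weighted_softmax_loss(f$scores, lab, wt)
  }
  probes <- list(
    list(g = g$down[[1]]$W,          get = function(p) p$down[[1]]$W,
         set = function(p, v) { p$down[[1]]$W <- v; p }),
    list(g = g$down[[1]]$gamma,      get = function(p) p$down[[1]]$gamma,
         set = function(p, v) { p$down[[1]]$gamma <- v; p }),
    list(g = g$res[[1]]$c2$W,        get = function(p) p$res[[1]]$c2$W,
         set = function(p, v) { p$res[[1]]$c2$W <- v; p }),
    list(g = g$res[[1]]$bn_out$beta, get = function(p) p$res[[1]]$bn_out$beta,
         set = function(p, v) { p$res[[1]]$bn_out$beta <- v; p }),
    list(g = g$up[[1]]$deconv$W,     get = function(p) p$up[[1]]$deconv$W,
         set = function(p, v) { p$up[[1]]$deconv$W <- v; p }),
    list(g = g$up[[1]]$skip_bn$gamma, get = function(p) p$up[[1]]$skip_bn$gamma,
         set = function(p, v) { p$up[[1]]$skip_bn$gamma <- v; p }),
    list(g = g$final$W,              get = function(p) p$final$W,
         set = function(p, v) { p$final$W <- v; p }))
  eps <- 1e-5
  set.seed(10)
  for (pr in probes) {
    vals <- pr$get(m$params)
    for (i in sample(length(vals), min(2, length(vals)))) {
      vp <- vals; vp[i] <- vp[i] + eps
      vm <- vals; vm[i] <- vm[i] - eps
      mp <- m; mp$params <- pr$set(mp$params, vp)
      mm <- m; mm$params <- pr$set(mm$params, vm)
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(pr$g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("short training runs descend and are seed-deterministic", {
  ds <- fixture_overfit_sample()
  m <- build_network(tiny_arch(), init_seed = 1)
  cfg <- training_config(total_iterations = 25, rng_seed = 5)
  fit1 <- train_network(m, ds, cfg)
  fit2 <- train_network(m, ds, cfg)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  expect_lt(mean(tail(fit1$loss_trace, 5)), mean(head(fit1$loss_trace, 5)))
  expect_true(all(is.finite(fit1$loss_trace)))
})

test_that("checkpoints are written and training resumes from them", {
  ds <- fixture_overfit_sample()
  m <- build_network(tiny_arch(), init_seed = 1)
  d <- withr::local_tempdir()
  cfg <- training_config(total_iterations = 10, rng_seed = 5,
                         checkpoint_every = 5, checkpoint_dir = d)
  fit <- train_network(m, ds, cfg)
  ck <- file.path(d, "checkpoint_latest.rds")
  expect_true(file.exists(ck))
  expect_true(file.exists(file.path(d, "loss_trace.csv")))
  cfg2 <- training_config(total_iterations = 15, rng_seed = 5,
                          checkpoint_every = 100, checkpoint_dir = d)
  fit2 <- train_network(m, ds, cfg2, resume_from = ck)
  expect_length(fit2$loss_trace, 15)
  expect_identical(fit2$loss_trace[1:10], fit$loss_trace)
})

test_that("models serialize with a plain-text architecture sidecar", {
  m <- build_network(tiny_arch(), init_seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".arch.yaml")))
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  arch <- yaml::read_yaml(paste0(f, ".arch.yaml"))
  expect_identical(arch$n_levels, 2L)
})
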