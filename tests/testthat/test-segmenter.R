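test_that("network backprop matches finite differences on a tiny net", {
  ns <- asNamespace("vctdbt")
  set.seed(1)
  ucfg <- unet_config(depth = 2, base_channels = 2)
  lcfg <- loss_config()
  params <- ns$unet_init_params(ucfg, seed = 2)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y <- one_hot(array(sample(0:2, 256, TRUE), c(8, 8, 4)))
  lossfun <- function(pp) {
    fw <- ns$unet_forward(pp, x, ucfg, keep_cache = FALSE)
    combined_loss(ns$softmax_channels(fw$logits), y, lcfg)
  }
  fw <- ns$unet_forward(params, x, ucfg, keep_cache = TRUE)
  pr <- ns$softmax_channels(fw$logits)
  dz <- ns$softmax_bwd(pr, ns$combined_loss_grad(pr, y, lcfg))
  grads <- ns$unet_backward(params, ucfg, fw$cache, dz)
  check <- function(path_get, path_set, gmat) {
    for (k in sample(length(gmat), 3)) {
      e <- 1e-5
      p2 <- path_set(params, k, e)
      p3 <- path_set(params, k, -e)
      num <- (lossfun(p2) - lossfun(p3)) / (2 * e)
      expect_equal(gmat[k], num, tolerance = 1e-4)
    }
  }
  check(NULL, function(p, k, e) { p$enc[[1]]$W1[k] <- p$enc[[1]]$W1[k] + e; p },
        grads$enc[[1]]$W1)
  check(NULL, function(p, k, e) { p$dec[[1]]$W2[k] <- p$dec[[1]]$W2[k] + e; p },
        grads$dec[[1]]$W2)
  check(NULL, function(p, k, e) { p$enc[[2]]$g1[k] <- p$enc[[2]]$g1[k] + e; p },
        grads$enc[[2]]$g1)
  check(NULL, function(p, k, e) { p$final$W[k] <- p$final$W[k] + e; p },
        grads$final$W)
})

test_that("training overfits one sample and keeps honest bookkeeping", {
  s <- separable_sample("p01", seed = 1)
  m <- train_segmenter(list(s, s), loss_config(),
                       unet_config(depth = 2, base_channels = 8),
                       train_config(max_epochs = 50, seed = 3))
  h <- m$history
  expect_equal(nrow(h), 50)
  expect_lt(h$train_loss[50], 0.25 * h$train_loss[1])
  expect_equal(m$checkpoints, seq(5, 50, by = 5))
})

test_that("training is deterministic under a seed", {
  samples <- lapply(1:2, function(i) separable_sample(sprintf("p%02d", i), i))
  cfg <- train_config(max_epochs = 1, seed = 11)
  ucfg <- unet_config(depth = 2, base_channels = 4)
  m1 <- train_segmenter(samples, loss_config(), ucfg, cfg)
  m2 <- train_segmenter(samples, loss_config(), ucfg, cfg)
  expect_equal(m1$history$train_loss[1], m2$history$train_loss[1],
               tolerance = 1e-5)
})

test_that("a separable phantom is segmented accurately after short training", {
  samples <- lapply(1:4, function(i) separable_sample(sprintf("p%02d", i), i))
  m <- train_segmenter(samples, loss_config(),
                       unet_config(depth = 2, base_channels = 8),
                       train_config(max_epochs = 10, seed = 5))
  probs <- predict_segmenter(m, samples[[1]]$recon)
  expect_equal(dim(probs), c(dim(samples[[1]]$recon$values), 3))
  sums <- apply(probs, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  pred <- argmax_labels(probs, 2.5)
  dice <- vctdbt:::hard_dice(pred$labels, samples[[1]]$mask$labels)
  expect_true(all(dice > 0.95))
})

test_that("patch-wise inference tiles with overlap and stays normalized", {
  s <- separable_sample("p01", seed = 2)
  m <- train_segmenter(list(s, s), loss_config(),
                       unet_config(depth = 2, base_channels = 4,
                                   patch_size = 16L),
                       train_config(max_epochs = 2, seed = 4))
  probs <- predict_segmenter(m, s$recon)
  expect_equal(dim(probs), c(dim(s$recon$values), 3))
  sums <- apply(probs, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("argmax labeling breaks ties toward air and matches brute force", {
  p <- array(1 / 3, c(2, 2, 1, 3))
  lab <- argmax_labels(p, 1)
  expect_true(all(lab$labels == 0L))
  set.seed(8)
  pr <- array(runif(4 * 3 * 2 * 3), c(4, 3, 2, 3))
  lab2 <- argmax_labels(pr, 1)
  brute <- array(0L, c(4, 3, 2))
  for (i in 1:4) for (j in 1:3) for (k in 1:2)
    brute[i, j, k] <- which.max(pr[i, j, k, ]) - 1L
  expect_identical(lab2$labels, brute)
})

test_that("degenerate configurations are rejected", {
  expect_error(unet_config(depth = 2, patch_size = 15), "divisible")
  expect_error(train_config(learning_rate = 0), "positive")
  expect_error(train_segmenter(list(), loss_config()), "at least 2")
})
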