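test_that("Tversky index matches hand-computed values", {
  # 2 voxels of the class: p = (1, 0), g = (1, 1): TP = 1, FN = 1, FP = 0
  # TI = 1 / (1 + alpha) for epsilon -> 0
  p <- array(0, c(2, 1, 1, 3))
  g <- array(0, c(2, 1, 1, 3))
  p[1, 1, 1, 2] <- 1; p[2, 1, 1, 1] <- 1
  g[, 1, 1, 2] <- 1
  cfg <- loss_config(alpha = 0.7, beta = 0.3, epsilon = 1e-12)
  expect_equal(tversky_index(p, g, 2, cfg), 1 / 1.7, tolerance = 1e-9)
  # perfect hard prediction: TI = 1 for any epsilon
  expect_equal(tversky_index(g, g, 2, loss_config(epsilon = 1)), 1)
})

test_that("alpha = beta = 0.5 reduces the Tversky index to soft Dice", {
  maps <- random_maps(c(5, 4, 3), seed = 21)
  cfg <- loss_config(alpha = 0.5, beta = 0.5, epsilon = 1e-12)
  for (cl in 1:3) {
    pc <- maps$p[, , , cl]
    gc <- maps$g[, , , cl]
    dice <- 2 * sum(pc * gc) / (2 * sum(pc * gc) + sum((1 - pc) * gc) +
                                  sum(pc * (1 - gc)))
    expect_equal(tversky_index(maps$p, maps$g, cl, cfg), dice,
                 tolerance = 1e-9)
  }
})

test_that("vectorized Tversky/FTL agree with the per-voxel brute force", {
  cfg <- loss_config(epsilon = 1e-6)
  for (seed in 1:100) {
    maps <- random_maps(c(4, 4, 4), seed = seed)
    for (cl in sample(1:3, 1)) {
      brute <- brute_tversky(maps$p, maps$g, cl, cfg$alpha, cfg$beta,
                             cfg$epsilon)
      expect_equal(tversky_index(maps$p, maps$g, cl, cfg), brute,
                   tolerance = 1e-9)
    }
    brute_ftl <- sum(sapply(1:3, function(cl)
      (1 - brute_tversky(maps$p, maps$g, cl, cfg$alpha, cfg$beta,
                         cfg$epsilon))^cfg$gamma))
    expect_equal(focal_tversky_loss(maps$p, maps$g, 1:3, cfg), brute_ftl,
                 tolerance = 1e-9)
  }
})

test_that("focal loss limits behave: scalar power, gamma = 1, perfection", {
  maps <- random_maps(c(4, 4, 4), seed = 77)
  # one class with TI = 0.5 at gamma = 3/4 gives 0.5^0.75
  p <- array(0, c(2, 1, 1, 3)); g <- array(0, c(2, 1, 1, 3))
  p[1, 1, 1, 2] <- 1; p[2, 1, 1, 1] <- 1
  g[, 1, 1, 2] <- 1
  cfg05 <- loss_config(alpha = 1, beta = 1, epsilon = 1e-12)  # TI = 1/2
  expect_equal(focal_tversky_loss(p, g, 2, cfg05), 0.5^0.75,
               tolerance = 1e-9)
  # gamma = 1: FTL = sum(1 - TI)
  cfg1 <- loss_config(gamma = 1)
  expect_equal(focal_tversky_loss(maps$p, maps$g, 1:3, cfg1),
               sum(sapply(1:3, function(cl)
                 1 - tversky_index(maps$p, maps$g, cl, cfg1))),
               tolerance = 1e-12)
  # perfect prediction on all classes: loss 0 (epsilon keeps TI = 1)
  expect_equal(focal_tversky_loss(maps$g, maps$g, 1:3, loss_config()), 0,
               tolerance = 1e-9)
  expect_error(focal_tversky_loss(maps$p, maps$g, integer(0)), "non-empty")
})

test_that("outline merge adds tissue probabilities and keeps air", {
  maps <- random_maps(c(3, 3, 3), seed = 5)
  out <- to_outline_targets(maps$p)
  expect_equal(dim(out), c(3, 3, 3, 2))
  expect_equal(out[, , , 1], maps$p[, , , 1])
  expect_equal(out[, , , 2], maps$p[, , , 2] + maps$p[, , , 3],
               tolerance = 1e-12)
  # all-air: tissue channel is zero
  g_air <- one_hot(array(0L, c(3, 3, 3)))
  expect_true(all(to_outline_targets(g_air)[, , , 2] == 0))
})

test_that("combined loss is additive and degenerates correctly", {
  maps <- random_maps(c(4, 4, 4), seed = 9)
  cfg <- loss_config(lambda_outline = 0.7)
  l1 <- focal_tversky_loss(maps$p, maps$g, 1:3, cfg)
  l2 <- focal_tversky_loss(to_outline_targets(maps$p),
                           to_outline_targets(maps$g), 1:2, cfg)
  expect_equal(combined_loss(maps$p, maps$g, cfg), l1 + 0.7 * l2,
               tolerance = 1e-12)
  cfg0 <- loss_config(lambda_outline = 0)
  expect_equal(combined_loss(maps$p, maps$g, cfg0), l1, tolerance = 1e-12)
  expect_equal(combined_loss(maps$g, maps$g, loss_config()), 0,
               tolerance = 1e-9)
})

test_that("TI stays in [0,1] and FTL decreases toward the target", {
  cfg <- loss_config()
  for (seed in 1:20) {
    maps <- random_maps(c(4, 4, 4), seed = 100 + seed)
    tis <- sapply(1:3, function(cl)
      tversky_index(maps$p, maps$g, cl, cfg))
    expect_true(all(tis >= 0 & tis <= 1))
    # interpolating p toward g strictly decreases the loss
    losses <- sapply(c(0, 0.3, 0.6, 0.9), function(w)
      combined_loss((1 - w) * maps$p + w * maps$g, maps$g, cfg))
    expect_true(all(diff(losses) < 0))
  }
})

test_that("the analytic loss gradient matches finite differences", {
  maps <- random_maps(c(4, 3, 2), seed = 33)
  cfg <- loss_config(lambda_outline = 0.5)
  gr <- vctdbt:::combined_loss_grad(maps$p, maps$g, cfg)
  set.seed(2)
  for (i in sample(length(maps$p), 6)) {
    e <- 1e-6
    p_hi <- maps$p; p_hi[i] <- p_hi[i] + e
    p_lo <- maps$p; p_lo[i] <- p_lo[i] - e
    num <- (combined_loss(p_hi, maps$g, cfg) -
              combined_loss(p_lo, maps$g, cfg)) / (2 * e)
    expect_equal(gr[i], num, tolerance = 1e-5)
  }
})
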