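test_that("slice distance is signed, centered, and monotone", {
  vol <- label_volume(array(0L, c(2, 2, 100)), 0.5)
  expect_equal(slice_distance(50, vol), 0)
  expect_equal(slice_distance(1, vol), -24.5)
  d <- slice_distance(1:100, vol)
  expect_true(all(diff(d) > 0))
  odd <- label_volume(array(0L, c(2, 2, 7)), 1)
  expect_equal(slice_distance(4, odd), 0)
})

test_that("slice confusion matches an exhaustive tally and its symmetries", {
  set.seed(12)
  mk <- function(lab) label_volume(array(lab, c(8, 8, 1)), 1)
  truth <- mk(sample(0:2, 64, TRUE))
  pred <- mk(sample(0:2, 64, TRUE))
  rec <- confusion_per_slice(pred, truth, 1)
  for (cl in 0:2) {
    r <- rec[rec$class == vctdbt:::class_names[cl + 1], ]
    expect_equal(r$TP, sum(pred$labels == cl & truth$labels == cl))
    expect_equal(r$FP, sum(pred$labels == cl & truth$labels != cl))
    expect_equal(r$FN, sum(pred$labels != cl & truth$labels == cl))
    expect_equal(r$TP + r$FP + r$FN + r$TN, 64)
  }
  # perfect prediction: no errors
  perf <- confusion_per_slice(truth, truth, 1)
  expect_true(all(perf$FP == 0) && all(perf$FN == 0))
  # swapping classes 1 and 2 turns class-1 FPs into class-2 FNs
  swapped <- mk(c(0L, 2L, 1L)[truth$labels + 1L])
  sw <- confusion_per_slice(swapped, truth, 1)
  expect_equal(sw$FP[sw$class == "adipose"], sw$FN[sw$class == "dense"])
})

test_that("metrics obey their identities and flag empty unions", {
  rec <- data.frame(TP = c(10, 0, 0), FP = c(0, 5, 0), FN = c(0, 5, 0),
                    TN = c(90, 90, 100))
  m <- slice_metrics(rec)
  expect_equal(m$jaccard[1], 1)
  expect_equal(m$dice[1], 1)
  expect_equal(m$jaccard_distance[1], 0)
  expect_equal(m$jaccard[2], 0)   # disjoint
  expect_equal(m$dice[2], 0)
  expect_equal(m$jaccard_distance[2], 1)
  expect_true(is.na(m$jaccard[3]) && m$undefined[3])
  # J = D / (2 - D) on random confusions
  set.seed(13)
  r <- data.frame(TP = rpois(50, 20), FP = rpois(50, 5), FN = rpois(50, 5))
  r$TN <- 100
  mm <- slice_metrics(r)
  ok <- !mm$undefined
  expect_equal(mm$jaccard[ok], mm$dice[ok] / (2 - mm$dice[ok]),
               tolerance = 1e-12)
})

test_that("distance binning partitions slices into equal-count deciles", {
  set.seed(14)
  recs <- do.call(rbind, lapply(1:10, function(ph) {
    nz <- sample(15:25, 1)
    vol <- label_volume(array(0L, c(2, 2, nz)), 2)
    data.frame(phantom = sprintf("p%02d", ph), z = 1:nz,
               d = slice_distance(1:nz, vol), class = "air",
               TP = 1, FP = 0, FN = 0, TN = 3,
               jaccard = 1, jaccard_distance = 0, undefined = FALSE,
               model = "m1")
  }))
  binned <- bin_by_distance(recs, 10)
  counts <- table(binned$bin)
  expect_equal(length(counts), 10)
  expect_lte(diff(range(counts)), 1)
  expect_equal(sum(counts), nrow(recs))      # every record in exactly one bin
  # bins ordered by distance
  means <- tapply(binned$d, binned$bin, mean)
  expect_true(all(diff(means) > 0))
  # equal-thickness phantoms: boundaries at the pooled d-deciles
  same <- recs[rep(recs$phantom == "p01", 1), ]
  same <- do.call(rbind, lapply(1:5, function(i) {
    x <- recs[recs$phantom == "p01", ]; x$phantom <- sprintf("q%d", i); x
  }))
  bs <- bin_by_distance(same, 10)
  qs <- quantile(same$d, seq(0.1, 0.9, 0.1), type = 1)
  for (b in 1:9)
    expect_lte(max(bs$d[bs$bin == b]), qs[b] + 1e-9)
})

test_that("improvement is the relative reduction in Jaccard distance", {
  expect_equal(improvement(0.10, 0.05), 50)
  expect_equal(improvement(0.2, 0.2), 0)
  # a representative bin: rounded means 0.064 -> 0.044 give ~31% resolved
  expect_equal(improvement(0.064, 0.044), 31.25, tolerance = 1e-9)
  expect_error(improvement(0, 0.1), "positive")
})

test_that("model comparisons: Kruskal-Wallis and exact rank-sum behavior", {
  recs <- data.frame(
    phantom = "p", z = rep(1:6, 2), d = rep(1:6, 2),
    class = "air", undefined = FALSE,
    jaccard_distance = c(1, 2, 3, 4, 5, 6, 4, 5, 6, 1, 2, 3) / 10,
    model = rep(c("a", "b"), each = 6), bin = rep(1:2, 6))
  out <- compare_models(recs, "jaccard_distance", "air", by_bin = FALSE)
  expect_true(all(out$pairwise$p_value >= 0 & out$pairwise$p_value <= 1))
  # identical groups: KW statistic 0
  recs2 <- recs
  recs2$jaccard_distance <- rep(c(1, 2, 3, 4, 5, 6) / 10, 2)
  out2 <- compare_models(recs2, "jaccard_distance", "air", by_bin = FALSE)
  expect_equal(unname(out2$omnibus$statistic), 0)
  # {1,2,3} vs {4,5,6}: exact two-sided rank-sum p = 0.1
  # (oracle: full enumeration of the 20 equally likely assignments)
  enumerate_p <- function(x, y) {
    pooled <- c(x, y)
    combos <- combn(6, 3)
    stat <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
    obs <- sum(rank(pooled)[1:3])
    mean(abs(stat - 10.5) >= abs(obs - 10.5))
  }
  expect_equal(enumerate_p(1:3, 4:6), 0.1)
  wt <- wilcox.test(1:3, 4:6)$p.value
  expect_equal(wt, 0.1, tolerance = 1e-12)
  recs3 <- data.frame(
    phantom = "p", z = 1:6, d = 1:6, class = "air", undefined = FALSE,
    jaccard_distance = 1:6, model = rep(c("a", "b"), each = 3), bin = 1)
  out3 <- compare_models(recs3, "jaccard_distance", "air", by_bin = FALSE)
  expect_equal(out3$pairwise$p_value, 0.1, tolerance = 1e-12)
})

test_that("accuracy colormap categories reproduce the confusion counts", {
  set.seed(15)
  mk <- function(lab) label_volume(array(lab, c(10, 10, 1)), 1)
  truth <- mk(sample(0:2, 100, TRUE))
  pred <- mk(sample(0:2, 100, TRUE))
  cm <- accuracy_colormap(pred, truth, 1)
  expect_false(any(is.na(cm)))
  ts <- truth$labels[, , 1]; ps <- pred$labels[, , 1]
  expect_equal(sum(cm == 1), sum(ts == 0 & ps == 0))
  expect_equal(sum(cm == 2), sum((ts == 0) != (ps == 0)))
  expect_equal(sum(cm == 3), sum(ts != 0 & ps != 0 & ts != ps))
  expect_equal(sum(cm == 4), sum(ts == 1 & ps == 1))
  expect_equal(sum(cm == 5), sum(ts == 2 & ps == 2))
  # perfect prediction: no error colors
  cmp <- accuracy_colormap(truth, truth, 1)
  expect_true(all(cmp != 2) && all(cmp != 3))
  # all-air truth vs all-adipose prediction: fully red
  cm2 <- accuracy_colormap(mk(rep(1L, 100)), mk(rep(0L, 100)), 1)
  expect_true(all(cm2 == 2))
  # PNG writing works
  path <- tempfile(fileext = ".png")
  write_colormap_png(cm, path)
  expect_true(file.exists(path) && file.info(path)$size > 0)
  unlink(path)
})
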