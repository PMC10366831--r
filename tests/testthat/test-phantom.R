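test_that("population sampling matches the target distribution and is seeded", {
  spec <- population_spec(n_phantoms = 1000, seed = 42L)
  pop <- sample_population(spec)
  expect_equal(nrow(pop), 1000)
  # pre-cap median within 5% of the clinical median
  expect_lt(abs(median(pop$cbt_raw_mm) - 60.50) / 60.50, 0.05)
  expect_lt(abs(median(pop$target_vbd * 100) - 12.75) / 12.75, 0.05)
  # IQR calibration within 5% pre-cap
  q <- quantile(pop$cbt_raw_mm, c(0.25, 0.75))
  expect_lt(abs(q[1] - 51.50) / 51.50, 0.05)
  expect_lt(abs(q[2] - 69.5) / 69.5, 0.05)
  # cap enforced on CBT only
  expect_true(all(pop$cbt_mm <= spec$cbt_cap_mm))
  # determinism
  pop2 <- sample_population(population_spec(n_phantoms = 1000, seed = 42L))
  expect_identical(pop, pop2)
})

test_that("degenerate or inverted quartiles are rejected", {
  expect_error(population_spec(5, cbt_q1_mm = 60.5, cbt_median_mm = 60.5,
                               cbt_q3_mm = 60.5),
               "q1 < median < q3")
  expect_error(population_spec(5, vbd_q1_pct = 25, vbd_median_pct = 12.75),
               "q1 < median < q3")
  expect_error(population_spec(0), "n_phantoms")
})

test_that("outline with no bulge is a prism with identical slices", {
  p <- outline_params(cbt_mm = 20, cnd_mm = 30, width_mm = 40, bulge_mm = 0)
  m <- generate_outline(p, voxel_mm = 1)
  areas <- apply(m, 3, sum)
  expect_true(all(areas == areas[1]))
})

test_that("half-cylinder outline volume matches the analytic formula", {
  r <- 30
  p <- outline_params(cbt_mm = 20, cnd_mm = r, width_mm = 2 * r,
                      bulge_mm = 0)
  m <- generate_outline(p, voxel_mm = 0.5)
  measured <- sum(m) * 0.5^3
  analytic <- pi * r^2 / 2 * 20
  expect_lt(abs(measured - analytic) / analytic, 0.02)
})

test_that("bulge makes mid-thickness slices larger, unimodally", {
  p <- outline_params(cbt_mm = 40, cnd_mm = 60, width_mm = 80,
                      bulge_mm = 8, contact_fraction = 0.4)
  m <- generate_outline(p, voxel_mm = 2)
  areas <- apply(m, 3, sum)
  nz <- length(areas)
  mid <- ceiling(nz / 2)
  expect_gt(areas[mid], areas[1])
  expect_gt(areas[mid], areas[nz])
  # unimodal: non-decreasing up to the max, non-increasing after
  pk <- which.max(areas)
  expect_true(all(diff(areas[1:pk]) >= 0))
  expect_true(all(diff(areas[pk:nz]) <= 0))
})

test_that("outline rejects sub-voxel thickness", {
  p <- outline_params(cbt_mm = 2, cnd_mm = 30, width_mm = 40)
  expect_error(generate_outline(p, voxel_mm = 1), "3 voxels")
})

test_that("octree fill hits the target density within half a point", {
  mask <- array(TRUE, dim = c(64, 64, 64))
  attr(mask, "voxel_mm") <- 1
  for (target in c(0.05, 0.2, 0.5)) {
    lv <- fill_tissue(mask, target, seed = 7)
    expect_lt(abs(measure_vbd(lv) - target), 0.005)
    expect_true(all(lv$labels %in% 0:2))
  }
})

test_that("octree fill is deterministic under a seed and all-adipose at 0", {
  p <- outline_params(cbt_mm = 20, cnd_mm = 30, width_mm = 40, bulge_mm = 4)
  m <- generate_outline(p, voxel_mm = 2)
  a <- fill_tissue(m, 0.15, seed = 11)
  b <- fill_tissue(m, 0.15, seed = 11)
  expect_identical(a$labels, b$labels)
  z <- fill_tissue(m, 0, seed = 11)
  expect_equal(measure_vbd(z), 0)
  expect_true(all(z$labels[m] == 1L))
})

test_that("measure_vbd equals the exhaustive voxel count", {
  set.seed(3)
  lab <- array(sample(0:2, 1000, replace = TRUE), c(10, 10, 10))
  v <- label_volume(lab, 1)
  brute <- sum(lab == 2) / (sum(lab == 2) + sum(lab == 1))
  expect_equal(measure_vbd(v), brute)
  expect_equal(measure_vbd(label_volume(array(1L, c(3, 3, 3)), 1)), 0)
  expect_error(measure_vbd(label_volume(array(0L, c(3, 3, 3)), 1)),
               "no tissue")
})

test_that("label volumes round-trip through NIfTI with pitch intact", {
  p <- outline_params(cbt_mm = 15, cnd_mm = 20, width_mm = 30, bulge_mm = 3)
  m <- generate_outline(p, voxel_mm = 2.5)
  lv <- fill_tissue(m, 0.2, seed = 5)
  path <- tempfile(fileext = ".nii.gz")
  write_label_volume(lv, path)
  back <- read_label_volume(path)
  expect_identical(back$labels, lv$labels)
  expect_equal(back$voxel_mm, lv$voxel_mm)
  unlink(path)
})
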