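test_that("material table enforces the attenuation ordering", {
  expect_error(material_table(mu_air = 0.1, mu_adipose = 0.05), "mu_air")
  m <- material_table()
  expect_lt(m$mu_air, m$mu_adipose)
  expect_lt(m$mu_adipose, m$mu_dense)
})

test_that("ray integrals through a uniform slab follow the closed form", {
  slab <- label_volume(array(1L, dim = c(10, 10, 10)), 1)
  mat <- material_table()
  # miss entirely
  expect_equal(ray_integral(slab, mat, c(-50, 5, 100), c(-50, 5, -10)), 0)
  # vertical ray: mu * t
  expect_equal(ray_integral(slab, mat, c(5, 5, 100), c(5, 5, -10)),
               mat$mu_adipose * 10, tolerance = 1e-12)
  # oblique ray: mu * t / cos(theta)
  th <- 0.3
  got <- ray_integral(slab, mat, c(5 - tan(th) * 95, 5, 100),
                      c(5 + tan(th) * 15, 5, -10))
  expect_equal(got, mat$mu_adipose * 10 / cos(th), tolerance = 1e-9)
  # src inside the volume is rejected
  expect_error(ray_integral(slab, mat, c(5, 5, 5), c(5, 5, -10)), "outside")
})

test_that("Siddon agrees with a dense-sampling oracle on random volumes", {
  set.seed(19)
  mat <- material_table()
  mu_vals <- c(mat$mu_air, mat$mu_adipose, mat$mu_dense)
  for (rep in 1:4) {
    lab <- array(sample(0:2, 16^3, replace = TRUE), c(16, 16, 16))
    lv <- label_volume(lab, 1)
    mu_vol <- array(mu_vals[lab + 1L], dim(lab))
    for (k in 1:25) {
      src <- c(runif(1, -5, 21), runif(1, -5, 21), 30 + runif(1, 0, 10))
      dst <- c(runif(1, 0, 16), runif(1, 0, 16), -5)
      exact <- ray_integral(lv, mat, src, dst)
      approx <- sampled_ray_integral(mu_vol, 1, c(0, 0, 0), src, dst)
      ref <- mat$mu_adipose * 16  # scale: a full tissue traversal
      expect_lt(abs(exact - approx) / ref, 1e-3)
    }
  }
})

test_that("forward projection is linear in mu and zero for air", {
  det <- test_detector(n_u = 24L, n_v = 20L)
  g <- make_conventional(n = 3, detector = det)
  empty <- label_volume(array(0L, c(10, 10, 8)), 2.5)
  p0 <- forward_project(empty, g, material_table())
  expect_true(all(p0$images == 0))

  lv <- point_phantom(dims = c(10L, 10L, 8L), at = c(5L, 5L, 4L))
  m1 <- material_table()
  m2 <- material_table(mu_adipose = 2 * m1$mu_adipose,
                       mu_dense = 2 * m1$mu_dense)
  p1 <- forward_project(lv, g, m1)
  p2 <- forward_project(lv, g, m2)
  expect_equal(p2$images, 2 * p1$images, tolerance = 1e-12)
  expect_true(all(p1$images >= 0))
})

test_that("a single dense voxel casts one shadow at its perspective position", {
  det <- test_detector(pitch = 1, n_u = 120L, n_v = 100L)
  lv <- point_phantom(dims = c(20L, 20L, 10L), at = c(8L, 12L, 5L),
                      voxel_mm = 2.5)
  g <- make_conventional(n = 3, detector = det)
  p <- forward_project(lv, g, material_table())
  org <- vctdbt:::volume_origin(dim(lv$labels), 2.5, det)
  vox <- org + (c(8, 12, 5) - 0.5) * 2.5
  for (s in 1:3) {
    img <- p$images[, , s]
    expect_gt(max(img), 0)
    pk <- arrayInd(which.max(img), dim(img))
    src <- g$sources[s, ]
    tt <- (-det$gap_mm - src[3]) / (vox[3] - src[3])
    expect_x <- src[1] + (vox[1] - src[1]) * tt
    expect_y <- src[2] + (vox[2] - src[2]) * tt
    # shadow center within one pixel of the geometric prediction
    expect_lt(abs((pk[1] - 0.5) * 1 - expect_x), 1.6)
    expect_lt(abs((pk[2] - 0.5) * 1 - expect_y), 1.6)
  }
})

test_that("projection of disjoint objects is the sum of the parts", {
  det <- test_detector(n_u = 30L, n_v = 24L)
  g <- make_conventional(n = 3, detector = det)
  mat <- material_table()
  a <- array(0L, c(12, 12, 8)); a[3:5, 3:5, 2:3] <- 1L
  b <- array(0L, c(12, 12, 8)); b[8:10, 8:10, 6:7] <- 2L
  both <- a + b
  pa <- forward_project(label_volume(a, 2.5), g, mat)
  pb <- forward_project(label_volume(b, 2.5), g, mat)
  pab <- forward_project(label_volume(both, 2.5), g, mat)
  expect_equal(pab$images, pa$images + pb$images, tolerance = 1e-10)
})

test_that("Poisson noise is seeded and shrinks with exposure", {
  det <- test_detector(n_u = 16L, n_v = 12L)
  g <- make_conventional(n = 2, detector = det)
  lv <- label_volume(array(1L, c(8, 8, 6)), 2.5)
  p <- forward_project(lv, g, material_table())
  expect_error(add_noise(p, 0), "positive")
  n1 <- add_noise(p, 1e4, exposure_scale = 1, seed = 9)
  n2 <- add_noise(p, 1e4, exposure_scale = 1, seed = 9)
  expect_identical(n1$images, n2$images)
  # noiseless limit: error vanishes relative to the projection scale
  nb <- add_noise(p, 1e12, exposure_scale = 1, seed = 9)
  expect_lt(max(abs(nb$images - p$images)) / max(p$images), 1e-3)
  # variance at 6x exposure is ~1/6 of the variance at 1x (delta method)
  pix <- p$images[8, 6, 1]
  draws <- function(scale, seed) {
    set.seed(seed)
    i0 <- 1e4 * scale
    counts <- pmax(rpois(10000, i0 * exp(-pix)), 1)
    -log(counts / i0)
  }
  v1 <- var(draws(1, 1))
  v6 <- var(draws(6, 2))
  expect_lt(abs(v6 / v1 - 1 / 6), 0.05 / 6 * 3)
})

test_that("projection sets round-trip through TIFF + sidecar", {
  det <- test_detector(n_u = 16L, n_v = 12L)
  g <- make_conventional(n = 3, detector = det)
  lv <- point_phantom(dims = c(8L, 8L, 6L), at = c(4L, 4L, 3L))
  p <- forward_project(lv, g, material_table())
  path <- tempfile(fileext = ".tiff")
  write_projection_set(p, path)
  back <- read_projection_set(path)
  expect_equal(back$images, p$images, tolerance = 1e-6)
  expect_equal(back$geometry$name, "conventional")
  unlink(c(path, paste0(path, ".json"), paste0(path, ".geom.json")))
})
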