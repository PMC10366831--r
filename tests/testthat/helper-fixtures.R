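# Shared fixtures, built in code at test time.

# small detector used throughout the unit tests
test_detector <- function(pitch = 2.5, n_u = 60L, n_v = 48L, gap = 25) {
  detector_spec(pixel_pitch_mm = pitch, n_u = n_u, n_v = n_v, gap_mm = gap)
}

# a phantom with a single dense voxel at a known location
point_phantom <- function(dims = c(40L, 40L, 20L), at = c(20L, 20L, 10L),
                          voxel_mm = 2.5) {
  lab <- array(0L, dims)
  lab[at[1], at[2], at[3]] <- 2L
  label_volume(lab, voxel_mm)
}

# toy sample with class-separable intensities (for segmenter tests)
separable_sample <- function(id, seed, dims = c(32L, 24L, 12L), sd = 0.2) {
  set.seed(seed)
  lab <- array(0L, dims)
  lab[8:24, 4:20, 3:10] <- 1L
  lab[12:20, 8:16, 5:8] <- 2L
  vals <- c(0, 1, 2)[lab + 1L] + stats::rnorm(length(lab), sd = sd)
  vct_sample(recon_volume(array(vals, dims), 2.5),
             label_volume(lab, 2.5), id, "conventional")
}

# random softmax probability map and one-hot target of a given spatial size
random_maps <- function(dims = c(4L, 4L, 4L), seed = 1L) {
  set.seed(seed)
  n <- prod(dims)
  logits <- matrix(stats::rnorm(n * 3), n, 3)
  e <- exp(logits)
  p <- array(e / rowSums(e), dim = c(dims, 3L))
  g <- one_hot(array(sample(0:2, n, replace = TRUE), dims))
  list(p = p, g = g)
}

# independent brute-force Tversky index: explicit per-voxel loop
brute_tversky <- function(p, g, cl, alpha, beta, eps) {
  d <- dim(p)
  num <- 0; fn <- 0; fp <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    pic <- p[i, j, k, cl]
    gic <- g[i, j, k, cl]
    num <- num + pic * gic
    fn <- fn + (1 - pic) * gic
    fp <- fp + pic * (1 - gic)
  }
  (num + eps) / (num + alpha * fn + beta * fp + eps)
}

# independent dense-sampling line-integral oracle (step-wise midpoint rule)
sampled_ray_integral <- function(mu_vol, voxel_mm, origin, src, dst,
                                 n_steps = 40000L) {
  t <- (seq_len(n_steps) - 0.5) / n_steps
  px <- src[1] + t * (dst[1] - src[1])
  py <- src[2] + t * (dst[2] - src[2])
  pz <- src[3] + t * (dst[3] - src[3])
  ix <- floor((px - origin[1]) / voxel_mm) + 1
  iy <- floor((py - origin[2]) / voxel_mm) + 1
  iz <- floor((pz - origin[3]) / voxel_mm) + 1
  d <- dim(mu_vol)
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  step_len <- sqrt(sum((dst - src)^2)) / n_steps
  sum(mu_vol[cbind(ix[ok], iy[ok], iz[ok])]) * step_len
}
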