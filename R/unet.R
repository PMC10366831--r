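# Internal 3D convolutional network machinery.
#
# All tensors are 4D arrays (nx, ny, nz, channels). 3x3x3 convolutions with
# zero padding 1 are evaluated as im2col matrix products so the heavy
# arithmetic runs in BLAS; gradients are hand-derived (col2im adjoint).

im2col3 <- function(a) im2col3_cpp(a)

col2im3 <- function(M, d) col2im3_cpp(M, as.integer(d))

conv3_fwd <- function(a, W, b) {
  X <- im2col3(a)
  Y <- X %*% W
  Y <- Y + rep(b, each = nrow(Y))
  d <- dim(a)
  list(y = array(Y, dim = c(d[1:3], length(b))), X = X, in_dim = d)
}

conv3_bwd <- function(dY4, cache, W) {
  dY <- matrix(dY4, ncol = dim(dY4)[4])
  list(dW = crossprod(cache$X, dY),
       db = colSums(dY),
       dx = col2im3(dY %*% t(W), cache$in_dim))
}

# leaky rectifier (negative slope 0.01): avoids dead units at the large
# prescribed learning rate
relu_fwd <- function(a) pmax(a, 0) + 0.01 * pmin(a, 0)
relu_bwd <- function(g, y) g * (0.01 + 0.99 * (y > 0))

# instance normalization: per-channel z-score over the spatial volume with a
# learned affine (gamma, beta); stabilizes whole-volume training
in_fwd <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a)
  M <- matrix(a, ncol = d[4])
  mu <- colMeans(M)
  xc <- M - rep(mu, each = nrow(M))
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * rep(inv, each = nrow(M))
  y <- xh * rep(gamma, each = nrow(M)) + rep(beta, each = nrow(M))
  list(y = array(y, dim = d), xh = xh, inv = inv, dim = d)
}

in_bwd <- function(g4, cache, gamma) {
  d <- cache$dim
  G <- matrix(g4, ncol = d[4])
  dgamma <- colSums(G * cache$xh)
  dbeta <- colSums(G)
  n <- nrow(G)
  t1 <- G - rep(dbeta / n, each = n) -
    cache$xh * rep(dgamma / n, each = n)
  dx <- t1 * rep(gamma * cache$inv, each = n)
  list(dx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

maxpool_fwd <- function(a) {
  d <- dim(a)
  xs <- seq(1L, d[1], 2L); ys <- seq(1L, d[2], 2L); zs <- seq(1L, d[3], 2L)
  offs <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  best <- a[xs, ys, zs, , drop = FALSE]
  win <- array(1L, dim = dim(best))
  for (k in 2:8) {
    sk <- a[xs + offs$dx[k], ys + offs$dy[k], zs + offs$dz[k], ,
            drop = FALSE]
    m <- sk > best
    best[m] <- sk[m]
    win[m] <- k
  }
  list(y = best, win = win, in_dim = d)
}

maxpool_bwd <- function(g, cache) {
  d <- cache$in_dim
  xs <- seq(1L, d[1], 2L); ys <- seq(1L, d[2], 2L); zs <- seq(1L, d[3], 2L)
  offs <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  out <- array(0, dim = d)
  for (k in 1:8) {
    gk <- g
    gk[cache$win != k] <- 0
    out[xs + offs$dx[k], ys + offs$dy[k], zs + offs$dz[k], ] <- gk
  }
  out
}

upsample_fwd <- function(a) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
    rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

upsample_bwd <- function(g) {
  d <- dim(g)
  xs <- seq(1L, d[1], 2L); ys <- seq(1L, d[2], 2L); zs <- seq(1L, d[3], 2L)
  out <- g[xs, ys, zs, , drop = FALSE] * 0
  offs <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  for (k in 1:8)
    out <- out + g[xs + offs$dx[k], ys + offs$dy[k], zs + offs$dz[k], ,
                   drop = FALSE]
  out
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

unet_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

double_block_params <- function(cin, cout) {
  list(W1 = he_init(27L * cin, cout), b1 = numeric(cout),
       g1 = rep(1, cout), be1 = numeric(cout),
       W2 = he_init(27L * cout, cout), b2 = numeric(cout),
       g2 = rep(1, cout), be2 = numeric(cout))
}

unet_init_params <- function(cfg, seed = 1L) {
  set.seed(seed)
  ch <- unet_channels(cfg)
  enc <- list()
  for (l in seq_len(cfg$depth)) {
    cin <- if (l == 1L) cfg$in_channels else ch[l - 1L]
    enc[[l]] <- double_block_params(cin, ch[l])
  }
  dec <- list()
  if (cfg$depth > 1L) {
    for (l in seq_len(cfg$depth - 1L))
      dec[[l]] <- double_block_params(ch[l + 1L] + ch[l], ch[l])
  }
  final <- list(W = he_init(ch[1], cfg$n_classes),
                b = numeric(cfg$n_classes))
  list(enc = enc, dec = dec, final = final)
}

# conv 3x3x3 -> instance norm -> leaky relu, twice
double_block_fwd <- function(a, prm) {
  c1 <- conv3_fwd(a, prm$W1, prm$b1)
  n1 <- in_fwd(c1$y, prm$g1, prm$be1)
  y1 <- relu_fwd(n1$y)
  c2 <- conv3_fwd(y1, prm$W2, prm$b2)
  n2 <- in_fwd(c2$y, prm$g2, prm$be2)
  y2 <- relu_fwd(n2$y)
  list(y = y2, c1 = c1, n1 = n1, y1 = y1, c2 = c2, n2 = n2, y2 = y2)
}

double_block_bwd <- function(da, cache, prm) {
  g2 <- relu_bwd(da, cache$y2)
  ib2 <- in_bwd(g2, cache$n2, prm$g2)
  b2 <- conv3_bwd(ib2$dx, cache$c2, prm$W2)
  g1 <- relu_bwd(b2$dx, cache$y1)
  ib1 <- in_bwd(g1, cache$n1, prm$g1)
  b1 <- conv3_bwd(ib1$dx, cache$c1, prm$W1)
  list(grads = list(W1 = b1$dW, b1 = b1$db, g1 = ib1$dgamma,
                    be1 = ib1$dbeta,
                    W2 = b2$dW, b2 = b2$db, g2 = ib2$dgamma,
                    be2 = ib2$dbeta),
       dx = b1$dx)
}

# pad spatial dims with zeros up to a multiple of 2^(depth-1)
pad_to_multiple <- function(a, m) {
  d <- dim(a)
  nd <- ceiling(d[1:3] / m) * m
  if (all(nd == d[1:3])) return(list(a = a, orig = d[1:3]))
  out <- array(0, dim = c(nd, d[4]))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- a
  list(a = out, orig = d[1:3])
}

unet_forward <- function(params, x, cfg, keep_cache = TRUE) {
  m <- 2L^(cfg$depth - 1L)
  padded <- pad_to_multiple(x, m)
  a <- padded$a
  cache <- list(orig = padded$orig, enc = list(), pool = list(),
                dec = list(), skips_dim = list())
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    blk <- double_block_fwd(a, params$enc[[l]])
    if (keep_cache) cache$enc[[l]] <- blk
    if (l < cfg$depth) {
      skips[[l]] <- blk$y
      mp <- maxpool_fwd(blk$y)
      if (keep_cache) cache$pool[[l]] <- mp
      a <- mp$y
    } else {
      a <- blk$y
    }
  }
  if (cfg$depth > 1L) {
    for (l in rev(seq_len(cfg$depth - 1L))) {
      up <- upsample_fwd(a)
      cat_in <- concat4(skips[[l]], up)
      blk <- double_block_fwd(cat_in, params$dec[[l]])
      if (keep_cache) {
        blk$skip_ch <- dim(skips[[l]])[4]
        cache$dec[[l]] <- blk
      }
      a <- blk$y
    }
  }
  d <- dim(a)
  A <- matrix(a, ncol = d[4])
  logits <- A %*% params$final$W +
    rep(params$final$b, each = nrow(A))
  if (keep_cache) {
    cache$final_in <- A
    cache$final_dim <- d
  }
  list(logits = array(logits, dim = c(d[1:3], cfg$n_classes)),
       cache = if (keep_cache) cache else NULL)
}

# dlogits: array (nx, ny, nz, n_classes) on the padded grid
unet_backward <- function(params, cfg, cache, dlogits) {
  grads <- list(enc = vector("list", cfg$depth),
                dec = vector("list", max(cfg$depth - 1L, 0L)),
                final = list())
  dL <- matrix(dlogits, ncol = dim(dlogits)[4])
  grads$final$W <- crossprod(cache$final_in, dL)
  grads$final$b <- colSums(dL)
  da <- array(dL %*% t(params$final$W), dim = cache$final_dim)

  dskips <- list()
  if (cfg$depth > 1L) {
    for (l in seq_len(cfg$depth - 1L)) {
      cd <- cache$dec[[l]]
      bk <- double_block_bwd(da, cd, params$dec[[l]])
      grads$dec[[l]] <- bk$grads
      sc <- cd$skip_ch
      dcat <- bk$dx
      dskips[[l]] <- dcat[, , , seq_len(sc), drop = FALSE]
      dup <- dcat[, , , (sc + 1L):dim(dcat)[4], drop = FALSE]
      da <- upsample_bwd(dup)
    }
  }
  # da now flows into the bottleneck encoder level (depth), dskips into the
  # shallower levels
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) {
      dp <- maxpool_bwd(da, cache$pool[[l]])
      da <- dp + dskips[[l]]
    }
    bk <- double_block_bwd(da, cache$enc[[l]], params$enc[[l]])
    grads$enc[[l]] <- bk$grads
    da <- bk$dx
  }
  grads
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  L <- matrix(logits, ncol = d[4])
  L <- L - apply(L, 1, max)
  E <- exp(L)
  P <- E / rowSums(E)
  array(P, dim = d)
}

# backprop dL/dp through the per-voxel softmax: dz = p * (dp - sum_j p_j dp_j)
softmax_bwd <- function(p, dp) {
  d <- dim(p)
  P <- matrix(p, ncol = d[4])
  D <- matrix(dp, ncol = d[4])
  inner <- rowSums(P * D)
  array(P * (D - inner), dim = d)
}

# elementwise tree arithmetic over nested parameter lists
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map(f, a[[nm]])
    out
  } else f(a)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
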