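#' Focal Tversky loss configuration
#'
#' Hyperparameters of the Tversky index and focal Tversky loss (FTL), and
#' the weight of the binary breast-outline term in the combined dual-task
#' loss. Defaults are alpha = 0.7, beta = 0.3, gamma = 3/4; epsilon guards
#' against division by zero when a class is absent.
#'
#' @param alpha Weight of false negatives in the Tversky denominator.
#' @param beta Weight of false positives.
#' @param gamma Focal exponent applied to (1 - TI) per class.
#' @param epsilon Numerical stability constant.
#' @param lambda_outline Weight of the binary air/tissue FTL term in
#'   [combined_loss()]; 0 recovers the tissue-only loss.
#' @param loss1_classes Class indices summed by the multi-class term
#'   (default all three channels: air, adipose, dense).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.7, beta = 0.3, gamma = 0.75,
                        epsilon = 1e-6, lambda_outline = 1,
                        loss1_classes = 1:3) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (gamma <= 0) stop("gamma must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (lambda_outline < 0) stop("lambda_outline must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon, lambda_outline = lambda_outline,
                 loss1_classes = loss1_classes),
            class = "loss_config")
}

check_prob_maps <- function(p, g) {
  if (!identical(dim(p), dim(g)))
    stop("probability and target maps must have identical shape")
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
}

# channel c of a (..., C) array as a plain vector
chan <- function(a, c) {
  nc <- dim(a)[length(dim(a))]
  n <- length(a) / nc
  a[((c - 1) * n + 1):(c * n)]
}

#' Tversky index of one class
#'
#' `TI_c = (sum p_c g_c + eps) / (sum p_c g_c + alpha sum (1-p_c) g_c +
#' beta sum p_c (1-g_c) + eps)`: a soft overlap measure whose alpha and
#' beta weights trade false negatives against false positives. With
#' alpha = beta = 0.5 it reduces to the soft Dice coefficient.
#'
#' @param p Probability array with a trailing class dimension; per-voxel
#'   class probabilities in \[0, 1\].
#' @param g One-hot target array of the same shape.
#' @param class Class index (1-based along the trailing dimension).
#' @param cfg A [loss_config()].
#' @return The index, a scalar in \[0, 1\].
#' @export
tversky_index <- function(p, g, class, cfg = loss_config()) {
  check_prob_maps(p, g)
  pc <- chan(p, class)
  gc <- chan(g, class)
  tp <- sum(pc * gc)
  fn <- sum((1 - pc) * gc)
  fp <- sum(pc * (1 - gc))
  (tp + cfg$epsilon) /
    (tp + cfg$alpha * fn + cfg$beta * fp + cfg$epsilon)
}

#' Focal Tversky loss over a set of classes
#'
#' `FTL = sum_c (1 - TI_c)^gamma`. The focal exponent gamma < 1 boosts the
#' gradient contribution of classes with poor overlap, countering class
#' imbalance.
#'
#' @inheritParams tversky_index
#' @param classes Non-empty vector of class indices to sum over.
#' @return A non-negative scalar.
#' @export
focal_tversky_loss <- function(p, g, classes, cfg = loss_config()) {
  if (length(classes) == 0) stop("classes must be non-empty")
  sum(vapply(classes, function(cl)
    (1 - tversky_index(p, g, cl, cfg))^cfg$gamma, numeric(1)))
}

#' Merge three-class maps into binary air/tissue maps
#'
#' Tissue = adipose plus dense; the air channel is unchanged. Probabilities
#' merge additively, one-hot targets by union.
#'
#' @param g Three-class array (air, adipose, dense along the trailing
#'   dimension); probabilities or one-hot targets.
#' @return A two-channel array (air, tissue) of the same spatial shape.
#' @export
to_outline_targets <- function(g) {
  d <- dim(g)
  nc <- d[length(d)]
  if (nc != 3L) stop("expected a three-class map")
  n <- length(g) / nc
  out <- c(chan(g, 1), chan(g, 2) + chan(g, 3))
  dim(out) <- c(d[-length(d)], 2L)
  out
}

#' Combined dual-task focal Tversky loss
#'
#' The multi-class tissue FTL (air/adipose/dense) plus `lambda_outline`
#' times the binary breast-outline FTL computed on the merged air/tissue
#' maps. With `lambda_outline = 0` this is the tissue loss alone.
#'
#' @inheritParams tversky_index
#' @return A non-negative scalar.
#' @export
combined_loss <- function(p, g, cfg = loss_config()) {
  check_prob_maps(p, g)
  l1 <- focal_tversky_loss(p, g, cfg$loss1_classes, cfg)
  if (cfg$lambda_outline == 0) return(l1)
  l2 <- focal_tversky_loss(to_outline_targets(p), to_outline_targets(g),
                           1:2, cfg)
  l1 + cfg$lambda_outline * l2
}

# Gradient of the combined loss with respect to the class probabilities,
# returned as an array shaped like p. Used by the network trainer.
combined_loss_grad <- function(p, g, cfg = loss_config()) {
  d <- dim(p)
  nc <- d[length(d)]
  n <- length(p) / nc
  grad <- numeric(length(p))

  add_ftl_grad <- function(pm, gm, classes, weight, nch) {
    # gradient of sum_c (1 - TI_c)^gamma wrt pm, accumulated per channel
    gout <- numeric(length(pm))
    for (cl in classes) {
      pc <- chan(pm, cl); gc <- chan(gm, cl)
      tp <- sum(pc * gc)
      fn <- sum((1 - pc) * gc)
      fp <- sum(pc * (1 - gc))
      num <- tp + cfg$epsilon
      den <- tp + cfg$alpha * fn + cfg$beta * fp + cfg$epsilon
      ti <- num / den
      one_m <- max(1 - ti, 1e-8)  # keeps the focal power finite at TI -> 1
      dL_dTI <- -cfg$gamma * one_m^(cfg$gamma - 1)
      # d num / d p_i = g_i ; d den / d p_i = g_i - alpha g_i + beta (1-g_i)
      dden <- gc * (1 - cfg$alpha) + cfg$beta * (1 - gc)
      dTI <- (gc * den - num * dden) / den^2
      nvox <- length(pc)
      rng <- ((cl - 1) * nvox + 1):(cl * nvox)
      gout[rng] <- gout[rng] + weight * dL_dTI * dTI
    }
    gout
  }

  grad <- grad + add_ftl_grad(p, g, cfg$loss1_classes, 1, nc)
  if (cfg$lambda_outline > 0) {
    p2 <- to_outline_targets(p)
    g2 <- to_outline_targets(g)
    g2grad <- add_ftl_grad(p2, g2, 1:2, cfg$lambda_outline, 2L)
    # chain rule through the channel merge: air passes through, the tissue
    # gradient feeds both adipose and dense
    g_air <- g2grad[1:n]
    g_tis <- g2grad[(n + 1):(2 * n)]
    grad[1:n] <- grad[1:n] + g_air
    grad[(n + 1):(2 * n)] <- grad[(n + 1):(2 * n)] + g_tis
    grad[(2 * n + 1):(3 * n)] <- grad[(2 * n + 1):(3 * n)] + g_tis
  }
  dim(grad) <- d
  grad
}

#' One-hot encode a label volume
#'
#' @param v A [label_volume()] (or raw integer array with values 0..2).
#' @param n_classes Number of classes (default 3).
#' @return A numeric array `(nx, ny, nz, n_classes)` of 0/1 indicators.
#' @export
one_hot <- function(v, n_classes = 3L) {
  labels <- if (inherits(v, "label_volume")) v$labels else v
  d <- dim(labels)
  out <- array(0, dim = c(d, n_classes))
  for (cl in seq_len(n_classes))
    out[, , , cl] <- as.numeric(labels == cl - 1L)
  out
}
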