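#' Compact 3D U-Net configuration
#'
#' A fixed small encoder-decoder (3x3x3 convolutions, max-pooling, nearest
#' upsampling, skip connections, softmax head) standing in for a
#' self-configuring full-resolution network: the quantities under study here
#' are the loss and the acquisition geometry, not the architecture.
#'
#' @param depth Number of resolution levels (`depth - 1` poolings).
#' @param base_channels Channels at the finest level (doubling per level).
#' @param patch_size Optional cubic patch edge for tiled inference; `NULL`
#'   processes whole volumes. Must be divisible by `2^(depth-1)`.
#' @param n_classes Output classes (fixed at 3: air, adipose, dense).
#' @param in_channels Input channels (1: the reconstruction).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 3L, base_channels = 16L, patch_size = NULL,
                        n_classes = 3L, in_channels = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  if (base_channels < 1) stop("base_channels must be >= 1")
  if (!is.null(patch_size) && patch_size %% 2L^(depth - 1L) != 0L)
    stop("patch_size must be divisible by 2^(depth-1)")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 patch_size = patch_size, n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "unet_config")
}

#' Training protocol configuration
#'
#' Adam with learning rate 0.01, batch size 2, and model checkpoints every
#' five epochs; the checkpoint with the best validation Dice is retained.
#'
#' @param learning_rate Adam step size (default 0.01).
#' @param batch_size Samples per gradient step (default 2).
#' @param max_epochs Number of training epochs.
#' @param checkpoint_every Checkpoint cadence in epochs (default 5).
#' @param val_fraction Fraction of phantoms held out for validation.
#' @param seed RNG seed for initialization, splitting, and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 2L,
                         max_epochs = 30L, checkpoint_every = 5L,
                         val_fraction = 0.2, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 checkpoint_every = as.integer(checkpoint_every),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

normalize_recon <- function(values) {
  mu <- mean(values)
  sd <- stats::sd(values)
  if (sd == 0) sd <- 1
  (values - mu) / sd
}

sample_tensors <- function(s) {
  x <- normalize_recon(s$recon$values)
  dim(x) <- c(dim(x), 1L)
  list(x = x, y = one_hot(s$mask), id = s$id)
}

# Dice of hard (argmax) labels against a one-hot target, per class.
hard_dice <- function(pred_labels, truth_labels, n_classes = 3L) {
  vapply(seq_len(n_classes) - 1L, function(cl) {
    tp <- sum(pred_labels == cl & truth_labels == cl)
    fp <- sum(pred_labels == cl & truth_labels != cl)
    fn <- sum(pred_labels != cl & truth_labels == cl)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

eval_sample_loss <- function(params, cfg, ten, loss_cfg) {
  fw <- unet_forward(params, ten$x, cfg, keep_cache = FALSE)
  probs <- softmax_channels(fw$logits)
  orig <- dim(ten$y)[1:3]
  probs <- probs[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), ,
                 drop = FALSE]
  loss <- combined_loss(probs, ten$y, loss_cfg)
  lab <- apply_argmax(probs)
  truth <- apply_argmax(ten$y)
  list(loss = loss, dice = hard_dice(lab, truth, cfg$n_classes))
}

apply_argmax <- function(p) {
  d <- dim(p)
  M <- matrix(p, ncol = d[length(d)])
  array(max.col(M, ties.method = "first") - 1L, dim = d[-length(d)])
}

#' Train the segmentation network
#'
#' Full-volume training with the combined focal Tversky loss: per epoch the
#' training samples are shuffled (seeded), gradients are accumulated over
#' `batch_size` samples and applied with Adam. Validation loss and hard
#' Dice per class are recorded every epoch; parameter snapshots are taken
#' every `checkpoint_every` epochs (plus the final epoch) and the snapshot
#' with the best mean validation Dice is returned as the model.
#'
#' @param samples List of at least two [vct_sample()] objects; the
#'   train/validation split is by phantom id.
#' @param loss_cfg A [loss_config()] (the model's loss variant).
#' @param unet_cfg A [unet_config()].
#' @param train_cfg A [train_config()].
#' @return An object of class `unet_model` with elements `params`,
#'   `unet_cfg`, `loss_cfg`, `history` (per-epoch data.frame),
#'   `checkpoints` (epochs at which snapshots were taken), `best_epoch`,
#'   and the id split.
#' @export
train_segmenter <- function(samples, loss_cfg = loss_config(),
                            unet_cfg = unet_config(),
                            train_cfg = train_config()) {
  if (length(samples) < 2) stop("need at least 2 samples to split")
  set.seed(train_cfg$seed)
  ids <- vapply(samples, function(s) s$id, character(1))
  uid <- unique(ids)
  n_val <- max(1L, round(train_cfg$val_fraction * length(uid)))
  val_ids <- sample(uid, n_val)
  tens <- lapply(samples, sample_tensors)
  train_set <- tens[!(ids %in% val_ids)]
  val_set <- tens[ids %in% val_ids]
  if (length(train_set) == 0) {  # degenerate tiny runs: train on everything
    train_set <- tens
  }

  params <- unet_init_params(unet_cfg, seed = train_cfg$seed)
  opt <- adam_init(params)
  hist <- vector("list", train_cfg$max_epochs)
  best <- list(dice = -Inf, params = params, epoch = 0L)
  checkpoints <- integer(0)

  for (epoch in seq_len(train_cfg$max_epochs)) {
    order <- sample(length(train_set))
    losses <- numeric(0)
    i <- 1L
    while (i <= length(order)) {
      batch <- order[i:min(i + train_cfg$batch_size - 1L, length(order))]
      gacc <- NULL
      for (j in batch) {
        ten <- train_set[[j]]
        fw <- unet_forward(params, ten$x, unet_cfg, keep_cache = TRUE)
        probs <- softmax_channels(fw$logits)
        orig <- dim(ten$y)[1:3]
        pd <- dim(probs)[1:3]
        # targets on the padded grid: padding is air
        ypad <- array(0, dim = c(pd, unet_cfg$n_classes))
        ypad[, , , 1] <- 1
        ypad[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), ] <-
          ten$y
        loss <- combined_loss(probs, ypad, loss_cfg)
        losses <- c(losses, loss)
        dp <- combined_loss_grad(probs, ypad, loss_cfg)
        dz <- softmax_bwd(probs, dp)
        g <- unet_backward(params, unet_cfg, fw$cache, dz)
        gacc <- if (is.null(gacc)) g else tree_map2(`+`, gacc, g)
      }
      gacc <- tree_map(function(x) x / length(batch), gacc)
      st <- adam_step(params, gacc, opt, train_cfg$learning_rate)
      params <- st$params
      opt <- st$state
      i <- i + train_cfg$batch_size
    }

    vs <- if (length(val_set) > 0) val_set else train_set
    ev <- lapply(vs, function(ten)
      eval_sample_loss(params, unet_cfg, ten, loss_cfg))
    val_loss <- mean(vapply(ev, `[[`, numeric(1), "loss"))
    vd <- rowMeans(vapply(ev, `[[`, numeric(3), "dice"), na.rm = TRUE)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = mean(losses),
                                val_loss = val_loss,
                                val_dice_air = vd[1],
                                val_dice_adipose = vd[2],
                                val_dice_dense = vd[3])
    is_ckpt <- epoch %% train_cfg$checkpoint_every == 0L ||
      epoch == train_cfg$max_epochs
    if (is_ckpt) {
      checkpoints <- c(checkpoints, epoch)
      mean_dice <- mean(vd, na.rm = TRUE)
      if (mean_dice > best$dice)
        best <- list(dice = mean_dice, params = params, epoch = epoch)
    }
  }

  structure(list(params = best$params, unet_cfg = unet_cfg,
                 loss_cfg = loss_cfg,
                 history = do.call(rbind, hist),
                 checkpoints = checkpoints, best_epoch = best$epoch,
                 val_ids = val_ids,
                 train_ids = setdiff(uid, val_ids)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "unet_model: depth %d, %d base channels; best checkpoint epoch %d\n",
    x$unet_cfg$depth, x$unet_cfg$base_channels, x$best_epoch))
  invisible(x)
}

#' Predict class probabilities for a reconstruction
#'
#' Normalizes the volume (per-volume z-score, as in training), runs the
#' network, and returns per-voxel class probabilities summing to one. If
#' the model's `patch_size` is set and smaller than the volume, inference
#' is tiled with half-patch overlap and the probabilities are averaged.
#'
#' @param model A trained `unet_model`.
#' @param recon A [recon_volume()].
#' @return A numeric array `(nx, ny, nz, n_classes)`.
#' @export
predict_segmenter <- function(model, recon) {
  stopifnot(inherits(model, "unet_model"), inherits(recon, "recon_volume"))
  cfg <- model$unet_cfg
  x <- normalize_recon(recon$values)
  d <- dim(x)
  ps <- cfg$patch_size
  run_block <- function(block) {
    dim(block) <- c(dim(block), 1L)
    fw <- unet_forward(model$params, block, cfg, keep_cache = FALSE)
    probs <- softmax_channels(fw$logits)
    ob <- dim(block)[1:3]
    probs[seq_len(ob[1]), seq_len(ob[2]), seq_len(ob[3]), , drop = FALSE]
  }
  if (is.null(ps) || all(d <= ps)) {
    p <- run_block(x)
  } else {
    acc <- array(0, dim = c(d, cfg$n_classes))
    cnt <- array(0, dim = d)
    starts <- function(n) {
      if (n <= ps) return(1L)
      s <- seq(1L, n - ps, by = max(ps %/% 2L, 1L))
      unique(c(s, n - ps + 1L))
    }
    for (sx in starts(d[1])) for (sy in starts(d[2])) for (sz in starts(d[3])) {
      ex <- min(sx + ps - 1L, d[1]); ey <- min(sy + ps - 1L, d[2])
      ez <- min(sz + ps - 1L, d[3])
      pb <- run_block(x[sx:ex, sy:ey, sz:ez, drop = FALSE])
      acc[sx:ex, sy:ey, sz:ez, ] <- acc[sx:ex, sy:ey, sz:ez, ] + pb
      cnt[sx:ex, sy:ey, sz:ez] <- cnt[sx:ex, sy:ey, sz:ez] + 1
    }
    p <- acc / array(rep(cnt, cfg$n_classes), dim = dim(acc))
  }
  p
}

#' Hard labels from class probabilities
#'
#' Per-voxel argmax with ties broken toward the lower class index
#' (air < adipose < dense).
#'
#' @param p Probability array `(nx, ny, nz, n_classes)`.
#' @param voxel_mm Voxel pitch for the returned volume (mm).
#' @return A [label_volume()].
#' @export
argmax_labels <- function(p, voxel_mm = 1) {
  label_volume(apply_argmax(p), voxel_mm)
}
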