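#' Signed distance of a slice to the central slice
#'
#' `d = (z - z_central) * voxel_mm`, with the central slice at index
#' `ceiling(n/2)`; negative values lie toward the breast support.
#'
#' @param z Slice index (1-based), possibly vectorized.
#' @param volume A `label_volume` or `recon_volume` (provides slice count
#'   and pitch).
#' @return Distance(s) in mm.
#' @export
slice_distance <- function(z, volume) {
  labels <- if (inherits(volume, "label_volume")) volume$labels
            else volume$values
  n <- dim(labels)[3]
  if (n < 1) stop("volume has no slices")
  (z - ceiling(n / 2)) * volume$voxel_mm
}

class_names <- c("air", "adipose", "dense")

#' One-vs-rest confusion counts for one slice
#'
#' @param pred,truth Congruent [label_volume()]s.
#' @param z Slice index.
#' @return A data.frame with one row per class: `class`, `z`, `d`, `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
confusion_per_slice <- function(pred, truth, z) {
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("pred and truth must be congruent")
  ps <- pred$labels[, , z]
  ts <- truth$labels[, , z]
  n <- length(ps)
  rows <- lapply(0:2, function(cl) {
    tp <- sum(ps == cl & ts == cl)
    fp <- sum(ps == cl & ts != cl)
    fn <- sum(ps != cl & ts == cl)
    data.frame(class = class_names[cl + 1], z = z,
               d = slice_distance(z, truth),
               TP = tp, FP = fp, FN = fn, TN = n - tp - fp - fn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap metrics from confusion counts
#'
#' Jaccard `TP/(TP+FP+FN)`, Dice `2TP/(2TP+FP+FN)`, precision, recall,
#' accuracy, and the Jaccard distance `1 - J` (the disjunct volume
#' normalized by the union). Slices with an empty union (`TP+FP+FN = 0`)
#' get `NA` ratio metrics and are flagged `undefined`.
#'
#' @param rec A data.frame with columns `TP`, `FP`, `FN`, `TN` (e.g. from
#'   [confusion_per_slice()]).
#' @return `rec` with metric columns appended.
#' @export
slice_metrics <- function(rec) {
  union <- rec$TP + rec$FP + rec$FN
  total <- union + rec$TN
  j <- ifelse(union > 0, rec$TP / union, NA_real_)
  rec$jaccard <- j
  rec$dice <- ifelse(union > 0, 2 * rec$TP / (union + rec$TP), NA_real_)
  rec$precision <- ifelse(rec$TP + rec$FP > 0,
                          rec$TP / (rec$TP + rec$FP), NA_real_)
  rec$recall <- ifelse(rec$TP + rec$FN > 0,
                       rec$TP / (rec$TP + rec$FN), NA_real_)
  rec$accuracy <- (rec$TP + rec$TN) / total
  rec$jaccard_distance <- 1 - j
  rec$undefined <- union == 0
  rec
}

#' Slice-wise evaluation of a predicted volume
#'
#' @param pred,truth Congruent [label_volume()]s.
#' @param phantom_id,model_id Identifiers carried into the records.
#' @return A data.frame of per-slice, per-class records with metrics.
#' @export
evaluate_volume <- function(pred, truth, phantom_id = "phantom",
                            model_id = "model") {
  nz <- dim(truth$labels)[3]
  recs <- do.call(rbind, lapply(seq_len(nz), function(z)
    confusion_per_slice(pred, truth, z)))
  recs <- slice_metrics(recs)
  recs$phantom <- phantom_id
  recs$model <- model_id
  recs
}

#' Bin slice records into equal-count distance categories
#'
#' Pools the signed distances of all distinct slices (across phantoms,
#' regardless of thickness) and splits them into `n_bins` equal-count bins
#' (deciles by default); every model's records of the same slice land in
#' the same bin. Bins are labeled by their mean distance.
#'
#' @param records Data.frame from [evaluate_volume()] (possibly several
#'   models/phantoms row-bound together).
#' @param n_bins Number of distance bins (default 10).
#' @return `records` with `bin` (integer, 1 = bottommost) and `bin_d`
#'   (mean distance of the bin, mm) columns.
#' @export
bin_by_distance <- function(records, n_bins = 10L) {
  key <- unique(records[, c("phantom", "z", "d")])
  if (nrow(key) < n_bins)
    stop(sprintf("need at least %d distinct slices to form %d bins",
                 n_bins, n_bins))
  key <- key[order(key$d, key$phantom, key$z), ]
  # equal-count split: bin sizes differ by at most one
  key$bin <- as.integer(ceiling(seq_len(nrow(key)) / nrow(key) * n_bins))
  bin_d <- tapply(key$d, key$bin, mean)
  key$bin_d <- as.numeric(bin_d[as.character(key$bin)])
  merge(records, key, by = c("phantom", "z", "d"), sort = FALSE)
}

#' Summarize binned records into a bin table
#'
#' Per (bin, model, class): slice count, mean and SD of each metric
#' (undefined slices excluded and counted in `n_undefined`), and the bin's
#' mean distance.
#'
#' @param records Output of [bin_by_distance()].
#' @param metrics Metric columns to aggregate.
#' @return A data.frame, one row per bin x model x class.
#' @export
summarize_bins <- function(records,
                           metrics = c("jaccard", "dice", "precision",
                                       "recall", "accuracy",
                                       "jaccard_distance")) {
  split_by <- interaction(records$bin, records$model, records$class,
                          drop = TRUE)
  rows <- lapply(split(records, split_by), function(gr) {
    ok <- !gr$undefined
    out <- data.frame(bin = gr$bin[1], bin_d = gr$bin_d[1],
                      model = gr$model[1], class = gr$class[1],
                      n_slices = nrow(gr), n_undefined = sum(!ok),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(gr[[m]][ok])
      out[[paste0(m, "_sd")]] <- stats::sd(gr[[m]][ok])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$class, out$model, out$bin), ]
}

#' Relative improvement of a dissimilarity
#'
#' `100 * (ref - new) / ref`: the percentage of the reference Jaccard
#' distance resolved by the new model.
#'
#' @param jd_ref Reference value (must be positive).
#' @param jd_new Comparison value.
#' @return Percent improvement (negative if `jd_new` is worse).
#' @export
improvement <- function(jd_ref, jd_new) {
  if (any(jd_ref <= 0)) stop("jd_ref must be positive")
  100 * (jd_ref - jd_new) / jd_ref
}

#' Non-parametric comparison of models
#'
#' Kruskal-Wallis omnibus test of a per-slice metric across models, plus
#' pairwise two-sided Wilcoxon-Mann-Whitney rank-sum tests (per distance
#' bin when `by_bin`). Raw p-values are reported; Holm adjustment is
#' available but off by default.
#'
#' @param records Binned records ([bin_by_distance()] output).
#' @param metric Metric column to compare.
#' @param class One-vs-rest class to restrict to.
#' @param by_bin Run pairwise tests within each distance bin.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A list with `omnibus` (Kruskal-Wallis `htest`) and `pairwise`
#'   (data.frame of model pairs and p-values).
#' @export
compare_models <- function(records, metric = "jaccard_distance",
                           class = "air", by_bin = TRUE,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  r <- records[records$class == class & !records$undefined, ]
  models <- unique(r$model)
  if (length(models) < 2) stop("need at least 2 models to compare")
  omnibus <- stats::kruskal.test(r[[metric]], factor(r$model))
  pairs <- utils::combn(models, 2, simplify = FALSE)
  bins <- if (by_bin && "bin" %in% names(r)) sort(unique(r$bin)) else NA
  rows <- list()
  for (b in bins) {
    rb <- if (is.na(b[1])) r else r[r$bin == b, ]
    for (pr in pairs) {
      x <- rb[[metric]][rb$model == pr[1]]
      y <- rb[[metric]][rb$model == pr[2]]
      if (length(x) < 2 || length(y) < 2)
        stop("each group needs at least 2 samples")
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, model_a = pr[1], model_b = pr[2], p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  pw <- do.call(rbind, rows)
  if (adjust == "holm") pw$p_adjusted <- stats::p.adjust(pw$p_value, "holm")
  list(omnibus = omnibus, pairwise = pw)
}

colormap_levels <- c(tn_air = "#2166AC", air_error = "#D7191C",
                     dense_error = "#FFD700", adipose = "#808080",
                     dense = "#FFFFFF")

#' Categorical accuracy colormap of one slice
#'
#' Blue = correctly predicted air (true negative background), red = air
#' errors in either direction (false positive or false negative
#' background), yellow = adipose/dense confusions (false positive or false
#' negative dense tissue), gray = correct adipose, white = correct dense.
#'
#' @param pred,truth Congruent [label_volume()]s.
#' @param z Slice index.
#' @return An integer matrix of category codes (1..5) with attributes
#'   `levels` (names) and `colors` (hex palette).
#' @export
accuracy_colormap <- function(pred, truth, z) {
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("pred and truth must be congruent")
  ps <- pred$labels[, , z]
  ts <- truth$labels[, , z]
  cat <- matrix(NA_integer_, nrow(ps), ncol(ps))
  cat[ts == 0L & ps == 0L] <- 1L                       # blue
  cat[(ts == 0L) != (ps == 0L)] <- 2L                  # red: air mismatch
  cat[ts != 0L & ps != 0L & ts != ps] <- 3L            # yellow: tissue swap
  cat[ts == 1L & ps == 1L] <- 4L                       # gray
  cat[ts == 2L & ps == 2L] <- 5L                       # white
  attr(cat, "levels") <- names(colormap_levels)
  attr(cat, "colors") <- unname(colormap_levels)
  cat
}

#' Write an accuracy colormap as PNG
#'
#' @param cmap Output of [accuracy_colormap()].
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
write_colormap_png <- function(cmap, path) {
  cols <- attr(cmap, "colors")
  rgb <- grDevices::col2rgb(cols[cmap]) / 255
  img <- array(0, dim = c(ncol(cmap), nrow(cmap), 3))
  for (k in 1:3) img[, , k] <- t(matrix(rgb[k, ], nrow(cmap), ncol(cmap)))
  png::writePNG(img, path)
  invisible(path)
}
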