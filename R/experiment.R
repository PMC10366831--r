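#' The four segmentation model variants
#'
#' Maps model ids to (acquisition geometry, loss) pairs: `I1` =
#' conventional geometry with the tissue loss only; `I1and2`, `II1and2`,
#' `III1and2` = conventional, T, and XWR geometry with the combined
#' tissue + outline loss.
#'
#' @return A data.frame with columns `model`, `geometry`, `lambda_outline`.
#' @export
model_specs <- function() {
  data.frame(model = c("I1", "I1and2", "II1and2", "III1and2"),
             geometry = c("conventional", "conventional", "T", "XWR"),
             lambda_outline = c(0, 1, 1, 1),
             stringsAsFactors = FALSE)
}

# deterministic per-stage seed fan-out from the master seed (kept < 2^31)
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629 + 1)
}

#' Experiment configuration for the scaled-down virtual clinical trial
#'
#' Bundles the population, geometry, reconstruction, dataset, loss, and
#' training settings of the end-to-end run. Defaults are desk-scale: real
#' anatomical dimensions on a coarse 2.5 mm grid, 10 phantoms, a depth-2
#' U-Net with 8 base channels, and short training. The full-scale
#' settings (550 phantoms, 0.1 mm phantoms, 0.085 mm reconstructions)
#' are expressible through the same fields but are cluster-scale.
#'
#' @param n_phantoms Number of phantoms in the cohort.
#' @param voxel_mm Phantom and reconstruction voxel pitch (mm).
#' @param grid_nx,grid_ny In-plane grid size (voxels); outlines are clamped
#'   to fit with an air margin.
#' @param detector A [detector_spec()].
#' @param sid_mm Source-to-support distance for the linear scans (mm).
#' @param downsample_factor Linear scale applied to samples before training.
#' @param materials A [material_table()].
#' @param unet_cfg,train_cfg Network and protocol configurations.
#' @param population Optional [population_spec()] override (its
#'   `n_phantoms`, `voxel_mm` and `seed` fields are taken from here).
#' @param out_dir Output directory of the run.
#' @param master_seed Master seed fanned out to per-stage seeds.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_phantoms = 10L, voxel_mm = 3,
                              grid_nx = 70L, grid_ny = 50L,
                              detector = detector_spec(),
                              sid_mm = 620,
                              downsample_factor = 0.5,
                              materials = material_table(),
                              unet_cfg = unet_config(depth = 2L,
                                                     base_channels = 6L),
                              train_cfg = train_config(max_epochs = 40L),
                              population = NULL,
                              out_dir = tempfile("vct_run_"),
                              master_seed = 1L) {
  if (is.null(population))
    population <- population_spec(n_phantoms = n_phantoms,
                                  voxel_mm = voxel_mm,
                                  seed = stage_seed(master_seed, "population"))
  structure(list(population = population, voxel_mm = voxel_mm,
                 grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 detector = detector, sid_mm = sid_mm,
                 downsample_factor = downsample_factor,
                 materials = materials,
                 unet_cfg = unet_cfg, train_cfg = train_cfg,
                 out_dir = out_dir, master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

build_geometries <- function(cfg) {
  list(conventional = make_conventional(sid_mm = cfg$sid_mm,
                                        detector = cfg$detector),
       T = make_t(sid_mm = cfg$sid_mm, detector = cfg$detector),
       XWR = make_xwr(detector = cfg$detector))
}

# clamp sampled outline parameters so the outline fits the fixed grid
clamp_population <- function(pop, cfg) {
  max_w <- cfg$grid_nx * cfg$voxel_mm - 2 * max(pop$bulge_mm) -
    4 * cfg$voxel_mm
  max_cnd <- cfg$grid_ny * cfg$voxel_mm - max(pop$bulge_mm) -
    2 * cfg$voxel_mm
  pop$width_mm <- pmin(pop$width_mm, max_w)
  pop$cnd_mm <- pmin(pop$cnd_mm, max_cnd)
  # the network needs >= 8 slices after downsampling
  k <- max(1L, as.integer(round(1 / cfg$downsample_factor)))
  pop$cbt_mm <- pmax(pop$cbt_mm, 8 * k * cfg$voxel_mm)
  pop
}

run_stage_phantoms <- function(cfg) {
  dir <- file.path(cfg$out_dir, "phantoms")
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    if (all(file.exists(file.path(dir, paste0(manifest$id, ".nii.gz")))))
      return(manifest)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- clamp_population(sample_population(cfg$population), cfg)
  pop$achieved_vbd <- NA_real_
  for (i in seq_len(nrow(pop))) {
    lv <- generate_phantom(pop[i, ], cfg$voxel_mm,
                           nx = cfg$grid_nx, ny = cfg$grid_ny)
    pop$achieved_vbd[i] <- measure_vbd(lv)
    write_label_volume(lv, file.path(dir, paste0(pop$id[i], ".nii.gz")))
  }
  utils::write.csv(pop, manifest_path, row.names = FALSE)
  pop
}

run_stage_recons <- function(cfg, manifest, geometries) {
  dir <- file.path(cfg$out_dir, "recons")
  for (gname in names(geometries)) {
    gdir <- file.path(dir, gname)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    for (id in manifest$id) {
      out <- file.path(gdir, paste0(id, ".nii.gz"))
      if (file.exists(out)) next
      lv <- read_label_volume(file.path(cfg$out_dir, "phantoms",
                                        paste0(id, ".nii.gz")))
      p <- forward_project(lv, geometries[[gname]], cfg$materials)
      rec <- backproject(p, geometries[[gname]], dim(lv$labels),
                         cfg$voxel_mm)
      write_recon_volume(rec, out)
    }
  }
  invisible(dir)
}

load_samples <- function(cfg, manifest, gname) {
  lapply(manifest$id, function(id) {
    lv <- read_label_volume(file.path(cfg$out_dir, "phantoms",
                                      paste0(id, ".nii.gz")))
    rec <- read_recon_volume(file.path(cfg$out_dir, "recons", gname,
                                       paste0(id, ".nii.gz")))
    s <- vct_sample(rec, lv, id, gname)
    downsample_sample(s, cfg$downsample_factor)
  })
}

run_stage_models <- function(cfg, manifest) {
  dir <- file.path(cfg$out_dir, "models")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- model_specs()
  models <- list()
  for (i in seq_len(nrow(specs))) {
    mid <- specs$model[i]
    path <- file.path(dir, paste0(mid, ".rds"))
    if (file.exists(path)) {
      models[[mid]] <- readRDS(path)
      next
    }
    samples <- load_samples(cfg, manifest, specs$geometry[i])
    lcfg <- loss_config(lambda_outline = specs$lambda_outline[i])
    tcfg <- cfg$train_cfg
    tcfg$seed <- stage_seed(cfg$master_seed, "train")
    model <- train_segmenter(samples, lcfg, cfg$unet_cfg, tcfg)
    saveRDS(model, path)
    utils::write.csv(model$history,
                     file.path(dir, paste0(mid, "_history.csv")),
                     row.names = FALSE)
    models[[mid]] <- model
  }
  models
}

run_stage_eval <- function(cfg, manifest, models) {
  dir <- file.path(cfg$out_dir, "eval")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- model_specs()
  # score the whole cohort: at desk scale the validation split is only a
  # handful of slices, and all four models are compared on identical
  # phantoms (labels are never seen at inference)
  eval_ids <- manifest$id
  records <- list()
  for (i in seq_len(nrow(specs))) {
    mid <- specs$model[i]
    samples <- load_samples(cfg, manifest[manifest$id %in% eval_ids, ],
                            specs$geometry[i])
    for (s in samples) {
      probs <- predict_segmenter(models[[mid]], s$recon)
      pred <- argmax_labels(probs, s$mask$voxel_mm)
      records[[length(records) + 1]] <-
        evaluate_volume(pred, s$mask, s$id, mid)
    }
  }
  records <- do.call(rbind, records)
  records <- bin_by_distance(records, n_bins = 10L)
  utils::write.csv(records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  records
}

#' Run the end-to-end scaled-down virtual clinical trial
#'
#' Population sampling, phantom generation, simulation and reconstruction
#' under the three geometries, training of the four models, slice-wise
#' evaluation binned by distance, model comparisons, and summary tables.
#' Each stage writes its outputs under `cfg$out_dir` and is skipped on
#' re-run if they already exist, so a partially deleted run resumes at the
#' missing stage.
#'
#' @param cfg An [experiment_config()].
#' @return A report list: `manifest`, `models`, `records` (binned slice
#'   records), `bin_table`, `comparisons`, `tables` (file paths), and
#'   `seeds` (per-stage seed manifest).
#' @export
run_vct <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  geometries <- build_geometries(cfg)
  manifest <- run_stage_phantoms(cfg)
  run_stage_recons(cfg, manifest, geometries)
  models <- run_stage_models(cfg, manifest)
  records <- run_stage_eval(cfg, manifest, models)
  bin_table <- summarize_bins(records)
  comparisons <- list(
    air_jd = compare_models(records, "jaccard_distance", "air",
                            by_bin = FALSE),
    adipose_j = compare_models(records, "jaccard", "adipose",
                               by_bin = FALSE),
    dense_j = compare_models(records, "jaccard", "dense", by_bin = FALSE))
  seeds <- data.frame(stage = c("master", "population", "train"),
                      seed = c(cfg$master_seed,
                               cfg$population$seed,
                               stage_seed(cfg$master_seed, "train")))
  report <- list(manifest = manifest, models = models, records = records,
                 bin_table = bin_table, comparisons = comparisons,
                 seeds = seeds, cfg = cfg)
  report$tables <- make_tables(report, file.path(cfg$out_dir, "tables"))
  utils::write.csv(seeds, file.path(cfg$out_dir, "seeds.csv"),
                   row.names = FALSE)
  report
}

reshape_bin_metric <- function(bin_table, class, metric) {
  bt <- bin_table[bin_table$class == class, ]
  out <- unique(bt[, c("bin", "bin_d")])
  for (m in unique(bt$model)) {
    sub <- bt[bt$model == m, ]
    out[[paste0(m, "_mean")]] <- sub[[paste0(metric, "_mean")]][
      match(out$bin, sub$bin)]
    out[[paste0(m, "_sd")]] <- sub[[paste0(metric, "_sd")]][
      match(out$bin, sub$bin)]
  }
  out[order(out$bin), ]
}

#' Write the three summary tables of a run
#'
#' `table3.csv`: air Jaccard distance by distance bin and model, with the
#' pairwise improvement columns computed from the unrounded bin means.
#' `table4.csv`: adipose and dense Jaccard by bin and model.
#' `table5.csv`: Dice, precision, recall, and accuracy per model and
#' tissue, averaged over slices.
#'
#' @param report A [run_vct()] report.
#' @param dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
make_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bt <- report$bin_table
  t3 <- reshape_bin_metric(bt, "air", "jaccard_distance")
  imp <- function(ref, new) ifelse(ref > 0, 100 * (ref - new) / ref,
                                   NA_real_)
  t3$imp_I1and2_over_I1 <- imp(t3$I1_mean, t3$I1and2_mean)
  t3$imp_II1and2_over_I1 <- imp(t3$I1_mean, t3$II1and2_mean)
  t3$imp_III1and2_over_I1 <- imp(t3$I1_mean, t3$III1and2_mean)
  t3$imp_II1and2_over_I1and2 <- imp(t3$I1and2_mean, t3$II1and2_mean)
  t3$imp_II1and2_over_III1and2 <- imp(t3$III1and2_mean, t3$II1and2_mean)

  t4 <- merge(reshape_bin_metric(bt, "adipose", "jaccard"),
              reshape_bin_metric(bt, "dense", "jaccard"),
              by = c("bin", "bin_d"), suffixes = c("_adipose", "_dense"))

  recs <- report$records
  rows <- list()
  for (cl in c("adipose", "dense")) for (m in unique(recs$model)) {
    r <- recs[recs$class == cl & recs$model == m & !recs$undefined, ]
    for (met in c("dice", "precision", "recall", "accuracy")) {
      rows[[length(rows) + 1]] <- data.frame(
        tissue = cl, model = m, metric = met,
        mean = mean(r[[met]], na.rm = TRUE),
        sd = stats::sd(r[[met]]), stringsAsFactors = FALSE)
    }
  }
  t5 <- do.call(rbind, rows)

  paths <- c(table3 = file.path(dir, "table3.csv"),
             table4 = file.path(dir, "table4.csv"),
             table5 = file.path(dir, "table5.csv"))
  utils::write.csv(t3, paths["table3"], row.names = FALSE)
  utils::write.csv(t4, paths["table4"], row.names = FALSE)
  utils::write.csv(t5, paths["table5"], row.names = FALSE)
  invisible(paths)
}
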