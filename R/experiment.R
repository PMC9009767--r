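pipeline_defaults <- function(config = list()) {
  base <- experiment_config(
    n_instances = 10L,
    levels = c(1.25, 2, 3, 6, 20, 40),
    n_train = 400L, n_val = 128L, n_test = 384L,
    n_pretrain_per_category = 80L,
    n_categories = 8L,
    style = style_params(),
    epochs = 30L, lr = 0.02, head_epochs = 60L,
    use_bn = FALSE,
    activation = activation_spec("rectifier"),
    gain_grid = gain_grid(41, c(0.5, 2))
  )
  cfg <- utils::modifyList(base, config)
  class(cfg) <- "experiment_config"
  cfg
}

#' Train the shared backbone and per-difficulty heads
#'
#' End-to-end training stage used by the experiment recipes: generates the
#' category pretraining set and the difficulty suite, pretrains the backbone
#' (at neutral gain), and fine-tunes `n_instances` heads per difficulty
#' level on the frozen backbone.
#'
#' @param config list of settings merged over the pipeline defaults (see
#'   [experiment_config()]; notable keys: `levels`, `n_train`, `n_val`,
#'   `n_test`, `n_instances`, `epochs`, `seed`, `style`).
#' @param verbose print progress.
#' @return list with `backbone`, `suite` (datasets by level), `heads` (by
#'   level), `pretrain` (history and validation accuracy), and `config`.
#' @export
train_difficulty_pipeline <- function(config = list(), verbose = FALSE) {
  cfg <- pipeline_defaults(config)
  cat_ds <- generate_category_dataset(cfg$n_categories,
                                      cfg$n_pretrain_per_category,
                                      seed = derive_seed(cfg$seed, 41L),
                                      style = cfg$style)
  n_cat <- n_images(cat_ds)
  n_val_cat <- max(2L * cfg$n_categories, round(n_cat * 0.15))
  cat_split <- split_dataset(cat_ds, n_cat - n_val_cat, n_val_cat, 0L,
                             seed = derive_seed(cfg$seed, 42L))
  if (verbose) message("pretraining backbone...")
  pre <- pretrain_backbone(cat_split$train, cat_split$val, cfg,
                           verbose = verbose)
  suite <- build_difficulty_suite(cfg$levels, cfg$n_train, cfg$n_val,
                                  cfg$n_test, seed = derive_seed(cfg$seed, 43L),
                                  style = cfg$style)
  heads <- list()
  for (lv in names(suite)) {
    if (verbose) message(sprintf("fine-tuning heads for level %s...", lv))
    heads[[lv]] <- finetune_head(pre$model, suite[[lv]], cfg,
                                 condition = as.numeric(lv))
  }
  list(backbone = pre$model, suite = suite, heads = heads,
       pretrain = pre[c("history", "val_accuracy")], config = cfg)
}

file_checksum <- function(path) {
  rlang::hash(readBin(path, "raw", file.info(path)$size))
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

write_manifest <- function(out_dir, recipe, cfg, files, extra = list()) {
  cfg_s <- strip_classes(unclass(cfg))
  cfg_s$pipeline <- NULL
  manifest <- c(list(recipe = recipe,
                     package_version = as.character(utils::packageVersion("gainsweep")),
                     config = unclass(cfg_s),
                     checksums = lapply(stats::setNames(files, basename(files)),
                                        file_checksum)),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Run a named experiment recipe
#'
#' Orchestrates a complete analysis and writes tidy long-format CSV tables
#' plus a JSON run manifest (config snapshot, seeds, package version,
#' per-file checksums) to `out_dir`. Deterministic given the config seed:
#' re-running a recipe reproduces identical CSV checksums.
#'
#' Recipes:
#' * `"yerkes_dodson"`: performance-gain profiles and peak gains per
#'   difficulty level (`profiles.csv`, `peaks.csv`).
#' * `"answer_options"`: AUC-gain profiles across answer-option set sizes
#'   (`profiles.csv`, `peaks.csv`).
#' * `"decoding"`: block-wise probe accuracies and mean activations
#'   (`records.csv`, `activations.csv`, `block_peaks.csv`).
#' * `"scrambling"`: importance-curve calibration and progressive disruption
#'   (`calibration.csv`, `profiles.csv`, `peaks.csv`).
#'
#' @param recipe recipe name.
#' @param config settings merged over the defaults (see
#'   [train_difficulty_pipeline()]); `config$pipeline` may carry a
#'   pre-trained pipeline to reuse.
#' @param out_dir output directory.
#' @param verbose print progress.
#' @return list of result tables (invisibly also written to `out_dir`).
#' @export
run_experiment <- function(recipe = c("yerkes_dodson", "answer_options",
                                      "decoding", "scrambling"),
                           config = list(), out_dir = tempfile("gainsweep_"),
                           verbose = FALSE) {
  recipe <- match.arg(recipe)
  cfg <- pipeline_defaults(config)
  validate_grid(cfg$gain_grid)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pipe <- config$pipeline
  if (recipe != "answer_options" && is.null(pipe)) {
    pipe <- train_difficulty_pipeline(cfg, verbose = verbose)
  }
  res <- switch(recipe,
    yerkes_dodson = {
      profs <- list(); pks <- list()
      for (lv in names(pipe$suite)) {
        prof <- sweep_gain(pipe$backbone, pipe$heads[[lv]],
                           pipe$suite[[lv]]$test, cfg$gain_grid)
        peak <- find_peak(profile_metric(prof, "accuracy"))
        profs[[lv]] <- prof
        pks[[lv]] <- data.frame(condition = as.numeric(lv),
                                median_peak = peak$median,
                                ci_lower = peak$ci$lower %||% NA_real_,
                                ci_upper = peak$ci$upper %||% NA_real_)
      }
      list(profiles = do.call(rbind, profs), peaks = do.call(rbind, pks))
    },
    answer_options = {
      answer_options_recipe(cfg, verbose)
    },
    decoding = {
      lv_test <- lapply(pipe$suite, `[[`, "test")
      pr <- probe_blocks(pipe$backbone, lv_test, cfg$gain_grid,
                         n_train = cfg$probe_n_train %||% 200L,
                         n_test = cfg$probe_n_test %||% 200L,
                         n_iter = cfg$probe_n_iter %||% 5L,
                         seed = derive_seed(cfg$seed, 61L))
      pk <- decoding_peak_gain(pr$records)
      list(records = pr$records, activations = pr$activations,
           block_peaks = pk$per_block,
           excluded_levels = data.frame(level = pk$excluded_levels))
    },
    scrambling = {
      lv <- names(pipe$suite)[1]
      head1 <- pipe$heads[[lv]][[1]]
      test <- pipe$suite[[lv]]$test
      cal <- calibrate_all_blocks(pipe$backbone, head1, test,
                                  p_grid = cfg$p_grid %||% seq(0, 1, 0.25),
                                  n_rep = cfg$scramble_reps %||% 3L,
                                  seed = derive_seed(cfg$seed, 71L))
      sw <- progressive_scramble_sweep(pipe$backbone, head1, test,
                                       "late_to_early", cal$rates,
                                       cfg$gain_grid,
                                       stages = cfg$stages %||% NULL,
                                       n_rep = cfg$scramble_reps %||% 3L,
                                       seed = derive_seed(cfg$seed, 72L))
      list(calibration = data.frame(block = as.integer(names(cal$rates)),
                                    p_star = unname(cal$rates)),
           curves = cal$curves, profiles = sw$profiles, peaks = sw$peaks)
    })
  files <- character(0)
  for (nm in names(res)) {
    if (is.data.frame(res[[nm]])) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(res[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  write_manifest(out_dir, recipe, cfg, files)
  invisible(res)
}

# Answer-option recipe: one multi-label head per resampled category subset,
# trained at neutral gain, AUC swept across the grid.
answer_options_recipe <- function(cfg, verbose = FALSE) {
  cat_ds <- generate_category_dataset(cfg$n_categories,
                                      cfg$n_option_per_category %||% 60L,
                                      seed = derive_seed(cfg$seed, 41L),
                                      style = cfg$style)
  n <- n_images(cat_ds)
  spl <- split_dataset(cat_ds, round(0.6 * n), 0L, n - round(0.6 * n) - 0L,
                       seed = derive_seed(cfg$seed, 45L))
  cat_cfg <- cfg
  cat_cfg$n_instances <- 1L
  n_tr <- n_images(spl$train)
  n_v <- max(cfg$n_categories, round(0.15 * n_tr))
  pre_val <- split_dataset(spl$train, n_tr - n_v, n_v, 0L,
                           seed = derive_seed(cfg$seed, 46L))
  pre <- pretrain_backbone(pre_val$train, pre_val$val, cat_cfg,
                           verbose = verbose)
  subsets <- subsample_answer_options(seq_len(cfg$n_categories),
                                      sizes = cfg$option_sizes %||% c(2, 4, 8),
                                      n_iterations = cfg$n_option_iterations %||% 20L,
                                      seed = derive_seed(cfg$seed, 47L))
  feats_tr <- pooled_features(pre$model, spl$train$images)
  profs <- list(); pks <- list(); ri <- 1L
  for (sz in names(subsets)) {
    for (it in seq_along(subsets[[sz]])) {
      subset <- subsets[[sz]][[it]]
      tr_sel <- spl$train$labels %in% subset
      te_sel <- spl$test$labels %in% subset
      remap <- match(spl$train$labels[tr_sel], subset)
      fit <- train_head_sgd(feats_tr[, tr_sel, drop = FALSE],
                            one_hot(remap, length(subset)),
                            seed = derive_seed(cfg$seed, 800L + ri),
                            epochs = cfg$head_epochs, lr = cfg$head_lr,
                            batch_size = cfg$batch_size)
      head_it <- new_task_head(fit$w, fit$b, paste0("size", sz),
                               ri, nrow(feats_tr))
      te_labels <- match(spl$test$labels[te_sel], subset)
      te_ds <- new_dataset(spl$test$images[, , , te_sel, drop = FALSE],
                           te_labels, split = "test")
      prof <- sweep_gain(pre$model, list(head_it), te_ds, cfg$gain_grid,
                         condition = as.numeric(sz))
      prof$instance <- it
      profs[[ri]] <- prof
      ri <- ri + 1L
    }
  }
  profiles <- do.call(rbind, profs)
  for (sz in unique(profiles$condition)) {
    sl <- profiles[profiles$condition == sz & profiles$metric == "auc", ]
    peak <- find_peak(sl[, c("instance", "delta", "value")])
    pks[[as.character(sz)]] <- data.frame(condition = sz,
                                          median_peak = peak$median,
                                          ci_lower = peak$ci$lower %||% NA_real_,
                                          ci_upper = peak$ci$upper %||% NA_real_)
  }
  list(profiles = profiles, peaks = do.call(rbind, pks))
}
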