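#' Write a dataset as PNG images plus a CSV manifest
#'
#' @param ds a `gain_dataset`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(ds, dir, prefix = "img") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_images(ds)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_len(n)))
  for (i in seq_len(n)) png::writePNG(ds$images[, , , i], paths[i])
  manifest <- data.frame(path = basename(paths), label = ds$labels,
                         split = ds$split,
                         level = ds$level %||% NA_real_,
                         seed = ds$provenance$seed %||% NA_integer_)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing PNGs and `manifest.csv`.
#' @return a `gain_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  imgs <- lapply(file.path(dir, manifest$path), png::readPNG)
  d <- dim(imgs[[1]])
  arr <- array(unlist(imgs), dim = c(d, length(imgs)))
  new_dataset(arr, manifest$label, split = manifest$split[1],
              level = manifest$level[1],
              provenance = list(seed = manifest$seed[1]))
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the complete weight and normalization state plus the
#' gain state and metadata (including the gain at which the model was
#' trained, always 1 in the standard pipeline).
#'
#' @param model a `gain_backbone` or `gain_mlp`.
#' @param path file path.
#' @return `save_checkpoint` returns the weight hash invisibly;
#'   `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(model_weight_hash(model))
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; unknown keys are
#' stored verbatim.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}
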