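# The trained pipeline used by the end-to-end replication tests. Training is
# expensive, so it runs once per session and is shared across test blocks.
acceptance_cache <- new.env(parent = emptyenv())

acceptance_pipeline <- function() {
  if (is.null(acceptance_cache$pipe)) {
    acceptance_cache$pipe <- train_difficulty_pipeline(
      list(levels = c(1.25, 20), n_instances = 5L, seed = 1L))
  }
  acceptance_cache$pipe
}

# Deterministic subset of a dataset (used to keep perturbation experiments
# within a sensible runtime).
dataset_head <- function(ds, n) {
  gainsweep:::new_dataset(ds$images[, , , seq_len(n), drop = FALSE],
                          ds$labels[seq_len(n)], split = ds$split,
                          level = ds$level, provenance = ds$provenance)
}
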