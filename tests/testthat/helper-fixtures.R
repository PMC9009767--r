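# Small fixtures shared across tests. Everything is generated in code.

tiny_style <- function() style_params(img_size = c(16, 16))

tiny_backbone <- function(use_bn = FALSE, kind = "rectifier", seed = 3L,
                          widths = c(4, 6), downsample = c(FALSE, TRUE),
                          n_classes = 2) {
  build_backbone(input_shape = c(16, 16, 3), widths = widths,
                 downsample = downsample, n_classes = n_classes,
                 activation = activation_spec(kind), use_bn = use_bn,
                 seed = seed)
}

random_batch <- function(n = 4, hw = 16, seed = 9L) {
  withr::with_seed(seed, array(runif(hw * hw * 3 * n), dim = c(hw, hw, 3, n)))
}

# A binary dataset whose classes differ in a simple, learnable way (bright
# left half vs bright right half), for head/probe tests.
lateral_dataset <- function(n = 64, hw = 16, seed = 5L) {
  withr::with_seed(seed, {
    images <- array(runif(hw * hw * 3 * n, 0, 0.3), dim = c(hw, hw, 3, n))
    labels <- rep(0:1, length.out = n)
    half <- seq_len(hw / 2)
    for (i in seq_len(n)) {
      cols <- if (labels[i] == 1) half else hw / 2 + half
      images[, cols, , i] <- images[, cols, , i] + 0.5
    }
    gainsweep:::new_dataset(images, labels, split = "test")
  })
}

# Deterministic per-instance accuracy profile data frame for peak tests.
profile_df <- function(deltas, values, instance = 1) {
  data.frame(instance = instance, delta = deltas, value = values)
}
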