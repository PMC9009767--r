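test_that("perfectly separable features decode at accuracy 1", {
  withr::with_seed(1, {
    labels <- rep(0:1, 50)
    feats <- matrix(rep(labels, 5), ncol = 5)  # label copied across dims
    rec <- decode_block(feats, labels, n_train = 50, n_test = 50, n_iter = 3,
                        seed = 2)
    expect_equal(rec$accuracy, rep(1, 3))
    expect_equal(rec$n_train, rep(50, 3))
  })
})

test_that("shuffled labels decode at chance", {
  withr::with_seed(5, {
    feats <- matrix(rnorm(400 * 20), 400, 20)
    labels <- sample(rep(0:1, 200))
    rec <- decode_block(feats, labels, n_train = 150, n_test = 250,
                        n_iter = 5, seed = 3)
    se <- sqrt(0.25 / 250)
    expect_true(all(abs(rec$accuracy - 0.5) < 3 * se + 1e-9))
  })
})

test_that("well-separated Gaussian classes decode almost perfectly", {
  withr::with_seed(6, {
    n <- 300
    labels <- rep(0:1, n / 2)
    feats <- matrix(rnorm(n * 4), n, 4) + 5 * labels
    rec <- decode_block(feats, labels, n_train = 150, n_test = 150,
                        n_iter = 3, seed = 4)
    expect_gt(mean(rec$accuracy), 0.95)
  })
})

test_that("probe accuracy is invariant to an orthogonal feature map", {
  withr::with_seed(9, {
    n <- 200
    labels <- rep(0:1, n / 2)
    feats <- matrix(rnorm(n * 6), n, 6) + 1.5 * labels
    q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
    a <- decode_block(feats, labels, n_train = 100, n_test = 100,
                      n_iter = 3, seed = 5)
    b <- decode_block(feats %*% q, labels, n_train = 100, n_test = 100,
                      n_iter = 3, seed = 5)
    expect_equal(a$accuracy, b$accuracy, tolerance = 0.03)
  })
})

test_that("random projection preserves probe accuracy to first order", {
  withr::with_seed(12, {
    n <- 240
    labels <- rep(0:1, n / 2)
    wide <- matrix(rnorm(n * 600, sd = 1), n, 600)
    wide[, 1:40] <- wide[, 1:40] + 1.2 * labels
    full <- decode_block(wide, labels, n_train = 120, n_test = 120,
                         n_iter = 3, seed = 6, n_proj = 10000)
    proj <- decode_block(wide, labels, n_train = 120, n_test = 120,
                         n_iter = 3, seed = 6, n_proj = 128)
    expect_lt(abs(mean(full$accuracy) - mean(proj$accuracy)), 0.15)
  })
})

test_that("tap arrays are flattened image-wise for the probe", {
  taps <- array(seq_len(2 * 2 * 3 * 4), dim = c(2, 2, 3, 4))
  flat <- gainsweep:::flatten_taps(taps)
  expect_equal(dim(flat), c(4, 12))
  expect_equal(flat[2, ], as.numeric(taps[, , , 2]))
})

test_that("mean activation is a plain scalar mean with the expected scaling", {
  expect_equal(mean_activation(array(0, dim = c(2, 2, 2, 2))), 0)
  spec <- activation_spec("rectifier")
  S <- withr::with_seed(2, array(rnorm(64), dim = c(4, 4, 2, 2)))
  m1 <- mean_activation(gained_activation(S, spec, 1))
  m2 <- mean_activation(gained_activation(S, spec, 2))
  expect_equal(m2, 2 * m1)
  expect_gte(m1, 0)
})

test_that("most informative block reporting follows the first/last tie rule", {
  expect_equal(most_informative_block(c(0.80, 0.95, 0.95, 0.90)),
               list(first = 2, last = 3))
  expect_equal(most_informative_block(c(0.5, 0.6, 0.7, 0.9)),
               list(first = 4, last = 4))
  expect_equal(most_informative_block(rep(0.7, 5)),
               list(first = 1, last = 5))
})

fake_records <- function(acc_by, levels, deltas, blocks, n_iter = 2,
                         instances = 1) {
  g <- expand.grid(instance = instances, block = blocks, delta = deltas,
                   level = levels, iteration = seq_len(n_iter))
  g$accuracy <- mapply(acc_by, g$block, g$delta, g$level)
  g
}

test_that("decoding peaks use the tie-median rule and exclude ceiling levels", {
  deltas <- c(0.5, 1, 2, 4)
  rec <- fake_records(function(b, d, lv) {
    if (lv == 20) 1.0            # solved at ceiling everywhere
    else if (d %in% c(1, 2)) 0.9 # tie at 1 and 2
    else 0.6
  }, levels = c(1.25, 20), deltas = deltas, blocks = 1:3)
  pk <- decoding_peak_gain(rec)
  expect_equal(pk$excluded_levels, 20)
  expect_equal(pk$per_block$median_peak, rep(1.5, 3))  # median of {1, 2}
  rec_all <- fake_records(function(b, d, lv) 1.0, levels = 20,
                          deltas = deltas, blocks = 1:2)
  expect_error(decoding_peak_gain(rec_all), "ceiling")
})

test_that("peak aggregation averages per-difficulty peaks within a block", {
  deltas <- c(0.5, 1, 2)
  rec <- fake_records(function(b, d, lv) {
    peak_at <- if (lv == 1.25) 1 else 2
    ifelse(d == peak_at, 0.9, 0.6)
  }, levels = c(1.25, 3), deltas = deltas, blocks = 1)
  pk <- decoding_peak_gain(rec)
  expect_equal(pk$per_block$median_peak, 1.5)  # mean of peaks 1 and 2
})

test_that("informative-block summaries are ordered and aggregated across instances", {
  deltas <- 1
  rec <- rbind(
    fake_records(function(b, d, lv) c(0.7, 0.9, 0.9)[b], levels = 1.25,
                 deltas = deltas, blocks = 1:3, instances = 1),
    fake_records(function(b, d, lv) c(0.9, 0.8, 0.7)[b], levels = 1.25,
                 deltas = deltas, blocks = 1:3, instances = 2))
  s <- informative_block_summary(rec, delta = 1, level = 1.25)
  expect_true(all(s$per_instance$first <= s$per_instance$last))
  expect_equal(s$first$median, 1.5)  # instances peak first at blocks 2 and 1
  expect_equal(s$last$median, 2)    # last-tied blocks 3 and 1
})
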