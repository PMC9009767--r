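test_that("scrambling preserves identity at p = 0 and value multisets at p = 1", {
  x <- random_batch(n = 3, hw = 8)
  expect_identical(scramble_block(x, 0, seed = 1), x)
  y <- scramble_block(x, 1, seed = 1)
  for (n in 1:3) for (ch in 1:3) {
    expect_identical(sort(as.numeric(y[, , ch, n])),
                     sort(as.numeric(x[, , ch, n])))
    expect_equal(mean(y[, , ch, n]), mean(x[, , ch, n]))
    expect_equal(var(as.numeric(y[, , ch, n])), var(as.numeric(x[, , ch, n])))
  }
})

test_that("a constant feature map is unchanged by scrambling", {
  x <- array(0.37, dim = c(4, 4, 2, 2))
  expect_equal(scramble_block(x, 1, seed = 2), x)
})

test_that("untouched maps are bit-identical and touched maps follow ceiling(p*C)", {
  withr::with_seed(31, {
    for (i in 1:20) {
      d <- c(sample(2:6, 2), sample(3:8, 1), sample(1:3, 1))
      x <- array(rnorm(prod(d)), dim = d)
      p <- runif(1)
      y <- scramble_block(x, p, seed = i)
      changed <- vapply(seq_len(d[3]), function(ch) {
        !identical(y[, , ch, , drop = FALSE], x[, , ch, , drop = FALSE])
      }, logical(1))
      expect_lte(sum(changed), ceiling(p * d[3]))
      for (ch in seq_len(d[3])) {
        for (n in seq_len(d[4])) {
          expect_identical(sort(as.numeric(y[, , ch, n])),
                           sort(as.numeric(x[, , ch, n])))
        }
      }
    }
  })
})

test_that("scramble plans validate and apply only to their target blocks", {
  expect_error(scramble_plan(1, p = 1.5), "\\[0, 1\\]")
  expect_error(scramble_plan(c(2, 3), p = c(0, 0.5, 1)), "length")
  plan <- scramble_plan(c(2, 3), p = c(0.5, 1), seed = 4)
  x <- random_batch(n = 2, hw = 4)
  expect_identical(gainsweep:::plan_apply(plan, x, 1), x)
  expect_false(identical(gainsweep:::plan_apply(plan, x, 3), x))
})

test_that("rate calibration solves the linear and step retention curves", {
  p <- seq(0, 1, by = 0.1)
  lin <- data.frame(p = p, mean_accuracy = 1 - p)
  expect_equal(calibrate_rate(lin, threshold = 0.2, chance = 0), 0.8)
  step <- data.frame(p = p, mean_accuracy = ifelse(p <= 0.4, 1, 0.1))
  # linear interpolation of retention between the bracketing grid points
  expected <- 0.4 + (1 - 0.2) / (1 - 0.1) * 0.1
  expect_lt(abs(calibrate_rate(step, threshold = 0.2, chance = 0) - expected), 1e-6)
})

test_that("flat curves fall back to p* = 1 with a warning and degenerate blocks error", {
  p <- seq(0, 1, by = 0.25)
  flat <- data.frame(p = p, mean_accuracy = rep(0.9, 5))
  expect_warning(ps <- calibrate_rate(flat, chance = 0.5), "never reaches")
  expect_equal(ps, 1)
  dead <- data.frame(p = p, mean_accuracy = rep(0.5, 5))
  expect_error(calibrate_rate(dead, chance = 0.5), "degenerate")
})

test_that("isotonic smoothing makes the calibration robust to non-monotone noise", {
  p <- seq(0, 1, by = 0.1)
  acc <- 1 - p
  acc[4] <- acc[3] + 0.05  # local bump
  sm <- gainsweep:::smooth_curve_decreasing(p, acc)
  expect_true(all(diff(sm) <= 1e-12))
  expect_true(is.finite(calibrate_rate(data.frame(p = p, mean_accuracy = acc),
                                       chance = 0)))
})

test_that("spatial scrambling destroys spatially coded information", {
  # every map carries the label only in its spatial arrangement: identical
  # value multisets per image, high values on the left for class 1
  withr::with_seed(8, {
    n <- 120; hw <- 4
    taps <- array(0, dim = c(hw, hw, 1, n))
    labels <- rep(0:1, n / 2)
    base <- seq(0, 1, length.out = hw * hw)
    for (i in seq_len(n)) {
      v <- base + rnorm(hw * hw, sd = 0.01)
      v <- if (labels[i] == 1) sort(v, decreasing = TRUE) else sort(v)
      taps[, , 1, i] <- matrix(v, hw, hw)
    }
    clean <- decode_block(taps, labels, n_train = 60, n_test = 60,
                          n_iter = 3, seed = 1)
    expect_gt(mean(clean$accuracy), 0.95)
    scr <- decode_block(scramble_block(taps, 1, seed = 2), labels,
                        n_train = 60, n_test = 60, n_iter = 3, seed = 1)
    expect_lt(mean(scr$accuracy), 0.7)
  })
})

test_that("importance curves anchor exactly at the unperturbed baseline", {
  m <- tiny_backbone()
  ds <- lateral_dataset(n = 32)
  feats <- pooled_features(m, ds$images)
  head <- gainsweep:::new_task_head(matrix(rnorm(6), 6, 1), 0, "toy", 1L, 6)
  curve <- importance_curve(m, head, ds, block = 1,
                            p_grid = c(0, 0.5, 1), n_rep = 2, seed = 3)
  sc <- gainsweep:::head_scores(head, feats)
  base_acc <- mean((sc[1, ] > 0) == (ds$labels == 1))
  expect_identical(curve$mean_accuracy[curve$p == 0], base_acc)
  expect_identical(curve$sd[curve$p == 0], 0)
  expect_error(importance_curve(m, head, ds, 1, p_grid = c(0, 0.5)), "include 0 and 1")
})

test_that("progressive scrambling covers complementary block sets in the two directions", {
  B <- 8
  late <- gainsweep:::stage_blocks("late_to_early", B - 1, B)
  early <- gainsweep:::stage_blocks("early_to_late", B - 1, B)
  expect_equal(length(late), length(early))
  expect_equal(sort(union(late, early)), 1:B)
  expect_equal(intersect(setdiff(1:B, late), early), setdiff(1:B, late))
})

test_that("progressive scrambling at stage zero equals the unperturbed sweep", {
  m <- tiny_backbone()
  ds <- lateral_dataset(n = 24)
  head <- gainsweep:::new_task_head(matrix(rnorm(6), 6, 1), 0, "toy", 1L, 6)
  grid <- c(0.5, 1, 2)
  base <- sweep_gain(m, list(head), ds, grid)
  sw <- progressive_scramble_sweep(m, head, ds, "late_to_early",
                                   rates = stats::setNames(rep(0, 2), 1:2),
                                   grid = grid, stages = 1L, n_rep = 1,
                                   seed = 2)
  # a rate of zero is a no-op: profiles must match the plain sweep exactly
  acc <- profile_metric(base, "accuracy")
  expect_equal(sw$profiles$accuracy, acc$value[order(acc$delta)])
})
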