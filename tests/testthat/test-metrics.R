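test_that("sensitivity and bias match the normal-quantile oracle", {
  res <- sdt_measures(45, 5, 10, 40)
  # oracle: direct quantile transform of the rates 0.9 and 0.2
  expect_equal(res$dprime, qnorm(0.9) - qnorm(0.2), tolerance = 1e-12)
  expect_equal(res$criterion, -0.5 * (qnorm(0.9) + qnorm(0.2)), tolerance = 1e-12)
  expect_lt(abs(res$dprime - 2.1232), 1e-4)
  expect_lt(abs(res$criterion - (-0.2200)), 1e-4)
})

test_that("d-prime is zero at equal rates and criterion zero at symmetric rates", {
  expect_equal(sdt_measures(30, 10, 30, 10)$dprime, 0)
  expect_equal(sdt_measures(25, 25, 25, 25)$criterion, 0)
})

test_that("d-prime is antisymmetric under class swap", {
  withr::with_seed(1, {
    for (i in 1:20) {
      h <- sample(0:40, 1); m <- sample(0:40, 1)
      f <- sample(0:40, 1); c <- sample(0:40, 1)
      if (h + m == 0 || f + c == 0) next
      a <- sdt_measures(h, m, f, c)
      b <- sdt_measures(f, c, h, m)
      expect_equal(a$dprime, -b$dprime)
    }
  })
})

test_that("extreme rates are corrected by the 1/(2N) rule", {
  res <- sdt_measures(50, 0, 0, 50)
  expect_true(is.finite(res$dprime))
  expect_equal(res$dprime, qnorm(1 - 1 / 100) - qnorm(1 / 100))
  expect_error(sdt_measures(0, 0, 5, 5), "signal and noise")
  expect_error(sdt_measures(-1, 2, 3, 4), "non-negative")
})

test_that("AUC handles the forced cases", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_score(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals exhaustive pair counting and is rank-invariant", {
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(4:20, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
      a <- auc_score(s, y)
      expect_identical(a, brute(s, y))
      expect_identical(auc_score(exp(3 * s), y), a)  # monotone transform
    }
  })
})

test_that("AUC agrees with an established ROC implementation", {
  withr::with_seed(11, {
    y <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
    y[1:2] <- 0:1
    s <- rnorm(60) + y
    expect_equal(auc_score(s, y), as.numeric(pROC::auc(y, s, quiet = TRUE)))
  })
})

test_that("multi-class AUC is the unweighted mean of one-vs-rest AUCs", {
  withr::with_seed(3, {
    n <- 30
    y <- sample(1:3, n, replace = TRUE)
    y[1:3] <- 1:3
    sc <- matrix(rnorm(n * 3), n, 3)
    sc[cbind(seq_len(n), y)] <- sc[cbind(seq_len(n), y)] + 1.5
    expected <- mean(sapply(1:3, function(k) auc_score(sc[, k], y == k)))
    expect_equal(auc_score(sc, y), expected)
  })
})

test_that("t-interval across instances behaves at the boundaries", {
  ci <- summarize_ci(rep(0.7, 5))
  expect_equal(c(ci$mean, ci$lower, ci$upper), c(0.7, 0.7, 0.7))
  ci2 <- summarize_ci(c(0, 1))
  expect_equal(ci2$mean, 0.5)
  expect_equal(ci2$upper - ci2$mean, ci2$mean - ci2$lower)
  expect_error(summarize_ci(1), "at least 2")
})

test_that("t-interval has close to nominal coverage", {
  withr::with_seed(123, {
    n_rep <- 10000
    covered <- 0L
    for (i in seq_len(n_rep)) {
      ci <- summarize_ci(rnorm(10))
      if (ci$lower <= 0 && ci$upper >= 0) covered <- covered + 1L
    }
    expect_gt(covered / n_rep, 0.94)
    expect_lt(covered / n_rep, 0.96)
  })
})

test_that("peak extraction applies the tie-median rule", {
  pk <- find_peak(profile_df(c(0.5, 1, 1.5, 2), c(0.6, 0.9, 0.9, 0.7)))
  expect_equal(pk$per_instance$peak_delta, 1.25)
  pk2 <- find_peak(profile_df(c(0.5, 1, 2), c(0.2, 0.9, 0.4)))
  expect_equal(pk2$per_instance$peak_delta, 1)
})

test_that("peak location is invariant to shifting the whole profile", {
  withr::with_seed(21, {
    for (i in 1:1000) {
      d <- sort(runif(8, 0.1, 8))
      v <- round(runif(8), 2)
      p1 <- gainsweep:::peak_of_curve(d, v)
      p2 <- gainsweep:::peak_of_curve(d, v + runif(1, -5, 5))
      expect_identical(p1, p2)
    }
  })
})

test_that("criterion peaks use the minimal absolute bias", {
  pk <- find_peak(profile_df(c(0.5, 1, 2), c(-0.6, 0.1, 0.9)), minimize_abs = TRUE)
  expect_equal(pk$per_instance$peak_delta, 1)
  empty <- data.frame(instance = integer(0), delta = numeric(0),
                      value = numeric(0))
  expect_error(find_peak(empty), "empty")
})

test_that("peaks are summarized across instances with median and t-CI", {
  prof <- rbind(profile_df(c(0.5, 1, 2), c(0.1, 0.9, 0.2), instance = 1),
                profile_df(c(0.5, 1, 2), c(0.1, 0.2, 0.9), instance = 2),
                profile_df(c(0.5, 1, 2), c(0.9, 0.2, 0.1), instance = 3))
  pk <- find_peak(prof)
  expect_equal(sort(pk$per_instance$peak_delta), c(0.5, 1, 2))
  expect_equal(pk$median, 1)
  expect_equal(pk$ci$mean, mean(c(0.5, 1, 2)))
})
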