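#' Signal detection measures from trial counts
#'
#' Computes sensitivity and response bias from a 2x2 table of binary
#' decisions: `d' = z(hit rate) - z(false-alarm rate)` and
#' `criterion = -0.5 * (z(hit rate) + z(false-alarm rate))`, where `z` is the
#' standard normal quantile. Extreme rates of exactly 0 or 1 are corrected to
#' `1/(2N)` and `1 - 1/(2N)` (N = trials of that class) before the quantile
#' transform so both measures stay finite.
#'
#' @param hits,misses counts on signal trials (`hits + misses > 0`).
#' @param fa,cr false alarms and correct rejections on noise trials
#'   (`fa + cr > 0`).
#' @return list with elements `dprime` and `criterion`.
#' @export
#' @examples
#' sdt_measures(45, 5, 10, 40)  # d' ~ 2.123, criterion ~ -0.220
sdt_measures <- function(hits, misses, fa, cr) {
  counts <- c(hits, misses, fa, cr)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n_sig <- hits + misses
  n_noise <- fa + cr
  if (n_sig == 0 || n_noise == 0) {
    stop("both signal and noise trials are required", call. = FALSE)
  }
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  zh <- qnorm(clamp(hits / n_sig, n_sig))
  zf <- qnorm(clamp(fa / n_noise, n_noise))
  list(dprime = zh - zf, criterion = -0.5 * (zh + zf))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted as one half (the
#' Mann-Whitney identity). For more than two classes, the unweighted mean of
#' the one-vs-rest AUCs.
#'
#' @param scores numeric vector (binary: higher means more positive) or an
#'   `N x K` matrix of per-class scores (multi-class).
#' @param labels for a vector of scores, a logical/0-1 vector marking
#'   positives; for a score matrix, integer labels `1..K`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (is.matrix(scores)) {
    k <- ncol(scores)
    if (length(unique(labels)) < 2) {
      stop("need at least two classes present", call. = FALSE)
    }
    present <- sort(unique(labels))
    return(mean(vapply(present, function(cl) {
      auc_score(scores[, cl], labels == cl)
    }, numeric(1))))
  }
  pos <- as.logical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)          # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Student-t 95% confidence interval across model instances
#'
#' @param values numeric vector of per-instance values (length >= 2).
#' @param level confidence level.
#' @return list with `mean`, `lower`, `upper`.
#' @export
summarize_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half)
}

# Median of the gain values attaining the best metric value, with a small
# tolerance so that exact ties in empirical accuracies are recognized.
peak_of_curve <- function(deltas, values, minimize_abs = FALSE, tol = 1e-9) {
  if (length(values) == 0) stop("empty profile", call. = FALSE)
  crit <- if (minimize_abs) -abs(values) else values
  best <- max(crit)
  median(deltas[crit >= best - tol])
}

#' Extract the gain state of peak performance
#'
#' For every model instance, finds the set of gain values achieving the best
#' metric value (maximum; for the bias/criterion metric, minimal absolute
#' value, i.e. "bias closest to zero") and summarizes ties by their median.
#' Across instances, reports the median peak and a 95% t-interval.
#'
#' @param profile a data frame with columns `instance`, `delta`, `value`
#'   (e.g. one metric slice of a [sweep()] result).
#' @param minimize_abs use the minimal-`|value|` rule (for criterion).
#' @return object of class `peak_estimate`: list with `per_instance` (data
#'   frame `instance`, `peak_delta`), `median`, and `ci` (or `NULL` for a
#'   single instance).
#' @export
find_peak <- function(profile, minimize_abs = FALSE) {
  stopifnot(all(c("instance", "delta", "value") %in% names(profile)))
  if (nrow(profile) == 0) stop("empty profile", call. = FALSE)
  inst <- split(profile, profile$instance)
  peaks <- vapply(inst, function(df) {
    peak_of_curve(df$delta, df$value, minimize_abs)
  }, numeric(1))
  per_instance <- data.frame(instance = names(inst), peak_delta = unname(peaks),
                             stringsAsFactors = FALSE)
  structure(list(per_instance = per_instance,
                 median = median(peaks),
                 ci = if (length(peaks) >= 2) summarize_ci(peaks) else NULL),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak_estimate> median peak delta = %.4g (n = %d instances)\n",
              x$median, nrow(x$per_instance)))
  if (!is.null(x$ci)) {
    cat(sprintf("  mean %.4g, 95%% CI [%.4g, %.4g]\n",
                x$ci$mean, x$ci$lower, x$ci$upper))
  }
  invisible(x)
}
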