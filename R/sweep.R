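#' Geometric grid of global gain values
#'
#' Gain acts multiplicatively, so the grid is geometrically spaced between
#' `range[1]` and `range[2]`; the neutral state 1 is always included (it is
#' inserted if the spacing misses it).
#'
#' @param n number of geometrically spaced points.
#' @param range lower and upper gain bounds (both > 0).
#' @return strictly increasing numeric vector containing 1.
#' @export
gain_grid <- function(n = 60, range = c(0.125, 8)) {
  stopifnot(length(range) == 2, all(range > 0), range[1] < range[2], n >= 2)
  g <- exp(seq(log(range[1]), log(range[2]), length.out = n))
  g[1] <- range[1]
  g[n] <- range[2]
  sort(unique(c(g, if (range[1] <= 1 && range[2] >= 1) 1)))
}

validate_grid <- function(grid) {
  if (!is.numeric(grid) || any(diff(grid) <= 0) || !any(grid == 1)) {
    stop("gain grid must be strictly increasing and contain the neutral state 1",
         call. = FALSE)
  }
  grid
}

binary_metrics_rows <- function(scores, labels) {
  pred <- scores > 0
  hits <- sum(pred & labels == 1)
  misses <- sum(!pred & labels == 1)
  fa <- sum(pred & labels == 0)
  cr <- sum(!pred & labels == 0)
  sdt <- sdt_measures(hits, misses, fa, cr)
  data.frame(metric = c("accuracy", "hit_rate", "fa_rate", "dprime", "criterion"),
             value = c((hits + cr) / length(labels),
                       hits / (hits + misses), fa / (fa + cr),
                       sdt$dprime, sdt$criterion))
}

#' Sweep task performance across global gain states
#'
#' Evaluates a set of fine-tuned instances (heads sharing one frozen
#' backbone) on a held-out dataset at every gain value of the grid. For
#' binary tasks the result contains accuracy, hit/false-alarm rates, d' and
#' criterion; for categorical tasks accuracy and mean one-vs-rest AUC.
#'
#' @param backbone a `gain_backbone`.
#' @param heads list of `task_head`s (the model instances).
#' @param dataset held-out `gain_dataset`.
#' @param grid gain values (must include 1), see [gain_grid()].
#' @param plan optional [scramble_plan()] applied during every forward pass.
#' @param condition condition identifier stored in the output.
#' @return a `performance_profile` data frame with columns `condition`,
#'   `instance`, `delta`, `metric`, `value`.
#' @export
sweep_gain <- function(backbone, heads, dataset, grid = gain_grid(),
                       plan = NULL, condition = dataset$level) {
  validate_grid(grid)
  binary <- all(dataset$labels %in% c(0L, 1L))
  rows <- vector("list", length(grid) * length(heads))
  ri <- 1L
  for (d in grid) {
    m_d <- set_global_gain(backbone, d)
    feats <- pooled_features(m_d, dataset$images, plan = plan)
    for (i in seq_along(heads)) {
      sc <- head_scores(heads[[i]], feats)
      part <- if (binary) {
        binary_metrics_rows(sc[1, ], dataset$labels)
      } else {
        data.frame(metric = c("accuracy", "auc"),
                   value = c(mean(apply(sc, 2, which.max) == dataset$labels),
                             auc_score(t(sc), dataset$labels)))
      }
      part$condition <- if (is.null(condition)) NA else condition
      part$instance <- i
      part$delta <- d
      rows[[ri]] <- part
      ri <- ri + 1L
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("condition", "instance", "delta", "metric", "value")]
  class(out) <- c("performance_profile", "data.frame")
  out
}

#' Slice one metric out of a performance profile
#'
#' @param profile a `performance_profile` from [sweep_gain()].
#' @param metric metric name (e.g. `"accuracy"`).
#' @return data frame with columns `instance`, `delta`, `value` suitable for
#'   [find_peak()].
#' @export
profile_metric <- function(profile, metric = "accuracy") {
  out <- profile[profile$metric == metric,
                 c("condition", "instance", "delta", "value")]
  if (nrow(out) == 0) stop(sprintf("metric '%s' not present", metric), call. = FALSE)
  rownames(out) <- NULL
  out
}
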