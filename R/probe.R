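flatten_taps <- function(taps) {
  if (is.matrix(taps)) return(taps)
  d <- dim(taps)
  m <- taps
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  t(m)
}

#' Linear decoding probe on block activations
#'
#' Quantifies the linearly decodable task information in a block's
#' activations with an L2-regularized logistic regression at a fixed default
#' strength. Runs `n_iter` iterations, each on a freshly drawn disjoint
#' train/test pair, and records the held-out accuracy. High-dimensional
#' features are first reduced with a seeded Gaussian random projection
#' (which preserves probe accuracy to first order).
#'
#' @param taps block activations: `H x W x C x N` array or `N x p` matrix.
#' @param labels binary labels (0/1) of the N inputs.
#' @param n_train,n_test images per draw (`n_train + n_test <= N`).
#' @param n_iter number of random train/test draws.
#' @param seed integer seed.
#' @param n_proj maximum feature dimension before the probe.
#' @param lambda ridge penalty of the logistic probe.
#' @return data frame with columns `iteration`, `accuracy`, `n_train`,
#'   `n_test`.
#' @export
decode_block <- function(taps, labels, n_train = 1000L, n_test = 1000L,
                         n_iter = 5L, seed = 1L, n_proj = 1024L,
                         lambda = 0.01) {
  x <- flatten_taps(taps)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (n_train + n_test > n) {
    stop("n_train + n_test exceeds the number of available images", call. = FALSE)
  }
  y <- as.integer(labels != 0)
  if (ncol(x) > n_proj) {
    proj <- local_seed(derive_seed(seed, 31L), {
      matrix(rnorm(ncol(x) * n_proj, sd = 1 / sqrt(n_proj)), ncol(x), n_proj)
    })
    x <- x %*% proj
  }
  acc <- numeric(n_iter)
  local_seed(derive_seed(seed, 32L), {
    for (it in seq_len(n_iter)) {
      repeat {
        ord <- sample.int(n, n_train + n_test)
        tr <- ord[seq_len(n_train)]
        te <- ord[n_train + seq_len(n_test)]
        if (min(table(factor(y[tr], levels = 0:1))) >= 2 &&
            min(table(factor(y[te], levels = 0:1))) >= 1) break
        message("degenerate single-class draw; redrawing")
      }
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 0, lambda = c(10, 1, 10 * lambda, lambda),
                            standardize = FALSE, maxit = 1000L)
      if (min(fit$lambda) > lambda * 1.001) {
        # warm-started path stopped early; fit the target penalty directly
        fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                              family = "binomial", alpha = 0,
                              lambda = lambda, standardize = FALSE,
                              maxit = 1000L)
      }
      nl <- length(fit$lambda)
      sc <- fit$a0[[nl]] + x[te, , drop = FALSE] %*% fit$beta[, nl]
      acc[it] <- mean(as.integer(sc > 0) == y[te])
    }
  })
  data.frame(iteration = seq_len(n_iter), accuracy = acc,
             n_train = n_train, n_test = n_test)
}

#' Mean activation of a block tap
#'
#' Scalar mean over images, channels and space; with rectifier or saturating
#' activations this is non-negative and scales with the gain state.
#'
#' @param taps activation array (any shape).
#' @return scalar mean.
#' @export
mean_activation <- function(taps) mean(taps)

#' Run decoding probes across blocks, gain states, and difficulty levels
#'
#' For every combination of gain value and difficulty level, computes the
#' block taps of a held-out dataset and fits decoding probes per block,
#' recording mean activations along the way.
#'
#' @param backbone a `gain_backbone`.
#' @param datasets named list (by difficulty level) of binary
#'   `gain_dataset`s.
#' @param grid gain values (must include 1).
#' @param n_train,n_test,n_iter,n_proj probe settings, see [decode_block()].
#' @param seed integer seed.
#' @param instance instance index recorded in the output.
#' @return list with `records` (data frame `instance`, `block`, `delta`,
#'   `level`, `iteration`, `accuracy`) and `activations` (data frame
#'   `instance`, `block`, `delta`, `level`, `mean_activation`).
#' @export
probe_blocks <- function(backbone, datasets, grid = gain_grid(),
                         n_train = 1000L, n_test = 1000L, n_iter = 5L,
                         n_proj = 1024L, seed = 1L, instance = 1L) {
  validate_grid(grid)
  rec <- list(); act <- list(); ri <- 1L
  for (lv in names(datasets)) {
    ds <- datasets[[lv]]
    for (d in grid) {
      m_d <- set_global_gain(backbone, d)
      tp <- forward_with_taps(m_d, ds$images)$taps
      for (b in seq_along(tp)) {
        dec <- decode_block(tp[[b]], ds$labels, n_train, n_test, n_iter,
                            seed = derive_seed(seed, b * 1000L + round(d * 64)),
                            n_proj = n_proj)
        dec$instance <- instance; dec$block <- b
        dec$delta <- d; dec$level <- as.numeric(lv)
        rec[[ri]] <- dec
        act[[ri]] <- data.frame(instance = instance, block = b, delta = d,
                                level = as.numeric(lv),
                                mean_activation = mean_activation(tp[[b]]))
        ri <- ri + 1L
      }
    }
  }
  list(records = do.call(rbind, rec)[, c("instance", "block", "delta", "level",
                                         "iteration", "accuracy")],
       activations = do.call(rbind, act))
}

#' Gain state of peak decoding accuracy per block
#'
#' Averages probe accuracy over iterations, excludes near-ceiling difficulty
#' levels (mean accuracy above `ceiling` for every block and gain state,
#' where peak location is unreliable), extracts the tie-median peak gain per
#' (instance, block, level), and averages peaks across the remaining levels
#' to one estimate per block, summarized across instances.
#'
#' @param records probe records from [probe_blocks()].
#' @param ceiling accuracy threshold above which a level counts as solved at
#'   ceiling.
#' @return list with `per_block` (data frame `block`, `median_peak`,
#'   `ci_lower`, `ci_upper` — CI columns `NA` for a single instance) and
#'   `excluded_levels`.
#' @export
decoding_peak_gain <- function(records, ceiling = 0.99) {
  agg <- stats::aggregate(accuracy ~ instance + block + delta + level,
                          data = records, FUN = mean)
  lv_min <- tapply(agg$accuracy, agg$level, min)
  excluded <- as.numeric(names(lv_min))[lv_min > ceiling]
  keep <- !(agg$level %in% excluded)
  if (!any(keep)) stop("all difficulty levels are at ceiling", call. = FALSE)
  agg <- agg[keep, ]
  cells <- split(agg, list(agg$instance, agg$block, agg$level), drop = TRUE)
  peaks <- do.call(rbind, lapply(cells, function(df) {
    data.frame(instance = df$instance[1], block = df$block[1],
               level = df$level[1],
               peak = peak_of_curve(df$delta, df$accuracy))
  }))
  by_ib <- stats::aggregate(peak ~ instance + block, data = peaks, FUN = mean)
  per_block <- do.call(rbind, lapply(split(by_ib, by_ib$block), function(df) {
    ci <- if (nrow(df) >= 2) summarize_ci(df$peak) else NULL
    data.frame(block = df$block[1], median_peak = median(df$peak),
               ci_lower = ci$lower %||% NA_real_,
               ci_upper = ci$upper %||% NA_real_)
  }))
  rownames(per_block) <- NULL
  list(per_block = per_block, excluded_levels = excluded)
}

#' Most informative block for a condition
#'
#' Given one accuracy per block, returns the block(s) with maximal accuracy;
#' ties are reported as the first and last tied block index.
#'
#' @param accuracy_by_block numeric vector indexed by block.
#' @param tol tolerance for recognizing ties.
#' @return list with `first` and `last` block indices.
#' @export
most_informative_block <- function(accuracy_by_block, tol = 1e-9) {
  best <- max(accuracy_by_block)
  idx <- which(accuracy_by_block >= best - tol)
  list(first = min(idx), last = max(idx))
}

#' Summary of most informative blocks across instances
#'
#' @param records probe records from [probe_blocks()] restricted (or
#'   restrictable via `delta`/`level`) to one gain state and difficulty.
#' @param delta,level cell to summarize.
#' @return list with per-instance first/last blocks and their across-instance
#'   median and 95% CI (CIs `NULL` for a single instance).
#' @export
informative_block_summary <- function(records, delta, level) {
  sel <- records[records$delta == delta & records$level == level, ]
  if (nrow(sel) == 0) stop("no records for the requested cell", call. = FALSE)
  agg <- stats::aggregate(accuracy ~ instance + block, data = sel, FUN = mean)
  per_inst <- do.call(rbind, lapply(split(agg, agg$instance), function(df) {
    df <- df[order(df$block), ]
    mib <- most_informative_block(df$accuracy)
    data.frame(instance = df$instance[1], first = mib$first, last = mib$last)
  }))
  rownames(per_inst) <- NULL
  if (any(per_inst$first > per_inst$last)) stop("internal tie ordering error")
  list(per_instance = per_inst,
       first = list(median = median(per_inst$first),
                    ci = if (nrow(per_inst) >= 2) summarize_ci(per_inst$first)),
       last = list(median = median(per_inst$last),
                   ci = if (nrow(per_inst) >= 2) summarize_ci(per_inst$last)))
}
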