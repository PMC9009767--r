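#' Plan a spatial-scrambling perturbation
#'
#' Describes which residual branches are perturbed and how strongly: for
#' every targeted block, a proportion `p` of its residual-branch feature maps
#' has its spatial positions permuted (independently per map and per image).
#' Scrambling preserves the value distribution within each map but destroys
#' its spatial information; untouched maps are bit-identical.
#'
#' @param blocks integer indices of the blocks to scramble.
#' @param p scrambling proportion(s) in `[0, 1]`; one value (applied to all
#'   targeted blocks) or one per entry of `blocks`, in the same order.
#' @param seed permutation seed of this repetition.
#' @param direction bookkeeping tag: `"late_to_early"`, `"early_to_late"` or
#'   `"single_block"`.
#' @param stage number of blocks currently scrambled (bookkeeping).
#' @return an object of class `scramble_plan`.
#' @export
scramble_plan <- function(blocks, p, seed = 1L,
                          direction = c("single_block", "late_to_early",
                                        "early_to_late"),
                          stage = length(blocks)) {
  direction <- match.arg(direction)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  blocks <- as.integer(blocks)
  if (!length(p) %in% c(1L, length(blocks))) {
    stop("`p` must have length 1 or one entry per targeted block", call. = FALSE)
  }
  p_by_block <- stats::setNames(rep_len(unname(p), length(blocks)), blocks)
  structure(list(blocks = blocks, p = p_by_block, seed = as.integer(seed),
                 direction = direction, stage = stage),
            class = "scramble_plan")
}

# Apply a plan to the residual-branch output of block `b` (no-op when the
# block is not targeted).
plan_apply <- function(plan, r, b) {
  if (!(b %in% plan$blocks)) return(r)
  scramble_block(r, plan$p[[as.character(b)]],
                 seed = derive_seed(plan$seed, 7000L + b))
}

#' Spatially scramble a proportion of feature maps
#'
#' Selects a seeded random subset of `ceiling(p * C)` feature maps and
#' permutes the spatial positions within each selected map, independently per
#' map and per image. The multiset of values within every scrambled map (and
#' hence its mean and variance) is exactly preserved; unselected maps are
#' returned bit-identical.
#'
#' @param x activations, `H x W x C x N` array.
#' @param p proportion of feature maps to scramble, in `[0, 1]`.
#' @param seed integer seed for map choice and permutations.
#' @return array shaped like `x`.
#' @export
scramble_block <- function(x, p, seed = 1L) {
  stopifnot(length(dim(x)) == 4)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (p == 0) return(x)
  d <- dim(x)
  hw <- d[1] * d[2]
  n_maps <- ceiling(p * d[3])
  local_seed(seed, {
    chans <- sample.int(d[3], n_maps)
    for (ch in chans) {
      for (n in seq_len(d[4])) {
        v <- x[, , ch, n]
        x[, , ch, n] <- v[sample.int(hw)]
      }
    }
    x
  })
}

#' Importance curve of a block at neutral gain
#'
#' Measures mean test accuracy at `delta = 1` while scrambling an increasing
#' proportion of the block's residual-branch feature maps, over `n_rep`
#' repetitions that differ only in their permutation seed. The `p = 0` point
#' is the exact unperturbed baseline.
#'
#' @param backbone a `gain_backbone` (evaluated at neutral gain).
#' @param head a `task_head`.
#' @param dataset held-out binary `gain_dataset`.
#' @param block block index to perturb.
#' @param p_grid proportions to test; must include 0 and 1.
#' @param n_rep repetitions per proportion.
#' @param seed integer seed.
#' @return data frame with columns `block`, `p`, `mean_accuracy`, `sd`.
#' @export
importance_curve <- function(backbone, head, dataset, block,
                             p_grid = seq(0, 1, by = 0.1), n_rep = 10L,
                             seed = 1L) {
  if (!any(p_grid == 0) || !any(p_grid == 1)) {
    stop("`p_grid` must include 0 and 1", call. = FALSE)
  }
  backbone <- set_global_gain(backbone, 1)
  eval_acc <- function(plan) {
    feats <- pooled_features(backbone, dataset$images, plan = plan)
    sc <- head_scores(head, feats)
    mean((sc[1, ] > 0) == (dataset$labels == 1))
  }
  base_acc <- eval_acc(NULL)
  rows <- lapply(sort(p_grid), function(p) {
    if (p == 0) {
      return(data.frame(block = block, p = 0, mean_accuracy = base_acc, sd = 0))
    }
    accs <- vapply(seq_len(n_rep), function(rep) {
      plan <- scramble_plan(block, p, seed = derive_seed(seed, rep * 131L))
      eval_acc(plan)
    }, numeric(1))
    data.frame(block = block, p = p, mean_accuracy = mean(accs),
               sd = stats::sd(accs))
  })
  do.call(rbind, rows)
}

# Isotonic non-increasing fit of accuracy over p (pool-adjacent-violators).
smooth_curve_decreasing <- function(p, acc) {
  ord <- order(p)
  fit <- stats::isoreg(p[ord], -acc[ord])
  stats::setNames(-fit$yf, p[ord])
}

#' Calibrate the scrambling rate of a block
#'
#' Finds the proportion `p*` at which the block's contribution to
#' performance has dropped to `threshold` (default 20%) of its possible
#' contribution. The importance curve is first smoothed isotonically
#' (non-increasing), then the retention
#' `r(p) = (perf(p) - floor) / (perf(0) - floor)` with
#' `floor = min(perf(1), chance)` is interpolated linearly between grid
#' points and `p*` is the smallest `p` with `r(p) <= threshold`. If the
#' retention never reaches the threshold, `p* = 1` is returned with a
#' warning.
#'
#' @param curve data frame from [importance_curve()] (columns `p`,
#'   `mean_accuracy`).
#' @param threshold retained fraction of the block's contribution.
#' @param chance chance-level accuracy of the task (0.5 for the binary task).
#' @return `p*` in `(0, 1]`.
#' @export
calibrate_rate <- function(curve, threshold = 0.2, chance = 0.5) {
  p <- curve$p
  acc <- smooth_curve_decreasing(p, curve$mean_accuracy)
  p <- as.numeric(names(acc))
  floor_val <- min(acc[[length(acc)]], chance)
  if (acc[[1]] <= floor_val) {
    stop("degenerate block: baseline performance does not exceed the floor",
         call. = FALSE)
  }
  r <- (acc - floor_val) / (acc[[1]] - floor_val)
  below <- which(r <= threshold)
  if (length(below) == 0) {
    warning("retention never reaches the threshold; returning p* = 1")
    return(1)
  }
  j <- min(below)
  if (j == 1) return(unname(p[1]))
  # linear interpolation between the bracketing grid points
  unname(p[j - 1] + (r[j - 1] - threshold) / (r[j - 1] - r[j]) *
           (p[j] - p[j - 1]))
}

#' Calibrate scrambling rates for every block
#'
#' @inheritParams importance_curve
#' @param threshold,chance see [calibrate_rate()].
#' @return list with `rates` (named numeric vector, one `p*` per block) and
#'   `curves` (row-bound importance curves).
#' @export
calibrate_all_blocks <- function(backbone, head, dataset,
                                 p_grid = seq(0, 1, by = 0.1), n_rep = 10L,
                                 threshold = 0.2, chance = 0.5, seed = 1L) {
  curves <- lapply(seq_len(backbone$n_blocks), function(b) {
    importance_curve(backbone, head, dataset, b, p_grid, n_rep,
                     seed = derive_seed(seed, b * 977L))
  })
  rates <- vapply(curves, calibrate_rate, numeric(1),
                  threshold = threshold, chance = chance)
  list(rates = stats::setNames(rates, seq_len(backbone$n_blocks)),
       curves = do.call(rbind, curves))
}

stage_blocks <- function(direction, stage, n_blocks) {
  if (direction == "late_to_early") seq(n_blocks - stage + 1L, n_blocks)
  else seq_len(stage)
}

#' Progressive scrambling under gain sweeps
#'
#' Starting from the late (or early) end of the hierarchy, scrambles an
#' increasing number of blocks at their calibrated rates and sweeps the gain
#' grid at every stage, with `n_rep` repetitions differing only in their
#' permutation seeds. Stage `s` scrambles the `s` outermost blocks in the
#' given direction.
#'
#' @param backbone a `gain_backbone`.
#' @param head a `task_head`.
#' @param dataset held-out binary `gain_dataset`.
#' @param direction `"late_to_early"` or `"early_to_late"`.
#' @param rates named vector of calibrated per-block rates `p*` (from
#'   [calibrate_all_blocks()]).
#' @param grid gain values (must include 1).
#' @param stages which stages to run (default `1:(B-1)`).
#' @param n_rep repetitions per stage.
#' @param seed integer seed.
#' @return list with `profiles` (data frame `direction`, `stage`, `delta`,
#'   `repetition`, `accuracy`) and `peaks` (data frame `direction`, `stage`,
#'   `median_peak`, `ci_lower`, `ci_upper`; repetitions play the role of
#'   instances).
#' @export
progressive_scramble_sweep <- function(backbone, head, dataset,
                                       direction = c("late_to_early",
                                                     "early_to_late"),
                                       rates, grid = gain_grid(),
                                       stages = NULL, n_rep = 10L,
                                       seed = 1L) {
  direction <- match.arg(direction)
  validate_grid(grid)
  B <- backbone$n_blocks
  if (length(rates) < B) stop("calibrated rates missing for some blocks", call. = FALSE)
  stages <- stages %||% seq_len(B - 1L)
  prof <- list(); pk <- list(); i <- 1L
  for (s in stages) {
    blocks <- stage_blocks(direction, s, B)
    rows <- list()
    for (rep in seq_len(n_rep)) {
      plan <- scramble_plan(blocks, rates[as.character(blocks)],
                            seed = derive_seed(seed, s * 211L + rep),
                            direction = direction, stage = s)
      for (d in grid) {
        m_d <- set_global_gain(backbone, d)
        feats <- pooled_features(m_d, dataset$images, plan = plan)
        sc <- head_scores(head, feats)
        rows[[length(rows) + 1L]] <-
          data.frame(direction = direction, stage = s, delta = d,
                     repetition = rep,
                     accuracy = mean((sc[1, ] > 0) == (dataset$labels == 1)))
      }
    }
    df <- do.call(rbind, rows)
    prof[[i]] <- df
    peak <- find_peak(data.frame(instance = df$repetition, delta = df$delta,
                                 value = df$accuracy))
    pk[[i]] <- data.frame(direction = direction, stage = s,
                          median_peak = peak$median,
                          ci_lower = peak$ci$lower %||% NA_real_,
                          ci_upper = peak$ci$upper %||% NA_real_)
    i <- i + 1L
  }
  list(profiles = do.call(rbind, prof), peaks = do.call(rbind, pk))
}
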