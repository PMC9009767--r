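#' Experiment configuration
#'
#' Collects the tunable training and evaluation settings of the pipeline in
#' one serializable list. All stochastic steps derive their seeds from
#' `seed`, so a config fully determines a run.
#'
#' @param n_instances number of independently seeded model instances per
#'   condition.
#' @param epochs training epochs for the backbone.
#' @param head_epochs epochs for head fine-tuning.
#' @param batch_size minibatch size.
#' @param lr,momentum SGD settings (cosine-decayed learning rate).
#' @param head_lr learning rate for head fine-tuning.
#' @param seed master seed.
#' @param gain_grid evaluation grid of global gain values (see [gain_grid()]).
#' @param ... further named settings stored verbatim.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(n_instances = 10L, epochs = 15L,
                              head_epochs = 30L, batch_size = 32L,
                              lr = 0.05, momentum = 0.9, head_lr = 0.5,
                              seed = 1L, gain_grid = NULL, ...) {
  cfg <- list(n_instances = as.integer(n_instances),
              epochs = as.integer(epochs),
              head_epochs = as.integer(head_epochs),
              batch_size = as.integer(batch_size),
              lr = lr, momentum = momentum, head_lr = head_lr,
              seed = as.integer(seed),
              gain_grid = gain_grid %||% gain_grid(), ...)
  class(cfg) <- "experiment_config"
  cfg
}

# Collect/replace model weights as a flat tree for the optimizer. The `n*`
# entries are the batch-norm affine parameters (gamma/beta) or, for the
# normalization-free variant, the per-channel convolution biases.
norm_params <- function(bn, bias) {
  if (!is.null(bn)) list(gamma = bn$gamma, beta = bn$beta) else bias
}

model_params <- function(model) {
  list(stem = list(w = model$stem$w,
                   n = norm_params(model$stem$bn, model$stem$b)),
       blocks = lapply(model$blocks, function(blk) {
         p <- list(conv1 = blk$conv1, n1 = norm_params(blk$bn1, blk$b1),
                   conv2 = blk$conv2, n2 = norm_params(blk$bn2, blk$b2))
         if (!is.null(blk$proj)) {
           p$proj <- blk$proj
           p$np <- norm_params(blk$bnp, blk$bp)
         }
         p
       }),
       head = list(w = model$head$w, b = model$head$b))
}

model_set_params <- function(model, par) {
  set_norm <- function(tgt, np) {
    if (model$use_bn) {
      tgt$bn$gamma <- np$gamma; tgt$bn$beta <- np$beta
    } else {
      tgt$bias <- np
    }
    tgt
  }
  model$stem$w <- par$stem$w
  if (model$use_bn) {
    model$stem$bn$gamma <- par$stem$n$gamma
    model$stem$bn$beta <- par$stem$n$beta
  } else {
    model$stem$b <- par$stem$n
  }
  for (b in seq_along(model$blocks)) {
    pb <- par$blocks[[b]]
    model$blocks[[b]]$conv1 <- pb$conv1
    model$blocks[[b]]$conv2 <- pb$conv2
    if (model$use_bn) {
      model$blocks[[b]]$bn1$gamma <- pb$n1$gamma
      model$blocks[[b]]$bn1$beta <- pb$n1$beta
      model$blocks[[b]]$bn2$gamma <- pb$n2$gamma
      model$blocks[[b]]$bn2$beta <- pb$n2$beta
    } else {
      model$blocks[[b]]$b1 <- pb$n1
      model$blocks[[b]]$b2 <- pb$n2
    }
    if (!is.null(pb$proj)) {
      model$blocks[[b]]$proj <- pb$proj
      if (model$use_bn) {
        model$blocks[[b]]$bnp$gamma <- pb$np$gamma
        model$blocks[[b]]$bnp$beta <- pb$np$beta
      } else {
        model$blocks[[b]]$bp <- pb$np
      }
    }
  }
  model$head$w <- par$head$w
  model$head$b <- par$head$b
  model
}

one_hot <- function(labels, n_classes) {
  t_mat <- matrix(0, n_classes, length(labels))
  t_mat[cbind(labels, seq_along(labels))] <- 1
  t_mat
}

#' Pretrain the shared backbone on a generic category task
#'
#' Trains all backbone weights with momentum SGD and a cosine-decayed
#' learning rate on a multi-category synthetic dataset, entirely at the
#' neutral gain state (`delta = 1`). The loss is multi-label sigmoid
#' cross-entropy against one-hot targets; accuracy is argmax.
#'
#' @param train,val `gain_dataset`s with integer labels `1..K`.
#' @param config an [experiment_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained `gain_backbone`), `history`
#'   (per-epoch loss), and `val_accuracy`.
#' @export
pretrain_backbone <- function(train, val, config = experiment_config(),
                              verbose = FALSE) {
  n_classes <- max(train$labels)
  model <- build_backbone(input_shape = dim(train$images)[1:3],
                          n_classes = n_classes,
                          activation = config$activation %||%
                            activation_spec("saturating"),
                          use_bn = config$use_bn %||% FALSE,
                          seed = derive_seed(config$seed, 11L))
  stopifnot(model$delta == 1)
  n <- n_images(train)
  targets <- one_hot(train$labels, n_classes)
  par <- model_params(model)
  vel <- tree_zeros(par)
  n_steps <- ceiling(n / config$batch_size) * config$epochs
  step <- 0L
  history <- numeric(config$epochs)
  local_seed(derive_seed(config$seed, 12L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- train$images[, , , idx, drop = FALSE]
        tb <- targets[, idx, drop = FALSE]
        fw <- backbone_forward(model, xb, train = TRUE)
        model <- fw$model  # running BN stats updated
        lo <- sigmoid_bce(fw$scores, tb)
        if (!is.finite(lo$loss)) stop("training diverged: non-finite loss", call. = FALSE)
        grads <- backbone_backward(model, fw$cache, lo$dscores)
        gnorm <- sqrt(tree_sumsq(grads))
        clip <- config$clip_norm %||% 2
        if (gnorm > clip) {
          grads <- tree_map2(function(g, .) g * (clip / gnorm), grads, grads)
        }
        lr_t <- config$lr * 0.5 * (1 + cos(pi * step / n_steps))
        vel <- tree_map2(function(v, g) config$momentum * v - lr_t * g,
                         vel, grads)
        par <- model_params(model)
        par <- tree_map2(`+`, par, vel)
        model <- model_set_params(model, par)
        ep_loss <- ep_loss + lo$loss
        nb <- nb + 1L
        step <- step + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d loss %.4f", ep, config$epochs,
                                   history[ep]))
    }
  })
  model$meta$trained_delta <- 1
  val_acc <- NA_real_
  if (!is.null(val)) {
    sc <- model_scores(model, val$images)
    val_acc <- mean(apply(sc, 2, which.max) == val$labels)
  }
  list(model = model, history = history, val_accuracy = val_acc)
}

new_task_head <- function(w, b, condition, seed, n_features,
                          center = NULL, scale = NULL) {
  structure(list(w = w, b = b, condition = condition,
                 seed = as.integer(seed), trained_delta = 1,
                 n_features = n_features, center = center, scale = scale),
            class = "task_head")
}

# The optional center/scale constants are train-set feature statistics frozen
# into the head at delta = 1; they are fixed affine preprocessing, not a
# per-gain renormalization.
head_scores <- function(head, features) {
  if (!is.null(head$center)) {
    features <- (features - head$center) / head$scale
  }
  crossprod(head$w, features) + head$b
}

# Minibatch SGD for a sigmoidal head on frozen pooled features.
train_head_sgd <- function(features, targets, seed, epochs, lr, batch_size,
                           momentum = 0.9, l2 = 1e-3) {
  p <- nrow(features)
  k <- nrow(targets)
  n <- ncol(features)
  local_seed(seed, {
    w <- matrix(rnorm(p * k, sd = 0.01), p, k)
    b <- rep(0, k)
    vw <- w * 0; vb <- b * 0
    n_steps <- ceiling(n / batch_size) * epochs
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        f <- features[, idx, drop = FALSE]
        s <- crossprod(w, f) + b
        d <- (sigmoid(s) - targets[, idx, drop = FALSE]) / length(idx)
        gw <- f %*% t(d) + l2 * w
        gb <- rowSums(d)
        lr_t <- lr * 0.5 * (1 + cos(pi * step / n_steps))
        vw <- momentum * vw - lr_t * gw
        vb <- momentum * vb - lr_t * gb
        w <- w + vw
        b <- b + vb
        step <- step + 1L
      }
    }
    list(w = w, b = b)
  })
}

#' Fine-tune per-condition task heads at neutral gain
#'
#' Trains `n_instances` sigmoidal output heads (one per seed) on the pooled
#' features of a frozen backbone, at `delta = 1` only. The backbone is never
#' modified; an integrity hash asserts this.
#'
#' @param backbone a trained `gain_backbone`.
#' @param data list with `train` and optionally `val` `gain_dataset`s. Binary
#'   labels (0/1) give a single-logit head; integer labels `1..K` give a
#'   K-unit multi-label head.
#' @param config an [experiment_config()].
#' @param condition identifier stored on each head (e.g. the difficulty
#'   level).
#' @return list of `task_head` objects (length `n_instances`), with the
#'   training-time validation accuracy in `attr(, "val_accuracy")`.
#' @export
finetune_head <- function(backbone, data, config = experiment_config(),
                          condition = data$train$level) {
  if (backbone$delta != 1) {
    stop("heads must be fine-tuned at the neutral gain state delta = 1", call. = FALSE)
  }
  hash_before <- model_weight_hash(backbone)
  feats <- pooled_features(backbone, data$train$images)
  standardize <- config$standardize_features %||% TRUE
  center <- NULL; scale <- NULL
  if (standardize) {
    center <- rowMeans(feats)
    scale <- pmax(apply(feats, 1, stats::sd), 1e-8)
    feats <- (feats - center) / scale
  }
  binary <- all(data$train$labels %in% c(0L, 1L))
  targets <- if (binary) {
    matrix(data$train$labels, 1)
  } else {
    one_hot(data$train$labels, max(data$train$labels))
  }
  boot <- config$bootstrap_instances %||% TRUE
  n_tr <- ncol(feats)
  heads <- lapply(seq_len(config$n_instances), function(i) {
    sd_i <- derive_seed(config$seed, 500L + i)
    idx <- if (boot && config$n_instances > 1) {
      local_seed(derive_seed(sd_i, 3L), sample.int(n_tr, n_tr, replace = TRUE))
    } else {
      seq_len(n_tr)
    }
    fit <- train_head_sgd(feats[, idx, drop = FALSE],
                          targets[, idx, drop = FALSE], seed = sd_i,
                          epochs = config$head_epochs, lr = config$head_lr,
                          batch_size = config$batch_size,
                          l2 = config$head_l2 %||% 1e-3)
    new_task_head(fit$w, fit$b, condition, sd_i, nrow(feats),
                  center = center, scale = scale)
  })
  if (!identical(model_weight_hash(backbone), hash_before)) {
    stop("backbone was mutated during head fine-tuning", call. = FALSE)
  }
  if (!is.null(data$val)) {
    fv <- pooled_features(backbone, data$val$images)
    accs <- vapply(heads, function(hd) {
      sc <- head_scores(hd, fv)
      if (binary) mean((sc[1, ] > 0) == (data$val$labels == 1))
      else mean(apply(sc, 2, which.max) == data$val$labels)
    }, numeric(1))
    attr(heads, "val_accuracy") <- accs
  }
  attr(heads, "backbone_hash") <- hash_before
  heads
}

#' Subsample answer-option category subsets
#'
#' For each requested size below the full category count, draws
#' `n_iterations` random subsets (categories distinct within a draw,
#' duplicates across iterations allowed); the full size yields the single
#' complete set.
#'
#' @param categories vector of category identifiers.
#' @param sizes subset sizes to draw (each `<= length(categories)`).
#' @param n_iterations number of random subsets per size.
#' @param seed integer seed.
#' @return named list (by size) of lists of category subsets.
#' @export
subsample_answer_options <- function(categories, sizes = c(2, 4, 8),
                                     n_iterations = 20L, seed = 1L) {
  stopifnot(all(sizes >= 1), all(sizes <= length(categories)))
  out <- list()
  for (s in sizes) {
    if (s == length(categories)) {
      out[[as.character(s)]] <- list(categories)
    } else {
      out[[as.character(s)]] <- local_seed(derive_seed(seed, 700L + s), {
        lapply(seq_len(n_iterations), function(i) sort(sample(categories, s)))
      })
    }
  }
  out
}
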