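#' Build a gain-modulated residual backbone
#'
#' Constructs a small residual convolutional network in the spirit of a
#' reduced ResNet: a convolutional stem followed by `length(widths)` residual
#' blocks of two 3x3 convolutions each, and skip connections (with a 1x1
#' projection where the block downsamples or changes width), ending in global
#' average pooling and a linear classification head. Every activation site
#' shares one global gain scalar `delta` (see [set_global_gain()]);
#' `delta = 1` reproduces a standard network.
#'
#' Two normalization variants are available. With `use_bn = TRUE` the
#' convolutions are followed by batch normalization (batch statistics during
#' training, frozen running statistics at evaluation so gain effects
#' propagate instead of being renormalized away). With `use_bn = FALSE`
#' (the pipeline default) the network has no normalization layers, only
#' per-channel convolution biases initialized at zero and a down-scaled
#' second residual convolution for stable training. The normalization-free
#' network is close to positively homogeneous, so its representation
#' degrades gradually and asymmetrically under gain changes — the regime in
#' which gain-performance profiles are informative at this scale.
#'
#' The per-block tap point used by decoding and activation analyses is the
#' output of the block's last activation, i.e. after the residual and skip
#' branches have been merged.
#'
#' @param input_shape integer vector `c(height, width, channels)`.
#' @param widths channel width of each residual block.
#' @param downsample logical vector: whether each block halves the spatial
#'   resolution (stride-2 first convolution).
#' @param n_classes number of output units of the head.
#' @param activation an [activation_spec()].
#' @param use_bn include batch normalization layers.
#' @param seed integer seed for weight initialization.
#' @return an object of class `gain_backbone`.
#' @export
build_backbone <- function(input_shape = c(32, 32, 3),
                           widths = c(8, 8, 16, 16, 32, 32, 64, 64),
                           downsample = c(FALSE, FALSE, TRUE, FALSE,
                                          TRUE, FALSE, TRUE, FALSE),
                           n_classes = 8,
                           activation = activation_spec("saturating"),
                           use_bn = FALSE,
                           seed = 1L) {
  stopifnot(length(input_shape) == 3, length(widths) == length(downsample),
            length(widths) >= 1)
  local_seed(seed, {
    mk_norm <- function(c_out) if (use_bn) make_bn(c_out) else NULL
    mk_bias <- function(c_out) if (use_bn) NULL else rep(0, c_out)
    stem <- list(w = make_conv(3, 3, input_shape[3], widths[1]),
                 b = mk_bias(widths[1]), bn = mk_norm(widths[1]))
    blocks <- vector("list", length(widths))
    c_in <- widths[1]
    for (b in seq_along(widths)) {
      c_out <- widths[b]
      stride <- if (downsample[b]) 2L else 1L
      proj <- NULL; bnp <- NULL; bp <- NULL
      if (stride != 1L || c_in != c_out) {
        proj <- make_conv(1, 1, c_in, c_out)
        bnp <- mk_norm(c_out)
        bp <- mk_bias(c_out)
      }
      conv2 <- make_conv(3, 3, c_out, c_out)
      if (!use_bn) conv2 <- conv2 * 0.25  # tame the residual branch at init
      blocks[[b]] <- list(conv1 = make_conv(3, 3, c_in, c_out),
                          b1 = mk_bias(c_out), bn1 = mk_norm(c_out),
                          conv2 = conv2,
                          b2 = mk_bias(c_out), bn2 = mk_norm(c_out),
                          proj = proj, bp = bp, bnp = bnp, stride = stride)
      c_in <- c_out
    }
    head <- list(w = matrix(rnorm(c_in * n_classes, sd = sqrt(1 / c_in)),
                            c_in, n_classes),
                 b = rep(0, n_classes))
    structure(list(input_shape = as.integer(input_shape), widths = widths,
                   downsample = downsample, n_blocks = length(widths),
                   n_classes = n_classes, activation = activation,
                   use_bn = use_bn, input_center = 0.5, delta = 1,
                   stem = stem, blocks = blocks, head = head,
                   meta = list(seed = as.integer(seed), trained_delta = 1)),
              class = "gain_backbone")
  })
}

#' Build a bias-free sequential rectifier network
#'
#' A plain fully-connected network without biases or normalization, with a
#' gain-scaled activation after every hidden layer and a linear output layer.
#' Because such a network is positively homogeneous, its logits under gain
#' `delta` equal `delta^L` times the neutral logits (`L` = number of
#' activation layers), which makes it the analytic oracle for the global-gain
#' mechanism.
#'
#' @param layer_widths widths of the hidden layers (one activation each).
#' @param n_in input dimension.
#' @param n_out output dimension.
#' @param activation an [activation_spec()]; the homogeneity identity only
#'   holds for the rectifier.
#' @param seed integer seed.
#' @return an object of class `gain_mlp`.
#' @export
build_sequential_net <- function(layer_widths, n_in, n_out,
                                 activation = activation_spec("rectifier"),
                                 seed = 1L) {
  local_seed(seed, {
    dims <- c(n_in, layer_widths)
    layers <- lapply(seq_along(layer_widths), function(l) {
      matrix(rnorm(dims[l + 1] * dims[l], sd = sqrt(2 / dims[l])),
             dims[l + 1], dims[l])
    })
    w_out <- matrix(rnorm(n_out * dims[length(dims)], sd = sqrt(1 / dims[length(dims)])),
                    n_out, dims[length(dims)])
    structure(list(layers = layers, w_out = w_out, activation = activation,
                   delta = 1, n_acts = length(layer_widths)),
              class = "gain_mlp")
  })
}

#' Set the global gain state of a model
#'
#' Returns a copy of the model whose every activation site uses the new gain
#' `delta`. Weights are untouched (the weight hash is unchanged), and the
#' scalar is stateless: setting it twice is equivalent to setting it once.
#'
#' @param model a `gain_backbone` or `gain_mlp`.
#' @param delta positive scalar gain (or a [global_gain_state()]).
#' @return the model with the new gain state.
#' @export
set_global_gain <- function(model, delta) UseMethod("set_global_gain")

#' @export
set_global_gain.gain_backbone <- function(model, delta) {
  model$delta <- as_delta(delta)
  model
}

#' @export
set_global_gain.gain_mlp <- function(model, delta) {
  model$delta <- as_delta(delta)
  model
}

#' Hash of a model's trainable weights
#'
#' The hash covers everything training can change (weights, biases,
#' normalization parameters and running statistics); the gain state is
#' excluded, so a frozen backbone keeps its hash through head fine-tuning
#' and gain sweeps.
#'
#' @param model a `gain_backbone` or `gain_mlp`.
#' @return a character hash.
#' @export
model_weight_hash <- function(model) {
  m <- unclass(model)
  m$delta <- NULL
  rlang::hash(m)
}

apply_act <- function(S, spec, delta) {
  out <- activation_base(S, spec)
  if (delta != 1) out <- delta * out
  out
}

# conv + (batch norm | bias). Returns y, updated norm state, cache.
conv_norm_forward <- function(x, w, bias, bn, stride, pad, train) {
  z <- conv_forward(x, w, stride, pad)
  if (!is.null(bn)) {
    bf <- bn_forward(z, bn, train)
    list(y = bf$y, bn = bf$bn,
         cache = if (train) list(x = x, bn = bf$cache) else NULL)
  } else {
    hw <- dim(z)[1] * dim(z)[2]
    if (any(bias != 0)) z <- z + ch_expand(bias, hw)
    list(y = z, bn = NULL, cache = if (train) list(x = x) else NULL)
  }
}

conv_norm_backward <- function(dy, w, bias, bn, cache, stride, pad) {
  if (!is.null(bn)) {
    bb <- bn_backward(dy, cache$bn)
    cw <- conv_backward(cache$x, w, bb$dx, stride, pad)
    list(dx = cw$dx, dw = cw$dw,
         dnorm = list(gamma = bb$dgamma, beta = bb$dbeta))
  } else {
    cw <- conv_backward(cache$x, w, dy, stride, pad)
    list(dx = cw$dx, dw = cw$dw, dnorm = ch_sum(dy))
  }
}

# Forward pass of the residual backbone.
#
# x:          H x W x C x N input images (or a hidden tensor when
#             `from_block` is set).
# taps:       collect the post-activation output of every block.
# train:      training mode (batch statistics, caches for backward).
# plan:       optional scramble_plan applied to the residual branch.
# from_block: start at block `from_block`, treating `x` as its input.
# to_block:   stop after block `to_block` and return the hidden tensor.
backbone_forward <- function(model, x, taps = FALSE, train = FALSE,
                             plan = NULL, from_block = NULL, to_block = NULL) {
  spec <- model$activation
  delta <- model$delta
  B <- model$n_blocks
  b0 <- from_block %||% 1L
  b1 <- to_block %||% B
  cache <- if (train) list(blocks = vector("list", B)) else NULL
  tap_list <- if (taps) vector("list", B) else NULL

  h <- x
  if (is.null(from_block)) {
    if (!identical(dim(x)[1:3], model$input_shape)) {
      stop("input batch does not match the model input shape", call. = FALSE)
    }
    if (dim(x)[4] < 1) stop("empty batch", call. = FALSE)
    x <- x - model$input_center
    fs <- conv_norm_forward(x, model$stem$w, model$stem$b, model$stem$bn,
                            1L, 1L, train)
    if (train) {
      model$stem$bn <- fs$bn
      cache$stem <- list(cn = fs$cache, pre = fs$y)
    }
    h <- apply_act(fs$y, spec, delta)
  }

  for (b in b0:b1) {
    blk <- model$blocks[[b]]
    f1 <- conv_norm_forward(h, blk$conv1, blk$b1, blk$bn1, blk$stride, 1L,
                            train)
    a1 <- apply_act(f1$y, spec, delta)
    f2 <- conv_norm_forward(a1, blk$conv2, blk$b2, blk$bn2, 1L, 1L, train)
    r <- f2$y
    if (!is.null(blk$proj)) {
      fp <- conv_norm_forward(h, blk$proj, blk$bp, blk$bnp, blk$stride, 0L,
                              train)
      skip <- fp$y
    } else {
      skip <- h
    }
    if (!is.null(plan)) r <- plan_apply(plan, r, b)
    pre <- r + skip
    if (train) {
      model$blocks[[b]]$bn1 <- f1$bn
      model$blocks[[b]]$bn2 <- f2$bn
      if (!is.null(blk$proj)) model$blocks[[b]]$bnp <- fp$bn
      cache$blocks[[b]] <- list(cn1 = f1$cache, pre1 = f1$y, a1 = a1,
                                cn2 = f2$cache,
                                cnp = if (is.null(blk$proj)) NULL else fp$cache,
                                pre = pre)
    }
    h <- apply_act(pre, spec, delta)
    if (taps) tap_list[[b]] <- h
  }

  if (!is.null(to_block)) {
    return(list(hidden = h, taps = tap_list))
  }
  pooled <- gap_forward(h)
  scores <- crossprod(model$head$w, pooled) + model$head$b
  if (train) {
    cache$pooled <- pooled
    cache$h_dim <- dim(h)
  }
  list(scores = scores, pooled = pooled, taps = tap_list, cache = cache,
       model = model)
}

# Backward pass matching backbone_forward(train = TRUE). Returns gradients
# shaped like the weight tree of model_params().
backbone_backward <- function(model, cache, dscores) {
  spec <- model$activation
  delta <- model$delta
  grads <- list(stem = NULL, blocks = vector("list", model$n_blocks),
                head = list(w = cache$pooled %*% t(dscores),
                            b = rowSums(dscores)))
  dpooled <- model$head$w %*% dscores
  dh <- gap_backward(dpooled, cache$h_dim)

  for (b in rev(seq_len(model$n_blocks))) {
    blk <- model$blocks[[b]]
    cb <- cache$blocks[[b]]
    dpre <- dh * (delta * activation_base_grad(cb$pre, spec))
    if (!is.null(blk$proj)) {
      bp <- conv_norm_backward(dpre, blk$proj, blk$bp, blk$bnp, cb$cnp,
                               blk$stride, 0L)
      dh_skip <- bp$dx
    } else {
      dh_skip <- dpre
      bp <- NULL
    }
    b2 <- conv_norm_backward(dpre, blk$conv2, blk$b2, blk$bn2, cb$cn2, 1L, 1L)
    dpre1 <- b2$dx * (delta * activation_base_grad(cb$pre1, spec))
    b1g <- conv_norm_backward(dpre1, blk$conv1, blk$b1, blk$bn1, cb$cn1,
                              blk$stride, 1L)
    dh <- b1g$dx + dh_skip
    grads$blocks[[b]] <- list(conv1 = b1g$dw, n1 = b1g$dnorm,
                              conv2 = b2$dw, n2 = b2$dnorm,
                              proj = if (is.null(bp)) NULL else bp$dw,
                              np = if (is.null(bp)) NULL else bp$dnorm)
  }
  dstem <- dh * (delta * activation_base_grad(cache$stem$pre, spec))
  bs <- conv_norm_backward(dstem, model$stem$w, model$stem$b, model$stem$bn,
                           cache$stem$cn, 1L, 1L)
  grads$stem <- list(w = bs$dw, n = bs$dnorm)
  grads
}

#' Forward pass with per-block tap activations
#'
#' Runs the backbone on an image batch and returns the activations recorded
#' at every block tap point (the output of the block's last activation, after
#' residual and skip branches are merged) together with the head scores.
#'
#' @param model a `gain_backbone`.
#' @param batch images as an `H x W x C x N` array with values in `[0, 1]`.
#' @param plan optional [scramble_plan()] applied during the pass.
#' @return list with `taps` (list of `H x W x C x N` arrays, one per block)
#'   and `scores` (`n_classes x N` matrix).
#' @export
forward_with_taps <- function(model, batch, plan = NULL) {
  out <- backbone_forward(model, batch, taps = TRUE, plan = plan)
  list(taps = out$taps, scores = out$scores)
}

#' Model scores for a batch
#'
#' @param model a `gain_backbone` or `gain_mlp`.
#' @param batch `H x W x C x N` image array (backbone) or `p x N` matrix (mlp).
#' @param plan optional [scramble_plan()].
#' @return `n_classes x N` score matrix (logits).
#' @export
model_scores <- function(model, batch, plan = NULL) UseMethod("model_scores")

#' @export
model_scores.gain_backbone <- function(model, batch, plan = NULL) {
  backbone_forward(model, batch, plan = plan)$scores
}

#' @export
model_scores.gain_mlp <- function(model, batch, plan = NULL) {
  h <- batch
  for (w in model$layers) h <- apply_act(w %*% h, model$activation, model$delta)
  model$w_out %*% h
}

#' Pooled features of the backbone
#'
#' Global-average-pooled final-block activations, the feature space in which
#' task heads are trained and evaluated.
#'
#' @inheritParams model_scores
#' @return `C x N` feature matrix.
#' @export
pooled_features <- function(model, batch, plan = NULL) {
  backbone_forward(model, batch, plan = plan)$pooled
}
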