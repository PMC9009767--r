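#' Synthetic image datasets with parametric perceptual difficulty
#'
#' The pipeline never downloads data: all stimuli are generated procedurally.
#' "Real" images are layered multi-scale oriented gratings plus soft
#' object-like blobs and a polygonal occluder, with per-image random contrast.
#' "Average" images are (weighted) pixel means of `k` real-like source images
#' drawn from a pool disjoint from the real class; larger `k` attenuates the
#' high-frequency structure and contrast of a single image, which makes the
#' real-versus-average discrimination easier.
#'
#' @name synthetic-data
NULL

#' Generator style settings
#'
#' @param img_size integer `c(height, width)` of generated images.
#' @param n_gratings number of oriented gratings layered per image.
#' @param n_blobs number of soft elliptical blobs per image.
#' @param contrast_sdlog log-sd of the per-image random contrast factor.
#' @param amplitude overall amplitude of the structured components.
#' @return a validated list of style parameters.
#' @export
style_params <- function(img_size = c(32, 32), n_gratings = 4, n_blobs = 3,
                         contrast_sdlog = 0.25, amplitude = 0.22,
                         shared_amplitude = 0.1) {
  if (length(img_size) != 2 || any(img_size < 8)) {
    stop("invalid style parameters: `img_size` must be two values >= 8", call. = FALSE)
  }
  if (n_gratings < 0 || n_blobs < 0 || contrast_sdlog < 0 || amplitude <= 0 ||
      shared_amplitude < 0) {
    stop("invalid style parameters", call. = FALSE)
  }
  list(img_size = as.integer(img_size), n_gratings = n_gratings,
       n_blobs = n_blobs, contrast_sdlog = contrast_sdlog,
       amplitude = amplitude, shared_amplitude = shared_amplitude)
}

# Shared low-frequency scene layout, constant across all images generated
# with a given style (the analogue of the common structure of natural
# scenes: luminance gradient plus a smooth field). Every image receives it
# at a positive random amplitude, which gives realistic positive pairwise
# correlations between scenes and lets blended averages retain contrast.
scene_layout <- function(style) {
  h <- style$img_size[1]; w <- style$img_size[2]
  yy <- matrix(seq_len(h), h, w) / h
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  layout <- local_seed(20201L, {
    g <- (0.5 - yy)  # brighter top, like sky over ground
    for (i in 1:3) {
      fx <- sample(0:2, 1); fy <- sample(1:2, 1)
      g <- g + runif(1, 0.3, 0.7) *
        cos(2 * pi * (fx * xx + fy * yy) + runif(1, 0, 2 * pi))
    }
    ch_w <- runif(3, 0.7, 1)
    arr <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) arr[, , ch] <- g * ch_w[ch]
    arr / stats::sd(arr)
  })
  layout
}

new_dataset <- function(images, labels, split = "pool", level = NA_real_,
                        provenance = list()) {
  stopifnot(length(dim(images)) == 4, dim(images)[4] == length(labels))
  structure(list(images = images, labels = labels, split = split,
                 level = level, provenance = provenance),
            class = "gain_dataset")
}

#' @export
print.gain_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<gain_dataset> %d images (%dx%dx%d), split=%s, level=%s\n",
              d[4], d[1], d[2], d[3], x$split,
              ifelse(is.na(x$level), "-", format(x$level))))
  invisible(x)
}

#' Number of images in a dataset
#' @param x a `gain_dataset`.
#' @param ... unused.
#' @export
n_images <- function(x, ...) dim(x$images)[4]

# One procedural structured image (H x W x 3 in [0, 1]).
render_real_image <- function(style, layout = NULL) {
  h <- style$img_size[1]; w <- style$img_size[2]
  yy <- matrix(seq_len(h), h, w) / h
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  img <- array(rep(runif(3, 0.35, 0.65), each = h * w), dim = c(h, w, 3))
  if (!is.null(layout) && style$shared_amplitude > 0) {
    img <- img + layout * (style$shared_amplitude * exp(rnorm(1, 0, 0.3)))
  }
  # multi-scale oriented gratings with per-channel weighting
  for (g in seq_len(style$n_gratings)) {
    theta <- runif(1, 0, pi)
    freq <- 2^runif(1, 1, 3.6)           # 2..12 cycles per image
    phase <- runif(1, 0, 2 * pi)
    patt <- sin(2 * pi * freq * (xx * cos(theta) + yy * sin(theta)) + phase)
    wch <- runif(3, 0.2, 1)
    amp <- style$amplitude * runif(1, 0.4, 1) / sqrt(style$n_gratings)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + amp * wch[ch] * patt
  }
  # soft elliptical blobs (object-like structure at a coarser scale)
  for (b in seq_len(style$n_blobs)) {
    cx <- runif(1, 0.15, 0.85); cy <- runif(1, 0.15, 0.85)
    sx <- runif(1, 0.06, 0.2); sy <- runif(1, 0.06, 0.2)
    rot <- runif(1, 0, pi)
    dx <- xx - cx; dy <- yy - cy
    u <- dx * cos(rot) + dy * sin(rot)
    v <- -dx * sin(rot) + dy * cos(rot)
    mask <- exp(-0.5 * ((u / sx)^2 + (v / sy)^2))
    col <- runif(3, -1, 1) * style$amplitude * 1.6
    for (ch in 1:3) img[, , ch] <- img[, , ch] + col[ch] * mask
  }
  # one random convex polygonal occluder (intersection of half-planes)
  nhp <- sample(3:5, 1)
  px <- runif(1, 0.25, 0.75); py <- runif(1, 0.25, 0.75)
  mask <- matrix(TRUE, h, w)
  for (i in seq_len(nhp)) {
    ang <- 2 * pi * i / nhp + runif(1, -0.4, 0.4)
    d0 <- runif(1, 0.08, 0.22)
    mask <- mask & ((xx - px) * cos(ang) + (yy - py) * sin(ang) < d0)
  }
  occ <- runif(3, -1, 1) * style$amplitude * 1.4
  for (ch in 1:3) img[, , ch] <- img[, , ch] + occ[ch] * mask
  # per-image global contrast factor (the main single-image cue that
  # averaging attenuates)
  cf <- exp(rnorm(1, 0, style$contrast_sdlog))
  mu <- mean(img)
  img <- mu + cf * (img - mu)
  pmin(pmax(img, 0), 1)
}

#' Generate procedurally structured "real" images
#'
#' Deterministic given `seed`. Single images carry high-frequency structure
#' and per-image contrast that pixel averaging demonstrably attenuates.
#'
#' @param n number of images (> 0).
#' @param seed integer seed.
#' @param style generator settings from [style_params()].
#' @return a `gain_dataset` with labels set to 1 (real).
#' @export
generate_real_images <- function(n, seed, style = style_params()) {
  stopifnot(n > 0)
  style <- do.call(style_params, style)  # re-validate
  h <- style$img_size[1]; w <- style$img_size[2]
  layout <- scene_layout(style)
  images <- array(0, dim = c(h, w, 3, n))
  local_seed(seed, {
    for (i in seq_len(n)) images[, , , i] <- render_real_image(style, layout)
  })
  new_dataset(images, rep(1L, n), split = "pool",
              provenance = list(generator = "real", seed = as.integer(seed),
                                style = style))
}

#' Blend source images into an average image
#'
#' For integer `k` the result is the unweighted mean of `k` sources. For
#' fractional `k = m + alpha` (0 < alpha < 1) it is the weighted mean of
#' `m + 1` sources with weights `(1, ..., 1, alpha) / k`, so `k = 1.25`
#' blends a full-weight image with a second image at alpha 25%.
#'
#' @param sources `H x W x C x M` array (or list of `H x W x C` arrays) with
#'   `M = ceiling(k)`.
#' @param k difficulty level, number of images per average (>= 1).
#' @return an `H x W x C` array with values in `[0, 1]`.
#' @export
make_average_image <- function(sources, k) {
  if (is.list(sources)) {
    sources <- array(unlist(sources),
                     dim = c(dim(sources[[1]]), length(sources)))
  }
  stop_if_not_scalar_number(k, "k")
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  m <- ceiling(k)
  if (dim(sources)[4] != m) {
    stop(sprintf("expected %d source images for k = %g, got %d",
                 m, k, dim(sources)[4]), call. = FALSE)
  }
  alpha <- k - floor(k)
  wts <- if (alpha > 0) c(rep(1, m - 1), alpha) / k else rep(1 / k, m)
  out <- array(0, dim = dim(sources)[1:3])
  for (i in seq_len(m)) out <- out + wts[i] * sources[, , , i]
  out
}

#' Build balanced train/val/test datasets for each difficulty level
#'
#' Real images are generated once and shared across levels; average images
#' are rebuilt per level from a source pool disjoint from the real pool.
#' Every split is exactly 50/50 real/average and splits are disjoint.
#'
#' @param levels difficulty levels `k` (images per average).
#' @param n_train,n_val,n_test images per split (must be even).
#' @param seed integer seed.
#' @param style generator settings.
#' @param source_pool_size size of the pool that average images are blended
#'   from.
#' @return named list: one `list(train, val, test)` of `gain_dataset`s per
#'   level.
#' @export
build_difficulty_suite <- function(levels, n_train = 400, n_val = 128,
                                   n_test = 256, seed = 1L,
                                   style = style_params(),
                                   source_pool_size = 128L) {
  stopifnot(length(levels) >= 1, all(levels >= 1))
  ns <- c(train = n_train, val = n_val, test = n_test)
  if (any(ns %% 2 != 0)) stop("split sizes must be even for 50/50 balance", call. = FALSE)
  if (source_pool_size < max(ceiling(levels))) {
    stop("source pool exhausted: increase `source_pool_size`", call. = FALSE)
  }
  n_real <- sum(ns) / 2
  reals <- generate_real_images(n_real, derive_seed(seed, 1L), style)
  pool <- generate_real_images(source_pool_size, derive_seed(seed, 2L), style)
  split_of <- rep(names(ns), times = ns / 2)

  out <- list()
  for (lv in levels) {
    m <- ceiling(lv)
    avg <- array(0, dim = dim(reals$images))
    local_seed(derive_seed(seed, 100L + round(lv * 8)), {
      for (i in seq_len(n_real)) {
        idx <- sample.int(source_pool_size, m)
        avg[, , , i] <- make_average_image(pool$images[, , , idx, drop = FALSE], lv)
      }
    })
    triplet <- list()
    for (sp in names(ns)) {
      sel <- which(split_of == sp)
      imgs <- array(0, dim = c(dim(reals$images)[1:3], 2 * length(sel)))
      imgs[, , , seq_along(sel)] <- reals$images[, , , sel, drop = FALSE]
      imgs[, , , length(sel) + seq_along(sel)] <- avg[, , , sel, drop = FALSE]
      labels <- c(rep(1L, length(sel)), rep(0L, length(sel)))
      # deterministic interleave so batches are balanced
      ord <- local_seed(derive_seed(seed, 200L + round(lv * 8)),
                        sample.int(length(labels)))
      triplet[[sp]] <- new_dataset(imgs[, , , ord, drop = FALSE], labels[ord],
                                   split = sp, level = lv,
                                   provenance = list(seed = as.integer(seed),
                                                     style = style, k = lv))
    }
    out[[as.character(lv)]] <- triplet
  }
  out
}

#' Generate a multi-category recognition dataset
#'
#' Category identity is carried by a controllable visual feature: a soft blob
#' with a category-specific location (on a ring) and color signature, placed
#' over an uninformative textured background shared across categories. The
#' categories are linearly decodable from raw pixels by design.
#'
#' @param n_categories number of categories (>= 2).
#' @param n_per_category images per category.
#' @param seed integer seed.
#' @param style generator settings.
#' @return a `gain_dataset` with integer labels `1..n_categories`.
#' @export
generate_category_dataset <- function(n_categories, n_per_category, seed,
                                      style = style_params()) {
  stopifnot(n_categories >= 2, n_per_category > 0)
  style <- do.call(style_params, style)
  h <- style$img_size[1]; w <- style$img_size[2]
  n <- n_categories * n_per_category
  images <- array(0, dim = c(h, w, 3, n))
  labels <- rep(seq_len(n_categories), each = n_per_category)
  yy <- matrix(seq_len(h), h, w) / h
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  # fixed category palette: hue around the color circle
  hue <- (seq_len(n_categories) - 1) / n_categories
  pal <- t(sapply(hue, function(u) {
    c(0.5 + 0.5 * cos(2 * pi * u),
      0.5 + 0.5 * cos(2 * pi * (u + 1 / 3)),
      0.5 + 0.5 * cos(2 * pi * (u + 2 / 3)))
  }))
  ang <- 2 * pi * (seq_len(n_categories) - 1) / n_categories
  cx0 <- 0.5 + 0.27 * cos(ang)
  cy0 <- 0.5 + 0.27 * sin(ang)
  layout <- scene_layout(style)
  local_seed(seed, {
    for (i in seq_len(n)) {
      cat_i <- labels[i]
      bg_style <- style
      bg_style$n_blobs <- 0
      img <- render_real_image(bg_style, layout)
      cx <- cx0[cat_i] + rnorm(1, 0, 0.03)
      cy <- cy0[cat_i] + rnorm(1, 0, 0.03)
      s <- runif(1, 0.08, 0.13)
      mask <- exp(-0.5 * (((xx - cx) / s)^2 + ((yy - cy) / s)^2))
      amp <- runif(1, 0.5, 0.9)
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] + amp * mask * (pal[cat_i, ch] - img[, , ch])
      }
      images[, , , i] <- pmin(pmax(img, 0), 1)
    }
    ord <- sample.int(n)
    images <- images[, , , ord, drop = FALSE]
    labels <- labels[ord]
  })
  new_dataset(images, labels, split = "pool",
              provenance = list(generator = "category",
                                seed = as.integer(seed), style = style,
                                n_categories = n_categories))
}

#' Split a dataset into train/val/test
#'
#' @param ds a `gain_dataset`.
#' @param n_train,n_val,n_test split sizes (must sum to at most `n_images(ds)`).
#' @param seed integer seed for the shuffle.
#' @return list of three `gain_dataset`s.
#' @export
split_dataset <- function(ds, n_train, n_val, n_test, seed = 1L) {
  n <- n_images(ds)
  stopifnot(n_train + n_val + n_test <= n)
  ord <- local_seed(seed, sample.int(n))
  take <- function(idx, sp) {
    new_dataset(ds$images[, , , idx, drop = FALSE], ds$labels[idx],
                split = sp, level = ds$level, provenance = ds$provenance)
  }
  list(train = take(ord[seq_len(n_train)], "train"),
       val = take(ord[n_train + seq_len(n_val)], "val"),
       test = take(ord[n_train + n_val + seq_len(n_test)], "test"))
}

#' Similarity between an average image and its sources
#'
#' Mean Pearson correlation between average images built at level `k` and the
#' individual real images they were blended from. This decreases with `k`:
#' the more images enter the blend, the less the average resembles any single
#' natural-looking image.
#'
#' @param k difficulty level.
#' @param n number of average images to build.
#' @param seed integer seed.
#' @param style generator settings.
#' @return mean correlation (scalar).
#' @export
average_source_similarity <- function(k, n = 40, seed = 1L,
                                      style = style_params()) {
  m <- ceiling(k)
  pool <- generate_real_images(max(2 * m, 16), derive_seed(seed, 3L), style)
  cors <- local_seed(derive_seed(seed, 4L), {
    vapply(seq_len(n), function(i) {
      idx <- sample.int(n_images(pool), m)
      avg <- make_average_image(pool$images[, , , idx, drop = FALSE], k)
      mean(vapply(idx, function(j) {
        stats::cor(as.numeric(avg), as.numeric(pool$images[, , , j]))
      }, numeric(1)))
    }, numeric(1))
  })
  mean(cors)
}

#' Contrast-based class separability of a binary dataset
#'
#' Difference between the mean per-image pixel standard deviation of the real
#' class and the average class, in units of the pooled spread of that
#' statistic. Larger values mean the two classes are easier to tell apart;
#' this grows with the difficulty level `k`.
#'
#' @param ds a binary `gain_dataset` (labels 1 = real, 0 = average).
#' @return scalar separation (d-prime-like, on the contrast feature).
#' @export
contrast_separation <- function(ds) {
  sds <- apply(ds$images, 4, stats::sd)
  a <- sds[ds$labels == 1]
  b <- sds[ds$labels == 0]
  (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
}
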