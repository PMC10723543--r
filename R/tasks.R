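#' Generate synthetic base images
#'
#' Renders `n` distinct 32x32 RGB images of colored geometric shapes (disks,
#' rectangles, triangles) over a smooth textured background. These stand in
#' for natural base images so that the task generators run without any
#' external image dataset; `source = "cifar100"` is reserved for a local copy
#' of CIFAR-100 and errors when unavailable.
#'
#' @param n Number of base images (>= 1).
#' @param source `"synthetic"` (default) or `"cifar100"`.
#' @param seed Integer seed; the same seed reproduces the images exactly.
#' @param size Image side length (default 32).
#' @return A `(size, size, 3, n)` array with values in `[0, 1]`.
#' @export
make_base_images <- function(n = 10L, source = c("synthetic", "cifar100"),
                             seed = 1L, size = 32L) {
  source <- match.arg(source)
  check_scalar(n, "n", 1, Inf, integer = TRUE)
  check_scalar(seed, "seed", -2^31, 2^31, integer = TRUE)
  if (source == "cifar100")
    stop("cifar100 source requires a local CIFAR-100 copy, which is not ",
         "bundled; use source = \"synthetic\"", call. = FALSE)
  gx <- matrix(rep(seq(0, 1, length.out = size), size), size)
  gy <- t(gx)
  with_seed(seed, {
    imgs <- array(0, c(size, size, 3, n))
    for (i in seq_len(n)) {
      # textured background: oriented smooth gradient + low-amplitude noise
      base_col <- stats::runif(3, 0.1, 0.9)
      ang <- stats::runif(1, 0, 2 * pi)
      grad <- (cos(ang) * gx + sin(ang) * gy + 1) / 2
      img <- array(0, c(size, size, 3))
      for (ch in 1:3)
        img[, , ch] <- base_col[ch] * (0.6 + 0.4 * grad) +
          matrix(stats::rnorm(size^2, sd = 0.03), size)
      n_shapes <- sample(1:3, 1)
      for (s in seq_len(n_shapes)) {
        col <- stats::runif(3)
        cx <- stats::runif(1, 0.2, 0.8) * size
        cy <- stats::runif(1, 0.2, 0.8) * size
        r <- stats::runif(1, 0.12, 0.3) * size
        kind <- sample(c("disk", "rect", "tri"), 1)
        px <- matrix(rep(seq_len(size), size), size)
        py <- t(px)
        mask <- switch(kind,
          disk = (px - cx)^2 + (py - cy)^2 <= r^2,
          rect = abs(px - cx) <= r & abs(py - cy) <= r * stats::runif(1, 0.5, 1.5),
          tri = (py - cy) >= -r & (py - cy) + 2 * abs(px - cx) <= r)
        for (ch in 1:3)
          img[, , ch][mask] <- 0.75 * col[ch] + 0.25 * img[, , ch][mask]
      }
      imgs[, , , i] <- clip01(img)
    }
    imgs
  })
}

#' Spatial-translation task dataset
#'
#' Each generated image is one of the base images translated by an integer
#' offset `(dx, dy)` drawn uniformly from `[-max_shift_px, max_shift_px]` in
#' both directions, with vacated pixels zero-filled; the label is the index
#' of the base image. Per base image, `n_train_per_base` training and
#' `n_test_per_base` test images are produced (defaults 5000 and 1000, i.e.
#' 50,000 training and 10,000 test images from 10 bases).
#'
#' @param bases `(H, W, 3, P)` array of base images.
#' @param max_shift_px Maximum absolute shift in pixels (default 16; must be
#'   smaller than the image width).
#' @param n_train_per_base,n_test_per_base Images generated per base.
#' @param seed Integer seed.
#' @return A list of class `"task_dataset"` with `train_images`,
#'   `test_images` (`(H, W, 3, n)` arrays), integer `train_labels`,
#'   `test_labels` in `[0, P)`, `base_images`, `task` and `gen_params`.
#' @export
gen_translation_dataset <- function(bases, max_shift_px = 16L,
                                    n_train_per_base = 5000L,
                                    n_test_per_base = 1000L, seed = 1L) {
  d <- dim(bases)
  stop_field(length(d) == 4 && d[3] == 3, "bases",
             "must be an (H, W, 3, P) array")
  check_scalar(max_shift_px, "max_shift_px", 0, Inf, integer = TRUE)
  stop_field(max_shift_px < d[2] && max_shift_px < d[1], "max_shift_px",
             "must be smaller than the image size")
  P <- d[4]
  gen <- function(n_per_base, sub_seed) with_seed(sub_seed, {
    n <- n_per_base * P
    imgs <- array(0, c(d[1], d[2], 3, n))
    labels <- integer(n)
    k <- 0L
    for (p in seq_len(P)) {
      base <- bases[, , , p]
      dx <- sample.int(2L * max_shift_px + 1L, n_per_base, replace = TRUE) -
        max_shift_px - 1L
      dy <- sample.int(2L * max_shift_px + 1L, n_per_base, replace = TRUE) -
        max_shift_px - 1L
      for (j in seq_len(n_per_base)) {
        k <- k + 1L
        imgs[, , , k] <- translate_image(base, dx[j], dy[j])
        labels[k] <- p - 1L
      }
    }
    list(images = imgs, labels = labels)
  })
  tr <- gen(n_train_per_base, derive_seed(seed, 11))
  te <- gen(n_test_per_base, derive_seed(seed, 13))
  structure(list(task = "translation",
                 train_images = tr$images, train_labels = tr$labels,
                 test_images = te$images, test_labels = te$labels,
                 base_images = bases,
                 gen_params = list(max_shift_px = max_shift_px,
                                   n_train_per_base = n_train_per_base,
                                   n_test_per_base = n_test_per_base,
                                   seed = seed)),
            class = "task_dataset")
}

# integer translation with zero fill; dy shifts rows (y), dx shifts columns
translate_image <- function(img, dx, dy) {
  d <- dim(img)
  out <- array(0, d)
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c), ] <- img[src_r[ok_r], src_c[ok_c], ,
                                           drop = FALSE]
  out
}

# vectorized RGB <-> HSV on (H, W, 3) arrays
rgb_to_hsv_arr <- function(img) {
  d <- dim(img)
  m <- grDevices::rgb2hsv(t(matrix(img, ncol = 3)), maxColorValue = 1)
  array(t(m), d)
}

hsv_to_rgb_arr <- function(hsv) {
  d <- dim(hsv)
  h <- as.vector(hsv[, , 1]) * 6
  s <- as.vector(hsv[, , 2]); v <- as.vector(hsv[, , 3])
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), d)
}

# n random color jitters of one base image; magnitudes in [lo, hi] with
# random sign, applied in fixed order: brightness, contrast, saturation,
# hue. Vectorized over images in chunks that bound peak memory; returns
# (H, W, 3, n).
color_jitter_batch <- function(img, n, lo, hi, chunk = 512L) {
  if (n > chunk) {
    d <- dim(img)
    out <- array(0, c(d[1], d[2], 3, n))
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      out[, , , idx] <- color_jitter_chunk(img, length(idx), lo, hi)
    }
    return(out)
  }
  color_jitter_chunk(img, n, lo, hi)
}

color_jitter_chunk <- function(img, n, lo, hi) {
  d <- dim(img)
  npix <- d[1] * d[2]
  mag <- matrix(stats::runif(4 * n, lo, hi), n, 4)
  sgn <- matrix(sample(c(-1, 1), 4 * n, replace = TRUE), n, 4)
  f <- 1 + sgn * mag
  f[, 1:3] <- pmax(f[, 1:3], 0)
  # X: npix x 3 x n
  X <- array(rep(as.vector(img), n), c(npix, 3, n))
  bright <- rep(f[, 1], each = npix * 3)
  X <- clip01(X * array(bright, dim(X)))                  # brightness
  lum_w <- c(0.299, 0.587, 0.114)
  lum <- X[, 1, ] * lum_w[1] + X[, 2, ] * lum_w[2] + X[, 3, ] * lum_w[3]
  lum <- matrix(lum, npix, n)
  gm <- colMeans(lum)                                     # gray mean per image
  gm_full <- array(rep(gm, each = npix * 3), dim(X))
  con <- array(rep(f[, 2], each = npix * 3), dim(X))
  X <- clip01(gm_full + con * (X - gm_full))              # contrast
  lum <- matrix(X[, 1, ] * lum_w[1] + X[, 2, ] * lum_w[2] +
                X[, 3, ] * lum_w[3], npix, n)
  lum3 <- aperm(array(rep(lum, 3), c(npix, n, 3)), c(1, 3, 2))
  sat <- array(rep(f[, 3], each = npix * 3), dim(X))
  X <- clip01(lum3 + sat * (X - lum3))                    # saturation
  # hue: one conversion for the whole batch
  m <- grDevices::rgb2hsv(matrix(aperm(X, c(2, 1, 3)), nrow = 3),
                          maxColorValue = 1)              # 3 x (npix*n)
  shift <- rep(sgn[, 4] * mag[, 4] * 0.5, each = npix)
  m[1, ] <- (m[1, ] + shift) %% 1
  hsv <- aperm(array(t(m), c(npix, n, 3)), c(1, 3, 2))
  out <- clip01(hsv_batch_to_rgb(hsv))
  array(out, c(d[1], d[2], 3, n))
}

# hsv: (npix, 3, n) -> rgb same shape, vectorized
hsv_batch_to_rgb <- function(hsv) {
  h <- as.vector(hsv[, 1, ]) * 6
  s <- as.vector(hsv[, 2, ]); v <- as.vector(hsv[, 3, ])
  i <- floor(h) %% 6
  fr <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - fr * s); t_ <- v * (1 - (1 - fr) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  d <- dim(hsv)
  out <- array(0, d)
  np <- d[1]; n <- d[3]
  out[, 1, ] <- matrix(r, np, n)
  out[, 2, ] <- matrix(g, np, n)
  out[, 3, ] <- matrix(b, np, n)
  out
}

# single-image convenience used by manifold builders
color_jitter_image <- function(img, lo, hi) {
  array(color_jitter_batch(img, 1L, lo, hi), dim(img))
}

#' Color-change task dataset
#'
#' Each generated image applies, in fixed order (brightness, contrast,
#' saturation, hue), a random color change to a base image. The change
#' magnitude `|factor - 1|` (hue: shift as a fraction of the half-turn) is
#' drawn uniformly from `[jitter_lo, jitter_hi]` with a random sign; the
#' defaults 0.5–1.0 correspond to 50–100% changes. Counts and labels follow
#' [gen_translation_dataset()].
#'
#' @inheritParams gen_translation_dataset
#' @param jitter_lo,jitter_hi Magnitude range, `0 <= jitter_lo <= jitter_hi`.
#' @return A `"task_dataset"` (see [gen_translation_dataset()]).
#' @export
gen_color_dataset <- function(bases, jitter_lo = 0.5, jitter_hi = 1.0,
                              n_train_per_base = 5000L,
                              n_test_per_base = 1000L, seed = 1L) {
  d <- dim(bases)
  stop_field(length(d) == 4 && d[3] == 3, "bases",
             "must be an (H, W, 3, P) array")
  check_scalar(jitter_lo, "jitter_lo", 0, Inf)
  check_scalar(jitter_hi, "jitter_hi", jitter_lo, Inf)
  P <- d[4]
  gen <- function(n_per_base, sub_seed) with_seed(sub_seed, {
    n <- n_per_base * P
    imgs <- array(0, c(d[1], d[2], 3, n))
    labels <- integer(n)
    for (p in seq_len(P)) {
      idx <- (p - 1L) * n_per_base + seq_len(n_per_base)
      imgs[, , , idx] <- color_jitter_batch(bases[, , , p], n_per_base,
                                            jitter_lo, jitter_hi)
      labels[idx] <- p - 1L
    }
    list(images = imgs, labels = labels)
  })
  tr <- gen(n_train_per_base, derive_seed(seed, 11))
  te <- gen(n_test_per_base, derive_seed(seed, 13))
  structure(list(task = "color",
                 train_images = tr$images, train_labels = tr$labels,
                 test_images = te$images, test_labels = te$labels,
                 base_images = bases,
                 gen_params = list(jitter_lo = jitter_lo,
                                   jitter_hi = jitter_hi,
                                   order = c("brightness", "contrast",
                                             "saturation", "hue"),
                                   hue_unit = "fraction of half-turn",
                                   n_train_per_base = n_train_per_base,
                                   n_test_per_base = n_test_per_base,
                                   seed = seed)),
            class = "task_dataset")
}

#' Synthetic 10-class classification dataset
#'
#' A stand-in for natural-image classification when no external dataset is
#' available: each class is a distinct synthetic base image (see
#' [make_base_images()]) and samples combine a small random translation with
#' a mild color jitter, so classes overlap in appearance but remain
#' identifiable.
#'
#' @param n_classes Number of classes (default 10).
#' @param n_train_per_class,n_test_per_class Images per class.
#' @param seed Integer seed.
#' @return A `"task_dataset"` with `task = "classification"`.
#' @export
gen_classification_dataset <- function(n_classes = 10L,
                                       n_train_per_class = 500L,
                                       n_test_per_class = 100L, seed = 1L) {
  bases <- make_base_images(n_classes, seed = derive_seed(seed, 3))
  d <- dim(bases)
  gen <- function(n_per, sub_seed) with_seed(sub_seed, {
    n <- n_per * n_classes
    imgs <- array(0, c(d[1], d[2], 3, n))
    labels <- integer(n)
    k <- 0L
    for (p in seq_len(n_classes)) {
      for (j in seq_len(n_per)) {
        k <- k + 1L
        dx <- sample(-4:4, 1); dy <- sample(-4:4, 1)
        img <- translate_image(bases[, , , p], dx, dy)
        imgs[, , , k] <- color_jitter_image(img, 0, 0.25)
        labels[k] <- p - 1L
      }
    }
    list(images = imgs, labels = labels)
  })
  tr <- gen(n_train_per_class, derive_seed(seed, 11))
  te <- gen(n_test_per_class, derive_seed(seed, 13))
  structure(list(task = "classification",
                 train_images = tr$images, train_labels = tr$labels,
                 test_images = te$images, test_labels = te$labels,
                 base_images = bases,
                 gen_params = list(synthetic_standin = TRUE,
                                   n_train_per_class = n_train_per_class,
                                   n_test_per_class = n_test_per_class,
                                   seed = seed)),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> %s: %d train / %d test images, %d classes\n",
              x$task, dim(x$train_images)[4], dim(x$test_images)[4],
              length(unique(x$train_labels))))
  invisible(x)
}
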