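#' @keywords internal
"_PACKAGE"

# Seeds are combined multiplicatively mod a Mersenne prime so that derived
# streams (per-epoch sampling, sub-shuffles, per-ensemble draws) stay inside
# the 32-bit integer range and never collide for small offsets.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 48271 + offset) %% 2147483587 + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lo = -Inf, hi = Inf, integer = FALSE) {
  stop_field(is.numeric(x) && length(x) == 1 && is.finite(x), field,
             "must be a finite numeric scalar")
  stop_field(x >= lo && x <= hi, field,
             sprintf("must be in [%s, %s]", format(lo), format(hi)))
  if (integer) stop_field(x == round(x), field, "must be an integer")
  invisible(x)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Bilinear resize of an H x W matrix to h2 x w2 (align-corners convention;
# degenerate single-row/col targets fall back to midpoint sampling).
resize_bilinear <- function(img, h2, w2) {
  h <- nrow(img); w <- ncol(img)
  if (h == h2 && w == w2) return(img)
  if (h == 1) { img <- img[c(1, 1), , drop = FALSE]; h <- 2 }
  if (w == 1) { img <- img[, c(1, 1), drop = FALSE]; w <- 2 }
  ry <- if (h2 > 1) (seq_len(h2) - 1) * (h - 1) / (h2 - 1) + 1 else (h + 1) / 2
  rx <- if (w2 > 1) (seq_len(w2) - 1) * (w - 1) / (w2 - 1) + 1 else (w + 1) / 2
  y0 <- pmin(floor(ry), h - 1L); x0 <- pmin(floor(rx), w - 1L)
  wy <- ry - y0; wx <- rx - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0 + 1, x0, drop = FALSE]
  c_ <- img[y0, x0 + 1, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  (1 - wy) %o% (1 - wx) * a + wy %o% (1 - wx) * b +
    (1 - wy) %o% wx * c_ + wy %o% wx * d
}
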