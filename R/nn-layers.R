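# Minimal convolutional-network layer toolkit: im2col convolutions, ReLU,
# 2x2 average pooling, global average pooling, dense layers and residual
# blocks, each with an explicit backward pass. Batches are stored as
# (H, W, C, B) arrays; dense activations as (features, B) matrices.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L,
                    tag_block = NULL, tag_relu = NULL) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad,
       W = he_init(c(k, k, in_ch, out_ch), k * k * in_ch),
       b = numeric(out_ch), tag_block = tag_block)
}

nn_relu <- function(tag_block = NULL, tag_relu = NULL) {
  list(type = "relu", tag_block = tag_block, tag_relu = tag_relu)
}

nn_pool_avg <- function(tag_block = NULL) {
  list(type = "pool_avg", tag_block = tag_block)
}

nn_gap <- function(tag_block = NULL) list(type = "gap", tag_block = tag_block)

nn_linear <- function(din, dout, tag_block = NULL) {
  list(type = "linear", din = din, dout = dout,
       W = he_init(c(dout, din), din), b = numeric(dout),
       tag_block = tag_block)
}

nn_resblock <- function(in_ch, out_ch, stride = 1L, tag_block = NULL,
                        tag_relu = NULL) {
  proj <- if (stride != 1L || in_ch != out_ch)
    nn_conv(in_ch, out_ch, k = 1L, stride = stride, pad = 0L) else NULL
  list(type = "resblock",
       conv1 = nn_conv(in_ch, out_ch, stride = stride),
       conv2 = nn_conv(out_ch, out_ch),
       proj = proj, tag_block = tag_block, tag_relu = tag_relu)
}

nn_seq <- function(...) list(type = "seq", layers = list(...))

# --- conv helpers ----------------------------------------------------------

conv_geom <- function(layer, H, W) {
  k <- layer$k; s <- layer$stride; p <- layer$pad
  Ho <- (H + 2 * p - k) %/% s + 1L
  Wo <- (W + 2 * p - k) %/% s + 1L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  C <- layer$in_ch
  Koff <- outer(seq_len(k), Hp * (seq_len(k) - 1L), "+")        # k x k
  Koff <- outer(as.vector(Koff), Hp * Wp * (seq_len(C) - 1L), "+")
  Soff <- outer((seq_len(Ho) - 1L) * s, (seq_len(Wo) - 1L) * s * Hp, "+")
  idx <- outer(as.vector(Koff), as.vector(Soff), "+")           # (kkC) x (HoWo)
  list(Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, idx = as.vector(idx))
}

conv_forward <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  stopifnot(C == layer$in_ch)
  g <- conv_geom(layer, H, W)
  p <- layer$pad
  if (p > 0) {
    xp <- array(0, c(g$Hp, g$Wp, C, B))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x
  } else xp <- x
  kkC <- layer$k^2 * C
  M <- matrix(xp, g$Hp * g$Wp * C, B)[g$idx, , drop = FALSE]
  dim(M) <- c(kkC, g$Ho * g$Wo * B)
  Wmat <- matrix(layer$W, kkC, layer$out_ch)
  out <- crossprod(Wmat, M) + layer$b
  y <- aperm(array(out, c(layer$out_ch, g$Ho, g$Wo, B)), c(2, 3, 1, 4))
  list(out = y, cache = list(M = M, g = g, dims = d))
}

conv_backward <- function(layer, cache, dy) {
  d <- cache$dims; g <- cache$g
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  oc <- layer$out_ch
  dy_mat <- matrix(aperm(dy, c(3, 1, 2, 4)), oc, g$Ho * g$Wo * B)
  db <- rowSums(dy_mat)
  dW_mat <- tcrossprod(dy_mat, cache$M)      # oc x kkC
  dW <- array(t(dW_mat), dim = dim(layer$W))
  Wmat <- matrix(layer$W, k * k * C, oc)
  dM <- Wmat %*% dy_mat                      # kkC x HoWoB
  dM6 <- array(dM, c(k, k, C, g$Ho, g$Wo, B))
  dxp <- array(0, c(g$Hp, g$Wp, C, B))
  rows0 <- s * (seq_len(g$Ho) - 1L)
  cols0 <- s * (seq_len(g$Wo) - 1L)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sl <- aperm(array(dM6[i, j, , , , ], c(C, g$Ho, g$Wo, B)), c(2, 3, 1, 4))
    dxp[i + rows0, j + cols0, , ] <-
      array(dxp[i + rows0, j + cols0, , , drop = FALSE], dim(sl)) + sl
  }
  dx <- if (p > 0) dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
        else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

pool_forward <- function(x) {
  d <- dim(x)
  r1 <- seq(1L, d[1], 2L); r2 <- seq(2L, d[1], 2L)
  c1 <- seq(1L, d[2], 2L); c2 <- seq(2L, d[2], 2L)
  y <- (x[r1, c1, , , drop = FALSE] + x[r2, c1, , , drop = FALSE] +
        x[r1, c2, , , drop = FALSE] + x[r2, c2, , , drop = FALSE]) / 4
  list(out = y, cache = d)
}

pool_backward <- function(cache, dy) {
  d <- cache
  dx <- array(0, d)
  r1 <- seq(1L, d[1], 2L); r2 <- seq(2L, d[1], 2L)
  c1 <- seq(1L, d[2], 2L); c2 <- seq(2L, d[2], 2L)
  q <- dy / 4
  dx[r1, c1, , ] <- q; dx[r2, c1, , ] <- q
  dx[r1, c2, , ] <- q; dx[r2, c2, , ] <- q
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
  list(out = y, cache = d)
}

gap_backward <- function(cache, dy) {
  d <- cache
  array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

# --- generic forward / backward -------------------------------------------

layer_forward <- function(layer, x, policy = NULL) {
  records <- list()
  out <- cache <- NULL
  switch(layer$type,
    conv = { r <- conv_forward(layer, x); out <- r$out; cache <- r$cache },
    relu = { out <- pmax(x, 0); cache <- NULL },
    pool_avg = { r <- pool_forward(x); out <- r$out; cache <- r$cache },
    gap = { r <- gap_forward(x); out <- r$out; cache <- r$cache },
    linear = {
      out <- layer$W %*% x + layer$b
      cache <- list(x = x)
    },
    resblock = {
      r1 <- conv_forward(layer$conv1, x)
      a1 <- pmax(r1$out, 0)
      r2 <- conv_forward(layer$conv2, a1)
      if (!is.null(layer$proj)) {
        rp <- conv_forward(layer$proj, x)
        sk <- rp$out; pcache <- rp$cache
      } else { sk <- x; pcache <- NULL }
      pre <- r2$out + sk
      out <- pmax(pre, 0)
      cache <- list(c1 = r1$cache, a1 = a1, c2 = r2$cache, pc = pcache,
                    mask_out = out > 0, mask_a1 = a1 > 0)
      if (!is.null(policy) && policy == "every-relu" &&
          !is.null(layer$tag_relu))
        records[[paste0(layer$tag_relu, ".relu1")]] <- a1
    },
    seq = {
      caches <- vector("list", length(layer$layers))
      h <- x
      for (i in seq_along(layer$layers)) {
        r <- layer_forward(layer$layers[[i]], h, policy)
        h <- r$out
        caches[[i]] <- r$cache
        records <- c(records, r$records)
        li <- layer$layers[[i]]
        if (!is.null(policy)) {
          if (policy == "per-block" && !is.null(li$tag_block))
            records[[li$tag_block]] <- h
          if (policy == "every-relu" && !is.null(li$tag_relu))
            records[[li$tag_relu]] <- h
        }
      }
      out <- h
      cache <- caches
    },
    stop("unknown layer type: ", layer$type))
  if (layer$type == "relu") cache <- out > 0
  list(out = out, cache = cache, records = records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      r <- conv_backward(layer, cache, dy)
      list(dx = r$dx, grads = r$grads)
    },
    relu = list(dx = dy * cache, grads = NULL),
    pool_avg = list(dx = pool_backward(cache, dy), grads = NULL),
    gap = list(dx = gap_backward(cache, dy), grads = NULL),
    linear = {
      list(dx = crossprod(layer$W, dy),
           grads = list(W = tcrossprod(dy, cache$x), b = rowSums(dy)))
    },
    resblock = {
      dpre <- dy * cache$mask_out
      r2 <- conv_backward(layer$conv2, cache$c2, dpre)
      da1 <- r2$dx * cache$mask_a1
      r1 <- conv_backward(layer$conv1, cache$c1, da1)
      if (!is.null(layer$proj)) {
        rp <- conv_backward(layer$proj, cache$pc, dpre)
        dx <- r1$dx + rp$dx
        grads <- list(conv1 = r1$grads, conv2 = r2$grads, proj = rp$grads)
      } else {
        dx <- r1$dx + dpre
        grads <- list(conv1 = r1$grads, conv2 = r2$grads)
      }
      list(dx = dx, grads = grads)
    },
    seq = {
      n <- length(layer$layers)
      grads <- vector("list", n)
      d <- dy
      for (i in rev(seq_len(n))) {
        r <- layer_backward(layer$layers[[i]], cache[[i]], d)
        d <- r$dx
        grads[i] <- list(r$grads)
      }
      list(dx = d, grads = grads)
    },
    stop("unknown layer type: ", layer$type))
}

# --- parameter flattening --------------------------------------------------

nn_params <- function(mod, prefix = "") {
  out <- list()
  if (mod$type %in% c("conv", "linear")) {
    out[[paste0(prefix, "W")]] <- mod$W
    out[[paste0(prefix, "b")]] <- mod$b
  } else if (mod$type == "resblock") {
    out <- c(out, nn_params(mod$conv1, paste0(prefix, "conv1.")))
    out <- c(out, nn_params(mod$conv2, paste0(prefix, "conv2.")))
    if (!is.null(mod$proj))
      out <- c(out, nn_params(mod$proj, paste0(prefix, "proj.")))
  } else if (mod$type == "seq") {
    for (i in seq_along(mod$layers))
      out <- c(out, nn_params(mod$layers[[i]], paste0(prefix, i, ".")))
  }
  out
}

nn_set_params <- function(mod, flat, prefix = "") {
  if (mod$type %in% c("conv", "linear")) {
    mod$W <- flat[[paste0(prefix, "W")]]
    mod$b <- flat[[paste0(prefix, "b")]]
  } else if (mod$type == "resblock") {
    mod$conv1 <- nn_set_params(mod$conv1, flat, paste0(prefix, "conv1."))
    mod$conv2 <- nn_set_params(mod$conv2, flat, paste0(prefix, "conv2."))
    if (!is.null(mod$proj))
      mod$proj <- nn_set_params(mod$proj, flat, paste0(prefix, "proj."))
  } else if (mod$type == "seq") {
    for (i in seq_along(mod$layers))
      mod$layers[[i]] <- nn_set_params(mod$layers[[i]], flat,
                                       paste0(prefix, i, "."))
  }
  mod
}

# grads come back in the same nested shape as the module; flatten to match
# nn_params naming
nn_flatten_grads <- function(mod, grads, prefix = "") {
  out <- list()
  if (mod$type %in% c("conv", "linear")) {
    out[[paste0(prefix, "W")]] <- grads$W
    out[[paste0(prefix, "b")]] <- grads$b
  } else if (mod$type == "resblock") {
    out <- c(out, nn_flatten_grads(mod$conv1, grads$conv1,
                                   paste0(prefix, "conv1.")))
    out <- c(out, nn_flatten_grads(mod$conv2, grads$conv2,
                                   paste0(prefix, "conv2.")))
    if (!is.null(mod$proj))
      out <- c(out, nn_flatten_grads(mod$proj, grads$proj,
                                     paste0(prefix, "proj.")))
  } else if (mod$type == "seq") {
    for (i in seq_along(mod$layers))
      if (!is.null(grads[[i]]))
        out <- c(out, nn_flatten_grads(mod$layers[[i]], grads[[i]],
                                       paste0(prefix, i, ".")))
  }
  out
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
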