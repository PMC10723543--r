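#' Encoder architecture specification
#'
#' Two backbones are available: `"tiny-conv"`, four 3x3 convolution + ReLU +
#' 2x2 average-pool blocks followed by global average pooling (used for
#' desk-scale runs and tests), and `"resnet18-like"`, an 18-layer residual
#' convnet (3x3 stem plus eight basic blocks in four stages of widths
#' 64/128/256/512, He-initialized, without normalization layers). The
#' projector is always a 3-stage multilayer perceptron applied to the
#' backbone embedding during contrastive pre-training and removed for task
#' evaluation.
#'
#' @param backbone `"tiny-conv"` or `"resnet18-like"`.
#' @param input_size Integer `c(H, W, C)` of encoder inputs; channels must
#'   be 1 or 3.
#' @param projector_dims Three positive integers, the widths of the
#'   projector stages (default `c(64, 64, 64)`; the full-scale value is
#'   `c(8192, 8192, 8192)`).
#' @param channels For `tiny-conv`, the four block widths; the last is the
#'   embedding dimension. Ignored for `resnet18-like` (embedding 512).
#' @return A list of class `"encoder_spec"`.
#' @export
encoder_spec <- function(backbone = c("tiny-conv", "resnet18-like"),
                         input_size = c(32, 32, 3),
                         projector_dims = c(64, 64, 64),
                         channels = c(16, 32, 64, 64)) {
  backbone <- match.arg(backbone)
  stop_field(length(input_size) == 3 && all(input_size >= 1), "input_size",
             "must be c(H, W, C)")
  stop_field(input_size[3] %in% c(1, 3), "input_size",
             "channel count must be 1 or 3")
  stop_field(length(projector_dims) == 3 && all(projector_dims >= 1),
             "projector_dims", "projector has exactly 3 linear stages")
  if (backbone == "tiny-conv") {
    stop_field(length(channels) == 4 && all(channels >= 1), "channels",
               "tiny-conv has exactly 4 conv blocks")
    stop_field(input_size[1] %% 16 == 0 && input_size[2] %% 16 == 0,
               "input_size", "tiny-conv needs H and W divisible by 16")
    embedding_dim <- channels[4]
  } else {
    embedding_dim <- 512L
  }
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 projector_dims = as.integer(projector_dims),
                 channels = as.integer(channels),
                 embedding_dim = as.integer(embedding_dim)),
            class = "encoder_spec")
}

#' Initialize an encoder
#'
#' Builds the backbone and projector with He (fan-in) random initialization.
#' The same constructor with training skipped is the random-initialized
#' control condition.
#'
#' @param spec An [encoder_spec()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `"wave_encoder"`.
#' @export
init_encoder <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "encoder_spec"))
  check_scalar(seed, "seed", -2^31, 2^31, integer = TRUE)
  with_seed(seed, {
    C <- spec$input_size[3]
    if (spec$backbone == "tiny-conv") {
      ch <- spec$channels
      backbone <- nn_seq(
        nn_conv(C, ch[1]), nn_relu(tag_relu = "relu1"),
        nn_pool_avg(tag_block = "block1"),
        nn_conv(ch[1], ch[2]), nn_relu(tag_relu = "relu2"),
        nn_pool_avg(tag_block = "block2"),
        nn_conv(ch[2], ch[3]), nn_relu(tag_relu = "relu3"),
        nn_pool_avg(tag_block = "block3"),
        nn_conv(ch[3], ch[4]), nn_relu(tag_relu = "relu4"),
        nn_pool_avg(tag_block = "block4"),
        nn_gap(tag_block = "embedding"))
    } else {
      widths <- c(64, 64, 128, 256, 512)
      layers <- list(nn_conv(C, 64),
                     nn_relu(tag_block = "stem", tag_relu = "stem"))
      bi <- 0L
      for (stage in 1:4) {
        for (rep in 1:2) {
          bi <- bi + 1L
          in_ch <- if (rep == 1) widths[stage] else widths[stage + 1]
          stride <- if (rep == 1 && stage > 1) 2L else 1L
          layers <- c(layers, list(
            nn_resblock(in_ch, widths[stage + 1], stride = stride,
                        tag_block = paste0("block", bi),
                        tag_relu = paste0("block", bi))))
        }
      }
      layers <- c(layers, list(nn_gap()))
      backbone <- do.call(nn_seq, layers)
    }
    pd <- spec$projector_dims
    projector <- nn_seq(
      nn_linear(spec$embedding_dim, pd[1]), nn_relu(),
      nn_linear(pd[1], pd[2]), nn_relu(),
      nn_linear(pd[2], pd[3]))
    structure(list(spec = spec, backbone = backbone, projector = projector,
                   seed = as.integer(seed)),
              class = "wave_encoder")
  })
}

#' @export
print.wave_encoder <- function(x, ...) {
  np <- sum(vapply(encoder_params(x), length, integer(1)))
  cat(sprintf("<wave_encoder> %s, input %s, embedding %d, projector %s (%d parameters)\n",
              x$spec$backbone, paste(x$spec$input_size, collapse = "x"),
              x$spec$embedding_dim,
              paste(x$spec$projector_dims, collapse = "x"), np))
  invisible(x)
}

#' Flattened encoder parameters
#'
#' @param encoder A [init_encoder()] object.
#' @return Named list of weight arrays (backbone and projector).
#' @export
encoder_params <- function(encoder) {
  c(nn_params(encoder$backbone, "backbone."),
    nn_params(encoder$projector, "projector."))
}

encoder_set_params <- function(encoder, flat) {
  encoder$backbone <- nn_set_params(encoder$backbone, flat, "backbone.")
  encoder$projector <- nn_set_params(encoder$projector, flat, "projector.")
  encoder
}

# images: (H, W, C, B) -> backbone embedding (E x B); with_projector adds the
# projector head. Returns caches when `train = TRUE`.
encoder_forward <- function(encoder, x, with_projector = FALSE,
                            train = FALSE, policy = NULL) {
  fb <- layer_forward(encoder$backbone, x, policy = policy)
  emb <- fb$out
  out <- emb
  fp <- NULL
  if (with_projector) {
    fp <- layer_forward(encoder$projector, emb)
    out <- fp$out
  }
  if (train || !is.null(policy))
    list(out = out, embedding = emb, cache_b = fb$cache,
         cache_p = if (with_projector) fp$cache, records = fb$records)
  else list(out = out, embedding = emb)
}

#' Embed a batch of images with a frozen encoder
#'
#' Runs the backbone (projector removed) in inference mode, in chunks.
#'
#' @param encoder A [init_encoder()] object (possibly pre-trained).
#' @param images `(H, W, C, n)` array.
#' @param chunk Number of images per forward chunk.
#' @return An `n x embedding_dim` matrix.
#' @export
encode_images <- function(encoder, images, chunk = 256L) {
  stopifnot(inherits(encoder, "wave_encoder"))
  d <- dim(images)
  stop_field(length(d) == 4, "images", "must be (H, W, C, n)")
  stop_field(all(d[1:3] == encoder$spec$input_size), "images",
             sprintf("size %s does not match encoder input %s",
                     paste(d[1:3], collapse = "x"),
                     paste(encoder$spec$input_size, collapse = "x")))
  n <- d[4]
  out <- matrix(0, n, encoder$spec$embedding_dim)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fb <- encoder_forward(encoder, images[, , , idx, drop = FALSE])
    out[idx, ] <- t(fb$embedding)
  }
  out
}
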