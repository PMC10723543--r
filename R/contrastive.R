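#' Pre-training configuration
#'
#' @param learning_rate Adam learning rate (default `1e-4`).
#' @param epochs Number of passes over all wave events (default 100; 0 skips
#'   training, which is the random-initialized control).
#' @param batch_frame_threshold Whole wave events are sampled without
#'   replacement into a batch until the cumulative frame count exceeds this
#'   threshold (default 3000).
#' @param temperature_tau SimCLR temperature (default 0.5).
#' @param pair_gap Temporal lag defining positive pairs: frame `t` is paired
#'   with frame `t + pair_gap` of the same wave event (default 1, i.e.
#'   consecutive frames).
#' @param seed Integer seed controlling initialization and event sampling.
#' @param chunk Frames per forward/backward chunk (memory control).
#' @return A list of class `"pretrain_config"`.
#' @export
pretrain_config <- function(learning_rate = 1e-4, epochs = 100L,
                            batch_frame_threshold = 3000L,
                            temperature_tau = 0.5, pair_gap = 1L,
                            seed = 0L, chunk = 128L) {
  check_scalar(learning_rate, "learning_rate", 1e-12, Inf)
  check_scalar(epochs, "epochs", 0, Inf, integer = TRUE)
  check_scalar(batch_frame_threshold, "batch_frame_threshold", 1, Inf,
               integer = TRUE)
  check_scalar(temperature_tau, "temperature_tau", 1e-12, Inf)
  check_scalar(pair_gap, "pair_gap", 1, Inf, integer = TRUE)
  check_scalar(seed, "seed", -2^31, 2^31, integer = TRUE)
  check_scalar(chunk, "chunk", 1, Inf, integer = TRUE)
  structure(as.list(environment()), class = "pretrain_config")
}

#' Assemble contrastive batches from wave events
#'
#' Per epoch, whole wave events are sampled without replacement into batches:
#' events are added to the current batch until its cumulative frame count
#' exceeds `cfg$batch_frame_threshold`, then a new batch is started, so every
#' event appears exactly once per epoch. Within a batch, frame `t` of an
#' event has frame `t + pair_gap` of the same event as positive partner (the
#' last `pair_gap` frames of each event have none, encoded as `NA`), and all
#' frames of other events are its negatives.
#'
#' @param movie A [wave_movie()] (used for validation only; batches reference
#'   frames by index).
#' @param events A [wave_events()] table with at least 2 events.
#' @param cfg A [pretrain_config()].
#' @param epoch Epoch index (changes the event sampling deterministically).
#' @return A list of batches; each batch is a list with `frame_idx` (1-based
#'   movie frame indices), `event_id`, `positive_index` (`NA` sentinel for
#'   anchors without a positive) and the `B x B` logical `negative_mask`.
#' @export
assemble_batches <- function(movie, events, cfg, epoch = 1L) {
  stopifnot(inherits(events, "wave_events"), inherits(cfg, "pretrain_config"))
  if (nrow(events) < 2)
    stop("need at least 2 wave events to form contrastive batches",
         call. = FALSE)
  if (!is.null(movie)) {
    stopifnot(inherits(movie, "wave_movie"))
    stop_field(max(events$end_frame) <= dim(movie$frames)[1], "events",
               "events exceed movie length")
  }
  lens <- event_lengths(events)
  ord <- with_seed(derive_seed(cfg$seed, 7919 * epoch),
                   sample.int(nrow(events)))
  batches <- list()
  cur <- integer(0); cum <- 0L
  flush <- function(ev_ids) {
    frame_idx <- integer(0); event_id <- integer(0); pos <- integer(0)
    for (e in ev_ids) {
      fr <- event_frame_idx(events, e)
      n <- length(fr)
      base <- length(frame_idx)
      frame_idx <- c(frame_idx, fr)
      event_id <- c(event_id, rep(e, n))
      p <- rep(NA_integer_, n)
      if (n > cfg$pair_gap)
        p[seq_len(n - cfg$pair_gap)] <- base + seq_len(n - cfg$pair_gap) +
          cfg$pair_gap
      pos <- c(pos, p)
    }
    list(frame_idx = frame_idx, event_id = event_id, positive_index = pos,
         negative_mask = outer(event_id, event_id, "!="))
  }
  for (e in ord) {
    cur <- c(cur, e); cum <- cum + lens[e]
    if (cum > cfg$batch_frame_threshold) {
      batches[[length(batches) + 1L]] <- flush(cur)
      cur <- integer(0); cum <- 0L
    }
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- flush(cur)
  batches
}

# loss and gradient w.r.t. the (unnormalized) embedding rows
ntxent_loss_grad <- function(Z, batch, tau, grad = TRUE) {
  B <- nrow(Z)
  stopifnot(length(batch$event_id) == B)
  anchors <- which(!is.na(batch$positive_index))
  if (!length(anchors))
    stop("degenerate batch: no anchor has a positive partner", call. = FALSE)
  norms <- sqrt(rowSums(Z^2))
  norms[norms < 1e-12] <- 1e-12
  U <- Z / norms
  S <- tcrossprod(U)
  nA <- length(anchors)
  pos <- batch$positive_index[anchors]
  allowed <- batch$negative_mask[anchors, , drop = FALSE]
  allowed[cbind(seq_len(nA), pos)] <- TRUE
  logits <- S[anchors, , drop = FALSE] / tau
  logits[!allowed] <- -Inf
  m <- apply(logits, 1, max)
  E <- exp(logits - m)
  E[!allowed] <- 0
  denom <- rowSums(E)
  pos_logit <- logits[cbind(seq_len(nA), pos)]
  loss <- mean(m + log(denom) - pos_logit)
  if (!grad) return(list(loss = loss))
  soft <- E / denom
  soft[cbind(seq_len(nA), pos)] <- soft[cbind(seq_len(nA), pos)] - 1
  dS <- matrix(0, B, B)
  dS[anchors, ] <- soft / (tau * nA)
  dU <- (dS + t(dS)) %*% U
  dZ <- (dU - U * rowSums(dU * U)) / norms
  list(loss = loss, dZ = dZ)
}

#' Temporal NT-Xent contrastive loss
#'
#' The SimCLR objective with temporal positive pairs: embeddings are
#' length-normalized and, for each anchor `i` with positive partner `p(i)`,
#' the per-anchor term is
#' `-log( exp(sim(i,p)/tau) / (exp(sim(i,p)/tau) + sum_j exp(sim(i,j)/tau)) )`
#' with cosine similarity `sim` and the sum running over the anchor's
#' negatives (frames of other wave events). Same-event non-positive frames
#' appear in neither numerator nor denominator. The loss is the mean over
#' anchors that have a positive.
#'
#' @param embeddings `B x E` matrix, rows aligned with the batch.
#' @param batch A batch from [assemble_batches()].
#' @param tau Positive temperature.
#' @return Nonnegative scalar loss.
#' @export
temporal_ntxent_loss <- function(embeddings, batch, tau = 0.5) {
  check_scalar(tau, "tau", 1e-12, Inf)
  ntxent_loss_grad(as.matrix(embeddings), batch, tau, grad = FALSE)$loss
}

# movie frames -> (H, W, C, T) array matched to the encoder input:
# per-movie min-max normalization, bilinear resize, channel replication
preprocess_movie <- function(movie, input_size) {
  fr <- movie$frames
  rng <- range(fr)
  if (rng[2] > rng[1]) fr <- (fr - rng[1]) / (rng[2] - rng[1])
  TT <- dim(fr)[1]
  H <- input_size[1]; W <- input_size[2]; C <- input_size[3]
  out <- array(0, c(H, W, C, TT))
  for (t in seq_len(TT)) {
    f <- resize_bilinear(matrix(fr[t, , ], dim(fr)[2], dim(fr)[3]), H, W)
    for (ch in seq_len(C)) out[, , ch, t] <- f
  }
  out
}

#' Pre-train an encoder on a wave movie
#'
#' Optimizes the temporal NT-Xent objective over wave-event batches with
#' Adam. With `cfg$epochs = 0` the returned weights equal the fresh
#' He-initialized weights (the random-initialized control).
#'
#' @param movie A [wave_movie()].
#' @param events A [wave_events()] table for `movie`.
#' @param spec An [encoder_spec()].
#' @param cfg A [pretrain_config()].
#' @param verbose Print a line per epoch.
#' @return A `"wave_encoder"` whose `$history` data frame logs
#'   `(epoch, mean_loss)`.
#' @export
pretrain_encoder <- function(movie, events, spec, cfg = pretrain_config(),
                             verbose = FALSE) {
  stopifnot(inherits(movie, "wave_movie"), inherits(spec, "encoder_spec"),
            inherits(cfg, "pretrain_config"))
  encoder <- init_encoder(spec, seed = cfg$seed)
  if (cfg$epochs == 0L) {
    encoder$history <- data.frame(epoch = integer(0), mean_loss = numeric(0))
    return(encoder)
  }
  if (nrow(events) < 2)
    stop("need at least 2 wave events for pre-training", call. = FALSE)
  if (all(event_lengths(events) <= cfg$pair_gap))
    stop("pair_gap is not smaller than any event length", call. = FALSE)
  x_all <- preprocess_movie(movie, spec$input_size)
  params <- encoder_params(encoder)
  adam <- adam_init(params)
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    batches <- assemble_batches(movie, events, cfg, epoch = epoch)
    losses <- numeric(0)
    for (batch in batches) {
      if (all(is.na(batch$positive_index))) next
      idx <- batch$frame_idx
      B <- length(idx)
      # pass 1: embeddings only
      Z <- matrix(0, B, spec$projector_dims[3])
      for (start in seq(1L, B, by = cfg$chunk)) {
        ci <- start:min(start + cfg$chunk - 1L, B)
        f <- encoder_forward(encoder, x_all[, , , idx[ci], drop = FALSE],
                             with_projector = TRUE)
        Z[ci, ] <- t(f$out)
      }
      lg <- ntxent_loss_grad(Z, batch, cfg$temperature_tau)
      if (!is.finite(lg$loss))
        stop(sprintf(
          "non-finite contrastive loss at epoch %d (batch of %d frames)",
          epoch, B), call. = FALSE)
      losses <- c(losses, lg$loss)
      # pass 2: chunked backward, gradients accumulate across chunks
      gacc <- NULL
      for (start in seq(1L, B, by = cfg$chunk)) {
        ci <- start:min(start + cfg$chunk - 1L, B)
        f <- encoder_forward(encoder, x_all[, , , idx[ci], drop = FALSE],
                             with_projector = TRUE, train = TRUE)
        dZ <- t(lg$dZ[ci, , drop = FALSE])
        bp <- layer_backward(encoder$projector, f$cache_p, dZ)
        bb <- layer_backward(encoder$backbone, f$cache_b, bp$dx)
        g <- c(nn_flatten_grads(encoder$backbone, bb$grads, "backbone."),
               nn_flatten_grads(encoder$projector, bp$grads, "projector."))
        gacc <- if (is.null(gacc)) g
                else stats::setNames(Map(`+`, gacc, g[names(gacc)]),
                                     names(gacc))
      }
      st <- adam_step(adam, params, gacc, cfg$learning_rate)
      adam <- st$state; params <- st$params
      encoder <- encoder_set_params(encoder, params)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, mean_loss = mean(losses)))
    if (verbose)
      message(sprintf("epoch %d/%d: mean loss %.4f", epoch, cfg$epochs,
                      mean(losses)))
  }
  encoder$history <- history
  encoder
}
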