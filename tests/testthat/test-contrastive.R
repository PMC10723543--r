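make_events <- function(lens) {
  ends <- cumsum(lens + 2L)
  starts <- ends - lens
  wave_events(starts, ends)
}

test_that("batch assembly samples whole events up to the frame threshold", {
  cfg <- pretrain_config(batch_frame_threshold = 3000L, seed = 1L)
  ev <- make_events(c(5L, 4L, 3L))
  b <- assemble_batches(NULL, ev, cfg)
  expect_length(b, 1)
  expect_length(b[[1]]$frame_idx, 12)

  ev2 <- make_events(c(2000L, 1500L, 1500L))
  b2 <- assemble_batches(NULL, ev2, cfg)
  expect_length(b2, 2)
  expect_equal(length(unique(b2[[1]]$event_id)), 2)  # stops after crossing
  expect_gt(length(b2[[1]]$frame_idx), 3000)
})

test_that("anchors with positives count len - pair_gap per included event", {
  for (gap in c(1L, 2L)) {
    cfg <- pretrain_config(batch_frame_threshold = 50L, pair_gap = gap,
                           seed = 3L)
    ev <- make_events(c(7L, 9L, 4L, 12L))
    for (b in assemble_batches(NULL, ev, cfg)) {
      lens <- table(b$event_id)
      expected <- sum(pmax(as.integer(lens) - gap, 0))
      expect_equal(sum(!is.na(b$positive_index)), expected)
      # positives point pair_gap ahead within the same event
      a <- which(!is.na(b$positive_index))
      expect_true(all(b$event_id[b$positive_index[a]] == b$event_id[a]))
    }
  }
})

test_that("every event appears exactly once per epoch across batches", {
  cfg <- pretrain_config(batch_frame_threshold = 40L, seed = 2L)
  ev <- make_events(c(11L, 7L, 19L, 5L, 9L, 13L))
  for (epoch in 1:3) {
    b <- assemble_batches(NULL, ev, cfg, epoch = epoch)
    seen <- sort(unlist(lapply(b, function(x) unique(x$event_id))))
    expect_equal(seen, seq_len(nrow(ev)))
    total <- sum(vapply(b, function(x) length(x$frame_idx), integer(1)))
    expect_equal(total, sum(event_lengths(ev)))
  }
  expect_identical(assemble_batches(NULL, ev, cfg, epoch = 1),
                   assemble_batches(NULL, ev, cfg, epoch = 1))
})

test_that("negative masks exclude all same-event frames", {
  cfg <- pretrain_config(batch_frame_threshold = 30L, seed = 4L)
  ev <- make_events(c(6L, 8L, 5L))
  for (b in assemble_batches(NULL, ev, cfg)) {
    expect_identical(b$negative_mask, outer(b$event_id, b$event_id, "!="))
    expect_false(any(diag(b$negative_mask)))
    expect_true(isSymmetric(b$negative_mask))
  }
})

test_that("contrastive loss matches the stated formula in closed cases", {
  # anchor with a positive and no valid negatives: -log(1) = 0
  b0 <- list(event_id = c(1L, 1L), positive_index = c(2L, NA),
             negative_mask = matrix(FALSE, 2, 2))
  Z0 <- rbind(c(1, 0.2), c(0.4, 1))
  expect_equal(temporal_ntxent_loss(Z0, b0, tau = 0.7), 0)

  # anchor equal to its positive, orthogonal to one negative, tau = 1
  b1 <- list(event_id = c(1L, 1L, 2L), positive_index = c(2L, NA, NA),
             negative_mask = outer(c(1L, 1L, 2L), c(1L, 1L, 2L), "!="))
  Z1 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(temporal_ntxent_loss(Z1, b1, tau = 1),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-10)

  # degenerate batch rejected
  b2 <- list(event_id = c(1L, 2L), positive_index = c(NA, NA),
             negative_mask = outer(1:2, 1:2, "!="))
  expect_error(temporal_ntxent_loss(diag(2), b2), "degenerate")
})

test_that("loss is nonnegative and invariant under common rotation", {
  withr::with_seed(11, {
    B <- 12
    eid <- rep(1:3, each = 4)
    pos <- ifelse(seq_len(B) %% 4 == 0, NA_integer_, seq_len(B) + 1L)
    b <- list(event_id = eid, positive_index = pos,
              negative_mask = outer(eid, eid, "!="))
    Z <- matrix(rnorm(B * 7), B)
    l1 <- temporal_ntxent_loss(Z, b, tau = 0.5)
    expect_gte(l1, 0)
    Q <- random_orthogonal(7, seed = 2)
    expect_equal(temporal_ntxent_loss(Z %*% Q, b, tau = 0.5), l1,
                 tolerance = 1e-10)
  })
})

test_that("analytic gradients agree with finite differences", {
  withr::with_seed(3, {
    eid <- c(1L, 1L, 1L, 2L, 2L)
    b <- list(event_id = eid, positive_index = c(2L, 3L, NA, 5L, NA),
              negative_mask = outer(eid, eid, "!="))
    Z <- matrix(rnorm(5 * 4), 5)
    lg <- ntxent_loss_grad(Z, b, tau = 0.5)
    eps <- 1e-6
    for (k in sample(length(Z), 8)) {
      Zp <- Z; Zp[k] <- Zp[k] + eps
      Zm <- Z; Zm[k] <- Zm[k] - eps
      fd <- (temporal_ntxent_loss(Zp, b, 0.5) -
             temporal_ntxent_loss(Zm, b, 0.5)) / (2 * eps)
      expect_equal(lg$dZ[k], fd, tolerance = 1e-5)
    }
  })
})

test_that("backprop through the conv encoder matches finite differences", {
  spec <- tiny_spec(channels = c(2, 2, 2, 3), projector = c(4, 4, 4))
  enc <- init_encoder(spec, seed = 1)
  withr::with_seed(5, {
    B <- 4
    x <- array(runif(32 * 32 * 3 * B), c(32, 32, 3, B))
    eid <- c(1L, 1L, 2L, 2L)
    b <- list(event_id = eid, positive_index = c(2L, NA, 4L, NA),
              negative_mask = outer(eid, eid, "!="))
    lossfun <- function(e) {
      f <- encoder_forward(e, x, with_projector = TRUE)
      temporal_ntxent_loss(t(f$out), b, 0.5)
    }
    f <- encoder_forward(enc, x, with_projector = TRUE, train = TRUE)
    lg <- ntxent_loss_grad(t(f$out), b, 0.5)
    bp <- layer_backward(enc$projector, f$cache_p, t(lg$dZ))
    bb <- layer_backward(enc$backbone, f$cache_b, bp$dx)
    g <- c(nn_flatten_grads(enc$backbone, bb$grads, "backbone."),
           nn_flatten_grads(enc$projector, bp$grads, "projector."))
    params <- encoder_params(enc)
    eps <- 1e-5
    for (nm in c("backbone.1.W", "backbone.7.W", "projector.3.W",
                 "projector.5.b")) {
      for (k in sample(length(params[[nm]]), 2)) {
        p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + eps
        p3 <- params; p3[[nm]][k] <- p3[[nm]][k] - eps
        fd <- (lossfun(encoder_set_params(enc, p2)) -
               lossfun(encoder_set_params(enc, p3))) / (2 * eps)
        expect_equal(g[[nm]][k], fd, tolerance = 5e-3)
      }
    }
  })
})

test_that("epochs = 0 returns freshly initialized weights", {
  fx <- tiny_wave_fixture()
  spec <- tiny_spec()
  cfg <- pretrain_config(epochs = 0L, seed = 42L)
  enc <- pretrain_encoder(fx$movie, fx$events, spec, cfg)
  expect_identical(encoder_params(enc),
                   encoder_params(init_encoder(spec, seed = 42L)))
  expect_equal(nrow(enc$history), 0)
})

test_that("pre-training is reproducible and the loss descends", {
  fx <- tiny_wave_fixture()
  spec <- tiny_spec(channels = c(3, 4, 5, 6), projector = c(8, 8, 8))
  cfg <- pretrain_config(learning_rate = 1e-3, epochs = 3L,
                         batch_frame_threshold = 120L, seed = 1L)
  e1 <- pretrain_encoder(fx$movie, fx$events, spec, cfg)
  e2 <- pretrain_encoder(fx$movie, fx$events, spec, cfg)
  expect_identical(encoder_params(e1), encoder_params(e2))
  expect_equal(e1$history$epoch, 1:3)
  # descent over 3 seeds, majority
  wins <- 0
  for (s in 1:3) {
    cfg$seed <- s
    h <- pretrain_encoder(fx$movie, fx$events, spec, cfg)$history
    if (h$mean_loss[3] <= h$mean_loss[1]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("pre-training raises within-event over cross-event similarity", {
  fx <- tiny_wave_fixture()
  spec <- tiny_spec(channels = c(3, 4, 5, 6), projector = c(8, 8, 8))
  wins <- 0
  for (s in 1:3) {
    cfg <- pretrain_config(learning_rate = 1e-3, epochs = 4L,
                           batch_frame_threshold = 120L, seed = s)
    enc <- pretrain_encoder(fx$movie, fx$events, spec, cfg)
    x <- preprocess_movie(fx$movie, spec$input_size)
    idx <- unlist(lapply(seq_len(nrow(fx$events)),
                         function(i) event_frame_idx(fx$events, i)))
    eid <- rep(seq_len(nrow(fx$events)), event_lengths(fx$events))
    E <- encode_images(enc, x[, , , idx, drop = FALSE])
    U <- E / sqrt(rowSums(E^2))
    S <- tcrossprod(U)
    consec <- which(diff(eid) == 0)
    within <- mean(S[cbind(consec, consec + 1)])
    cross <- mean(S[outer(eid, eid, "!=")])
    if (within > cross) wins <- wins + 1
  }
  expect_gte(wins, 2)
})
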