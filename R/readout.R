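#' Train a linear readout on frozen encoder features
#'
#' Replaces the projector with a single `embedding_dim x n_classes` linear
#' layer trained by minibatch cross-entropy with Adam while the encoder
#' weights stay fixed (features are extracted once through the frozen
#' backbone). Defaults follow the evaluation protocol: 100 epochs, batch
#' size 100, learning rate `1e-4`.
#'
#' @param encoder A `"wave_encoder"` (pre-trained or freshly initialized).
#' @param dataset A `"task_dataset"`.
#' @param lr Learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed (readout init and batch shuffling).
#' @return A list of class `"readout_result"` with `test_accuracy`,
#'   `train_accuracy`, `per_class_accuracy`, the readout weights and the
#'   seed.
#' @export
train_linear_readout <- function(encoder, dataset, lr = 1e-4, epochs = 100L,
                                 batch_size = 100L, seed = 0L) {
  stopifnot(inherits(encoder, "wave_encoder"),
            inherits(dataset, "task_dataset"))
  check_scalar(lr, "lr", 1e-12, Inf)
  check_scalar(epochs, "epochs", 1, Inf, integer = TRUE)
  check_scalar(batch_size, "batch_size", 1, Inf, integer = TRUE)
  feats_tr <- encode_images(encoder, dataset$train_images)
  feats_te <- encode_images(encoder, dataset$test_images)
  # z-score features with training statistics so the readout optimization is
  # comparable across encoders with very different feature scales
  mu <- colMeans(feats_tr)
  sdv <- apply(feats_tr, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  feats_tr <- sweep(sweep(feats_tr, 2, mu), 2, sdv, "/")
  feats_te <- sweep(sweep(feats_te, 2, mu), 2, sdv, "/")
  fit_linear_softmax(feats_tr, dataset$train_labels, feats_te,
                     dataset$test_labels, lr = lr, epochs = epochs,
                     batch_size = batch_size, seed = seed)
}

# multinomial logistic regression on fixed features, minibatch Adam
fit_linear_softmax <- function(feats_tr, y_tr, feats_te, y_te, lr = 1e-4,
                               epochs = 100L, batch_size = 100L, seed = 0L) {
  classes <- sort(unique(c(y_tr, y_te)))
  K <- length(classes)
  ytr_i <- match(y_tr, classes)
  yte_i <- match(y_te, classes)
  E <- ncol(feats_tr)
  n <- nrow(feats_tr)
  with_seed(derive_seed(seed, 17), {
    W <- matrix(stats::rnorm(K * E, sd = sqrt(2 / E)), K, E)
    b <- numeric(K)
    params <- list(W = W, b = b)
    adam <- adam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        X <- t(feats_tr[idx, , drop = FALSE])        # E x B
        logits <- params$W %*% X + params$b          # K x B
        logits <- sweep(logits, 2, apply(logits, 2, max))
        Pm <- exp(logits)
        Pm <- sweep(Pm, 2, colSums(Pm), "/")
        Ym <- matrix(0, K, length(idx))
        Ym[cbind(ytr_i[idx], seq_along(idx))] <- 1
        dlogits <- (Pm - Ym) / length(idx)
        grads <- list(W = tcrossprod(dlogits, X), b = rowSums(dlogits))
        st <- adam_step(adam, params, grads, lr)
        adam <- st$state; params <- st$params
      }
    }
    pred <- function(feats) {
      logits <- params$W %*% t(feats) + params$b
      classes[max.col(t(logits), ties.method = "first")]
    }
    pr_tr <- pred(feats_tr)
    pr_te <- pred(feats_te)
    per_class <- vapply(classes, function(k) {
      mean(pr_te[y_te == k] == k)
    }, numeric(1))
    names(per_class) <- classes
    structure(list(test_accuracy = mean(pr_te == y_te),
                   train_accuracy = mean(pr_tr == y_tr),
                   per_class_accuracy = per_class,
                   weights = params, seed = seed),
              class = "readout_result")
  })
}

#' @export
print.readout_result <- function(x, ...) {
  cat(sprintf("<readout_result> test accuracy %.3f (train %.3f)\n",
              x$test_accuracy, x$train_accuracy))
  invisible(x)
}
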