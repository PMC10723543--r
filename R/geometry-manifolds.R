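#' Extract layerwise activations
#'
#' Runs images through the encoder in inference mode and returns flattened
#' activations per layer, ordered input to output, beginning with the raw
#' pixels as layer `"pixels"`. Layers wider than `max_N` features are
#' reduced by a seeded Gaussian random projection (recorded in the result's
#' `"projection"` attribute), which preserves the geometry relevant to
#' capacity analysis while bounding memory.
#'
#' @param encoder A `"wave_encoder"`.
#' @param images `(H, W, C, n)` array.
#' @param layer_policy `"per-block"` (default; block outputs) or
#'   `"every-relu"`.
#' @param max_N Feature cap per layer (default 2000).
#' @param proj_seed Seed for the random projections.
#' @param chunk Images per forward chunk.
#' @return Named list of `n x N` matrices, `"pixels"` first.
#' @export
extract_activations <- function(encoder, images,
                                layer_policy = c("per-block", "every-relu"),
                                max_N = 2000L, proj_seed = 1L,
                                chunk = 256L) {
  stopifnot(inherits(encoder, "wave_encoder"))
  layer_policy <- match.arg(layer_policy)
  d <- dim(images)
  stop_field(length(d) == 4, "images", "must be (H, W, C, n)")
  n <- d[4]
  acts <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    f <- encoder_forward(encoder, images[, , , idx, drop = FALSE],
                         policy = layer_policy)
    recs <- c(list(pixels = images[, , , idx, drop = FALSE]), f$records)
    flat <- lapply(recs, function(a) {
      if (length(dim(a)) == 4) {
        dd <- dim(a)
        t(matrix(a, dd[1] * dd[2] * dd[3], dd[4]))
      } else t(a)
    })
    if (is.null(acts)) {
      acts <- lapply(flat, function(m) {
        out <- matrix(0, n, ncol(m)); out[idx, ] <- m; out
      })
    } else {
      for (nm in names(flat)) acts[[nm]][idx, ] <- flat[[nm]]
    }
  }
  projected <- character(0)
  for (nm in names(acts)) {
    if (ncol(acts[[nm]]) > max_N) {
      acts[[nm]] <- with_seed(derive_seed(proj_seed, which(names(acts) == nm)),
                              gaussian_project(acts[[nm]], max_N))
      projected <- c(projected, nm)
    }
  }
  attr(acts, "projection") <- list(max_N = max_N, proj_seed = proj_seed,
                                   projected_layers = projected)
  acts
}

#' Build object manifolds for geometry analysis
#'
#' Constructs `P` manifolds of `M` examples each and embeds them at one
#' encoder layer:
#' \describe{
#'   \item{`translation`}{`M` random integer shifts with `|dx|, |dy| <=
#'     max_shift_px` (default 3) of each of `P` base images;}
#'   \item{`color`}{`M` random color jitters with magnitude in
#'     `[jitter_lo, jitter_hi]` (default 0.5–1.5, i.e. 50–150% changes) of
#'     each base;}
#'   \item{`classification`}{`M` exemplars per class drawn from
#'     `images`/`labels` — ranked by the `M` highest softmax scores of
#'     `classifier` (a `"readout_result"`) when one is provided, uniformly
#'     at random otherwise (recorded in `exemplar_selection`);}
#'   \item{`wave`}{`M` frames sampled from each of `P` wave events of a
#'     movie.}
#' }
#'
#' @param task One of `"translation"`, `"color"`, `"classification"`,
#'   `"wave"`.
#' @param encoder A `"wave_encoder"`.
#' @param P,M Number of manifolds and examples per manifold (defaults 50
#'   and 20).
#' @param bases Base images for translation/color (`(H, W, 3, >= P)`).
#' @param images,labels Labeled pool for classification.
#' @param classifier Optional `"readout_result"` for ranked exemplar
#'   selection.
#' @param movie,events Wave movie and events for `task = "wave"`.
#' @param layer Layer name to embed at (default `"embedding"`).
#' @param max_shift_px,jitter_lo,jitter_hi Task-manifold ranges.
#' @param max_N,proj_seed Passed to [extract_activations()].
#' @param seed Integer seed.
#' @return A [manifold_set()] of dimension `P x M x N`.
#' @export
build_manifolds <- function(task = c("translation", "color",
                                     "classification", "wave"),
                            encoder, P = 50L, M = 20L,
                            bases = NULL, images = NULL, labels = NULL,
                            classifier = NULL, movie = NULL, events = NULL,
                            layer = "embedding", max_shift_px = 3L,
                            jitter_lo = 0.5, jitter_hi = 1.5,
                            max_N = 2000L, proj_seed = 1L, seed = 1L) {
  mi <- manifold_task_images(task = task, encoder = encoder, P = P, M = M,
                             bases = bases, images = images, labels = labels,
                             classifier = classifier, movie = movie,
                             events = events, max_shift_px = max_shift_px,
                             jitter_lo = jitter_lo, jitter_hi = jitter_hi,
                             seed = seed)
  acts <- extract_activations(encoder, mi$imgs, max_N = max_N,
                              proj_seed = proj_seed)
  stop_field(layer %in% names(acts), "layer",
             sprintf("unknown layer %s; available: %s", layer,
                     paste(names(acts), collapse = ", ")))
  ms <- activations_to_manifold_set(acts[[layer]], P, M, mi$task, layer,
                                    mi$man_labels)
  ms$exemplar_selection <- mi$sel
  ms
}

# reshape a (P*M) x N activation matrix (examples fastest) to a manifold set
activations_to_manifold_set <- function(A, P, M, task, layer, labels) {
  pts <- aperm(array(A, c(M, P, ncol(A))), c(2, 1, 3))
  manifold_set(pts, task = task, layer_name = layer, labels = labels)
}

# builds the P*M stimulus images for each manifold construction
manifold_task_images <- function(task = c("translation", "color",
                                          "classification", "wave"),
                                 encoder, P, M, bases = NULL, images = NULL,
                                 labels = NULL, classifier = NULL,
                                 movie = NULL, events = NULL,
                                 max_shift_px = 3L, jitter_lo = 0.5,
                                 jitter_hi = 1.5, seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(encoder, "wave_encoder"))
  check_scalar(P, "P", 2, Inf, integer = TRUE)
  check_scalar(M, "M", 1, Inf, integer = TRUE)
  sel <- "random"
  if (task %in% c("translation", "color")) {
    stop_field(!is.null(bases) && length(dim(bases)) == 4, "bases",
               "base images required for task manifolds")
    stop_field(dim(bases)[4] >= P, "P",
               sprintf("only %d base images available", dim(bases)[4]))
    d <- dim(bases)
    imgs <- array(0, c(d[1], d[2], d[3], P * M))
    with_seed(derive_seed(seed, 23), {
      k <- 0L
      for (p in seq_len(P)) for (j in seq_len(M)) {
        k <- k + 1L
        if (task == "translation") {
          dx <- sample(-max_shift_px:max_shift_px, 1)
          dy <- sample(-max_shift_px:max_shift_px, 1)
          imgs[, , , k] <- translate_image(bases[, , , p], dx, dy)
        } else {
          imgs[, , , k] <- color_jitter_image(bases[, , , p], jitter_lo,
                                              jitter_hi)
        }
      }
    })
    man_labels <- seq_len(P) - 1L
  } else if (task == "classification") {
    stop_field(!is.null(images) && !is.null(labels), "images",
               "images and labels required for classification manifolds")
    classes <- sort(unique(labels))
    stop_field(length(classes) >= P, "P",
               sprintf("only %d classes available", length(classes)))
    classes <- classes[seq_len(P)]
    d <- dim(images)
    imgs <- array(0, c(d[1], d[2], d[3], P * M))
    if (!is.null(classifier)) {
      stopifnot(inherits(classifier, "readout_result"))
      feats <- encode_images(encoder, images)
      logits <- classifier$weights$W %*% t(feats) + classifier$weights$b
      sm <- exp(sweep(logits, 2, apply(logits, 2, max)))
      sm <- sweep(sm, 2, colSums(sm), "/")
      sel <- "ranked-softmax"
    }
    with_seed(derive_seed(seed, 29), {
      k <- 0L
      for (pi in seq_along(classes)) {
        pool <- which(labels == classes[pi])
        stop_field(length(pool) >= M, "M",
                   sprintf("class %s has only %d examples", classes[pi],
                           length(pool)))
        pick <- if (sel == "ranked-softmax") {
          cls_row <- match(as.character(classes[pi]),
                           as.character(sort(unique(labels))))
          pool[order(sm[cls_row, pool], decreasing = TRUE)[seq_len(M)]]
        } else sample(pool, M)
        for (j in pick) {
          k <- k + 1L
          imgs[, , , k] <- images[, , , j]
        }
      }
    })
    man_labels <- classes
  } else { # wave
    stop_field(!is.null(movie) && !is.null(events), "movie",
               "movie and events required for wave-event manifolds")
    stop_field(nrow(events) >= P, "P",
               sprintf("only %d wave events available", nrow(events)))
    lens <- event_lengths(events)
    short <- which(lens[seq_len(P)] < M)
    if (length(short))
      stop(sprintf("wave event %d has only %d frames, fewer than M = %d",
                   short[1] - 1L, lens[short[1]], M), call. = FALSE)
    x_all <- preprocess_movie(movie, encoder$spec$input_size)
    d <- dim(x_all)
    imgs <- array(0, c(d[1], d[2], d[3], P * M))
    with_seed(derive_seed(seed, 31), {
      k <- 0L
      for (p in seq_len(P)) {
        fr <- sort(sample(event_frame_idx(events, p), M))
        for (j in fr) {
          k <- k + 1L
          imgs[, , , k] <- x_all[, , , j]
        }
      }
    })
    man_labels <- seq_len(P) - 1L
  }
  list(imgs = imgs, man_labels = man_labels, task = task,
       sel = if (task == "classification") sel else NULL)
}
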