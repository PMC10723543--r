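#' The nine experimental conditions
#'
#' Two movie sources (real, simulated) crossed with four shuffle kinds
#' (none, spatial, temporal, spatiotemporal), plus the He random-initialized
#' control that skips pre-training.
#'
#' @return A data frame with columns `condition`, `source`, `shuffle`,
#'   `pretrained` (9 rows).
#' @export
condition_grid <- function() {
  g <- expand.grid(source = c("real", "simulated"),
                   shuffle = c("none", "spatial", "temporal",
                               "spatiotemporal"),
                   stringsAsFactors = FALSE)
  g$pretrained <- TRUE
  g$condition <- paste0(g$source, "-",
                        ifelse(g$shuffle == "none", "unshuffled", g$shuffle))
  g <- rbind(g, data.frame(source = "none", shuffle = "none",
                           pretrained = FALSE, condition = "random"))
  g[, c("condition", "source", "shuffle", "pretrained")]
}

#' Experiment configuration
#'
#' Bundles all sub-configurations for [run_condition()]. `scale = "desk"`
#' (default) uses sizes that run on one CPU: a 32x32 simulated movie of
#' 3000 frames, the tiny-conv encoder with a 64x64x64 projector, 20
#' pre-training epochs, and geometry with P = 20 manifolds of M = 10
#' examples. `scale = "full"` mirrors the full-scale protocol (resnet18-like,
#' 8192x8192x8192 projector, 100 epochs, 5000/1000 images per base,
#' P = 50, M = 20) and is intended for long runs, not tests.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seeds Integer vector of network-initialization seeds (default
#'   `c(0, 1, 2)`).
#' @param out_dir Output directory for result bundles.
#' @param real_movie_path Optional path to a saved real movie (required for
#'   `source = "real"` conditions).
#' @param ... Named overrides of individual sub-config entries, e.g.
#'   `wave = wave_sim_params(...)`, `pretrain_epochs = 5`,
#'   `n_train_per_base = 200`.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(scale = c("desk", "full"), seeds = c(0L, 1L, 2L),
                              out_dir = file.path(tempdir(), "retwave-out"),
                              real_movie_path = NULL, ...) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  cfg <- list(
    scale = scale,
    seeds = as.integer(seeds),
    out_dir = out_dir,
    real_movie_path = real_movie_path,
    wave = wave_sim_params(height = 32, width = 32,
                           n_frames = if (desk) 3000L else 237000L,
                           strength_alpha = 0.5),
    event_threshold = 0.2,
    min_event_frames = 2L,
    encoder = if (desk)
      encoder_spec("tiny-conv", projector_dims = c(64, 64, 64))
    else
      encoder_spec("resnet18-like", projector_dims = c(8192, 8192, 8192)),
    pretrain_epochs = if (desk) 20L else 100L,
    pretrain_lr = 1e-4,
    batch_frame_threshold = 3000L,
    temperature_tau = 0.5,
    pair_gap = 1L,
    n_bases = 10L,
    n_train_per_base = if (desk) 300L else 5000L,
    n_test_per_base = if (desk) 100L else 1000L,
    max_shift_px = 16L,
    color_jitter = c(0.5, 1.0),
    base_seed = 42L,
    readout_lr = if (desk) 1e-2 else 1e-4,
    readout_epochs = if (desk) 50L else 100L,
    readout_batch = 100L,
    geom_P = if (desk) 20L else 50L,
    geom_M = if (desk) 10L else 20L,
    geom_max_shift = 3L,
    geom_jitter = c(0.5, 1.5),
    geom_samples = if (desk) 100L else 200L,
    max_N = 2000L,
    tasks = c("translation", "color", "classification")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm, call. = FALSE)
    cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "experiment_config")
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

# fixed task datasets shared by every condition (network seeds only affect
# encoders and readouts)
pipeline_datasets <- function(cfg) {
  bases <- make_base_images(cfg$n_bases, seed = cfg$base_seed)
  ds <- list()
  if ("translation" %in% cfg$tasks)
    ds$translation <- gen_translation_dataset(
      bases, max_shift_px = cfg$max_shift_px,
      n_train_per_base = cfg$n_train_per_base,
      n_test_per_base = cfg$n_test_per_base, seed = cfg$base_seed)
  if ("color" %in% cfg$tasks)
    ds$color <- gen_color_dataset(
      bases, jitter_lo = cfg$color_jitter[1], jitter_hi = cfg$color_jitter[2],
      n_train_per_base = cfg$n_train_per_base,
      n_test_per_base = cfg$n_test_per_base, seed = cfg$base_seed)
  if ("classification" %in% cfg$tasks)
    ds$classification <- gen_classification_dataset(
      n_classes = cfg$n_bases, n_train_per_class = cfg$n_train_per_base,
      n_test_per_class = cfg$n_test_per_base, seed = cfg$base_seed)
  list(bases = bases, datasets = ds)
}

#' Run one experimental condition end-to-end
#'
#' Executes wave preparation, (optional) contrastive pre-training, linear
#' readout evaluation on the configured tasks, and layerwise geometry, for
#' each network seed, writing `accuracy.csv` and `geometry.csv` under
#' `out_dir/<condition>/<seed>/`. Stages whose output files already exist
#' are skipped, so interrupted runs resume.
#'
#' @param condition One row of [condition_grid()] (or its `condition`
#'   string).
#' @param cfg An [experiment_config()].
#' @param data Optional pre-built result of the internal dataset stage;
#'   passing the same object to several conditions avoids regenerating the
#'   task datasets.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the per-seed accuracy and geometry data
#'   frames (also written as CSV).
#' @export
run_condition <- function(condition, cfg, data = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  grid <- condition_grid()
  if (is.character(condition)) {
    stop_field(condition %in% grid$condition, "condition",
               paste("must be one of:", paste(grid$condition, collapse = ", ")))
    condition <- grid[grid$condition == condition, ]
  }
  cond <- as.list(condition)
  if (cond$source == "real" && is.null(cfg$real_movie_path))
    stop("condition uses real waves but cfg$real_movie_path is not set",
         call. = FALSE)
  if (is.null(data)) data <- pipeline_datasets(cfg)
  acc_all <- list(); geo_all <- list()
  for (seed in cfg$seeds) {
    sdir <- file.path(cfg$out_dir, cond$condition, seed)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    acc_path <- file.path(sdir, "accuracy.csv")
    geo_path <- file.path(sdir, "geometry.csv")
    if (file.exists(acc_path) && file.exists(geo_path)) {
      log_stage(verbose, "%s seed %d: cached", cond$condition, seed)
      acc_all[[as.character(seed)]] <- utils::read.csv(acc_path)
      geo_all[[as.character(seed)]] <- utils::read.csv(geo_path)
      next
    }
    # --- wave preparation + pre-training -------------------------------
    pcfg <- pretrain_config(learning_rate = cfg$pretrain_lr,
                            epochs = if (cond$pretrained) cfg$pretrain_epochs
                                     else 0L,
                            batch_frame_threshold = cfg$batch_frame_threshold,
                            temperature_tau = cfg$temperature_tau,
                            pair_gap = cfg$pair_gap, seed = as.integer(seed))
    if (cond$pretrained) {
      log_stage(verbose, "%s seed %d: preparing waves", cond$condition, seed)
      movie <- if (cond$source == "simulated") {
        wp <- cfg$wave; wp$seed <- derive_seed(seed, 1000)
        simulate_waves(wp)
      } else load_movie(cfg$real_movie_path)
      events <- extract_events(movie, cfg$event_threshold,
                               cfg$min_event_frames)
      sh <- shuffle_movie(movie, events, cond$shuffle,
                          seed = derive_seed(seed, 2000))
      movie <- sh$movie; events <- sh$events
      log_stage(verbose, "%s seed %d: pre-training (%d events, %d epochs)",
                cond$condition, seed, nrow(events), cfg$pretrain_epochs)
      encoder <- pretrain_encoder(movie, events, cfg$encoder, pcfg)
    } else {
      movie <- NULL; events <- NULL
      encoder <- init_encoder(cfg$encoder, seed = as.integer(seed))
      encoder$history <- data.frame(epoch = integer(0),
                                    mean_loss = numeric(0))
    }
    utils::write.csv(encoder$history, file.path(sdir, "pretrain_loss.csv"),
                     row.names = FALSE)
    # --- task readouts ---------------------------------------------------
    acc <- list()
    for (task in names(data$datasets)) {
      log_stage(verbose, "%s seed %d: readout on %s", cond$condition, seed,
                task)
      rr <- train_linear_readout(encoder, data$datasets[[task]],
                                 lr = cfg$readout_lr,
                                 epochs = cfg$readout_epochs,
                                 batch_size = cfg$readout_batch,
                                 seed = as.integer(seed))
      acc[[task]] <- data.frame(condition = cond$condition,
                                source = cond$source,
                                shuffle = cond$shuffle, task = task,
                                seed = seed,
                                test_accuracy = rr$test_accuracy,
                                train_accuracy = rr$train_accuracy)
    }
    acc <- do.call(rbind, acc)
    utils::write.csv(acc, acc_path, row.names = FALSE)
    # --- geometry --------------------------------------------------------
    geo <- list()
    for (task in intersect(cfg$tasks, c("translation", "color",
                                        "classification"))) {
      log_stage(verbose, "%s seed %d: geometry on %s manifolds",
                cond$condition, seed, task)
      args <- list(task = task, encoder = encoder, P = cfg$geom_P,
                   M = cfg$geom_M, max_N = cfg$max_N,
                   proj_seed = derive_seed(seed, 3000),
                   seed = derive_seed(seed, 4000))
      if (task %in% c("translation", "color")) {
        args$bases <- data$bases
        args$max_shift_px <- cfg$geom_max_shift
        args$jitter_lo <- cfg$geom_jitter[1]
        args$jitter_hi <- cfg$geom_jitter[2]
        if (dim(data$bases)[4] < cfg$geom_P) {
          args$bases <- make_base_images(cfg$geom_P,
                                         seed = derive_seed(cfg$base_seed, 5))
        }
      } else {
        ds <- data$datasets$classification
        args$images <- ds$test_images
        args$labels <- ds$test_labels
      }
      geo[[task]] <- geometry_layer_table(args, cond, seed, cfg)
    }
    geo <- do.call(rbind, geo)
    utils::write.csv(geo, geo_path, row.names = FALSE)
    acc_all[[as.character(seed)]] <- acc
    geo_all[[as.character(seed)]] <- geo
  }
  invisible(list(accuracy = do.call(rbind, acc_all),
                 geometry = do.call(rbind, geo_all)))
}

# geometry summary across all recorded layers for one manifold construction
geometry_layer_table <- function(args, cond, seed, cfg) {
  task <- args$task
  enc <- args$encoder
  max_N <- args$max_N; proj_seed <- args$proj_seed
  mi_args <- args[setdiff(names(args), c("max_N", "proj_seed"))]
  mi <- do.call(manifold_task_images, mi_args)
  acts <- extract_activations(enc, mi$imgs, max_N = max_N,
                              proj_seed = proj_seed)
  rows <- list()
  for (ly in names(acts)) {
    ms <- activations_to_manifold_set(acts[[ly]], args$P, args$M, mi$task,
                                      ly, mi$man_labels)
    mf <- meanfield_geometry(ms, n_gaussian_samples = cfg$geom_samples,
                             seed = derive_seed(seed, 5000))
    fl <- manifold_flatten(ms)
    rows[[ly]] <- data.frame(
      condition = cond$condition, seed = seed, task = task, layer = ly,
      alpha_c = mf$alpha_c_mean, D_M = mf$D_M_mean, R_M = mf$R_M_mean,
      PR = participation_ratio(fl$X),
      center_corr = center_correlation(ms),
      ev_dims = explained_variance_dims(fl$X, 0.9))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare condition result bundles
#'
#' Aggregates accuracy and geometry over seeds (mean and standard
#' deviation) and evaluates the directional checks: pre-training on
#' unshuffled waves beating the random control on translation accuracy and
#' final-layer translation-manifold capacity, and temporally /
#' spatiotemporally shuffled pre-training showing higher final-layer
#' participation ratio than unshuffled. Each flag is decided by majority
#' over seeds (`"pass"`, `"fail"`, or `"tie"`).
#'
#' @param out_dir Directory populated by [run_condition()].
#' @param final_layer Layer used for the geometry flags (default
#'   `"embedding"`).
#' @return A list with `accuracy_table`, `geometry_table` and `flags`.
#' @export
compare_conditions <- function(out_dir, final_layer = "embedding") {
  acc_files <- list.files(out_dir, "accuracy.csv", recursive = TRUE,
                          full.names = TRUE)
  geo_files <- list.files(out_dir, "geometry.csv", recursive = TRUE,
                          full.names = TRUE)
  if (!length(acc_files)) stop("no result bundles under ", out_dir,
                               call. = FALSE)
  acc <- do.call(rbind, lapply(acc_files, utils::read.csv))
  geo <- do.call(rbind, lapply(geo_files, utils::read.csv))
  layer_sets <- unique(tapply(geo$layer, geo$condition, function(x)
    paste(sort(unique(x)), collapse = ",")))
  if (length(layer_sets) > 1)
    stop("bundles have mismatched layer sets", call. = FALSE)
  agg <- function(df, value) {
    s <- stats::aggregate(df[[value]],
                          by = df[intersect(c("condition", "task", "layer"),
                                            names(df))],
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    cbind(s[setdiff(names(s), "x")],
          stats::setNames(as.data.frame(s$x), paste0(value, c("_mean", "_sd"))))
  }
  acc_tab <- agg(acc, "test_accuracy")
  geo_tab <- NULL
  for (v in c("alpha_c", "D_M", "R_M", "PR", "center_corr", "ev_dims")) {
    a <- agg(geo, v)
    geo_tab <- if (is.null(geo_tab)) a else
      merge(geo_tab, a, by = c("condition", "task", "layer"))
  }
  majority_flag <- function(a, b) {
    # a, b: per-seed values aligned by seed
    if (!length(a) || length(a) != length(b)) return(NA_character_)
    wins <- sum(a > b); losses <- sum(a < b)
    if (wins > losses) "pass" else if (losses > wins) "fail" else "tie"
  }
  per_seed <- function(df, condition, value, task = NULL, layer = NULL) {
    sel <- df$condition == condition
    if (!is.null(task)) sel <- sel & df$task == task
    if (!is.null(layer)) sel <- sel & df$layer == layer
    x <- df[sel, ]
    x[[value]][order(x$seed)]
  }
  unsh <- grep("-unshuffled$", unique(acc$condition), value = TRUE)[1]
  flags <- list()
  if (!is.na(unsh) && "random" %in% acc$condition) {
    flags$translation_accuracy_unshuffled_gt_random <- majority_flag(
      per_seed(acc, unsh, "test_accuracy", task = "translation"),
      per_seed(acc, "random", "test_accuracy", task = "translation"))
    flags$translation_capacity_unshuffled_gt_random <- majority_flag(
      per_seed(geo, unsh, "alpha_c", task = "translation",
               layer = final_layer),
      per_seed(geo, "random", "alpha_c", task = "translation",
               layer = final_layer))
  }
  if (!is.na(unsh)) {
    src <- sub("-unshuffled$", "", unsh)
    for (k in c("temporal", "spatiotemporal")) {
      cn <- paste0(src, "-", k)
      if (cn %in% geo$condition)
        flags[[paste0("PR_", k, "_gt_unshuffled")]] <- majority_flag(
          per_seed(geo, cn, "PR", task = "translation", layer = final_layer),
          per_seed(geo, unsh, "PR", task = "translation",
                   layer = final_layer))
    }
  }
  list(accuracy_table = acc_tab, geometry_table = geo_tab, flags = flags)
}
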