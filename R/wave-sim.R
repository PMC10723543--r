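#' Parameters for the excitable-medium retinal-wave simulator
#'
#' Bundles and validates the settings of [simulate_waves()]. The simulator is
#' a three-state cellular automaton (quiescent, active, refractory) on a 2-D
#' grid of retinal ganglion cells: quiescent cells initiate activity
#' spontaneously at a rate proportional to the wave "strength" `strength_alpha`,
#' active cells recruit their quiescent 4-neighbors, and cells that finish
#' their active period enter a refractory period of randomized length. The
#' rendered intensity is a calcium-like leaky integration of the active state.
#'
#' @param height,width Grid size in cells.
#' @param n_frames Number of frames to simulate.
#' @param strength_alpha Wave-strength parameter; the spontaneous initiation
#'   probability per quiescent cell per frame is
#'   `strength_alpha * init_rate_scale`. The default 0.5 gives frequent waves
#'   separated by short quiescent intervals.
#' @param init_rate_scale Baseline per-cell initiation rate multiplying
#'   `strength_alpha` (default `1e-4`).
#' @param recruit_prob Probability that an active cell recruits a given
#'   quiescent 4-neighbor on each frame.
#' @param active_duration_frames Frames a cell stays active once recruited.
#' @param refractory_mean_frames,refractory_jitter_frames Mean and half-range
#'   (uniform jitter) of the refractory period, in frames.
#' @param calcium_decay_per_frame Decay factor `d` in `[0, 1)` of the rendered
#'   calcium trace: `c_t = d * c_{t-1} + (1 - d) * active_t`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (clipped to `[0, 1]` after adding).
#' @param frame_rate_hz Frame rate stored in the movie metadata.
#' @param seed Integer seed; identical parameters and seed give
#'   bitwise-identical movies.
#' @return A list of class `"wave_sim_params"`.
#' @seealso [simulate_waves()]
#' @export
wave_sim_params <- function(height = 32, width = 32, n_frames = 3000,
                            strength_alpha = 0.5, init_rate_scale = 1e-4,
                            recruit_prob = 0.55, active_duration_frames = 3,
                            refractory_mean_frames = 40,
                            refractory_jitter_frames = 10,
                            calcium_decay_per_frame = 0.6, noise_sd = 0.01,
                            frame_rate_hz = 10, seed = 1L) {
  check_scalar(height, "height", 1, Inf, integer = TRUE)
  check_scalar(width, "width", 1, Inf, integer = TRUE)
  check_scalar(n_frames, "n_frames", 1, Inf, integer = TRUE)
  check_scalar(strength_alpha, "strength_alpha", 0, Inf)
  check_scalar(init_rate_scale, "init_rate_scale", 0, 1)
  check_scalar(recruit_prob, "recruit_prob", 0, 1)
  check_scalar(active_duration_frames, "active_duration_frames", 1, Inf,
               integer = TRUE)
  check_scalar(refractory_mean_frames, "refractory_mean_frames", 0, Inf,
               integer = TRUE)
  check_scalar(refractory_jitter_frames, "refractory_jitter_frames", 0, Inf,
               integer = TRUE)
  stop_field(refractory_jitter_frames <= refractory_mean_frames,
             "refractory_jitter_frames", "must not exceed refractory_mean_frames")
  check_scalar(calcium_decay_per_frame, "calcium_decay_per_frame", 0, 1 - 1e-12)
  check_scalar(noise_sd, "noise_sd", 0, Inf)
  check_scalar(frame_rate_hz, "frame_rate_hz", 1e-9, Inf)
  check_scalar(seed, "seed", -2^31, 2^31, integer = TRUE)
  out <- as.list(environment())
  for (nm in c("height", "width", "n_frames", "active_duration_frames",
               "refractory_mean_frames", "refractory_jitter_frames", "seed"))
    out[[nm]] <- as.integer(out[[nm]])
  structure(out, class = "wave_sim_params")
}

#' Construct a retinal-wave movie object
#'
#' @param frames Numeric `T x H x W` array with intensities in `[0, 1]`.
#' @param frame_rate_hz Positive frame rate.
#' @param source_tag Character tag, e.g. `"simulated"`, `"real"` or
#'   `"shuffled-spatial"`.
#' @param seed Optional integer seed recorded in the metadata.
#' @return An object of class `"wave_movie"`.
#' @export
wave_movie <- function(frames, frame_rate_hz, source_tag = "simulated",
                       seed = NULL) {
  stop_field(is.array(frames) && length(dim(frames)) == 3, "frames",
             "must be a T x H x W array")
  stop_field(all(dim(frames) >= 1), "frames", "all dimensions must be >= 1")
  rng <- range(frames)
  stop_field(is.finite(rng[1]) && rng[1] >= 0 && rng[2] <= 1, "frames",
             "intensities must lie in [0, 1]")
  check_scalar(frame_rate_hz, "frame_rate_hz", 1e-9, Inf)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 source_tag = source_tag, seed = seed),
            class = "wave_movie")
}

#' @export
print.wave_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<wave_movie> %d frames of %dx%d, %.3g Hz, source=%s\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$source_tag))
  invisible(x)
}

#' @export
print.wave_sim_params <- function(x, ...) {
  cat(sprintf("<wave_sim_params> %dx%d grid, %d frames, alpha=%.3g, seed=%d\n",
              x$height, x$width, x$n_frames, x$strength_alpha, x$seed))
  invisible(x)
}

#' Simulate a retinal-wave movie
#'
#' Runs the excitable-medium cellular automaton described in
#' [wave_sim_params()] and renders a calcium-like intensity movie. Each cell
#' cycles quiescent -> active -> refractory -> quiescent; waves start as
#' spontaneous single-cell initiations and spread to 4-neighbors, producing
#' spatially contiguous propagating events separated by quiescence, with event
#' frequency controlled by `strength_alpha`.
#'
#' @param params A [wave_sim_params()] object.
#' @return A [wave_movie()] with `source_tag = "simulated"`.
#' @examples
#' m <- simulate_waves(wave_sim_params(height = 16, width = 16, n_frames = 200))
#' dim(m$frames)
#' @export
simulate_waves <- function(params) {
  stopifnot(inherits(params, "wave_sim_params"))
  p <- params
  H <- p$height; W <- p$width; TT <- p$n_frames
  with_seed(p$seed, {
    # active_left > 0: active; refr_left > 0: refractory; both 0: quiescent
    active_left <- matrix(0L, H, W)
    refr_left <- matrix(0L, H, W)
    calcium <- matrix(0, H, W)
    frames <- array(0, dim = c(TT, H, W))
    p_init <- p$strength_alpha * p$init_rate_scale
    d <- p$calcium_decay_per_frame
    for (t in seq_len(TT)) {
      active <- active_left > 0L
      quiescent <- !active & refr_left == 0L
      # count active 4-neighbors by shifting the activity mask
      nb <- matrix(0L, H, W)
      if (H > 1) {
        nb[-1, ] <- nb[-1, ] + active[-H, ]
        nb[-H, ] <- nb[-H, ] + active[-1, ]
      }
      if (W > 1) {
        nb[, -1] <- nb[, -1] + active[, -W]
        nb[, -W] <- nb[, -W] + active[, -1]
      }
      # recruitment: independent trial per active neighbor
      p_recruit <- 1 - (1 - p$recruit_prob)^nb
      u <- matrix(stats::runif(H * W), H, W)
      recruit <- quiescent & nb > 0L & u < p_recruit
      # spontaneous initiation
      u2 <- matrix(stats::runif(H * W), H, W)
      init <- quiescent & !recruit & (u2 < p_init)
      new_active <- recruit | init
      # advance clocks
      ending <- active_left == 1L
      active_left <- pmax(active_left - 1L, 0L)
      refr_left <- pmax(refr_left - 1L, 0L)
      if (any(ending)) {
        n_end <- sum(ending)
        jit <- if (p$refractory_jitter_frames > 0)
          sample.int(2L * p$refractory_jitter_frames + 1L, n_end,
                     replace = TRUE) - p$refractory_jitter_frames - 1L
        else rep(0L, n_end)
        refr_left[ending] <- pmax(p$refractory_mean_frames + jit, 0L)
      }
      active_left[new_active] <- p$active_duration_frames
      active_now <- active_left > 0L
      calcium <- d * calcium + (1 - d) * active_now
      fr <- calcium
      if (p$noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(H * W, sd = p$noise_sd), H, W)
      frames[t, , ] <- clip01(fr)
    }
    wave_movie(frames, p$frame_rate_hz, source_tag = "simulated",
               seed = p$seed)
  })
}
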