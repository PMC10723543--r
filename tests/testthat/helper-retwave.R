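# Shared micro fixtures, built in code.

# a movie whose per-frame activity pattern is given exactly: active frames
# carry a single bright pixel, inactive frames are zero
movie_from_activity <- function(active, h = 4, w = 4, bright = 0.9) {
  TT <- length(active)
  fr <- array(0, c(TT, h, w))
  for (t in which(active > 0)) fr[t, 1, 1] <- bright
  wave_movie(fr, frame_rate_hz = 10, source_tag = "simulated")
}

tiny_spec <- function(channels = c(3, 4, 5, 6), projector = c(8, 8, 8)) {
  encoder_spec("tiny-conv", input_size = c(32, 32, 3),
               projector_dims = projector, channels = channels)
}

# small structured wave movie + events, memoised per session
tiny_wave_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- simulate_waves(wave_sim_params(height = 16, width = 16,
                                          n_frames = 250,
                                          strength_alpha = 0.5,
                                          init_rate_scale = 1e-3, seed = 7))
      cache <<- list(movie = m, events = extract_events(m, 0.2, 2))
    }
    cache
  }
})

# i.i.d. standard-normal manifold set
gaussian_manifolds <- function(P, M, N, seed) {
  withr::with_seed(seed, manifold_set(array(rnorm(P * M * N), c(P, M, N))))
}

# data matrix with exactly the given covariance spectrum (via orthonormal
# factors), n rows
data_with_spectrum <- function(eigvals, n, seed = 1) {
  N <- length(eigvals)
  withr::with_seed(seed, {
    # left factors orthogonal to the ones vector, so column means are exactly
    # zero and the centered sample covariance has exactly this spectrum
    U <- qr.Q(qr(cbind(1, matrix(rnorm(n * n), n))))[, 1 + seq_len(N),
                                                     drop = FALSE]
    V <- qr.Q(qr(matrix(rnorm(N * N), N)))
    U %*% diag(sqrt(eigvals * (n - 1)), N) %*% t(V)
  })
}

random_orthogonal <- function(N, seed = 1) {
  withr::with_seed(seed, qr.Q(qr(matrix(rnorm(N * N), N))))
}
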