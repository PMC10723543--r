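#' Shuffled control datasets for pre-training
#'
#' Builds the shuffle controls used to dissect which statistics of retinal
#' waves drive learning:
#' \describe{
#'   \item{`spatial`}{an independent random pixel permutation is applied to
#'     each frame, preserving every frame's intensity distribution while
#'     destroying spatial contiguity;}
#'   \item{`temporal`}{a single random permutation of frame order is applied
#'     to the whole movie; the original event index-ranges are kept as the
#'     event structure over the permuted stack, so "events" now contain
#'     temporally scrambled content;}
#'   \item{`spatiotemporal`}{the temporal shuffle followed by the spatial
#'     shuffle (sub-seeds `seed` and `seed + 1`);}
#'   \item{`none`}{the identity.}
#' }
#'
#' @param movie A [wave_movie()].
#' @param events A [wave_events()] table valid for `movie`.
#' @param kind One of `"none"`, `"spatial"`, `"temporal"`,
#'   `"spatiotemporal"`.
#' @param seed Integer seed; results are deterministic given `seed`.
#' @return A list with elements `movie` (the shuffled [wave_movie()], with
#'   `source_tag` suffixed `shuffled-<kind>`) and `events`.
#' @export
shuffle_movie <- function(movie, events, kind = c("none", "spatial",
                                                  "temporal",
                                                  "spatiotemporal"),
                          seed = 1L) {
  stopifnot(inherits(movie, "wave_movie"), inherits(events, "wave_events"))
  kind <- match.arg(kind)
  check_scalar(seed, "seed", -2^31, 2^31, integer = TRUE)
  d <- dim(movie$frames)
  if (nrow(events))
    stop_field(max(events$end_frame) <= d[1], "events",
               "events exceed movie length")
  out <- movie
  if (kind == "none") return(list(movie = movie, events = events))
  if (kind == "temporal" || kind == "spatiotemporal") {
    perm <- with_seed(seed, sample.int(d[1]))
    out$frames <- out$frames[perm, , , drop = FALSE]
  }
  if (kind == "spatial" || kind == "spatiotemporal") {
    sseed <- if (kind == "spatiotemporal") seed + 1L else seed
    npix <- d[2] * d[3]
    fr <- matrix(aperm(out$frames, c(2, 3, 1)), nrow = npix)  # pixels x T
    with_seed(sseed, {
      for (t in seq_len(d[1])) fr[, t] <- fr[sample.int(npix), t]
    })
    out$frames <- aperm(array(fr, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  }
  out$source_tag <- paste0("shuffled-", kind)
  out$seed <- seed
  list(movie = out, events = events)
}
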