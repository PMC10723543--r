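#' Construct a wave-event table
#'
#' Wave events are half-open, 0-based frame ranges `[start_frame, end_frame)`
#' of continuous activity within a movie. Events must be disjoint and sorted.
#'
#' @param start_frame,end_frame Integer vectors (0-based; `end_frame`
#'   exclusive).
#' @param n_frames Optional movie length used to validate the upper bound.
#' @return A `data.frame` of class `"wave_events"` with columns
#'   `start_frame`, `end_frame`.
#' @export
wave_events <- function(start_frame, end_frame, n_frames = NULL) {
  stop_field(length(start_frame) == length(end_frame), "end_frame",
             "must have the same length as start_frame")
  if (length(start_frame)) {
    stop_field(all(start_frame == round(start_frame)) &&
               all(end_frame == round(end_frame)), "start_frame",
               "frame indices must be integers")
    stop_field(all(start_frame >= 0), "start_frame", "must be >= 0")
    stop_field(all(end_frame > start_frame), "end_frame",
               "must exceed start_frame (half-open ranges)")
    if (!is.null(n_frames))
      stop_field(all(end_frame <= n_frames), "end_frame",
                 "must not exceed the number of frames")
    o <- order(start_frame)
    start_frame <- as.integer(start_frame[o])
    end_frame <- as.integer(end_frame[o])
    if (length(start_frame) > 1)
      stop_field(all(start_frame[-1] >= end_frame[-length(end_frame)]),
                 "start_frame", "events must be disjoint")
  } else {
    start_frame <- integer(0); end_frame <- integer(0)
  }
  structure(data.frame(start_frame = start_frame, end_frame = end_frame),
            class = c("wave_events", "data.frame"))
}

event_lengths <- function(events) events$end_frame - events$start_frame

# 1-based frame indices of one event row
event_frame_idx <- function(events, i) {
  (events$start_frame[i] + 1L):events$end_frame[i]
}

#' Segment a movie into wave events
#'
#' A frame is active iff any pixel exceeds `activity_threshold`; maximal runs
#' of at least `min_event_frames` consecutive active frames become wave
#' events. Shorter runs are discarded.
#'
#' @param movie A [wave_movie()].
#' @param activity_threshold Pixel intensity threshold in `[0, 1]`.
#' @param min_event_frames Minimum run length (frames) to keep.
#' @return A [wave_events()] table (0-based, half-open, disjoint, sorted).
#' @examples
#' m <- simulate_waves(wave_sim_params(height = 16, width = 16, n_frames = 300))
#' extract_events(m, activity_threshold = 0.2)
#' @export
extract_events <- function(movie, activity_threshold = 0.2,
                           min_event_frames = 2L) {
  stopifnot(inherits(movie, "wave_movie"))
  check_scalar(activity_threshold, "activity_threshold", 0, 1)
  check_scalar(min_event_frames, "min_event_frames", 1, Inf, integer = TRUE)
  TT <- dim(movie$frames)[1]
  if (TT < 1) stop("empty movie: no frames to segment", call. = FALSE)
  fmax <- apply(movie$frames, 1, max)
  active <- fmax > activity_threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_event_frames
  wave_events(starts[keep] - 1L, ends[keep], n_frames = TT)
}

#' Write / read wave events as CSV
#'
#' Events are serialized with 0-based half-open columns
#' `start_frame,end_frame`.
#'
#' @param events A [wave_events()] table.
#' @param path CSV file path.
#' @return `save_events` returns `path` invisibly; `load_events` returns a
#'   [wave_events()] table.
#' @export
save_events <- function(events, path) {
  stopifnot(inherits(events, "wave_events"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_events
#' @export
load_events <- function(path) {
  df <- utils::read.csv(path)
  stop_field(all(c("start_frame", "end_frame") %in% names(df)), "path",
             "CSV must have start_frame,end_frame columns")
  wave_events(df$start_frame, df$end_frame)
}
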