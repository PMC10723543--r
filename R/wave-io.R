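#' Save / load a wave movie
#'
#' Movies are stored either as a grayscale multi-page TIFF stack
#' (ImageJ-compatible, 16-bit; intensities are quantized to the 65535-level
#' grid) or as an R array archive (`.rds`, bit-exact). A JSON sidecar
#' `<path>.json` records `frame_rate_hz`, `source_tag` and `seed` so that a
#' round trip reproduces the metadata exactly. Use [quantize_movie()] first
#' if a bit-exact TIFF round trip is required.
#'
#' @param movie A [wave_movie()].
#' @param path Output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.rds`).
#' @return `save_movie` returns `path` invisibly; `load_movie` returns a
#'   [wave_movie()].
#' @export
save_movie <- function(movie, path) {
  stopifnot(inherits(movie, "wave_movie"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    TT <- dim(movie$frames)[1]
    pages <- lapply(seq_len(TT), function(t) movie$frames[t, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (ext == "rds") {
    saveRDS(movie$frames, path)
  } else {
    stop_field(FALSE, "path", "must end in .tif, .tiff or .rds")
  }
  meta <- list(frame_rate_hz = movie$frame_rate_hz,
               source_tag = movie$source_tag, seed = movie$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_movie
#' @export
load_movie <- function(path) {
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nd <- length(dim(pages[[1]]))
    if (nd == 3)
      stop(sprintf(
        "movie stack is not grayscale: frames have %d channels, expected 1",
        dim(pages[[1]])[3]), call. = FALSE)
    frames <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  } else if (ext == "rds") {
    frames <- readRDS(path)
    stop_field(is.array(frames) && length(dim(frames)) == 3, "path",
               "archive must contain a T x H x W array")
    if (length(dim(frames)) == 3 && dim(frames)[1] >= 1 &&
        (min(frames) < 0 || max(frames) > 1))
      stop("movie intensities outside [0, 1]; rescale before saving",
           call. = FALSE)
  } else {
    stop_field(FALSE, "path", "must end in .tif, .tiff or .rds")
  }
  wave_movie(frames, frame_rate_hz = as.numeric(meta$frame_rate_hz),
             source_tag = as.character(meta$source_tag),
             seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed))
}

#' Quantize movie intensities to the 16-bit TIFF grid
#'
#' @param movie A [wave_movie()].
#' @return The movie with intensities rounded to multiples of `1/65535`, so
#'   that a TIFF round trip via [save_movie()] is exact.
#' @export
quantize_movie <- function(movie) {
  stopifnot(inherits(movie, "wave_movie"))
  movie$frames <- round(movie$frames * 65535) / 65535
  movie
}
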