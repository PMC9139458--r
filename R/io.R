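# File I/O: 16-bit TIFF stacks for movies, 8-bit labeled TIFF masks, and
# TrackMate-dialect CSV track tables.

#' Write a movie stack as 16-bit multi-page TIFF
#'
#' @param stack Numeric array (height x width x frames) of photon counts, or
#'   an `spt_movie` object.
#' @param path Output file path.
#' @param max_count Count mapped to the top of the 16-bit range; defaults to
#'   65535 (counts are stored 1:1).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path, max_count = 65535) {
  if (inherits(stack, "spt_movie")) stack <- stack$stack
  stopifnot(length(dim(stack)) == 3L)
  frames <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(stack[, , f] / max_count, 0), 1)
    m
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a single-channel multi-page TIFF into a numeric array
#'
#' @param path TIFF file path.
#' @param max_count Scale factor mapping the unit range back to counts
#'   (inverse of [write_movie_tiff()]).
#' @return Numeric array height x width x frames.
#' @export
read_movie_tiff <- function(path, max_count = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1] # drop extra channels if present
    m * max_count
  })
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Write a region mask as 8-bit labeled TIFF
#' @param mask A `region_mask` or integer label matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  lab <- if (inherits(mask, "region_mask")) mask$label_image else mask
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit labeled TIFF into an integer label matrix
#' @param path TIFF file path.
#' @return Integer matrix of region codes.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write tracks in TrackMate-compatible CSV dialect
#'
#' Columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`, `QUALITY`
#' (positions in micrometres), one row per localized spot.
#'
#' @param tracks Data.frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   and optionally `quality`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  out <- data.frame(
    TRACK_ID = tracks$track_id,
    FRAME = tracks$frame,
    POSITION_X = tracks$x_um,
    POSITION_Y = tracks$y_um,
    QUALITY = if ("quality" %in% names(tracks)) tracks$quality else NA_real_
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a TrackMate-style track CSV
#'
#' Accepts both this package's output and TrackMate spot exports (extra
#' columns and TrackMate's repeated-header rows are tolerated), returning the
#' internal dialect: `track_id`, `frame`, `x_um`, `y_um`, `quality`.
#'
#' @param path CSV path.
#' @return Data.frame ordered by track then frame.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(df)))
    stop("tracks CSV lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  # TrackMate exports sometimes repeat the header / units as leading rows
  keep <- suppressWarnings(!is.na(as.numeric(df$FRAME)))
  df <- df[keep, , drop = FALSE]
  out <- data.frame(
    track_id = as.integer(as.numeric(df$TRACK_ID)),
    frame = as.integer(as.numeric(df$FRAME)),
    x_um = as.numeric(df$POSITION_X),
    y_um = as.numeric(df$POSITION_Y),
    quality = if ("QUALITY" %in% names(df))
      suppressWarnings(as.numeric(df$QUALITY)) else NA_real_
  )
  out[order(out$track_id, out$frame), , drop = FALSE]
}
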