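#' Construct an RGB frame
#'
#' A frame is the unit of processing: an H x W x 3 array of 8-bit RGB
#' intensities (0–255) indexed `[row, col, channel]` with row 1 at the top,
#' plus a timestamp in seconds and an integer frame id.
#'
#' @param pixels H x W x 3 numeric array with values in \[0, 255\].
#' @param timestamp Seconds (wall-clock or monotonic).
#' @param frame_id Non-negative integer.
#' @return A `sv_frame` object.
#' @export
new_frame <- function(pixels, timestamp = 0, frame_id = 0L) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    abort("frame pixels must be an H x W x 3 array", class = "sv_config_error")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    abort("frame must have H >= 1 and W >= 1", class = "sv_config_error")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    abort("frame channel values must lie in [0, 255]", class = "sv_config_error")
  if (frame_id < 0)
    abort("frame_id must be non-negative", class = "sv_config_error")
  structure(list(pixels = pixels, timestamp = as.numeric(timestamp),
                 frame_id = as.integer(frame_id)),
            class = "sv_frame")
}

#' @export
print.sv_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sv_frame %d x %d, id %d, t = %.3f s>\n",
              d[1], d[2], x$frame_id, x$timestamp))
  invisible(x)
}

#' Read a single frame from disk
#'
#' PNG files are read with the png package; JPEG/TIFF fall back to
#' [EBImage::readImage()]. Grayscale images are replicated to three
#' channels; an alpha channel is dropped.
#'
#' @param path Image file path.
#' @param timestamp,frame_id Metadata attached to the frame.
#' @return A `sv_frame`.
#' @export
read_frame <- function(path, timestamp = 0, frame_id = 0L) {
  if (!file.exists(path))
    abort(paste0("cannot read frame: ", path), class = "sv_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    px <- EBImage::imageData(img)
    px <- if (length(dim(px)) == 3) aperm(px, c(2, 1, 3)) else t(px)
  }
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  new_frame(px * 255, timestamp = timestamp, frame_id = frame_id)
}

#' Write a frame as PNG
#'
#' @param frame A `sv_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "sv_frame"))
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' List image frames in a directory, in name order
#'
#' @param dir Directory path.
#' @param pattern Filename regex (default PNG/JPEG/TIFF).
#' @return Character vector of full paths, sorted.
#' @export
list_frames <- function(dir, pattern = "\\.(png|jpe?g|tiff?)$") {
  if (!dir.exists(dir))
    abort(paste0("not a directory: ", dir), class = "sv_io_error")
  sort(list.files(dir, pattern = pattern, full.names = TRUE,
                  ignore.case = TRUE))
}
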