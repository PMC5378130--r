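#' Grayscale frame sequences
#'
#' Frames are plain numeric matrices on the 0-255 intensity scale, indexed
#' `[row, col]` with row 1 at the top. Pixel coordinates reported by the
#' package are 0-based with x rightward (column) and y downward (row),
#' the usual image convention. A sequence is a list of such matrices in
#' temporal order.
#'
#' @name gray-frames
NULL

# validate a frame sequence: non-empty, all matrices, constant shape
check_frames <- function(frames) {
  if (length(frames) == 0) stop_invalid("empty frame sequence")
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop_invalid("frames must be matrices")
  }
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop_invalid("all frames must share one shape")
  invisible(d)
}

#' Read a numbered image sequence from a directory
#'
#' PNG and TIFF files are read in lexicographic order, which is taken as
#' temporal order. Images must be single-channel 8-bit grayscale (RGB with
#' identical channels is accepted and collapsed). A multi-page TIFF may be
#' read by pointing `path` at the file itself.
#'
#' @param path Directory of numbered `.png`/`.tif(f)` files, or one
#'   multi-page TIFF file.
#' @param invert Invert intensities (for bright animals on dark ground).
#' @return List of numeric matrices on the 0-255 scale.
#' @export
read_frames <- function(path, invert = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop_invalid("no PNG/TIFF frames found in ", path)
    frames <- lapply(files, read_one_image)
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE)
      frames <- lapply(pages, collapse_gray)
    } else {
      frames <- list(read_one_image(path))
    }
  } else {
    stop_invalid("input path does not exist: ", path)
  }
  if (invert) frames <- lapply(frames, function(f) 255 - f)
  check_frames(frames)
  frames
}

read_one_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  collapse_gray(img)
}

# accept [H,W] or [H,W,C]; rescale from [0,1] to 0-255
collapse_gray <- function(img) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 255)
}

#' Write frames as numbered PNG files
#'
#' @param frames List of 0-255 matrices.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; frames are numbered `%05d` from 0.
#' @return Character vector of file paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  check_frames(frames)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("%s%05d.png", prefix, i - 1L))
    png::writePNG(pmin(pmax(frames[[i]], 0), 255) / 255, paths[i])
  }
  invisible(paths)
}

#' Write a background model image as PNG
#'
#' @param bg A `background_model` (see [build_background()]).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "background_model"))
  png::writePNG(pmin(pmax(bg$pixels, 0), 255) / 255, path)
  invisible(path)
}

# coordinate codecs between 0-based (x, y) and 1-based column-major linear
# indices of an H-row matrix
xy_to_idx <- function(x, y, h) as.integer(x) * h + as.integer(y) + 1L
idx_to_xy <- function(idx, h) {
  idx0 <- idx - 1L
  cbind(x = idx0 %/% h, y = idx0 %% h)
}
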