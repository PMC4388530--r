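# Frame containers and the sum-difference transform.

#' Construct a frame stack
#'
#' An ordered series of equally sized 8-bit intensity matrices plus the
#' acquisition metadata needed to convert pixel displacements into
#' physical speeds. The canonical series is 30 frames at 30 fps (one
#' second of video) at 94.2 nm per pixel.
#'
#' @param frames list of numeric/integer matrices, identical dimensions,
#'   values in 0-255.
#' @param fps frame rate, frames per second.
#' @param pixel_size_nm physical pixel edge length in nanometres.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps = 30, pixel_size_nm = 94.2) {
  stopifnot(is.list(frames), length(frames) >= 1, fps > 0,
            pixel_size_nm > 0)
  d <- dim(frames[[1]])
  for (f in frames)
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices of identical dimensions")
  structure(list(frames = frames, fps = fps,
                 pixel_size_nm = pixel_size_nm),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %g fps, %g nm/px\n",
              length(x$frames), d[2], d[1], x$fps, x$pixel_size_nm))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Convert a color frame to 8-bit grayscale
#'
#' Fixed ITU-R BT.601 luma weighting `0.299 R + 0.587 G + 0.114 B`,
#' rounded to integer. Single-channel input passes through unchanged.
#'
#' @param frame an `h x w` matrix (already gray) or `h x w x 3` array of
#'   8-bit channel values (0-255).
#' @return An integer matrix of the same height/width.
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) {
    storage.mode(frame) <- "integer"
    return(frame)
  }
  if (!(is.array(frame) && length(dim(frame)) == 3 && dim(frame)[3] == 3))
    stop("unsupported channel count: expected 1 or 3 channels")
  g <- round(0.299 * frame[, , 1] + 0.587 * frame[, , 2] +
               0.114 * frame[, , 3])
  storage.mode(g) <- "integer"
  g
}

# internal constructor
sum_diff_image <- function(values, source_index, normalized) {
  structure(list(values = values, source_index = source_index,
                 normalized = normalized),
            class = "sum_diff_image")
}

#' @export
print.sum_diff_image <- function(x, ...) {
  cat(sprintf("<sum_diff_image> frame %d, %d x %d, %s, max %g\n",
              x$source_index, ncol(x$values), nrow(x$values),
              if (x$normalized) "normalized" else "raw",
              max(x$values)))
  invisible(x)
}

#' Indexed serial subtraction: the sum-difference image
#'
#' For frame `k` of an `N`-frame series, forms the component-wise sum of
#' the absolute differences against each of the other `N - 1` frames:
#' `B_k = sum_{j != k} |A_k - A_j|`. Pixels belonging to objects that
#' never move cancel in every term, so static content (debris, dirt on
#' the optics) vanishes exactly; a moving cell lights up strongly at its
#' frame-`k` position and only weakly along its trail. Accumulation is
#' done in double precision, which represents the integer sums exactly
#' (the maximum possible value, `(N-1) * 255`, is far below 2^53).
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @param k frame index, 1-based.
#' @return An unnormalized [sum_diff_image] (`values >= 0`).
#' @export
sum_difference <- function(stack, k) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (n < 2) stop("need at least 2 frames for differencing")
  if (k < 1 || k > n) stop("frame index out of range: ", k)
  ak <- stack$frames[[k]]
  b <- matrix(0, nrow(ak), ncol(ak))
  for (j in seq_len(n)[-k])
    b <- b + abs(ak - stack$frames[[j]])
  sum_diff_image(b, source_index = k, normalized = FALSE)
}

#' Sum-difference images for every frame of a series
#'
#' @param stack a [frame_stack()].
#' @param normalize if `TRUE` (default), each image is also passed
#'   through [denoise_normalize()].
#' @return A list of [sum_diff_image] objects, one per frame.
#' @export
sum_difference_stack <- function(stack, normalize = TRUE) {
  out <- lapply(seq_len(length(stack$frames)),
                function(k) sum_difference(stack, k))
  if (normalize) out <- lapply(out, denoise_normalize)
  out
}

#' Denoise and normalize a sum-difference image
#'
#' Subtracts twice the global pixel mean (clipping negatives to zero) to
#' remove the diffuse noise floor, then linearly rescales so that the
#' maximum equals 255, rounding to 8 bits. A constant input (nothing
#' moved) yields an all-zero image rather than an error; downstream
#' detection then reports zero particles.
#'
#' @param B an unnormalized [sum_diff_image].
#' @return A normalized [sum_diff_image] with `min = 0` and `max = 255`
#'   (unless identically zero).
#' @export
denoise_normalize <- function(B) {
  stopifnot(inherits(B, "sum_diff_image"))
  if (B$normalized) stop("input is already normalized")
  v <- pmax(B$values - 2 * mean(B$values), 0)
  m <- max(v)
  if (m > 0) v <- round(v / m * 255)
  sum_diff_image(v, source_index = B$source_index, normalized = TRUE)
}

#' Read a PNG frame series from a directory
#'
#' Files are loaded in lexical name order (the naming convention of
#' [write_series()] guarantees this matches acquisition order). Color
#' frames are converted with [to_grayscale()]; files without a `.png`
#' extension are skipped with a warning. The files on disk are never
#' modified.
#'
#' @param directory path containing the PNG series.
#' @param fps,pixel_size_nm acquisition metadata for the returned stack.
#' @return A [frame_stack()].
#' @export
read_series <- function(directory, fps = 30, pixel_size_nm = 94.2) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  all_files <- sort(list.files(directory, full.names = TRUE))
  all_files <- all_files[!dir.exists(all_files)]
  is_png <- grepl("\\.png$", all_files, ignore.case = TRUE)
  if (any(!is_png))
    warning("skipping non-PNG files: ",
            paste(basename(all_files[!is_png]), collapse = ", "))
  files <- all_files[is_png]
  if (length(files) < 2)
    stop("need at least 2 PNG frames, found ", length(files))
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3]
    a <- round(a * 255)
    to_grayscale(if (length(dim(a)) == 3) a else as.matrix(a))
  })
  d <- dim(frames[[1]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d))
      stop("frame dimension mismatch at ", basename(files[i]))
  frame_stack(frames, fps = fps, pixel_size_nm = pixel_size_nm)
}
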