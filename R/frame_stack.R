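#' Construct a video frame stack
#'
#' A `frame_stack` holds a grayscale high-speed video as a 3-D intensity
#' array indexed `(time, row, column)` together with its acquisition frame
#' rate. It is the substrate for all spectral analysis: beat frequencies are
#' only interpretable relative to `fps`, so a stack cannot exist without one.
#'
#' @param frames numeric 3-D array, dimensions `(T, H, W)` with `T >= 2`
#'   frames. All intensities must be finite and non-negative.
#' @param fps acquisition frame rate in Hz (must be `> 0`). Clinical
#'   high-speed recordings of ciliated epithelium are typically acquired at
#'   500 fps.
#' @param pixel_size_um optional microns per pixel.
#' @param source_id free-text provenance label.
#'
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `fps`, `pixel_size_um` and `source_id`.
#' @export
#' @examples
#' arr <- array(100, dim = c(8, 4, 4))
#' fs <- frame_stack(arr, fps = 500)
#' n_frames(fs)
frame_stack <- function(frames, fps, pixel_size_um = NULL, source_id = "") {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array indexed (time, row, column)", call. = FALSE)
  }
  if (dim(frames)[1] < 2L) {
    stop("a frame stack needs at least 2 frames", call. = FALSE)
  }
  if (!is.numeric(frames) || anyNA(frames) || any(!is.finite(frames))) {
    stop("all frame intensities must be finite numbers", call. = FALSE)
  }
  if (any(frames < 0)) {
    stop("frame intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive frame rate in Hz", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = as.numeric(fps),
         pixel_size_um = pixel_size_um, source_id = source_id),
    class = "frame_stack"
  )
}

#' @rdname frame_stack
#' @param x a `frame_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  dim(x$frames)[1]
}

#' @rdname frame_stack
#' @export
frame_dim <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  c(height = dim(x$frames)[2], width = dim(x$frames)[3])
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %g fps (%.3f s)\n",
              d[1], d[2], d[3], x$fps, d[1] / x$fps))
  if (!is.null(x$pixel_size_um)) cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  if (nzchar(x$source_id)) cat(sprintf("  source: %s\n", x$source_id))
  invisible(x)
}

# constructor for internally generated frames whose invariants hold by
# construction (skips the O(T*H*W) validation scans)
.frame_stack_fast <- function(frames, fps, source_id = "") {
  structure(list(frames = frames, fps = as.numeric(fps),
                 pixel_size_um = NULL, source_id = source_id),
            class = "frame_stack")
}
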