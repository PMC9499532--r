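#' Image frame and frame-series containers
#'
#' A frame is one grayscale rhizotron image: a matrix of non-negative
#' intensities (16-bit range by convention) plus the acquisition time in
#' hours since the start of the experiment and a plant identifier. A frame
#' series is the ordered per-plant stack with strictly increasing times.
#'
#' @param pixels numeric matrix of non-negative intensities; rows are `y`
#'   (downward), columns are `x` (rightward).
#' @param time_h acquisition time, hours since experiment start.
#' @param plant_id plant/rhizotron identifier.
#' @return `new_frame()` returns a `rhizo_frame`; `frame_series()` a
#'   `frame_series` (a list of frames).
#' @export
new_frame <- function(pixels, time_h, plant_id = "plant") {
  stopifnot(is.matrix(pixels), all(pixels >= 0))
  structure(list(pixels = pixels, time_h = as.numeric(time_h),
                 plant_id = plant_id),
            class = "rhizo_frame")
}

#' @param frames list of `rhizo_frame` objects, same shape, increasing time.
#' @rdname new_frame
#' @export
frame_series <- function(frames) {
  stopifnot(length(frames) >= 1)
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames in a series must have the same shape")
  times <- vapply(frames, function(f) f$time_h, numeric(1))
  if (any(diff(times) <= 0))
    stop("acquisition times must be strictly increasing")
  structure(frames, class = "frame_series")
}

#' @export
print.rhizo_frame <- function(x, ...) {
  cat(sprintf("<rhizo_frame %s t=%gh %dx%d px, max %g>\n", x$plant_id,
              x$time_h, ncol(x$pixels), nrow(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series %s: %d frames, t = %s h>\n", x[[1]]$plant_id,
              length(x),
              paste(vapply(x, function(f) f$time_h, numeric(1)),
                    collapse = ", ")))
  invisible(x)
}

series_times <- function(series) {
  vapply(series, function(f) f$time_h, numeric(1))
}

#' Cumulative binary mask series
#'
#' Ordered logical masks aligned to a frame series; the mask at day `d` must
#' contain the mask at day `d - 1` (cumulative root accumulation).
#'
#' @param masks list of logical matrices.
#' @param times_h numeric acquisition times.
#' @param plant_id identifier.
#' @param check if `TRUE`, verify the cumulative invariant.
#' @return a `binary_series` object.
#' @export
binary_series <- function(masks, times_h, plant_id = "plant", check = TRUE) {
  stopifnot(length(masks) == length(times_h))
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  if (check && length(masks) > 1) {
    for (i in 2:length(masks)) {
      if (any(masks[[i - 1]] & !masks[[i]]))
        stop("binary series is not cumulative: mask ", i,
             " does not contain mask ", i - 1)
    }
  }
  structure(list(masks = masks, times_h = as.numeric(times_h),
                 plant_id = plant_id),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("<binary_series %s: %d masks, final coverage %.3f%%>\n",
              x$plant_id, length(x$masks),
              100 * mean(x$masks[[length(x$masks)]])))
  invisible(x)
}
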