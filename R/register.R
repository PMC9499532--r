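# translate matrix content by (dx, dy) pixels (x rightward, y downward),
# filling exposed borders with 0
translate_pixels <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register a frame series by translation-only template matching
#'
#' The first frame is the reference. Each subsequent frame is translated by
#' the integer shift maximizing the normalized cross-correlation of a fixed
#' template region against the reference, searched over
#' `[-max_shift, max_shift]` in both axes. Frames whose correlation peak
#' falls below `min_corr` are flagged as unalignable and left unshifted
#' (reported, not silently moved) for manual screening. Pixels translated in
#' from outside the frame are 0.
#'
#' @param series a [frame_series()].
#' @param template_box `c(x, y, w, h)`: 0-based upper-left corner and size
#'   of the template region; must lie inside the frame.
#' @param max_shift search radius, px.
#' @param min_corr correlation confidence below which a frame is flagged.
#' @return list with `series` (registered [frame_series()]) and `report`
#'   (data.frame `plant_id, time_h, dx, dy, correlation, flagged` of applied
#'   shifts).
#' @export
register_series <- function(series, template_box, max_shift = 50,
                            min_corr = 0.5) {
  stopifnot(inherits(series, "frame_series"), length(template_box) == 4)
  ref <- series[[1]]$pixels
  x0 <- as.integer(template_box[1]); y0 <- as.integer(template_box[2])
  w <- as.integer(template_box[3]); h <- as.integer(template_box[4])
  if (x0 < 0 || y0 < 0 || w < 2 || h < 2 ||
      y0 + h > nrow(ref) || x0 + w > ncol(ref))
    stop("template_box outside frame bounds")
  n <- length(series)
  rep_df <- data.frame(plant_id = series[[1]]$plant_id,
                       time_h = series_times(series),
                       dx = 0L, dy = 0L, correlation = 1, flagged = FALSE)
  out <- series
  if (n > 1) for (i in 2:n) {
    res <- .cpp_ncc_shift(ref, series[[i]]$pixels, y0, x0, h, w, max_shift)
    dx <- -res$dj; dy <- -res$di
    flagged <- !is.finite(res$corr) || res$corr < min_corr
    if (!flagged && (dx != 0 || dy != 0))
      out[[i]]$pixels <- translate_pixels(series[[i]]$pixels, dx, dy)
    rep_df$dx[i] <- if (flagged) 0L else dx
    rep_df$dy[i] <- if (flagged) 0L else dy
    rep_df$correlation[i] <- res$corr
    rep_df$flagged[i] <- flagged
  }
  list(series = out, report = rep_df)
}
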