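# 3x3 median ("Despeckle"): every pixel replaced by the median of its 3x3
# neighbourhood (edges replicated)
median3 <- function(x, maxv = NULL) {
  .cpp_median3(x)
}

median3_binary <- function(b) {
  .cpp_median3(matrix(as.numeric(b), nrow(b), ncol(b))) > 0.5
}

brush3 <- function() EBImage::makeBrush(3, shape = "box")

erode3 <- function(b) EBImage::erode(matrix(as.numeric(b), nrow(b), ncol(b)),
                                     brush3()) > 0.5
dilate3 <- function(b) EBImage::dilate(matrix(as.numeric(b), nrow(b), ncol(b)),
                                       brush3()) > 0.5

# drop connected components (8-connected) smaller than min_px
remove_small_components <- function(b, min_px) {
  if (min_px <= 1 || !any(b)) return(b)
  lab <- label_components(b)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(b), ncol(b))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find pass.
label_components <- function(b) {
  lab <- EBImage::bwlabel(matrix(as.numeric(b), nrow(b), ncol(b)))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; d1 <- lab[-1, -1]    # down-right diagonal
  b1 <- lab[-nr, -1]; d2 <- lab[-1, -nc]   # down-left diagonal
  pairs <- rbind(cbind(a[a > 0 & d1 > 0], d1[a > 0 & d1 > 0]),
                 cbind(b1[b1 > 0 & d2 > 0], d2[b1 > 0 & d2 > 0]))
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Subtract the blank (no-rhizotron) image from a frame
#'
#' Removes the imager's fixed background pattern: pixelwise
#' `max(frame - blank, 0)`.
#'
#' @param frame,blank `rhizo_frame` objects of identical shape (`blank` may
#'   also be a plain matrix).
#' @return the corrected `rhizo_frame`.
#' @export
subtract_blank <- function(frame, blank) {
  b <- if (inherits(blank, "rhizo_frame")) blank$pixels else blank
  if (!all(dim(frame$pixels) == dim(b)))
    stop("frame and blank have different shapes")
  frame$pixels <- pmax(frame$pixels - b, 0)
  frame
}

#' The denoise arithmetic chain
#'
#' The first three steps of the denoising macro, applied in the printed
#' order on the working intensity scale: subtract `c1` (clamp at 0) to drop
#' low values, multiply by `m` (clamp at `working_max`) to amplify high
#' values, subtract `c2` (clamp at 0) to drop values that were not
#' amplified. Exposed separately so the order of operations can be probed:
#' a working value of 10 maps to `(10 - 1.5) * 3 - 8 = 17.5`.
#'
#' @param x numeric matrix (or vector) on the working scale.
#' @param c1,m,c2 chain constants (defaults 1.5, 3, 8).
#' @param working_max top of the working intensity scale.
#' @return transformed values, same shape as `x`.
#' @export
denoise_arithmetic <- function(x, c1 = 1.5, m = 3, c2 = 8,
                               working_max = 255) {
  x <- pmax(x - c1, 0)
  x <- pmin(x * m, working_max)
  pmax(x - c2, 0)
}

#' Denoise a registered frame series into cumulative binary root masks
#'
#' Per frame, in order: rescale intensities to the working range; the
#' subtract-multiply-subtract chain ([denoise_arithmetic()]); 3x3 median
#' filter; global threshold to binary; 3x3 median filter; one binary erosion
#' then one binary dilation (3x3 box); removal of connected components
#' smaller than `min_particle_px`; finally pixelwise OR with the previous
#' day's output, so each day of imaging is added to the previous days and
#' the output masks are cumulative. Accumulation is what preserves old root
#' tissue whose signal has decayed below the threshold in later frames.
#'
#' @param series a [frame_series()].
#' @param c1,m,c2 arithmetic-chain constants (defaults 1.5, 3, 8).
#' @param threshold global binarization threshold on the working scale.
#' @param min_particle_px minimum connected-component area kept, px.
#' @param working_max working intensity scale top (default 255, an
#'   8-bit-like range on which the chain constants are meaningful).
#' @param input_max full-scale value of the input frames (default 16-bit).
#' @return a [binary_series()] of cumulative root masks.
#' @export
denoise_overlay <- function(series, c1 = 1.5, m = 3, c2 = 8,
                            threshold = 10, min_particle_px = 20,
                            working_max = 255, input_max = 65535) {
  stopifnot(inherits(series, "frame_series"))
  if (length(series) == 0) stop("empty series")
  acc <- NULL
  masks <- vector("list", length(series))
  for (i in seq_along(series)) {
    x <- series[[i]]$pixels * (working_max / input_max)
    x <- denoise_arithmetic(x, c1, m, c2, working_max)
    x <- median3(x, working_max)
    b <- x >= threshold
    b <- median3_binary(b)
    b <- dilate3(erode3(b))
    b <- remove_small_components(b, min_particle_px)
    acc <- if (is.null(acc)) b else (acc | b)
    masks[[i]] <- acc
  }
  binary_series(masks, series_times(series),
                plant_id = series[[1]]$plant_id, check = FALSE)
}

#' Invert binary masks
#'
#' Logical complement of each mask, making the root black on white as
#' required by downstream vectorization tools; applying twice is the
#' identity.
#'
#' @param series a [binary_series()] (or a single logical matrix for
#'   [invert_mask()]).
#' @return the complemented series (cumulativity no longer applies, so it
#'   is not re-checked).
#' @export
invert_series <- function(series) {
  stopifnot(inherits(series, "binary_series"))
  binary_series(lapply(series$masks, function(m) !m), series$times_h,
                series$plant_id, check = FALSE)
}

#' @rdname invert_series
#' @param mask logical matrix.
#' @export
invert_mask <- function(mask) !mask

#' Isolate new growth between two consecutive cumulative masks
#'
#' Dilates the earlier mask twice (3x3 box) and removes it from the later
#' mask: `curr & !dilate(dilate(prev))`. The double dilation guarantees the
#' result is disjoint from a 2-pixel margin around the earlier root system,
#' so only genuinely new growth remains.
#'
#' @param prev,curr logical masks from consecutive days of a cumulative
#'   series, same shape.
#' @return logical mask of new growth.
#' @export
tip_tracking <- function(prev, curr) {
  if (!all(dim(prev) == dim(curr))) stop("masks have different shapes")
  if (!any(prev)) return(curr)
  curr & !dilate3(dilate3(prev))
}

#' Tip (new-growth) masks for a whole cumulative series
#'
#' @param series a cumulative [binary_series()].
#' @return a list of new-growth masks, one per frame; the first entry is
#'   the first mask itself (everything is new on the first imaging day).
#' @export
tip_series <- function(series) {
  stopifnot(inherits(series, "binary_series"))
  n <- length(series$masks)
  out <- vector("list", n)
  out[[1]] <- series$masks[[1]]
  if (n > 1) for (i in 2:n)
    out[[i]] <- tip_tracking(series$masks[[i - 1]], series$masks[[i]])
  out
}
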