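#' Liver gray window
#'
#' The gray range in which liver tissue concentrates on abdominal CT,
#' commonly 130 to 150 gray units.
#'
#' @param low,high window edges in gray units, `low < high`.
#' @return object of class `liver_window`.
#' @export
liver_window <- function(low = 130, high = 150) {
  if (!(low < high)) rs_stop("window requires low < high", "ropseg_parameter_error")
  structure(list(low = low, high = high), class = "liver_window")
}

#' Estimate the liver window from an image patch
#'
#' Builds the integer-bin gray histogram of the patch, takes its mode as the
#' liver peak, and returns `peak +/- w` where `w` is the half-width at half
#' maximum of the histogram (never below 5 gray units). Without a patch the
#' standard window (130, 150) is returned.
#'
#' @param image 2D matrix.
#' @param patch_bbox a [bbox2d] selecting the statistics patch, or `NULL`.
#' @return a [liver_window].
#' @export
estimate_liver_window <- function(image, patch_bbox = NULL) {
  if (is.null(patch_bbox)) return(liver_window())
  patch <- crop(image, patch_bbox)
  if (diff(range(patch)) < 1e-12) {
    rs_stop("constant patch: cannot estimate a window", "ropseg_estimation_error")
  }
  g <- round(as.vector(patch))
  shift <- min(g)
  counts <- tabulate(g - shift + 1L)
  peak_bin <- which.max(counts)
  half <- counts[peak_bin] / 2
  lo <- peak_bin
  while (lo > 1L && counts[lo - 1L] >= half) lo <- lo - 1L
  hi <- peak_bin
  while (hi < length(counts) && counts[hi + 1L] >= half) hi <- hi + 1L
  w <- max(peak_bin - lo, hi - peak_bin, 5L)
  peak <- peak_bin + shift - 1L
  liver_window(peak - w, peak + w)
}

#' Window and contrast-stretch an image
#'
#' Pixels outside `[low, high]` are set to 0; in-window pixels are mapped
#' linearly with `low -> 1` and `high -> out_max`, so preserved pixels never
#' collide with the zeroed background.
#'
#' @param image 2D matrix.
#' @param window a [liver_window].
#' @param out_max output gray ceiling (default 255).
#' @return windowed and stretched matrix in `{0} U [1, out_max]`.
#' @export
window_and_stretch <- function(image, window = liver_window(), out_max = 255) {
  inside <- image >= window$low & image <= window$high
  out <- matrix(0, nrow(image), ncol(image))
  out[inside] <- 1 + (image[inside] - window$low) /
    (window$high - window$low) * (out_max - 1)
  out
}

#' 5x5 median smoothing
#'
#' @param image 2D matrix, at least 5x5; borders are edge-replicated.
#' @return median-filtered matrix of the same shape.
#' @export
median5 <- function(image) median_filter(image, 5L)

#' Preprocess a CT slice
#'
#' Pipeline order: liver-window selection (histogram of the patch, or the
#' standard 130-150 window), contrast stretching, then 5x5 median smoothing.
#'
#' @param image 2D matrix.
#' @param patch_bbox optional statistics patch for window estimation.
#' @param window explicit [liver_window] overriding estimation.
#' @param out_max output gray ceiling.
#' @return preprocessed matrix.
#' @export
preprocess_slice <- function(image, patch_bbox = NULL, window = NULL,
                             out_max = 255) {
  if (is.null(window)) {
    window <- tryCatch(estimate_liver_window(image, patch_bbox),
                       ropseg_estimation_error = function(e) liver_window())
  }
  median5(window_and_stretch(image, window, out_max))
}
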