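#' Segmentation evaluation metrics
#'
#' The six standard volumetric and surface criteria for comparing a predicted
#' mask `B` against a ground-truth mask `A`: volumetric overlap error (VOE,
#' the complement of the Jaccard coefficient), signed relative volume
#' difference (RVD), average / root-mean-square / maximum symmetric surface
#' distance (ASD, RMSD, MSD, in mm) and the Dice score. Surface voxels are
#' foreground voxels with at least one background face-neighbour
#' (6-connectivity in 3D, 4-connectivity in 2D; out-of-grid counts as
#' background). Distances are Euclidean between voxel centres after scaling
#' each axis by its spacing, so anisotropic grids are handled.
#'
#' @name metrics
NULL

#' Extract surface voxels of a binary mask
#'
#' @param mask binary array, matrix or [ct_mask].
#' @return integer matrix of 0-based voxel coordinates, one row per surface
#'   voxel; columns `(slice, row, col)` (or `(row, col)` for a single-slice
#'   mask passed as a matrix). Empty mask gives a 0-row matrix.
#' @export
surface_voxels <- function(mask) {
  was_matrix <- is.matrix(if (inherits(mask, "ct_mask")) mask$voxels else mask)
  v <- mask_array(mask)
  surf <- surface_indicator(v)
  idx <- which(surf != 0, arr.ind = TRUE)
  out <- idx - 1L
  if (was_matrix) out <- out[, 2:3, drop = FALSE]
  colnames(out) <- if (ncol(out) == 3L) c("slice", "row", "col") else c("row", "col")
  out
}

# Binary array of same shape marking surface voxels (face-connectivity).
surface_indicator <- function(v) {
  d <- dim(v)
  if (all(d == 1L)) return((v != 0) * 1)
  bg <- array(FALSE, dim = d)
  for (ax in 1:3) {
    if (d[ax] == 1L) next  # flat axis: treat as 2D, no surface from this axis?
    nb_lo <- shift_array(v, ax, 1L)
    nb_hi <- shift_array(v, ax, -1L)
    bg <- bg | nb_lo == 0 | nb_hi == 0
  }
  # A flat axis still exposes the voxel to out-of-grid background on that
  # axis ONLY in true 3D use; a single-slice mask is treated as 2D, so flat
  # axes are ignored above and genuinely 2D surfaces result.
  (v != 0 & bg) * 1
}

# Shift array along axis by k, filling with 0 (out-of-grid = background).
shift_array <- function(v, axis, k) {
  d <- dim(v)
  idx <- lapply(d, seq_len)
  src <- idx[[axis]] - k
  pad <- src < 1L | src > d[axis]
  src[pad] <- 1L
  out <- do.call(`[`, c(list(v), replace(idx, axis, list(src)), drop = FALSE))
  if (any(pad)) {
    sel <- replace(idx, axis, list(which(pad)))
    out <- do.call(`[<-`, c(list(out), sel, list(0)))
  }
  out
}

#' @rdname metrics
#' @param A,B binary masks of identical shape (ground truth, prediction).
#' @return `voe(A, B)`: percent volumetric overlap error.
#' @export
voe <- function(A, B) {
  a <- mask_array(A); b <- mask_array(B)
  check_same_shape(a, b)
  uni <- sum(a | b)
  if (uni == 0) rs_stop("VOE undefined for two empty masks", "ropseg_metric_error")
  100 * (1 - sum(a & b) / uni)
}

#' @rdname metrics
#' @return `rvd(A, B)`: signed percent relative volume difference
#'   `100 (|B| - |A|) / |A|` (asymmetric by definition).
#' @export
rvd <- function(A, B) {
  a <- mask_array(A); b <- mask_array(B)
  check_same_shape(a, b)
  na <- sum(a)
  if (na == 0) rs_stop("RVD undefined for empty ground truth", "ropseg_metric_error")
  100 * (sum(b) - na) / na
}

#' @rdname metrics
#' @return `dice(A, B)`: percent Dice score `100 * 2|A n B| / (|A| + |B|)`.
#' @export
dice <- function(A, B) {
  a <- mask_array(A); b <- mask_array(B)
  check_same_shape(a, b)
  tot <- sum(a) + sum(b)
  if (tot == 0) rs_stop("Dice undefined for two empty masks", "ropseg_metric_error")
  100 * 2 * sum(a & b) / tot
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    rs_stop("masks must have identical shapes", "ropseg_validation_error")
  }
}

# Directed nearest-surface distances from each row of pts_from to the set
# pts_to (physical mm coordinates). Chunked vectorized computation.
directed_min_dists <- function(pts_from, pts_to, chunk = 1024L) {
  nf <- nrow(pts_from)
  out <- numeric(nf)
  i <- 1L
  while (i <= nf) {
    j <- min(i + chunk - 1L, nf)
    blk <- pts_from[i:j, , drop = FALSE]
    # per-axis differences keep full fp precision (no cancellation)
    d2 <- outer(blk[, 1], pts_to[, 1], "-")^2 +
      outer(blk[, 2], pts_to[, 2], "-")^2 +
      outer(blk[, 3], pts_to[, 3], "-")^2
    out[i:j] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

surface_points_mm <- function(mask, spacing) {
  v <- mask_array(mask)
  s <- surface_voxels(v)
  if (nrow(s) == 0L) {
    rs_stop("surface distance undefined for an empty mask", "ropseg_metric_error")
  }
  sweep(s, 2L, spacing, `*`)
}

symmetric_surface_dists <- function(A, B, spacing) {
  spacing <- as.numeric(spacing)
  a <- mask_array(A); b <- mask_array(B)
  check_same_shape(a, b)
  pa <- surface_points_mm(a, spacing)
  pb <- surface_points_mm(b, spacing)
  list(ab = directed_min_dists(pa, pb), ba = directed_min_dists(pb, pa))
}

#' @rdname metrics
#' @param spacing `(z, y, x)` voxel spacing in mm.
#' @return `asd(A, B, spacing)`: average symmetric surface distance in mm.
#' @export
asd <- function(A, B, spacing = c(1, 1, 1)) {
  d <- symmetric_surface_dists(A, B, spacing)
  (sum(d$ab) + sum(d$ba)) / (length(d$ab) + length(d$ba))
}

#' @rdname metrics
#' @return `rmsd(A, B, spacing)`: root-mean-square symmetric surface distance
#'   in mm.
#' @export
rmsd <- function(A, B, spacing = c(1, 1, 1)) {
  d <- symmetric_surface_dists(A, B, spacing)
  sqrt((sum(d$ab^2) + sum(d$ba^2)) / (length(d$ab) + length(d$ba)))
}

#' @rdname metrics
#' @return `msd(A, B, spacing)`: maximum symmetric surface distance in mm
#'   (max of the two directed maxima).
#' @export
msd <- function(A, B, spacing = c(1, 1, 1)) {
  d <- symmetric_surface_dists(A, B, spacing)
  max(max(d$ab), max(d$ba))
}

#' Evaluate all six segmentation metrics
#'
#' @param A ground-truth binary mask.
#' @param B predicted binary mask, same shape.
#' @param spacing `(z, y, x)` spacing in mm.
#' @return a `metrics_report` list with fields `voe`, `rvd`, `asd`, `rmsd`,
#'   `msd`, `dice`, voxel counts, spacing, and per-metric `flags` naming any
#'   metric that was undefined (its value is then `NA`).
#' @export
evaluate_all <- function(A, B, spacing = c(1, 1, 1)) {
  a <- mask_array(A); b <- mask_array(B)
  check_same_shape(a, b)
  flags <- character(0)
  safe <- function(name, f) {
    tryCatch(f(), ropseg_metric_error = function(e) {
      flags <<- c(flags, name)
      NA_real_
    })
  }
  surf_ok <- sum(a) > 0 && sum(b) > 0
  d <- if (surf_ok) symmetric_surface_dists(a, b, spacing) else NULL
  rep <- list(
    voe = safe("voe", function() voe(a, b)),
    rvd = safe("rvd", function() rvd(a, b)),
    asd = if (surf_ok) (sum(d$ab) + sum(d$ba)) / (length(d$ab) + length(d$ba)) else {
      flags <- c(flags, "asd"); NA_real_
    },
    rmsd = if (surf_ok) sqrt((sum(d$ab^2) + sum(d$ba^2)) / (length(d$ab) + length(d$ba))) else NA_real_,
    msd = if (surf_ok) max(max(d$ab), max(d$ba)) else NA_real_,
    dice = safe("dice", function() dice(a, b)),
    n_voxels_A = sum(a), n_voxels_B = sum(b),
    spacing = as.numeric(spacing)
  )
  if (!surf_ok) flags <- unique(c(flags, "asd", "rmsd", "msd"))
  rep$flags <- flags
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("VOE %.2f%%  RVD %+.2f%%  ASD %.3f mm  RMSD %.3f mm  MSD %.3f mm  DICE %.2f%%\n",
              x$voe, x$rvd, x$asd, x$rmsd, x$msd, x$dice))
  if (length(x$flags)) cat("flagged undefined:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report` from [evaluate_all()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  out <- unclass(report)
  out$schema <- "ropseg-metrics-v1"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
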