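#' Registration-based organ positioning (ROP)
#'
#' ROP finds a per-slice liver bounding box on an unseen CT volume without
#' segmenting it: a standard template subject (the one whose convex-hull
#' liver volume is closest to the cohort mean) is registered, slice by slice,
#' onto the unseen slice. The template slice is always the float image and
#' the unseen slice the reference, so the box is carried forward through the
#' forward transform and no inverse registration is ever run. The template's
#' liver-label extent, mapped through the recovered affine, gives the box.
#'
#' @name rop
NULL

#' 2D affine transform
#'
#' Maps 0-based float-image pixel coordinates `(row, col)` into reference
#' coordinates: `p' = A p + t`.
#'
#' @param matrix 2x3 matrix `[A | t]` with non-singular linear part.
#' @return object of class `affine2d`.
#' @export
affine2d <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 2L, 3L)
  if (abs(det(m[, 1:2])) <= 1e-8) {
    rs_stop("affine linear part is singular", "ropseg_geometry_error")
  }
  structure(list(matrix = m), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d [A | t]:\n")
  print(round(x$matrix, 4))
  invisible(x)
}

# Apply an affine2d to 0-based (row, col) points given as an n x 2 matrix.
affine_apply <- function(tf, pts) {
  t(tf$matrix[, 1:2] %*% t(pts)) + rep(tf$matrix[, 3], each = nrow(pts))
}

affine_identity <- function() affine2d(cbind(diag(2), c(0, 0)))

#' Interpolate a volume (and its label) along z
#'
#' Linear interpolation onto a grid of spacing `target_dz`; the label is
#' interpolated as a real field and re-binarized at 0.5.
#'
#' @param volume a [ct_volume] with at least 2 slices.
#' @param label optional [ct_mask] aligned to `volume`.
#' @param target_dz target slice spacing in mm (> 0).
#' @return list with interpolated `volume` and (if given) `label`.
#' @export
interpolate_z <- function(volume, label = NULL, target_dz = 1.60) {
  stopifnot(inherits(volume, "ct_volume"))
  if (target_dz <= 0) rs_stop("target_dz must be > 0", "ropseg_parameter_error")
  d <- dim(volume$voxels)
  if (d[1] < 2L) {
    rs_stop("z interpolation needs at least 2 slices", "ropseg_parameter_error")
  }
  dz <- volume$spacing[1]
  extent <- (d[1] - 1) * dz
  n_out <- round(extent / target_dz) + 1L
  zpos <- seq(0, extent, length.out = n_out) / dz  # in input slice units
  lo <- pmin(floor(zpos), d[1] - 2)
  w <- zpos - lo
  out <- array(0, dim = c(n_out, d[2], d[3]))
  lab_out <- if (!is.null(label)) array(0, dim = c(n_out, d[2], d[3]))
  lab_v <- if (!is.null(label)) mask_array(label)
  for (i in seq_len(n_out)) {
    a <- lo[i] + 1L
    out[i, , ] <- (1 - w[i]) * volume$voxels[a, , ] + w[i] * volume$voxels[a + 1L, , ]
    if (!is.null(label)) {
      lab_out[i, , ] <- ((1 - w[i]) * lab_v[a, , ] + w[i] * lab_v[a + 1L, , ] >= 0.5) * 1
    }
  }
  res <- list(volume = ct_volume(out, spacing = c(target_dz, volume$spacing[2:3]),
                                 id = volume$id))
  if (!is.null(label)) {
    res$label <- ct_mask(lab_out, label_name = label$label_name,
                         spacing = res$volume$spacing)
  }
  res
}

#' Select the standard template subject from a cohort
#'
#' Scores each subject by the convex-hull volume of its liver label and picks
#' the subject closest to the cohort mean volume (ties to the lowest index).
#' The template pack records the standard volume, label, per-slice tight
#' boxes, and provenance.
#'
#' @param cohort list of subjects, each a list with `volume` ([ct_volume])
#'   and `liver` ([ct_mask]).
#' @return a `template_pack` list with `standard_volume`, `standard_label`,
#'   `bboxes` (per-slice [bbox2d] or `NULL`), `provenance`.
#' @export
select_template <- function(cohort) {
  if (length(cohort) < 2L) {
    rs_stop("template selection needs a cohort of at least 2 subjects",
            "ropseg_parameter_error")
  }
  vols <- vapply(cohort, function(s) {
    convex_hull_volume(s$liver, spacing = s$volume$spacing)
  }, numeric(1))
  pick <- which.min(abs(vols - mean(vols)))  # which.min takes the first tie
  std <- cohort[[pick]]
  lab <- mask_array(std$liver)
  boxes <- lapply(seq_len(dim(lab)[1]), function(i) tight_bbox(lab[i, , ]))
  structure(list(standard_volume = std$volume, standard_label = std$liver,
                 bboxes = boxes,
                 provenance = list(subject_index = pick, subject_id = std$volume$id,
                                   hull_volume_cm3 = vols[pick],
                                   cohort_mean_cm3 = mean(vols))),
            class = "template_pack")
}

#' @export
print.template_pack <- function(x, ...) {
  cat(sprintf("template_pack from subject %d ('%s'), hull volume %.0f cm^3 (cohort mean %.0f)\n",
              x$provenance$subject_index, x$provenance$subject_id,
              x$provenance$hull_volume_cm3, x$provenance$cohort_mean_cm3))
  invisible(x)
}

# --- slice registration ------------------------------------------------------

# Build the 2x3 matrix for parameter vector
# p = (t_row, t_col, rot, log_scale_row, log_scale_col, shear)
# mapping float (row, col) -> reference (row, col) about the image centres.
params_to_affine <- function(p, centre_float, centre_ref) {
  rot <- p[3]
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  S <- matrix(c(exp(p[4]), 0, p[6], exp(p[5])), 2, 2)
  A <- R %*% S
  t <- centre_ref + p[1:2] - A %*% centre_float
  cbind(A, t)
}

# Sample `float_img` at reference-frame points `coords` under parameters p.
# Pulls back through the closed-form inverse of the 2x2 linear part.
resample_float <- function(float_img, p, centre_float, ref_shape, coords) {
  M <- params_to_affine(p, centre_float, c((ref_shape[1] - 1) / 2, (ref_shape[2] - 1) / 2))
  Ainv <- solve(M[, 1:2])
  src <- t(Ainv %*% (t(coords) - M[, 3]))
  bilinear_sample(float_img, src[, 1], src[, 2])
}

ref_coords <- function(shape, stride = 1L) {
  rows <- seq.int(0L, shape[1] - 1L, by = stride)
  cols <- seq.int(0L, shape[2] - 1L, by = stride)
  cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
}

# Negative normalized cross-correlation over the valid overlap (vectors).
metric_ncc <- function(refv, smpv) {
  ok <- !is.na(smpv)
  if (mean(ok) < 0.3) return(2)
  r <- refv[ok]; s <- smpv[ok]
  if (stats::sd(r) < 1e-12 || stats::sd(s) < 1e-12) return(2)
  1 - stats::cor(r, s)
}

# Mean squared difference on range-normalized intensities (vectors).
metric_mse <- function(refv, smpv, ref_scale) {
  ok <- !is.na(smpv)
  if (mean(ok) < 0.3) return(2)
  mean(((refv[ok] - smpv[ok]) / ref_scale)^2)
}

downsample2 <- function(m) {
  n <- (nrow(m) %/% 2) * 2; k <- (ncol(m) %/% 2) * 2
  m <- m[1:n, 1:k, drop = FALSE]
  (m[seq(1, n, 2), seq(1, k, 2)] + m[seq(2, n, 2), seq(1, k, 2)] +
     m[seq(1, n, 2), seq(2, k, 2)] + m[seq(2, n, 2), seq(2, k, 2)]) / 4
}

#' Register a float slice onto a reference slice
#'
#' Two-stage intensity-based 2D affine registration: a coarse stage driven by
#' cross-correlation on 2x-downsampled images with a large optimizer step,
#' then a fine stage with mean-squares metric, a step one tenth the size and
#' four times the iterations. The fine stage starts from the coarse optimum,
#' so its objective never ends above the coarse one.
#'
#' @param reference 2D matrix, the fixed target frame (must be non-constant).
#' @param float_img 2D matrix, the image being transformed (the template).
#' @param coarse_then_fine run the coarse stage first (default) or only the
#'   fine stage (used when warm-starting from a neighbouring slice).
#' @param init optional `affine2d`-free warm start: a parameter vector from a
#'   previous `slice_registration`.
#' @return object of class `slice_registration`: the recovered [affine2d]
#'   (float to reference), the parameter vector, final metric values and a
#'   `converged` flag (non-convergence warns and returns best-so-far).
#' @export
register_slice <- function(reference, float_img, coarse_then_fine = TRUE,
                           init = NULL) {
  if (!identical(length(dim(reference)), length(dim(float_img)))) {
    rs_stop("reference and float must both be 2D", "ropseg_validation_error")
  }
  if (stats::sd(reference) < 1e-12) {
    rs_stop("reference image is constant", "ropseg_validation_error")
  }
  p0 <- if (is.null(init)) rep(0, 6) else as.numeric(init)
  cf <- c((nrow(float_img) - 1) / 2, (ncol(float_img) - 1) / 2)
  coarse_val <- NA_real_

  if (coarse_then_fine) {
    ref_lo <- downsample2(reference)
    flo_lo <- downsample2(float_img)
    cf_lo <- c((nrow(flo_lo) - 1) / 2, (ncol(flo_lo) - 1) / 2)
    coords_lo <- ref_coords(dim(ref_lo))
    refv_lo <- ref_lo[coords_lo[, 1] + 1 + coords_lo[, 2] * nrow(ref_lo)]
    p_lo <- p0
    p_lo[1:2] <- p_lo[1:2] / 2
    obj_lo <- function(p) {
      metric_ncc(refv_lo, resample_float(flo_lo, p, cf_lo, dim(ref_lo), coords_lo))
    }
    oc <- stats::optim(p_lo, obj_lo, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-6,
                                      parscale = c(6, 6, 0.12, 0.08, 0.08, 0.08)))
    p0 <- oc$par
    p0[1:2] <- p0[1:2] * 2
    coarse_val <- oc$value
  }

  # fine metric sampled on a stride-2 grid of the full-resolution images
  coords <- ref_coords(dim(reference), stride = 2L)
  refv <- reference[coords[, 1] + 1 + coords[, 2] * nrow(reference)]
  ref_scale <- max(diff(range(reference)), 1e-8)
  obj <- function(p) {
    metric_mse(refv, resample_float(float_img, p, cf, dim(reference), coords),
               ref_scale)
  }
  of <- stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 800, reltol = 1e-7,
                                    parscale = c(0.6, 0.6, 0.012, 0.008, 0.008, 0.008)))
  converged <- of$convergence == 0L
  if (!converged) {
    rs_warn("fine registration hit the iteration cap; returning best-so-far transform",
            "ropseg_registration_warning")
  }
  tf <- affine2d(params_to_affine(of$par, cf,
                                  c((nrow(reference) - 1) / 2, (ncol(reference) - 1) / 2)))
  structure(list(transform = tf, params = of$par, metric_fine = of$value,
                 metric_coarse = coarse_val, converged = converged),
            class = "slice_registration")
}

#' Propagate a label bounding box through a transform
#'
#' All label-1 pixel coordinates of the template slice are pushed through the
#' float-to-reference affine; the box is the min/max of the transformed
#' coordinates, rounded outward (floor on minima, ceiling on maxima), clipped
#' to the reference frame, and converted to half-open indexing.
#'
#' @param transform an [affine2d] (or a `slice_registration`).
#' @param standard_label_slice binary matrix, non-empty.
#' @param reference_shape `(n_rows, n_cols)` of the reference slice.
#' @param margin extra pixels added on every side after propagation.
#' @return a [bbox2d].
#' @export
propagate_bbox <- function(transform, standard_label_slice, reference_shape,
                           margin = 0L) {
  if (inherits(transform, "slice_registration")) transform <- transform$transform
  idx <- which(standard_label_slice != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    rs_stop("standard label slice is empty", "ropseg_positioning_error")
  }
  pts <- affine_apply(transform, idx - 1)
  rmin <- floor(min(pts[, 1])); rmax <- ceiling(max(pts[, 1])) + 1L
  cmin <- floor(min(pts[, 2])); cmax <- ceiling(max(pts[, 2])) + 1L
  rmin <- max(rmin, 0L); cmin <- max(cmin, 0L)
  rmax <- min(rmax, reference_shape[1]); cmax <- min(cmax, reference_shape[2])
  if (rmin >= rmax || cmin >= cmax) {
    rs_stop("transformed label falls outside the reference frame",
            "ropseg_positioning_error")
  }
  b <- bbox2d(rmin, cmin, rmax, cmax)
  if (margin > 0L) b <- bbox_expand(b, as.integer(margin), reference_shape)
  b
}

#' Position the liver in an unseen volume
#'
#' For every slice of `volume`, registers the z-corresponding template slice
#' (proportional index after both grids are brought to a common z spacing)
#' onto it and propagates the template liver box. Slices whose corresponding
#' template slice carries no liver within `z_extend` slices return no box.
#' Consecutive slices warm-start from the previous transform; the coarse
#' stage reruns whenever the warm-started fine metric degrades.
#'
#' @param volume a [ct_volume].
#' @param template a `template_pack` from [select_template()].
#' @param margin box margin in pixels (default 5).
#' @param enhanced preprocess both slices (liver windowing) before
#'   registration (default TRUE, matching the pipeline order).
#' @param z_extend how many slices beyond the template's liver range the
#'   nearest liver-bearing template slice may be borrowed (default 4).
#' @param target_dz common z spacing in mm for template/volume
#'   correspondence (default 1.60); `NULL` skips resampling.
#' @return list of per-slice records `(slice, bbox, flagged)`; `bbox` is
#'   `NULL` where no box applies.
#' @export
position_liver <- function(volume, template, margin = 5L, enhanced = TRUE,
                           z_extend = 4L, target_dz = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(template, "template_pack"))
  tvol <- template$standard_volume
  tlab <- mask_array(template$standard_label)
  if (!is.null(target_dz) && dim(tvol$voxels)[1] > 1L &&
      abs(tvol$spacing[1] - target_dz) > 1e-9) {
    r <- interpolate_z(tvol, template$standard_label, target_dz)
    tvol <- r$volume; tlab <- mask_array(r$label)
  }
  nz_t <- dim(tvol$voxels)[1]
  nz_v <- dim(volume$voxels)[1]
  liver_slices <- which(apply(tlab, 1, sum) > 0)
  prep <- function(sl) if (enhanced) preprocess_slice(sl) else sl
  tslices <- lapply(seq_len(nz_t), function(j) prep(tvol$voxels[j, , ]))

  out <- vector("list", nz_v)
  warm <- NULL
  prev_metric <- Inf
  for (i in seq_len(nz_v)) {
    j <- if (nz_v > 1L) round((i - 1) * (nz_t - 1) / (nz_v - 1)) + 1L else
      round(stats::median(liver_slices))
    rec <- list(slice = i - 1L, bbox = NULL, flagged = FALSE)
    if (length(liver_slices) == 0L) {
      out[[i]] <- rec
      next
    }
    jn <- liver_slices[which.min(abs(liver_slices - j))]
    if (abs(jn - j) > z_extend) {
      out[[i]] <- rec
      next
    }
    ref <- prep(volume$voxels[i, , ])
    res <- tryCatch({
      if (stats::sd(ref) < 1e-12) rs_stop("constant slice", "ropseg_validation_error")
      reg <- withCallingHandlers(
        register_slice(ref, tslices[[jn]],
                       coarse_then_fine = is.null(warm) || prev_metric > 0.05,
                       init = warm),
        ropseg_registration_warning = function(w) invokeRestart("muffleWarning"))
      warm <<- reg$params
      prev_metric <<- reg$metric_fine
      rec$bbox <- propagate_bbox(reg, tlab[jn, , ], dim(ref), margin = margin)
      rec
    }, ropseg_error = function(e) {
      rec$flagged <- TRUE
      rec
    })
    out[[i]] <- res
  }
  out
}
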