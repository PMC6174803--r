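#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid in `(slice, row, col)` order with
#' physical voxel spacing `(z, y, x)` in millimetres. Slices are ascending
#' along z. All coordinates used in the package are 0-based and boxes are
#' half-open.
#'
#' @param voxels numeric 3D array `(slice, row, col)`; a matrix is promoted to
#'   a single-slice volume.
#' @param spacing numeric length-3, `(z, y, x)` spacing in mm, all positive.
#' @param id subject identifier string.
#' @return object of class `ct_volume` with fields `voxels`, `spacing`, `id`.
#' @export
ct_volume <- function(voxels, spacing = c(1.60, 0.78, 0.78), id = "subject") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L) {
    rs_stop("voxels must be a non-empty 3D array (slice, row, col)",
            "ropseg_validation_error")
  }
  if (!all(is.finite(voxels))) {
    rs_stop("voxels must be finite", "ropseg_validation_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    rs_stop("spacing must be three positive numbers (z, y, x) in mm",
            "ropseg_validation_error")
  }
  structure(list(voxels = voxels, spacing = spacing, id = as.character(id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume '%s': %d slices of %dx%d, spacing (%.3g, %.3g, %.3g) mm\n",
              x$id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Binary mask container
#'
#' A binary grid aligned to a [ct_volume] (or a single slice). Values must be
#' exactly 0 or 1.
#'
#' @param voxels binary array or matrix.
#' @param label_name one of `liver`, `tumor`, `coarse`, `fcm`, `elm`, `fine`.
#' @param spacing optional `(z, y, x)` spacing in mm carried for metric
#'   evaluation.
#' @return object of class `ct_mask`.
#' @export
ct_mask <- function(voxels, label_name = "liver", spacing = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L) {
    rs_stop("mask voxels must be a non-empty 3D array", "ropseg_validation_error")
  }
  if (!is_binary(voxels)) {
    rs_stop("mask values must all be 0 or 1", "ropseg_validation_error")
  }
  label_name <- match.arg(label_name,
                          c("liver", "tumor", "coarse", "fcm", "elm", "fine"))
  structure(list(voxels = voxels, label_name = label_name,
                 spacing = if (!is.null(spacing)) as.numeric(spacing)),
            class = "ct_mask")
}

#' @export
print.ct_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_mask '%s': %d slices of %dx%d, %d foreground voxels\n",
              x$label_name, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# Accept a ct_mask, array or matrix and return a binary 3D array.
mask_array <- function(x) {
  v <- if (inherits(x, "ct_mask")) x$voxels else x
  if (is.matrix(v)) v <- array(v, dim = c(1L, dim(v)))
  if (!is_binary(v)) rs_stop("mask values must all be 0 or 1",
                             "ropseg_validation_error")
  v
}

#' Per-slice axis-aligned bounding box
#'
#' 0-based half-open pixel box `[row_min, row_max) x [col_min, col_max)`.
#'
#' @param row_min,col_min,row_max,col_max integer pixel indices.
#' @return object of class `bbox2d`.
#' @export
bbox2d <- function(row_min, col_min, row_max, col_max) {
  b <- structure(list(row_min = as.integer(row_min), col_min = as.integer(col_min),
                      row_max = as.integer(row_max), col_max = as.integer(col_max)),
                 class = "bbox2d")
  if (b$row_min < 0L || b$col_min < 0L ||
      b$row_min >= b$row_max || b$col_min >= b$col_max) {
    rs_stop("bbox must satisfy 0 <= min < max on both axes",
            "ropseg_geometry_error")
  }
  b
}

#' @export
print.bbox2d <- function(x, ...) {
  cat(sprintf("bbox2d rows [%d, %d) cols [%d, %d)\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

bbox_area <- function(b) (b$row_max - b$row_min) * (b$col_max - b$col_min)

# Expand a box by `margin` pixels and clip to an image shape (n_rows, n_cols).
bbox_expand <- function(b, margin, shape) {
  bbox2d(max(0L, b$row_min - margin), max(0L, b$col_min - margin),
         min(shape[1], b$row_max + margin), min(shape[2], b$col_max + margin))
}

#' Tight bounding box of a binary slice
#'
#' @param mask2d binary matrix.
#' @return a [bbox2d] (half-open) covering exactly the foreground, or `NULL`
#'   for an empty slice.
#' @export
tight_bbox <- function(mask2d) {
  idx <- which(mask2d != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  bbox2d(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L, max(idx[, 1]), max(idx[, 2]))
}

#' Crop a 2D grid to a bounding box
#'
#' @param image matrix.
#' @param bbox a [bbox2d] inside the image bounds.
#' @return the cropped matrix of shape
#'   `(row_max - row_min, col_max - col_min)`.
#' @export
crop <- function(image, bbox) {
  if (bbox$row_max > nrow(image) || bbox$col_max > ncol(image)) {
    rs_stop("bbox exceeds image bounds", "ropseg_geometry_error")
  }
  image[(bbox$row_min + 1L):bbox$row_max, (bbox$col_min + 1L):bbox$col_max,
        drop = FALSE]
}

nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Read a CT volume
#'
#' Reads either a NIfTI file (spacing from the header) or a directory of
#' equally sized 8/16-bit grayscale PNG slices in ascending filename order
#' (spacing from the `spacing` argument).
#'
#' @param path NIfTI file or slice-stack directory.
#' @param spacing `(z, y, x)` mm used for slice stacks; ignored for NIfTI.
#' @param id subject identifier; defaults to the file/directory name.
#' @return a [ct_volume].
#' @export
read_volume <- function(path, spacing = c(1.60, 0.78, 0.78), id = NULL) {
  if (!file.exists(path)) {
    rs_stop(sprintf("no such file or directory: %s", path),
            "ropseg_not_found_error")
  }
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) {
      rs_stop(sprintf("no PNG slices found in %s", path), "ropseg_format_error")
    }
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f, info = TRUE)
      depth <- attr(m, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      if (length(dim(m)) == 3L) m <- m[, , 1]  # grayscale stored with channels
      round(m * (2^depth - 1))
    })
    shp <- dim(slices[[1]])
    if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1)))) {
      rs_stop("slices in the stack have inconsistent shapes",
              "ropseg_format_error")
    }
    vox <- array(0, dim = c(length(slices), shp[1], shp[2]))
    for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]
    return(ct_volume(vox, spacing, id))
  }
  if (!nifti_path(path)) {
    rs_stop(sprintf("unsupported volume format: %s", path), "ropseg_format_error")
  }
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  pd <- RNifti::pixdim(img)  # (x, y, z)
  vox <- aperm(a, c(3L, 2L, 1L))  # file (x, y, z) -> (slice, row, col)
  ct_volume(vox, spacing = c(pd[3], pd[2], pd[1]), id = id)
}

#' Write a CT volume
#'
#' NIfTI (`.nii`/`.nii.gz`) round-trips float64 voxel data bit-exactly; any
#' other path is treated as a directory and written as an 8-bit PNG slice
#' stack (integer values in `[0, 255]` only). 8- and 16-bit stacks can both
#' be read back.
#'
#' @param volume a [ct_volume].
#' @param path output NIfTI file or stack directory.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dirname(path))) {
    rs_stop(sprintf("parent directory does not exist: %s", dirname(path)),
            "ropseg_not_found_error")
  }
  if (nifti_path(path)) {
    a <- aperm(volume$voxels, c(3L, 2L, 1L))  # (slice,row,col) -> (x,y,z)
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- c(volume$spacing[3], volume$spacing[2], volume$spacing[1])
    RNifti::writeNifti(img, path, datatype = "double")
    return(invisible(path))
  }
  v <- volume$voxels
  if (any(v != round(v)) || any(v < 0) || any(v > 255)) {
    rs_stop("PNG stacks require integer voxel values in [0, 255]",
            "ropseg_validation_error")
  }
  if (!dir.exists(path)) dir.create(path)
  nz <- dim(v)[1]
  for (i in seq_len(nz)) {
    f <- file.path(path, sprintf("slice_%04d.png", i - 1L))
    png::writePNG(v[i, , ] / 255, f)
  }
  invisible(path)
}

#' Read a binary mask
#'
#' @inheritParams read_volume
#' @param label_name mask label recorded on the result.
#' @return a [ct_mask]; values are validated to be 0/1.
#' @export
read_mask <- function(path, label_name = "liver", spacing = c(1.60, 0.78, 0.78)) {
  v <- read_volume(path, spacing = spacing)
  vox <- v$voxels
  if (!is_binary(vox)) {
    rs_stop("mask file contains values outside {0, 1}", "ropseg_validation_error")
  }
  ct_mask(vox, label_name = label_name, spacing = v$spacing)
}

#' Write a binary mask
#'
#' @param mask a [ct_mask] (or binary array).
#' @param path output NIfTI file or stack directory.
#' @param spacing spacing used when `mask` carries none.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1.60, 0.78, 0.78)) {
  vox <- mask_array(mask)
  sp <- if (inherits(mask, "ct_mask") && !is.null(mask$spacing)) mask$spacing else spacing
  write_volume(ct_volume(vox, spacing = sp, id = "mask"), path)
}

#' Serialize per-slice bounding boxes to JSON
#'
#' @param boxes named or unnamed list; each element either `NULL` or a
#'   [bbox2d], with slice indices taken from `slices`.
#' @param slices 0-based slice indices parallel to `boxes`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_bboxes <- function(boxes, slices, path) {
  recs <- list()
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    if (is.null(b)) next
    recs[[length(recs) + 1L]] <- list(slice = slices[i], row_min = b$row_min,
                                      col_min = b$col_min, row_max = b$row_max,
                                      col_max = b$col_max)
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read per-slice bounding boxes from JSON
#'
#' @param path JSON file written by [write_bboxes()].
#' @return list with `slices` (integer vector) and `boxes` (list of [bbox2d]).
#' @export
read_bboxes <- function(path) {
  recs <- jsonlite::read_json(path)
  list(slices = vapply(recs, function(r) as.integer(r$slice), integer(1)),
       boxes = lapply(recs, function(r) {
         bbox2d(r$row_min, r$col_min, r$row_max, r$col_max)
       }))
}
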