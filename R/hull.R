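# 3D convex hull volume (incremental hull). Used by template selection to
# score each subject's liver via the hull of its foreground voxel centres.

# Volume of the convex hull of a set of 3D points (rows of `pts`).
hull3d_volume <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4L) {
    rs_stop("convex hull volume needs at least 4 distinct points",
            "ropseg_geometry_error")
  }
  scale <- max(apply(pts, 2, function(x) diff(range(x))), 1e-12)
  eps <- 1e-9 * scale

  # initial extreme tetrahedron
  i1 <- order(pts[, 1], pts[, 2], pts[, 3])[1]
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  e12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crossn <- cbind(rel[, 2] * e12[3] - rel[, 3] * e12[2],
                  rel[, 3] * e12[1] - rel[, 1] * e12[3],
                  rel[, 1] * e12[2] - rel[, 2] * e12[1])
  dline <- rowSums(crossn^2)
  i3 <- which.max(dline)
  if (dline[i3] <= eps^2 * sum(e12^2)) {
    rs_stop("points are collinear; convex hull volume undefined",
            "ropseg_geometry_error")
  }
  nrm <- vcross(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= eps) {
    rs_stop("points are coplanar; convex hull volume undefined",
            "ropseg_geometry_error")
  }

  verts <- c(i1, i2, i3, i4)
  centroid <- colMeans(pts[verts, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, pts = pts, inside = centroid))

  todo <- setdiff(seq_len(n), verts)
  for (pi in todo) {
    p <- pts[pi, ]
    # signed distance of p above each face
    nrms <- face_normals(faces, pts)
    sd <- nrms$nx * (p[1] - nrms$px) + nrms$ny * (p[2] - nrms$py) +
      nrms$nz * (p[3] - nrms$pz)
    vis <- sd > eps
    if (!any(vis)) next
    visible <- faces[vis, , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    # horizon = edges appearing exactly once among visible faces
    edges <- rbind(visible[, c(1, 2)], visible[, c(2, 3)], visible[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    newf <- cbind(horizon, pi)
    newf <- t(apply(newf, 1, orient_face, pts = pts, inside = centroid))
    faces <- rbind(faces, newf)
  }

  # volume via signed tetrahedra against the interior centroid
  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  cc <- pts[faces[, 3], , drop = FALSE]
  va <- sweep(a, 2, centroid); vb <- sweep(b, 2, centroid); vc <- sweep(cc, 2, centroid)
  det3 <- va[, 1] * (vb[, 2] * vc[, 3] - vb[, 3] * vc[, 2]) -
    va[, 2] * (vb[, 1] * vc[, 3] - vb[, 3] * vc[, 1]) +
    va[, 3] * (vb[, 1] * vc[, 2] - vb[, 2] * vc[, 1])
  sum(abs(det3)) / 6
}

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Reorder a face's vertices so its normal points away from `inside`.
orient_face <- function(f, pts, inside) {
  nrm <- vcross(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  if (sum(nrm * (inside - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

face_normals <- function(faces, pts) {
  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  cc <- pts[faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  list(nx = nx / len, ny = ny / len, nz = nz / len,
       px = a[, 1], py = a[, 2], pz = a[, 3])
}

#' Convex hull volume of a binary mask
#'
#' Computes the volume (cm^3) of the convex hull of the foreground voxel
#' centre coordinates, scaled by the voxel spacing. This is the volume score
#' used to pick the standard template subject.
#'
#' Candidate hull vertices are first reduced per slice with the 2D convex
#' hull, since a 3D hull vertex must be a 2D hull vertex of its slice.
#'
#' @param mask binary array/matrix or [ct_mask] with at least 4 non-coplanar
#'   foreground voxels.
#' @param spacing `(z, y, x)` spacing in mm; taken from the mask when it
#'   carries one.
#' @return hull volume in cm^3.
#' @export
convex_hull_volume <- function(mask, spacing = NULL) {
  v <- mask_array(mask)
  if (is.null(spacing)) {
    spacing <- if (inherits(mask, "ct_mask") && !is.null(mask$spacing)) {
      mask$spacing
    } else c(1, 1, 1)
  }
  idx <- which(v != 0, arr.ind = TRUE)
  if (nrow(idx) < 4L) {
    rs_stop("convex hull volume needs at least 4 foreground voxels",
            "ropseg_geometry_error")
  }
  if (length(unique(idx[, 1])) == 1L) {
    # single-slice mask (2D fast mode): hull area times slice thickness
    pts2 <- (idx[, 2:3, drop = FALSE] - 1) *
      matrix(spacing[2:3], nrow(idx), 2, byrow = TRUE)
    h <- grDevices::chull(pts2[, 1], pts2[, 2])
    if (length(h) < 3L) {
      rs_stop("collinear single-slice mask; hull area undefined",
              "ropseg_geometry_error")
    }
    poly <- pts2[h, , drop = FALSE]
    nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
    area <- abs(sum(poly[, 1] * nxt[, 2] - nxt[, 1] * poly[, 2])) / 2
    return(area * spacing[1] / 1000)
  }
  keep <- NULL
  for (z in unique(idx[, 1])) {
    sl <- idx[idx[, 1] == z, , drop = FALSE]
    if (nrow(sl) <= 3L) {
      keep <- rbind(keep, sl)
    } else {
      h <- tryCatch(grDevices::chull(sl[, 2], sl[, 3]), error = function(e) NULL)
      keep <- rbind(keep, if (is.null(h)) sl else sl[h, , drop = FALSE])
    }
  }
  pts <- sweep((keep - 1), 2, as.numeric(spacing), `*`)
  hull3d_volume(pts) / 1000
}
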