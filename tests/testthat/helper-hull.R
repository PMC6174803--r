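# Brute-force convex hull volume by facet enumeration: a triple of points is
# a hull facet iff every point lies on one side of its plane. Valid for small
# clouds in general position.
oracle_hull_volume <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    u <- b - a; v <- cc - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    if (sum(nrm^2) < 1e-18) next
    s <- as.vector(pts %*% nrm) - sum(nrm * a)
    s <- s / sqrt(sum(nrm^2))
    if (all(s >= -1e-9) || all(s <= 1e-9)) {
      vol <- vol + abs(det(rbind(a - ctr, b - ctr, cc - ctr))) / 6
    }
  }
  vol
}

# Subject stub whose liver is a solid box of the given voxel dims.
box_subject <- function(dims, grid = dims + 4L, id = "s") {
  liver <- array(0, dim = grid)
  liver[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- 1
  vox <- array(100, dim = grid) + liver * 40
  list(volume = ct_volume(vox, spacing = c(1, 1, 1), id = id),
       liver = ct_mask(liver, "liver", spacing = c(1, 1, 1)))
}
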