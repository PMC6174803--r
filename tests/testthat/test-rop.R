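# --- convex hull volume ------------------------------------------------------

test_that("hull volume of a solid box equals the closed-form hull of centres", {
  m <- array(0, dim = c(6, 9, 7))
  m[2:5, 2:8, 2:6] <- 1  # 4 x 7 x 5 voxels
  expect_equal(convex_hull_volume(m, spacing = c(1, 1, 1)) * 1000,
               3 * 6 * 4, tolerance = 1e-9)
  # anisotropic spacing scales each axis
  expect_equal(convex_hull_volume(m, spacing = c(2, 1, 3)) * 1000,
               (3 * 2) * 6 * (4 * 3), tolerance = 1e-9)
})

test_that("degenerate point sets raise geometry errors", {
  lin <- array(0, dim = c(5, 5, 5))
  lin[1:3, 2, 2] <- 1  # 3 collinear voxels
  expect_error(convex_hull_volume(lin), class = "ropseg_geometry_error")
  sheet <- array(0, dim = c(5, 5, 5))
  sheet[1:3, 2, 2:4] <- 1  # coplanar across slices
  expect_error(convex_hull_volume(sheet), class = "ropseg_geometry_error")
  line2d <- array(0, dim = c(3, 5, 5))
  line2d[2, 2, 2:4] <- 1  # single-slice but collinear
  expect_error(convex_hull_volume(line2d), class = "ropseg_geometry_error")
  # a proper single-slice mask degrades to hull area x slice thickness
  flat <- array(0, dim = c(3, 5, 5))
  flat[2, 2:4, 2:4] <- 1
  expect_equal(convex_hull_volume(flat, spacing = c(2, 1, 1)) * 1000,
               2 * 2 * 2, tolerance = 1e-9)
})

test_that("incremental hull matches brute-force facet enumeration", {
  set.seed(21)
  for (trial in 1:10) {
    pts <- matrix(runif(3 * sample(8:16, 1), 0, 10), ncol = 3)
    expect_equal(ropseg:::hull3d_volume(pts), oracle_hull_volume(pts),
                 tolerance = 1e-8)
  }
})

test_that("hull volume is at least the voxel volume up to the half-voxel shell", {
  set.seed(22)
  for (trial in 1:20) {
    v <- random_mask(c(14, 14, 14), n_blobs = 2)
    if (sum(v) < 30) next
    hull <- tryCatch(convex_hull_volume(v, spacing = c(1, 1, 1)) * 1000,
                     ropseg_geometry_error = function(e) NA)
    if (is.na(hull)) next
    voxvol <- sum(v)
    # hull of centres loses up to a half-voxel shell around the blob surface
    expect_gte(hull, voxvol * (1 - 0.65))
    expect_gt(hull, 0)
  }
})

# --- template selection ------------------------------------------------------

test_that("template selection picks the subject nearest the mean hull volume", {
  # boxes of (a-1)(b-1)(c-1) = 64, 128, 192 -> mean 128 attained exactly
  co <- list(box_subject(c(5, 5, 5)), box_subject(c(5, 5, 9)),
             box_subject(c(5, 9, 9)))
  expect_equal(select_template(co)$provenance$subject_index, 2)
  # volumes 64, 125, 192: mean 127 -> subject 2 (125) is nearest
  co2 <- list(box_subject(c(5, 5, 5)), box_subject(c(6, 6, 6)),
              box_subject(c(5, 9, 9)))
  expect_equal(select_template(co2)$provenance$subject_index, 2)
  # equidistant tie goes to the lower index
  co3 <- list(box_subject(c(3, 5, 5)), box_subject(c(5, 5, 7)),
              box_subject(c(3, 5, 5)), box_subject(c(5, 5, 7)))
  vols <- sapply(co3, function(s) convex_hull_volume(s$liver, c(1, 1, 1)))
  expect_equal(abs(vols[1] - mean(vols)), abs(vols[2] - mean(vols)))
  expect_equal(select_template(co3)$provenance$subject_index, 1)
  expect_error(select_template(co3[1]), class = "ropseg_parameter_error")
})

# --- z interpolation ---------------------------------------------------------

test_that("z interpolation is identity at the source spacing and linear otherwise", {
  set.seed(23)
  vox <- array(runif(4 * 6 * 6, 0, 200), dim = c(4, 6, 6))
  vol <- ct_volume(vox, spacing = c(2, 1, 1))
  same <- interpolate_z(vol, target_dz = 2)
  expect_equal(same$volume$voxels, vox)

  two <- ct_volume(vox[1:2, , ], spacing = c(2, 1, 1))
  fine <- interpolate_z(two, target_dz = 1)
  expect_equal(dim(fine$volume$voxels)[1], 3)
  expect_equal(fine$volume$voxels[2, , ], (vox[1, , ] + vox[2, , ]) / 2)
  expect_equal(fine$volume$voxels[1, , ], vox[1, , ])

  ones <- ct_mask(array(1, dim = c(2, 6, 6)))
  r <- interpolate_z(two, ones, target_dz = 0.5)
  expect_true(all(r$label$voxels == 1))

  single <- ct_volume(array(1, dim = c(1, 6, 6)))
  expect_error(interpolate_z(single, target_dz = 1), class = "ropseg_parameter_error")
})

# --- registration ------------------------------------------------------------

phantom_slice <- function(seed) {
  p <- phantom_params(shape = c(1, 128, 128), spacing = c(1.6, 0.78, 0.78),
                      seed = seed)
  ph <- generate_phantom(p)
  list(img = ph$volume$voxels[1, , ], liver = ph$liver$voxels[1, , ])
}

test_that("registering an image to itself recovers the identity", {
  sl <- phantom_slice(3)$img
  r <- register_slice(sl, sl)
  expect_lt(max(abs(r$params[1:2])), 0.5)
  A <- r$transform$matrix[, 1:2]
  expect_lt(max(abs(A - diag(2))), 1e-2)
})

test_that("a known translation is recovered within half a pixel", {
  sl <- phantom_slice(3)$img
  ref <- matrix(0, 128, 128)
  ref[7:128, 1:124] <- sl[1:122, 5:128]  # content moved by (+6, -4)
  r <- register_slice(ref, sl)
  expect_lt(abs(r$params[1] - 6), 0.5)
  expect_lt(abs(r$params[2] + 4), 0.5)
})

test_that("cross-subject registration aligns the liver label with DSC >= 70", {
  a <- phantom_slice(10); b <- phantom_slice(20)
  ra <- preprocess_slice(a$img); rb <- preprocess_slice(b$img)
  r <- register_slice(ra, rb)
  idx <- which(b$liver == 1, arr.ind = TRUE) - 1
  pts <- round(ropseg:::affine_apply(r$transform, idx)) + 1
  keep <- pts[, 1] >= 1 & pts[, 1] <= 128 & pts[, 2] >= 1 & pts[, 2] <= 128
  warp <- matrix(0, 128, 128)
  warp[pts[keep, , drop = FALSE]] <- 1
  expect_gte(dice(a$liver, warp), 70)
})

# --- bbox propagation --------------------------------------------------------

test_that("bbox propagation matches enumerated-coordinate oracles exactly", {
  lab <- matrix(0, 32, 32)
  lab[10:15, 8:20] <- 1
  tight <- tight_bbox(lab)

  ident <- ropseg:::affine_identity()
  b <- propagate_bbox(ident, lab, c(32, 32))
  expect_equal(unclass(b), unclass(tight))

  shift <- affine2d(cbind(diag(2), c(5, 7)))
  bs <- propagate_bbox(shift, lab, c(40, 40))
  expect_equal(c(bs$row_min, bs$col_min, bs$row_max, bs$col_max),
               c(tight$row_min + 5, tight$col_min + 7,
                 tight$row_max + 5, tight$col_max + 7))

  # 90 degree rotation about the image centre swaps the bar's extent
  bar <- matrix(0, 32, 32)
  bar[5:6, 10:15] <- 1  # 2 x 6 bar
  ctr <- c((32 - 1) / 2, (32 - 1) / 2)
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  rot <- affine2d(cbind(R, ctr - R %*% ctr))
  br <- propagate_bbox(rot, bar, c(32, 32))
  # oracle: transform every labelled pixel and take floor/ceil bounds
  idx <- which(bar == 1, arr.ind = TRUE) - 1
  pts <- t(R %*% t(idx)) + rep(ctr - R %*% ctr, each = nrow(idx))
  expect_equal(br$row_min, floor(min(pts[, 1])))
  expect_equal(br$col_min, floor(min(pts[, 2])))
  expect_equal(br$row_max, ceiling(max(pts[, 1])) + 1)
  expect_equal(br$col_max, ceiling(max(pts[, 2])) + 1)
  # exact integer coordinates: no outward padding, dimensions swap (6 x 2)
  expect_equal(br$row_max - br$row_min, 6)
  expect_equal(br$col_max - br$col_min, 2)

  far <- affine2d(cbind(diag(2), c(500, 500)))
  expect_error(propagate_bbox(far, lab, c(32, 32)),
               class = "ropseg_positioning_error")
  empty <- matrix(0, 32, 32)
  expect_error(propagate_bbox(ident, empty, c(32, 32)),
               class = "ropseg_positioning_error")
})

test_that("boxes are monotone under the margin", {
  lab <- matrix(0, 64, 64)
  lab[20:40, 15:45] <- 1
  ident <- ropseg:::affine_identity()
  prev <- propagate_bbox(ident, lab, c(64, 64), margin = 0)
  for (m in c(2, 5, 9)) {
    b <- propagate_bbox(ident, lab, c(64, 64), margin = m)
    expect_lte(b$row_min, prev$row_min)
    expect_lte(b$col_min, prev$col_min)
    expect_gte(b$row_max, prev$row_max)
    expect_gte(b$col_max, prev$col_max)
    prev <- b
  }
})

test_that("no inverse-registration call path exists in the package", {
  ns <- ls(getNamespace("ropseg"), all.names = TRUE)
  expect_false(any(grepl("inverse|invert", ns, ignore.case = TRUE)))
  # propagation consumes only the forward float-to-reference transform
  expect_true("transform" %in% names(formals(propagate_bbox)))
})

# --- positioning -------------------------------------------------------------

test_that("self-positioning boxes cover every liver pixel of the template subject", {
  p <- phantom_params(shape = c(8, 96, 96), spacing = c(16, 4, 4))
  co <- generate_cohort(2, p, seed = 4)
  tpl <- select_template(co)
  own <- co[[tpl$provenance$subject_index]]
  boxes <- position_liver(own$volume, tpl, target_dz = NULL)
  lab <- own$liver$voxels
  for (i in seq_len(dim(lab)[1])) {
    sl <- lab[i, , ]
    if (sum(sl) == 0) next
    b <- boxes[[i]]$bbox
    expect_false(is.null(b))
    tb <- tight_bbox(sl)
    expect_lte(b$row_min, tb$row_min)
    expect_lte(b$col_min, tb$col_min)
    expect_gte(b$row_max, tb$row_max)
    expect_gte(b$col_max, tb$col_max)
  }
})

test_that("a template with no liver yields an empty box list", {
  p <- phantom_params(shape = c(4, 64, 64), spacing = c(16, 4, 4))
  co <- generate_cohort(2, p, seed = 6)
  tpl <- select_template(co)
  tpl$standard_label <- ct_mask(array(0, dim = dim(tpl$standard_label$voxels)),
                                "liver")
  boxes <- position_liver(co[[2]]$volume, tpl, target_dz = NULL)
  expect_true(all(vapply(boxes, function(r) is.null(r$bbox), logical(1))))
})
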