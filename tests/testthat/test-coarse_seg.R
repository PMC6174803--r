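# --- fuzzy c-means -----------------------------------------------------------

test_that("fcm defaults to four clusters with normalized membership rows", {
  set.seed(61)
  x <- c(rnorm(100, 20, 3), rnorm(100, 90, 3), rnorm(100, 150, 3),
         rnorm(100, 220, 3))
  r <- fcm_cluster(x)
  expect_equal(ncol(r$U), 4)
  expect_true(all(abs(rowSums(r$U) - 1) < 1e-9))
  expect_true(r$converged)
})

test_that("the fcm objective is non-increasing across iterations", {
  set.seed(62)
  for (seed in 1:5) {
    x <- runif(300, 0, 255)
    r <- fcm_cluster(x, c = 4, seed = seed)
    expect_true(all(diff(r$objective) <= 1e-8 * max(1, r$objective[1])))
  }
})

test_that("two separated intensity groups are recovered exactly", {
  x <- c(rep(100, 10) + seq(-0.4, 0.4, length.out = 10),
         rep(200, 10) + seq(-0.4, 0.4, length.out = 10))
  r <- fcm_cluster(x, c = 2, seed = 1)
  expect_lt(abs(r$centers[1] - 100), 1)
  expect_lt(abs(r$centers[2] - 200), 1)
  hard <- max.col(r$U)
  expect_equal(hard, rep(c(1, 2), each = 10))
  # exhaustive two-cluster search on the same 20 points agrees
  best <- Inf; best_cut <- NA
  ord <- order(x)
  for (cut in 1:19) {
    g1 <- x[ord[1:cut]]; g2 <- x[ord[(cut + 1):20]]
    ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    if (ss < best) { best <- ss; best_cut <- cut }
  }
  expect_equal(best_cut, 10)
})

test_that("degenerate clustering inputs are rejected; ties hard-assign", {
  expect_error(fcm_cluster(rep(c(1, 2, 3), 10), c = 4),
               class = "ropseg_clustering_error")
  # pixel exactly on a center gets membership 1 there
  x <- c(rep(0, 5), rep(100, 5), 50)
  r <- fcm_cluster(x, c = 2, seed = 3, max_iter = 500)
  onc <- which(abs(x - r$centers[1]) < 1e-9)
  if (length(onc) > 0) expect_true(all(r$U[onc, 1] == 1))
})

# --- stage masks -------------------------------------------------------------

phantom_stage_fixture <- function(seed = 8) {
  p <- phantom_params(shape = c(1, 128, 128), spacing = c(1.6, 0.78, 0.78),
                      n_tumors = 0, seed = seed)
  ph <- generate_phantom(p)
  img <- preprocess_slice(ph$volume$voxels[1, , ])
  truth <- ph$liver$voxels[1, , ]
  bb <- bbox_expand(tight_bbox(truth), 5L, dim(img))
  list(img = img, truth = truth, bb = bb)
}

test_that("the fcm stage recalls the liver inside its box", {
  fx <- phantom_stage_fixture()
  px <- as.vector(crop(fx$img, fx$bb))
  r <- fcm_cluster(px, c = 4, seed = 0)
  out <- fcm_liver_mask(r, fx$img, fx$bb)
  recall <- sum(out$mask * fx$truth) / sum(fx$truth)
  expect_gte(recall, 0.95)  # oversegmentation tolerated, undersegmentation not
  expect_true(all(out$mask %in% c(0, 1)))
  expect_true(all(out$soft >= 0 & out$soft <= 1))
})

test_that("an out-of-window slice yields an empty fcm mask with a warning", {
  img <- matrix(30, 64, 64) + matrix(runif(64 * 64), 64, 64)  # all below window
  prep <- preprocess_slice(img)  # everything zeroed
  bb <- bbox2d(8, 8, 56, 56)
  px <- as.vector(crop(prep, bb)) + seq(0, 3.9, length.out = 48 * 48) * 1e-6
  r <- fcm_cluster(px, c = 4, seed = 0)
  expect_warning(out <- fcm_liver_mask(r, prep, bb),
                 class = "ropseg_empty_mask_warning")
  # cluster nearest the stretched window midpoint is empty or degenerate
  expect_lte(sum(out$mask), 48 * 48 * 0.05)
})

test_that("the elm stage reproduces a slice it was trained on", {
  fx <- phantom_stage_fixture()
  fm <- extract_features(fx$img, fx$bb)
  labels <- fx$truth[fm$pixel_index + 1L]
  model <- elm_train(fm$values, labels, L = 200, seed = 5)
  model$signature <- ropseg:::spec_signature()
  out <- elm_liver_mask(fx$img, fx$bb, model)
  expect_gte(dice(array(fx$truth, c(1, 128, 128)),
                  array(out$mask, c(1, 128, 128))), 95)
  # confined to the box
  outside <- out$mask
  outside[(fx$bb$row_min + 1):fx$bb$row_max,
          (fx$bb$col_min + 1):fx$bb$col_max] <- 0
  expect_equal(sum(outside), 0)
  # signature mismatch is refused
  bad <- model; bad$signature <- "other"
  expect_error(elm_liver_mask(fx$img, fx$bb, bad),
               class = "ropseg_validation_error")
})

# --- fusion ------------------------------------------------------------------

test_that("fusion weights follow the accuracy-ratio formula", {
  w <- fusion_weights(0.8, 0.6)
  expect_equal(w$w_F, 4 / 7, tolerance = 1e-12)
  expect_equal(w$w_E, 3 / 7, tolerance = 1e-12)
  same <- fusion_weights(rep(0.7, 12), rep(0.7, 12))
  expect_equal(same$w_F, 0.5)
  set.seed(63)
  for (k in 1:10) {
    aF <- runif(20, 0.1, 1); aE <- runif(20, 0.1, 1)
    w <- fusion_weights(aF, aE)
    expect_equal(w$w_F + w$w_E, 1, tolerance = 1e-12)
    expect_true(w$w_F > 0 && w$w_F < 1)
  }
  expect_error(fusion_weights(c(0.5, 0), c(0.5, 0)),
               class = "ropseg_validation_error")
  expect_error(fusion_weights(0.5, numeric(0)), class = "ropseg_validation_error")
})

test_that("top-K ranking by the better stage accuracy drives the weights", {
  # two good slices (K=2) and many poor ones; only the good pair counts
  aF <- c(0.9, 0.8, rep(0.2, 8))
  aE <- c(0.6, 0.7, rep(0.75, 8))
  w <- fusion_weights(aF, aE, top_k = 2)
  expect_equal(w$w_F, mean(c(0.9 / 1.5, 0.8 / 1.5)), tolerance = 1e-12)
})

test_that("fusing identical masks is a fixed point; thresholds break ties to 1", {
  # a full-width band is invariant under the shared 5x5 median, so fusing
  # two copies of it must reproduce it exactly for any weights
  m <- matrix(0, 32, 32); m[10:20, ] <- 1
  w <- fusion_weights(0.8, 0.6)
  expect_equal(fuse(m, m, w), m)
  # single differing pixel deep inside agreeing region cannot flip; use
  # uniform half-scores to check the tie rule instead
  half_F <- matrix(1, 16, 16); half_E <- matrix(0, 16, 16)
  weq <- fusion_weights(0.5, 0.5)  # fused value exactly 0.5
  expect_true(all(fuse(half_F, half_E, weq) == 1))
  expect_error(fuse(matrix(0, 4, 4), matrix(0, 5, 5), w),
               class = "ropseg_validation_error")
  expect_error(fuse(matrix(2, 8, 8), matrix(0, 8, 8), w),
               class = "ropseg_validation_error")
})

test_that("degenerate weights reproduce the single stages after shared postprocessing", {
  set.seed(64)
  F <- (matrix(runif(40 * 40), 40, 40) > 0.5) * 1
  E <- (matrix(runif(40 * 40), 40, 40) > 0.5) * 1
  post <- function(m) (ropseg:::median_filter(m, 5L) >= 0.5) * 1
  expect_equal(fuse(F, E, structure(list(w_F = 1, w_E = 0),
                                    class = "fusion_weights")), post(F))
  expect_equal(fuse(F, E, structure(list(w_F = 0, w_E = 1),
                                    class = "fusion_weights")), post(E))
})

test_that("fuse is monotone in each input score", {
  set.seed(65)
  F <- matrix(runif(30 * 30), 30, 30)
  E <- matrix(runif(30 * 30), 30, 30)
  w <- fusion_weights(0.7, 0.5)
  base <- fuse(F, E, w)
  for (k in 1:5) {
    F2 <- pmin(F + matrix(runif(900, 0, 0.3), 30, 30), 1)
    up <- fuse(F2, E, w)
    expect_true(all(up >= base))
  }
})
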