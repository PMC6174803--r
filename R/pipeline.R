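#' Pipeline configuration
#'
#' Bundles the parameter groups of every stage with the seeds that make a
#' run reproducible. Any field can be overridden via `...`.
#'
#' @param ... named overrides of the defaults below.
#' @return a `pipeline_config` list: `window` ([liver_window]), `out_max`,
#'   `margin` (box margin, px), `enhanced` (register on preprocessed
#'   slices), `z_extend`, `target_dz`, `elm` (L, seed, max_train_pixels),
#'   `fcm` (c, m, tol, max_iter, seed), `snake` ([snake_params]), `refine`
#'   (run the contour stage), `fusion_top_k`, `use_soft_fusion`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window = liver_window(),
    out_max = 255,
    margin = 5L,
    enhanced = TRUE,
    z_extend = 4L,
    target_dz = NULL,
    elm = list(L = 630L, seed = 101L, max_train_pixels = 60000L),
    fcm = list(c = 4L, m = 2, tol = 1e-5, max_iter = 300L, seed = 202L),
    snake = snake_params(),
    refine = TRUE,
    fusion_top_k = 100L,
    use_soft_fusion = TRUE)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

# Slices of a subject that carry liver label.
liver_slice_indices <- function(liver) {
  lab <- mask_array(liver)
  which(apply(lab, 1, sum) > 0)
}

#' Train the liver segmentation bundle
#'
#' Builds the registration template ([select_template()]), trains the pixel
#' ELM on features from the true-liver bounding boxes (liver pixels = 1,
#' in-box background = 0), measures the per-slice training accuracies of
#' the clustering and classifier stages, and derives the fusion weights.
#'
#' @param cohort list of subjects, each `list(volume, liver)` with a
#'   [ct_volume] and a [ct_mask].
#' @param config a [pipeline_config].
#' @return a `liver_bundle`: `template`, `model` (`elm_model`), `weights`
#'   ([fusion_weights]), `config`, `accuracies` (per training slice).
#' @export
train_liver <- function(cohort, config = pipeline_config()) {
  if (length(cohort) < 3L) {
    rs_stop("liver training needs at least 3 labelled subjects",
            "ropseg_parameter_error")
  }
  template <- select_template(cohort)

  feats <- list(); labs <- list()
  slice_meta <- list()
  for (si in seq_along(cohort)) {
    sub <- cohort[[si]]
    lab3 <- mask_array(sub$liver)
    for (zi in liver_slice_indices(sub$liver)) {
      img <- preprocess_slice(sub$volume$voxels[zi, , ],
                              window = config$window, out_max = config$out_max)
      truth <- lab3[zi, , ]
      bb <- bbox_expand(tight_bbox(truth), config$margin, dim(img))
      fm <- extract_features(img, bb)
      feats[[length(feats) + 1L]] <- fm$values
      labs[[length(labs) + 1L]] <- truth[fm$pixel_index + 1L]
      slice_meta[[length(slice_meta) + 1L]] <-
        list(subject = si, slice = zi, img = img, truth = truth, bb = bb,
             fm_rows = nrow(fm$values))
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  keep <- seq_len(nrow(X))
  if (nrow(X) > config$elm$max_train_pixels) {
    keep <- with_seed(config$elm$seed,
                      sort(sample.int(nrow(X), config$elm$max_train_pixels)))
  }
  model <- elm_train(X[keep, , drop = FALSE], y[keep], L = config$elm$L,
                     seed = config$elm$seed)
  model$signature <- spec_signature()

  # per-slice training accuracies of both stages inside the true box
  acc_F <- numeric(0); acc_E <- numeric(0)
  for (mi in seq_along(slice_meta)) {
    sm <- slice_meta[[mi]]
    truth_box <- crop(sm$truth, sm$bb)
    px <- as.vector(crop(sm$img, sm$bb))
    fcm_acc <- tryCatch({
      r <- fcm_cluster(px, c = config$fcm$c, m = config$fcm$m,
                       tol = config$fcm$tol, max_iter = config$fcm$max_iter,
                       seed = config$fcm$seed)
      fmask <- withCallingHandlers(
        fcm_liver_mask(r, sm$img, sm$bb, config$window, config$out_max),
        ropseg_empty_mask_warning = function(w) invokeRestart("muffleWarning"))
      mean(crop(fmask$mask, sm$bb) == truth_box)
    }, ropseg_error = function(e) NA_real_)
    emask <- elm_liver_mask(sm$img, sm$bb, model)
    elm_acc <- mean(crop(emask$mask, sm$bb) == truth_box)
    acc_F <- c(acc_F, fcm_acc)
    acc_E <- c(acc_E, elm_acc)
  }
  ok <- is.finite(acc_F) & is.finite(acc_E) & (acc_F + acc_E) > 0
  weights <- fusion_weights(acc_F[ok], acc_E[ok], top_k = config$fusion_top_k)

  structure(list(template = template, model = model, weights = weights,
                 config = config,
                 accuracies = data.frame(
                   subject = vapply(slice_meta, `[[`, 0, "subject"),
                   slice = vapply(slice_meta, `[[`, 0, "slice"),
                   acc_fcm = acc_F, acc_elm = acc_E)),
            class = "liver_bundle")
}

#' @export
print.liver_bundle <- function(x, ...) {
  cat(sprintf("liver_bundle: template subject %d, ELM L=%d, weights (%.3f, %.3f)\n",
              x$template$provenance$subject_index, x$model$L,
              x$weights$w_F, x$weights$w_E))
  invisible(x)
}

# Segment one positioned slice; returns masks and intermediates.
segment_slice <- function(raw_slice, bb, bundle, config) {
  stretched <- window_and_stretch(raw_slice, config$window, config$out_max)
  img <- median5(stretched)
  px <- as.vector(crop(img, bb))
  f_soft <- NULL
  f_mask <- matrix(0, nrow(img), ncol(img))
  fcm_ok <- tryCatch({
    r <- fcm_cluster(px, c = config$fcm$c, m = config$fcm$m,
                     tol = config$fcm$tol, max_iter = config$fcm$max_iter,
                     seed = config$fcm$seed)
    fres <- withCallingHandlers(
      fcm_liver_mask(r, img, bb, config$window, config$out_max),
      ropseg_empty_mask_warning = function(w) invokeRestart("muffleWarning"))
    f_mask <- fres$mask
    f_soft <- fres$soft
    TRUE
  }, ropseg_error = function(e) FALSE)
  eres <- elm_liver_mask(img, bb, bundle$model)
  F_in <- if (config$use_soft_fusion && fcm_ok) f_soft else f_mask
  E_in <- if (config$use_soft_fusion) eres$soft else eres$mask
  coarse <- fuse(F_in, E_in, bundle$weights)
  fine <- coarse
  flagged <- FALSE
  if (config$refine && any(coarse != 0)) {
    # the snake runs on the stretched (pre-median) slice: the median filter
    # erodes the windowed liver support by about a pixel, which would bias
    # the contour inward
    fine <- refine(stretched, coarse, config$snake)
    flagged <- isTRUE(attr(fine, "flagged"))
  }
  list(fcm = f_mask, elm = eres$mask, coarse = coarse,
       fine = matrix(as.numeric(fine), nrow(img), ncol(img)),
       flagged = flagged)
}

#' Segment the liver in an unseen volume
#'
#' Runs the full inference chain per slice: ROP positioning, preprocessing,
#' clustering and classifier masks, accuracy-weighted fusion, and contour
#' refinement; slices are stacked into a 3D mask.
#'
#' @param volume a [ct_volume].
#' @param bundle a `liver_bundle` from [train_liver()].
#' @param config optional [pipeline_config] overriding the bundle's.
#' @param keep_intermediates return per-slice stage masks as well.
#' @return a [ct_mask] (label `fine`); when `keep_intermediates` is TRUE a
#'   list `(fine, coarse, fcm, elm, boxes, flags)` of [ct_mask]es and
#'   per-slice records.
#' @export
segment_liver <- function(volume, bundle, config = NULL,
                          keep_intermediates = FALSE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(bundle, "liver_bundle"))
  if (is.null(config)) config <- bundle$config
  d <- dim(volume$voxels)
  boxes <- position_liver(volume, bundle$template, margin = config$margin,
                          enhanced = config$enhanced, z_extend = config$z_extend,
                          target_dz = config$target_dz)
  fine <- array(0, dim = d); coarse <- array(0, dim = d)
  fcm_a <- array(0, dim = d); elm_a <- array(0, dim = d)
  flags <- logical(d[1])
  for (i in seq_len(d[1])) {
    bb <- boxes[[i]]$bbox
    if (is.null(bb)) next
    res <- tryCatch(
      segment_slice(volume$voxels[i, , ], bb, bundle, config),
      ropseg_error = function(e) NULL)
    if (is.null(res)) {
      flags[i] <- TRUE
      next
    }
    fine[i, , ] <- res$fine
    coarse[i, , ] <- res$coarse
    fcm_a[i, , ] <- res$fcm
    elm_a[i, , ] <- res$elm
    flags[i] <- res$flagged
  }
  fine_mask <- ct_mask(fine, "fine", spacing = volume$spacing)
  if (!keep_intermediates) return(fine_mask)
  list(fine = fine_mask,
       coarse = ct_mask(coarse, "coarse", spacing = volume$spacing),
       fcm = ct_mask(fcm_a, "fcm", spacing = volume$spacing),
       elm = ct_mask(elm_a, "elm", spacing = volume$spacing),
       boxes = boxes, flags = flags)
}

#' Train the tumor classifier
#'
#' A second ELM trained on the same 126-d features, restricted to pixels
#' inside the true liver (tumor = 1, other liver tissue = 0).
#'
#' @param cohort list of subjects `list(volume, liver, tumor)`.
#' @param config a [pipeline_config].
#' @return an `elm_model` with the feature-spec signature set.
#' @export
train_tumor <- function(cohort, config = pipeline_config()) {
  feats <- list(); labs <- list()
  for (sub in cohort) {
    liver3 <- mask_array(sub$liver)
    tumor3 <- mask_array(sub$tumor)
    for (zi in liver_slice_indices(sub$liver)) {
      img <- preprocess_slice(sub$volume$voxels[zi, , ],
                              window = config$window, out_max = config$out_max)
      sel <- liver3[zi, , ]
      if (!any(sel != 0)) next
      fm <- extract_features(img, sel)
      feats[[length(feats) + 1L]] <- fm$values
      labs[[length(labs) + 1L]] <- tumor3[zi, , ][fm$pixel_index + 1L]
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  keep <- seq_len(nrow(X))
  if (nrow(X) > config$elm$max_train_pixels) {
    keep <- with_seed(config$elm$seed + 1L,
                      sort(sample.int(nrow(X), config$elm$max_train_pixels)))
  }
  model <- elm_train(X[keep, , drop = FALSE], y[keep], L = config$elm$L,
                     seed = config$elm$seed + 1L)
  model$signature <- spec_signature()
  model
}

#' Segment tumors inside a segmented liver
#'
#' Features are computed only for liver-interior pixels; scores are
#' median-filtered, thresholded at 0.5, and intersected with the liver, so
#' the output is a subset of the liver mask by construction.
#'
#' @param volume a [ct_volume].
#' @param liver liver [ct_mask] (predicted at inference, ground truth during
#'   training-time evaluation).
#' @param tumor_model `elm_model` from [train_tumor()].
#' @param config a [pipeline_config].
#' @return a [ct_mask] with label `tumor`.
#' @export
segment_tumor <- function(volume, liver, tumor_model, config = pipeline_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  liver3 <- mask_array(liver)
  d <- dim(volume$voxels)
  out <- array(0, dim = d)
  for (zi in seq_len(d[1])) {
    sel <- liver3[zi, , ]
    if (sum(sel) < 1) next
    img <- preprocess_slice(volume$voxels[zi, , ],
                            window = config$window, out_max = config$out_max)
    fm <- extract_features(img, sel)
    sc <- elm_predict(tumor_model, fm$values)
    smap <- matrix(0, d[2], d[3])
    smap[fm$pixel_index + 1L] <- pmin(pmax(sc[, 1], 0), 1)
    if (d[2] >= 5L && d[3] >= 5L) smap <- median_filter(smap, 5L)
    out[zi, , ] <- (smap >= 0.5) * sel
  }
  ct_mask(out, "tumor", spacing = volume$spacing)
}

#' Subject-level cross-validation plan
#'
#' @param n_subjects cohort size.
#' @param k number of folds (default 10).
#' @param seed permutation seed.
#' @return a `cv_plan`: list `folds` of disjoint subject-index vectors whose
#'   union is `1:n_subjects`.
#' @export
cv_plan <- function(n_subjects, k = 10L, seed = 0L) {
  if (n_subjects < k) {
    rs_stop("cross-validation needs at least as many subjects as folds",
            "ropseg_parameter_error")
  }
  perm <- with_seed(seed, sample.int(n_subjects))
  sizes <- rep(n_subjects %/% k, k)
  extra <- n_subjects %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- split(perm, rep(seq_len(k), times = sizes))
  structure(list(folds = unname(folds), k = as.integer(k),
                 n_subjects = as.integer(n_subjects)), class = "cv_plan")
}

#' Run subject-level k-fold cross-validation
#'
#' For each fold the liver bundle is trained on the remaining subjects and
#' every held-out subject is segmented and scored with all six metrics.
#' Feature extraction dominates the cost, so per-subject features are
#' implicitly recomputed per fold only for training; keep cohorts small.
#'
#' @param cohort list of subjects `list(volume, liver, ...)`.
#' @param k folds (default 10).
#' @param config a [pipeline_config].
#' @param seed plan seed.
#' @return list with `plan` (`cv_plan`), `reports` (per-subject
#'   `metrics_report`s), `mean` (named vector of metric means).
#' @export
run_cv <- function(cohort, k = 10L, config = pipeline_config(), seed = 0L) {
  plan <- cv_plan(length(cohort), k, seed)
  reports <- list()
  for (fi in seq_along(plan$folds)) {
    test_idx <- plan$folds[[fi]]
    train_idx <- setdiff(seq_along(cohort), test_idx)
    bundle <- train_liver(cohort[train_idx], config)
    for (ti in test_idx) {
      pred <- segment_liver(cohort[[ti]]$volume, bundle)
      rep <- evaluate_all(cohort[[ti]]$liver$voxels, pred$voxels,
                          spacing = cohort[[ti]]$volume$spacing)
      reports[[as.character(ti)]] <- rep
    }
  }
  nums <- vapply(reports, function(r) {
    c(voe = r$voe, rvd = r$rvd, asd = r$asd, rmsd = r$rmsd, msd = r$msd,
      dice = r$dice)
  }, numeric(6))
  list(plan = plan, reports = reports, mean = rowMeans(nums, na.rm = TRUE))
}
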