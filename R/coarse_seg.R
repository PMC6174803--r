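#' Fuzzy c-means clustering of gray values
#'
#' Standard alternating-update fuzzy c-means on a 1D sample of pixel gray
#' values: memberships `U_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centers
#' `v_i = sum_k U_ik^m x_k / sum_k U_ik^m`, iterated until the largest center
#' shift drops below `tol`. The objective `J_m = sum U^m d^2` is
#' non-increasing across iterations. Four clusters by default, since a liver
#' bounding box contains liver, fat, background, and other organs.
#'
#' @param pixels numeric vector of gray values (needs at least `c` distinct
#'   values).
#' @param c number of clusters (default 4).
#' @param m fuzzifier (> 1, default 2).
#' @param tol center-shift convergence tolerance.
#' @param max_iter iteration cap.
#' @param seed seed for the random center initialization (uniform over the
#'   data range).
#' @return object of class `fcm_result`: `U` (n x c memberships, rows sum to
#'   1), `centers` (sorted ascending), `n_iter`, `converged`, `objective`
#'   (per-iteration trace).
#' @export
fcm_cluster <- function(pixels, c = 4L, m = 2, tol = 1e-5, max_iter = 300L,
                        seed = 0L) {
  x <- as.numeric(pixels)
  c <- as.integer(c)
  if (length(unique(x)) < c) {
    rs_stop(sprintf("need at least %d distinct values for %d clusters", c, c),
            "ropseg_clustering_error")
  }
  if (m <= 1) rs_stop("fuzzifier m must be > 1", "ropseg_parameter_error")
  rng <- range(x)
  v <- with_seed(seed, sort(stats::runif(c, rng[1], rng[2])))
  # nudge coincident initial centers apart
  while (anyDuplicated(v)) v <- v + seq_len(c) * 1e-9
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  U <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    D <- abs(outer(x, v, "-"))
    zero <- D < 1e-12
    W <- D^(-expo)
    U <- W / rowSums(W)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    Um <- U^m
    obj <- c(obj, sum(Um * D^2))
    v_new <- colSums(Um * x) / colSums(Um)
    shift <- max(abs(v_new - v))
    ord <- order(v_new)
    v <- v_new[ord]
    U <- U[, ord, drop = FALSE]
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(U = U, centers = v, n_iter = n_iter, converged = converged,
                 objective = obj),
            class = "fcm_result")
}

#' FCM-based liver mask for one slice
#'
#' Pixels inside the box are hard-assigned to their maximum-membership
#' cluster. Clusters whose centers fall in the upper stretched range
#' (above a quarter of the stretch ceiling) represent in-window tissue and
#' become foreground; with four clusters on a windowed slice this merges the
#' sub-modes of the broad liver distribution while the zeroed background
#' cluster stays out. (Selecting only the single cluster nearest the window
#' midpoint proved brittle: c = 4 routinely splits the liver mode, so one
#' cluster recalls only a band of it.) The largest 8-connected component is
#' then kept (ties to the component holding the lexicographically smallest
#' `(row, col)` pixel), closed with a disc of radius 3 and hole-filled — a
#' neighbouring in-window organ forms its own component and is dropped here,
#' unless it touches the liver, which is the oversegmentation failure mode
#' this stage is known for.
#'
#' @param result `fcm_result` from clustering the box pixels.
#' @param image the preprocessed slice the pixels came from.
#' @param bbox the [bbox2d] that was clustered.
#' @param window the [liver_window] used during preprocessing.
#' @param out_max stretch ceiling used during preprocessing.
#' @return list: `mask` (binary matrix, full image frame), `soft` (liver
#'   cluster membership restricted to the processed component), `flagged`.
#' @export
fcm_liver_mask <- function(result, image, bbox, window = liver_window(),
                           out_max = 255) {
  stopifnot(inherits(result, "fcm_result"))
  fg <- which(result$centers >= 0.25 * out_max)
  full <- matrix(0, nrow(image), ncol(image))
  soft <- matrix(0, nrow(image), ncol(image))
  if (length(fg) == 0L) {
    # no cluster in the tissue range: the slice holds nothing in-window
    rs_warn("no FCM cluster falls in the liver window on this slice",
            "ropseg_empty_mask_warning")
    return(list(mask = full, soft = soft, flagged = TRUE))
  }
  hard <- max.col(result$U, ties.method = "first")
  nr <- bbox$row_max - bbox$row_min
  sel <- matrix(hard %in% fg, nr, bbox$col_max - bbox$col_min)
  memb <- matrix(rowSums(result$U[, fg, drop = FALSE]),
                 nr, bbox$col_max - bbox$col_min)
  if (!any(sel)) {
    rs_warn("FCM liver cluster is empty on this slice", "ropseg_empty_mask_warning")
    return(list(mask = full, soft = soft, flagged = TRUE))
  }
  comp <- largest_component(sel * 1)
  comp <- EBImage::closing(comp, EBImage::makeBrush(7L, "disc"))
  comp <- EBImage::fillHull(comp)
  comp <- matrix(as.numeric(comp) != 0, nr, ncol(sel))
  rows <- (bbox$row_min + 1):bbox$row_max
  cols <- (bbox$col_min + 1):bbox$col_max
  full[rows, cols] <- comp * 1
  soft[rows, cols] <- memb * comp
  list(mask = full, soft = soft, flagged = FALSE)
}

#' ELM-based liver mask for one slice
#'
#' Extracts the 126-d features of every pixel inside the box, scores them
#' with the trained ELM, median-filters the score map (5x5), thresholds at
#' 0.5 and re-embeds the mask into the image frame.
#'
#' @param image preprocessed slice.
#' @param bbox liver [bbox2d].
#' @param model trained `elm_model` whose feature signature matches the
#'   current [feature_spec()].
#' @return list: `mask` (binary, image frame), `soft` (median-filtered score
#'   map clamped to `[0, 1]`).
#' @export
elm_liver_mask <- function(image, bbox, model) {
  stopifnot(inherits(model, "elm_model"))
  if (!is.null(model$signature) && model$signature != spec_signature()) {
    rs_stop("model feature signature does not match the current feature spec",
            "ropseg_validation_error")
  }
  fm <- extract_features(image, bbox)
  scores <- elm_predict(model, fm$values)
  nr <- bbox$row_max - bbox$row_min
  smap <- matrix(pmin(pmax(scores[, 1], 0), 1), nr, bbox$col_max - bbox$col_min)
  smap <- if (nr >= 5L && ncol(smap) >= 5L) median_filter(smap, 5L) else smap
  mask_box <- (smap >= 0.5) * 1
  full <- matrix(0, nrow(image), ncol(image))
  soft <- matrix(0, nrow(image), ncol(image))
  rows <- (bbox$row_min + 1):bbox$row_max
  cols <- (bbox$col_min + 1):bbox$col_max
  full[rows, cols] <- mask_box
  soft[rows, cols] <- smap
  list(mask = full, soft = soft)
}

#' Accuracy-weighted fusion weights
#'
#' Per training slice `i` with stage accuracies `A_F^i` (clustering) and
#' `A_E^i` (pixel classifier), the slice weights are
#' `A_F^i / (A_F^i + A_E^i)` and `A_E^i / (A_F^i + A_E^i)`. The final pair
#' is the mean of the per-slice pairs over the top-K slices ranked by
#' `max(A_F^i, A_E^i)` with `K = min(100, n)`.
#'
#' @param acc_F,acc_E equal-length vectors of per-slice accuracies in (0, 1].
#' @param top_k ranking cutoff (default 100).
#' @return object of class `fusion_weights`: `w_F`, `w_E`, summing to 1.
#' @export
fusion_weights <- function(acc_F, acc_E, top_k = 100L) {
  if (length(acc_F) != length(acc_E) || length(acc_F) == 0L) {
    rs_stop("accuracy lists must be equal-length and non-empty",
            "ropseg_validation_error")
  }
  if (any(acc_F + acc_E == 0)) {
    rs_stop("a slice has zero total accuracy", "ropseg_validation_error")
  }
  if (any(acc_F < 0 | acc_F > 1 | acc_E < 0 | acc_E > 1)) {
    rs_stop("accuracies must lie in [0, 1]", "ropseg_validation_error")
  }
  wf <- acc_F / (acc_F + acc_E)
  k <- min(as.integer(top_k), length(wf))
  sel <- order(pmax(acc_F, acc_E), decreasing = TRUE)[seq_len(k)]
  w_F <- mean(wf[sel])
  structure(list(w_F = w_F, w_E = 1 - w_F), class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("fusion_weights: w_F = %.4f, w_E = %.4f\n", x$w_F, x$w_E))
  invisible(x)
}

#' Fuse two stage outputs into the coarse mask
#'
#' Computes `w_F * F + w_E * E` on score maps (or binary masks) in `[0, 1]`,
#' applies a 5x5 median filter and thresholds at 0.5 (ties to 1).
#'
#' @param score_F,score_E matrices of identical shape with values in `[0, 1]`
#'   (soft memberships/scores or binary masks).
#' @param weights a [fusion_weights].
#' @return binary matrix.
#' @export
fuse <- function(score_F, score_E, weights) {
  stopifnot(inherits(weights, "fusion_weights"))
  if (!identical(dim(score_F), dim(score_E))) {
    rs_stop("fusion inputs must have identical shapes", "ropseg_validation_error")
  }
  if (min(score_F, score_E) < 0 || max(score_F, score_E) > 1) {
    rs_stop("fusion inputs must lie in [0, 1]", "ropseg_validation_error")
  }
  fused <- weights$w_F * score_F + weights$w_E * score_E
  fused <- if (nrow(fused) >= 5L && ncol(fused) >= 5L) median_filter(fused, 5L) else fused
  (fused >= 0.5) * 1
}
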