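#' The per-pixel feature specification
#'
#' The pixel classifier consumes a fixed 126-dimensional descriptor per
#' pixel, assembled from 16 classic texture/edge feature families: gray
#' intensity; first- and second-order Gaussian derivatives; local standard
#' deviation; bottom-hat filtering; phase congruency; Canny edge indicator;
#' Harris corner response; uniform rotation-invariant LBP histograms; Gabor
#' magnitudes; Hessian eigenvalues; neighbourhood mean and variance; local
#' entropy; gray-level co-occurrence statistics; Laws' texture energy; and
#' sum-and-difference histogram statistics. The per-family dimensionalities
#' below are this package's fixed convention (they sum to 126); all scales
#' and window sizes are frozen here so that extraction is fully
#' reproducible.
#'
#' @return data.frame with columns `block`, `dims`, `params`; `sum(dims)` is
#'   always 126.
#' @export
feature_spec <- function() {
  s <- data.frame(
    block = c("gray", "gauss_d1", "gauss_d2", "local_sd", "bottom_hat",
              "phase_congruency", "canny", "harris", "lbp_hist", "gabor",
              "hessian_eig", "nbhd_mean_var", "entropy", "glcm", "laws",
              "sdh"),
    dims = c(1L, 6L, 6L, 3L, 2L, 1L, 1L, 1L, 10L, 12L, 4L, 6L, 2L, 16L, 25L,
             30L),
    params = c(
      "raw intensity",
      "sigma {1,2,4} x {d/dy, d/dx}",
      "sigma {1,2,4} x {d2/dy2, d2/dx2}",
      "window {3,5,9}",
      "disc radius {3,5}",
      "log-Gabor scales {0.08,0.16,0.32} cyc/px, Riesz odd filters",
      "sigma 1.5, non-max suppression, 0.85-quantile threshold",
      "sigma 1 gradients, sigma 2 window, kappa 0.04",
      "LBP(8,1) riu2, 10 bins, 9x9 window",
      "orientations {0,45,90,135} deg x freq {0.1,0.2,0.4} cyc/px",
      "sigma {1,2}, eigenvalues (high, low)",
      "window {3,5,9} x {mean, var}",
      "window {5,9}, 16 gray levels",
      "offsets {(0,1),(1,0),(1,1),(1,-1)}, 16 levels, 9x9 window, {contrast, correlation, energy, homogeneity}",
      "Laws 5x5 kernels L5/E5/S5/W5/R5 outer products, 7x7 energy window",
      "directions {(0,1),(1,0),(1,1)} x distance {1,2} x {mean_s, var_s, contrast, homogeneity, energy}, 9x9 window"),
    stringsAsFactors = FALSE)
  stopifnot(sum(s$dims) == 126L)
  s
}

# Compact signature used to match a trained model with the extractor config.
spec_signature <- function(spec = feature_spec()) {
  paste(paste(spec$block, spec$dims, sep = ":"), collapse = "|")
}

#' Extract per-pixel features
#'
#' Computes all 126 feature maps of [feature_spec()] on a (preprocessed) 2D
#' slice and returns the rows for the selected pixels.
#'
#' @param image 2D matrix.
#' @param pixel_selection binary matrix of the image's shape, or a [bbox2d]
#'   selecting a rectangular region.
#' @return object of class `feature_matrix`: `values` (n_pixels x 126),
#'   `pixel_index` (n x 2, 0-based `(row, col)`), `spec`.
#' @export
extract_features <- function(image, pixel_selection) {
  sel <- if (inherits(pixel_selection, "bbox2d")) {
    m <- matrix(FALSE, nrow(image), ncol(image))
    m[(pixel_selection$row_min + 1):pixel_selection$row_max,
      (pixel_selection$col_min + 1):pixel_selection$col_max] <- TRUE
    m
  } else pixel_selection != 0
  if (!any(sel)) {
    rs_stop("pixel selection is empty", "ropseg_parameter_error")
  }
  maps <- feature_maps(image)
  spec <- feature_spec()
  idx <- which(sel)
  n <- length(idx)
  values <- matrix(0, n, 126L)
  col <- 0L
  for (b in seq_len(nrow(spec))) {
    blk <- maps[[spec$block[b]]]
    stopifnot(length(blk) == spec$dims[b])
    for (m in blk) {
      col <- col + 1L
      values[, col] <- m[idx]
    }
    if (!all(is.finite(values[, (col - spec$dims[b] + 1L):col]))) {
      rs_stop(sprintf("non-finite feature values in block '%s'", spec$block[b]),
              "ropseg_computation_error")
    }
  }
  rc <- cbind((idx - 1L) %% nrow(image), (idx - 1L) %/% nrow(image))
  colnames(rc) <- c("row", "col")
  structure(list(values = values, pixel_index = rc, spec = spec,
                 signature = spec_signature(spec)),
            class = "feature_matrix")
}

# All feature maps, as a named list of lists of matrices (one per dimension).
feature_maps <- function(img) {
  maps <- list()
  maps$gray <- list(img)

  sigmas <- c(1, 2, 4)
  d1 <- list(); d2 <- list()
  for (s in sigmas) {
    d1[[length(d1) + 1L]] <- conv2(img, gauss_deriv_kernel(s, dy = 1L))
    d1[[length(d1) + 1L]] <- conv2(img, gauss_deriv_kernel(s, dx = 1L))
    d2[[length(d2) + 1L]] <- conv2(img, gauss_deriv_kernel(s, dy = 2L))
    d2[[length(d2) + 1L]] <- conv2(img, gauss_deriv_kernel(s, dx = 2L))
  }
  maps$gauss_d1 <- d1
  maps$gauss_d2 <- d2

  maps$local_sd <- lapply(c(3L, 5L, 9L), function(w) {
    sqrt(pmax(box_mean(img^2, w) - box_mean(img, w)^2, 0))
  })

  maps$bottom_hat <- lapply(c(3L, 5L), function(r) {
    gray_closing(img, r) - img
  })

  maps$phase_congruency <- list(phase_congruency_map(img))
  maps$canny <- list(canny_map(img))
  maps$harris <- list(harris_map(img))
  maps$lbp_hist <- lbp_hist_maps(img)
  maps$gabor <- gabor_maps(img)
  maps$hessian_eig <- hessian_maps(img)

  nm <- list()
  for (w in c(3L, 5L, 9L)) {
    mu <- box_mean(img, w)
    nm[[length(nm) + 1L]] <- mu
    nm[[length(nm) + 1L]] <- pmax(box_mean(img^2, w) - mu^2, 0)
  }
  maps$nbhd_mean_var <- nm

  maps$entropy <- entropy_maps(img)
  maps$glcm <- glcm_maps(img)
  maps$laws <- laws_maps(img)
  maps$sdh <- sdh_maps(img)
  maps
}

# Grayscale morphological closing with a disc structuring element.
gray_closing <- function(img, radius) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(img)
  # EBImage grayscale morphology expects values in [0, 1]
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  out <- EBImage::closing(scaled, EBImage::makeBrush(2L * radius + 1L, "disc"))
  out <- matrix(as.numeric(out), nrow(img), ncol(img))
  out * (rng[2] - rng[1]) + rng[1]
}

phase_congruency_map <- function(img, pad = 16L) {
  p <- pad_replicate(img, pad)
  n <- nrow(p); k <- ncol(p)
  Fimg <- stats::fft(p)
  u <- seq_len(n) - 1; u[u > n / 2] <- u[u > n / 2] - n; u <- u / n
  v <- seq_len(k) - 1; v[v > k / 2] <- v[v > k / 2] - k; v <- v / k
  U <- matrix(u, n, k); V <- matrix(v, n, k, byrow = TRUE)
  R <- sqrt(U^2 + V^2); R[1, 1] <- 1
  H1 <- (0+1i) * U / R; H2 <- (0+1i) * V / R
  sE <- 0; sO1 <- 0; sO2 <- 0; sA <- 0
  for (f0 in c(0.08, 0.16, 0.32)) {
    lg <- exp(-(log(R / f0))^2 / (2 * log(2)^2))
    lg[1, 1] <- 0
    even <- Re(stats::fft(Fimg * lg, inverse = TRUE)) / (n * k)
    odd1 <- Re(stats::fft(Fimg * lg * H1, inverse = TRUE)) / (n * k)
    odd2 <- Re(stats::fft(Fimg * lg * H2, inverse = TRUE)) / (n * k)
    sE <- sE + even; sO1 <- sO1 + odd1; sO2 <- sO2 + odd2
    sA <- sA + sqrt(even^2 + odd1^2 + odd2^2)
  }
  pc <- sqrt(sE^2 + sO1^2 + sO2^2) / (sA + 1e-6)
  pc[(pad + 1):(pad + nrow(img)), (pad + 1):(pad + ncol(img)), drop = FALSE]
}

sobel_y <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # d/drow
sobel_x <- t(sobel_y)

canny_map <- function(img) {
  sm <- conv2(img, gauss_deriv_kernel(1.5))
  gy <- conv2(sm, sobel_y)
  gx <- conv2(sm, sobel_x)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx < 1e-9) return(matrix(0, nrow(img), ncol(img)))
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E, 1:NE, 2:N, 3:NW
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(img), ncol(img))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    n1 <- shift_replicate(mag, o[1], o[2])
    n2 <- shift_replicate(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  thr <- stats::quantile(mag[mag > 1e-12 * mx], 0.85, names = FALSE)
  (keep & mag >= thr) * 1
}

harris_map <- function(img) {
  gy <- conv2(img, gauss_deriv_kernel(1, dy = 1L))
  gx <- conv2(img, gauss_deriv_kernel(1, dx = 1L))
  w <- gauss_deriv_kernel(2)
  sxx <- conv2(gx * gx, w); syy <- conv2(gy * gy, w); sxy <- conv2(gx * gy, w)
  sxx * syy - sxy^2 - 0.04 * (sxx + syy)^2
}

# Raw LBP(8,1) codes: bit i set when neighbour i >= centre. Exposed for
# direct inspection in tests.
lbp_codes <- function(img) {
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
               c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  code <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(offs)) {
    o <- offs[[i]]
    nb <- shift_replicate(img, o[1], o[2])
    code <- code + bitwShiftL(1L, i - 1L) * (nb >= img)
  }
  code
}

# riu2 mapping: uniform patterns (<= 2 circular transitions) map to their
# bit count (0..8), everything else to bin 9.
lbp_riu2_table <- function() {
  tbl <- integer(256)
  for (c0 in 0:255) {
    bits <- as.integer(intToBits(c0)[1:8])
    trans <- sum(bits != c(bits[-1], bits[1]))
    tbl[c0 + 1L] <- if (trans <= 2L) sum(bits) else 9L
  }
  tbl
}

lbp_hist_maps <- function(img, w = 9L) {
  bins <- lbp_riu2_table()[lbp_codes(img) + 1L]
  dim(bins) <- dim(img)
  lapply(0:9, function(b) box_sum((bins == b) * 1, w) / (w * w))
}

gabor_maps <- function(img) {
  out <- list()
  for (th in c(0, 45, 90, 135) * pi / 180) {
    for (f in c(0.1, 0.2, 0.4)) {
      sg <- 0.5 / f
      r <- ceiling(2.5 * sg)
      gx <- outer(rep(1, 2 * r + 1), seq(-r, r))
      gy <- outer(seq(-r, r), rep(1, 2 * r + 1))
      rotu <- gx * cos(th) + gy * sin(th)
      env <- exp(-(gx^2 + gy^2) / (2 * sg^2))
      even <- env * cos(2 * pi * f * rotu)
      even <- even - mean(even)  # remove DC so flat regions respond zero
      odd <- env * sin(2 * pi * f * rotu)
      out[[length(out) + 1L]] <- sqrt(conv2(img, even)^2 + conv2(img, odd)^2)
    }
  }
  out
}

hessian_maps <- function(img) {
  out <- list()
  for (s in c(1, 2)) {
    dyy <- conv2(img, gauss_deriv_kernel(s, dy = 2L))
    dxx <- conv2(img, gauss_deriv_kernel(s, dx = 2L))
    dxy <- conv2(img, gauss_deriv_kernel(s, dy = 1L, dx = 1L))
    tr <- dxx + dyy
    q <- sqrt((dxx - dyy)^2 + 4 * dxy^2)
    out[[length(out) + 1L]] <- (tr + q) / 2
    out[[length(out) + 1L]] <- (tr - q) / 2
  }
  out
}

quantize_levels <- function(img, g = 16L, rng = range(img)) {
  if (rng[2] - rng[1] < 1e-12) return(matrix(1L, nrow(img), ncol(img)))
  lev <- pmin(pmax(floor((img - rng[1]) / (rng[2] - rng[1]) * g) + 1L, 1L), g)
  matrix(as.integer(lev), nrow(img), ncol(img))
}

entropy_maps <- function(img, g = 16L) {
  lev <- quantize_levels(img, g)
  lapply(c(5L, 9L), function(w) {
    ent <- 0
    for (l in seq_len(g)) {
      p <- box_sum((lev == l) * 1, w) / (w * w)
      nz <- p > 0
      term <- matrix(0, nrow(img), ncol(img))
      term[nz] <- -p[nz] * log2(p[nz])
      ent <- ent + term
    }
    ent
  })
}

glcm_maps <- function(img, g = 16L, w = 9L) {
  lev <- quantize_levels(img, g)
  levn <- lev * 1
  inds <- lapply(seq_len(g), function(l) (lev == l) * 1)
  out <- list()
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    partner <- shift_replicate(levn, -o[1], -o[2])
    diffm <- levn - partner
    contrast <- box_mean(diffm^2, w)
    homog <- box_mean(1 / (1 + diffm^2), w)
    mu_i <- box_mean(levn, w); mu_j <- box_mean(partner, w)
    var_i <- pmax(box_mean(levn^2, w) - mu_i^2, 0)
    var_j <- pmax(box_mean(partner^2, w) - mu_j^2, 0)
    cov_ij <- box_mean(levn * partner, w) - mu_i * mu_j
    denom <- sqrt(var_i * var_j)
    corr <- matrix(0, nrow(img), ncol(img))
    okd <- denom > 1e-12
    corr[okd] <- cov_ij[okd] / denom[okd]
    energy <- 0
    bshift <- lapply(inds, function(bi) shift_replicate(bi, -o[1], -o[2]))
    for (i in seq_len(g)) {
      ai <- inds[[i]]
      for (j in seq_len(g)) {
        cij <- box_sum(ai * bshift[[j]], w) / (w * w)
        energy <- energy + cij^2
      }
    }
    out <- c(out, list(contrast, corr, energy, homog))
  }
  out
}

laws_vectors <- function() {
  list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1), S5 = c(-1, 0, 2, 0, -1),
       W5 = c(-1, 2, 0, -2, 1), R5 = c(1, -4, 6, -4, 1))
}

laws_maps <- function(img, w = 7L) {
  vs <- laws_vectors()
  out <- list()
  for (a in vs) for (b in vs) {
    resp <- conv2(img, outer(a, b))
    out[[length(out) + 1L]] <- box_mean(abs(resp), w)
  }
  out
}

sdh_maps <- function(img, w = 9L, g = 16L) {
  out <- list()
  rng <- range(img)
  # sum/difference ranges derived from the image range so quantization is
  # a function of the image's global extremes only
  rng_s <- 2 * rng
  rng_d <- c(rng[1] - rng[2], rng[2] - rng[1])
  for (dirn in list(c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
    for (dist in c(1L, 2L)) {
      o <- dirn * dist
      partner <- shift_replicate(img, -o[1], -o[2])
      S <- img + partner
      D <- img - partner
      mean_s <- box_mean(S, w)
      var_s <- pmax(box_mean(S^2, w) - mean_s^2, 0)
      contrast <- box_mean(D^2, w)
      homog <- box_mean(1 / (1 + D^2), w)
      ps2 <- 0
      lev_s <- quantize_levels(S, g, rng_s)
      for (l in seq_len(g)) {
        p <- box_sum((lev_s == l) * 1, w) / (w * w)
        ps2 <- ps2 + p^2
      }
      pd2 <- 0
      lev_d <- quantize_levels(D, g, rng_d)
      for (l in seq_len(g)) {
        p <- box_sum((lev_d == l) * 1, w) / (w * w)
        pd2 <- pd2 + p^2
      }
      energy <- ps2 * pd2
      out <- c(out, list(mean_s, var_s, contrast, homog, energy))
    }
  }
  out
}
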