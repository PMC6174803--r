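#' Active contour (snake) refinement
#'
#' The coarse liver boundary is refined with a parametric snake: a closed
#' polyline that minimizes the sum of an internal energy (continuity and
#' curvature terms weighted by `alpha` and `beta`) and an external energy
#' (negative gradient magnitude of the Gaussian-smoothed image, weighted by
#' `w_edge`). Evolution uses the classic semi-implicit update
#' `x <- (I + gamma A)^{-1} (x + gamma f(x))` with the pentadiagonal
#' stiffness matrix `A`; whenever a step would raise the total energy it is
#' rejected and the step size halved, so the accepted energy trace is
#' non-increasing. No balloon force is used: the coarse contour is assumed
#' close to the target, so the image gradient alone steers it.
#'
#' @param alpha continuity weight (default 0.1).
#' @param beta smoothness (curvature) weight (default 0.5).
#' @param gamma step size (default 0.5).
#' @param w_edge external force weight (default 1.0).
#' @param max_iter iteration cap (default 500).
#' @param tol mean point displacement (px) below which evolution stops.
#' @return a `snake_params` list.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.5, gamma = 0.5, w_edge = 1.0,
                         max_iter = 500L, tol = 0.02) {
  if (alpha < 0 || beta < 0 || gamma <= 0 || w_edge < 0 || max_iter < 1L) {
    rs_stop("snake weights must be >= 0, gamma > 0 and max_iter >= 1",
            "ropseg_parameter_error")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, w_edge = w_edge,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "snake_params")
}

#' Trace a mask boundary as a closed contour
#'
#' The boundary of the largest foreground component is traced and resampled
#' to `n_points` points equally spaced by arc length.
#'
#' @param mask binary matrix with a non-empty foreground (a warning is
#'   raised if several components exist; the largest is used).
#' @param n_points number of contour points (default 200).
#' @return a `contour` object: `points` (n x 2 real matrix of 0-based
#'   `(row, col)`).
#' @export
mask_to_contour <- function(mask, n_points = 200L) {
  bin <- (if (inherits(mask, "ct_mask")) mask$voxels[1, , ] else mask) != 0
  if (!any(bin)) rs_stop("cannot trace an empty mask", "ropseg_contour_error")
  lab <- label_components(bin * 1)
  if (max(lab) > 1L) {
    rs_warn("mask has several components; tracing the largest",
            "ropseg_topology_warning")
    bin <- largest_component(bin * 1) != 0
  }
  oc <- EBImage::ocontour(bin * 1)[[1]]  # (row, col), 0-based pixel centres
  pts <- resample_closed(oc, n_points)
  # boundary pixel centres sit half a pixel inside the true region edge;
  # push the polyline outward so the contour marks the region boundary
  pts <- offset_contour(pts, 0.5)
  structure(list(points = pts, n_points = nrow(pts)), class = "contour")
}

# Offset a closed polyline along its outward normals by d pixels.
offset_contour <- function(pts, d) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  tang <- nxt - prv
  nrm <- cbind(tang[, 2], -tang[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  # orient outward using the polygon's signed area
  area2 <- sum(pts[, 1] * nxt[, 2] - nxt[, 1] * pts[, 2])
  if (area2 < 0) nrm <- -nrm
  pts + d * nrm
}

# Arc-length resampling of a closed polyline to n points.
resample_closed <- function(pts, n) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) {
    return(matrix(rep(pts[1, ], n), ncol = 2, byrow = TRUE))
  }
  t_out <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  r <- stats::approx(cum, closed[, 1], xout = t_out)$y
  cc <- stats::approx(cum, closed[, 2], xout = t_out)$y
  cbind(r, cc)
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("contour with %d points, perimeter %.1f px\n", x$n_points,
              contour_perimeter(x)))
  invisible(x)
}

contour_perimeter <- function(contour) {
  p <- contour$points
  sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2)))
}

# Pentadiagonal circulant stiffness matrix for the internal energy.
snake_stiffness <- function(n, alpha, beta) {
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    A[i, idx(i - 1)] <- A[i, idx(i - 1)] - alpha - 4 * beta
    A[i, idx(i + 1)] <- A[i, idx(i + 1)] - alpha - 4 * beta
    A[i, i] <- A[i, i] + 2 * alpha + 6 * beta
    A[i, idx(i - 2)] <- A[i, idx(i - 2)] + beta
    A[i, idx(i + 2)] <- A[i, idx(i + 2)] + beta
  }
  A
}

snake_energy <- function(pts, alpha, beta, w_edge, mag) {
  nxt <- pts[c(2:nrow(pts), 1), , drop = FALSE]
  prv <- pts[c(nrow(pts), 1:(nrow(pts) - 1)), , drop = FALSE]
  cont <- sum((nxt - pts)^2)
  curv <- sum((prv - 2 * pts + nxt)^2)
  ext <- -sum(bilinear_sample(mag, pts[, 1], pts[, 2]), na.rm = TRUE)
  alpha * cont + beta * curv + w_edge * ext
}

#' Evolve a snake on an image
#'
#' @param image 2D matrix (typically the preprocessed slice).
#' @param contour initial `contour` (from [mask_to_contour()]).
#' @param params a [snake_params].
#' @return evolved `contour`; attributes `energy_trace` (accepted energies)
#'   and `iterations`.
#' @export
evolve_snake <- function(image, contour, params = snake_params()) {
  stopifnot(inherits(contour, "contour"), inherits(params, "snake_params"))
  pts <- contour$points
  n <- nrow(pts)
  if (n < 8L) rs_stop("contour needs at least 8 points", "ropseg_contour_error")

  sm <- conv2(image, gauss_deriv_kernel(2))
  gy <- conv2(sm, sobel_y) / 8
  gx <- conv2(sm, sobel_x) / 8
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  # force field = gradient of the (normalized) edge magnitude, diffused with
  # a wide Gaussian so the capture range extends several pixels from the
  # edge, then normalized to unit vectors (its direction is what matters;
  # the energy-descent check below still guards every step)
  fy <- conv2(conv2(mag, sobel_y) / 8, gauss_deriv_kernel(1))
  fx <- conv2(conv2(mag, sobel_x) / 8, gauss_deriv_kernel(1))
  fmag <- sqrt(fy^2 + fx^2)
  fcut <- 1e-4 * max(fmag)
  scale_f <- ifelse(fmag > fcut, 1 / fmag, 0)
  fy <- fy * scale_f
  fx <- fx * scale_f

  A <- snake_stiffness(n, params$alpha, params$beta)
  gamma <- params$gamma
  inv <- solve(diag(n) + gamma * A)
  energy <- snake_energy(pts, params$alpha, params$beta, params$w_edge, mag)
  trace <- energy
  iters <- 0L
  nr <- nrow(image); nc <- ncol(image)
  for (it in seq_len(params$max_iter)) {
    iters <- it
    f_r <- bilinear_sample(fy, pts[, 1], pts[, 2])
    f_c <- bilinear_sample(fx, pts[, 1], pts[, 2])
    f_r[is.na(f_r)] <- 0; f_c[is.na(f_c)] <- 0
    cand <- inv %*% (pts + gamma * params$w_edge * cbind(f_r, f_c))
    cand[, 1] <- pmin(pmax(cand[, 1], 0), nr - 1)
    cand[, 2] <- pmin(pmax(cand[, 2], 0), nc - 1)
    e_new <- snake_energy(cand, params$alpha, params$beta, params$w_edge, mag)
    if (e_new > energy + 1e-12) {
      gamma <- gamma / 2
      if (gamma < params$gamma * 1e-4) break
      inv <- solve(diag(n) + gamma * A)
      next
    }
    disp <- mean(sqrt(rowSums((cand - pts)^2)))
    pts <- cand
    energy <- e_new
    trace <- c(trace, energy)
    if (disp < params$tol) break
  }
  out <- structure(list(points = pts, n_points = n), class = "contour")
  attr(out, "energy_trace") <- trace
  attr(out, "iterations") <- iters
  out
}

#' Rasterize a closed contour to a mask
#'
#' Even-odd scanline fill over pixel centres.
#'
#' @param contour a `contour`.
#' @param shape `(n_rows, n_cols)` of the output.
#' @return binary matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  pts <- contour$points
  n <- nrow(pts)
  out <- matrix(0, shape[1], shape[2])
  nxt <- c(2:n, 1)
  r1 <- pts[, 1]; c1 <- pts[, 2]
  r2 <- pts[nxt, 1]; c2 <- pts[nxt, 2]
  for (row in 0:(shape[1] - 1)) {
    # edges crossing the horizontal line at this row of pixel centres
    crosses <- (r1 <= row & r2 > row) | (r2 <= row & r1 > row)
    if (!any(crosses)) next
    t <- (row - r1[crosses]) / (r2[crosses] - r1[crosses])
    xs <- sort(c1[crosses] + t * (c2[crosses] - c1[crosses]))
    i <- 1L
    while (i + 1L <= length(xs)) {
      a <- ceiling(xs[i]); b <- floor(xs[i + 1L])
      a <- max(a, 0); b <- min(b, shape[2] - 1)
      if (a <= b) out[row + 1L, (a + 1L):(b + 1L)] <- 1
      i <- i + 2L
    }
  }
  out
}

#' Refine a coarse mask with the active contour
#'
#' Traces the coarse boundary, evolves the snake, rasterizes the result and
#' keeps a single connected component. On any refinement failure the coarse
#' mask is returned flagged (the snake is sensitive to its initial contour,
#' so a fail-safe matters).
#'
#' @param image 2D matrix.
#' @param coarse binary matrix (non-empty for refinement to run).
#' @param params a [snake_params].
#' @param n_points contour resolution.
#' @return binary matrix with attribute `flagged` (TRUE when the fail-safe
#'   fired) and, on success, `energy_trace`.
#' @export
refine <- function(image, coarse, params = snake_params(), n_points = 200L) {
  if (!any(coarse != 0)) {
    out <- coarse
    attr(out, "flagged") <- TRUE
    return(out)
  }
  res <- tryCatch({
    ct <- withCallingHandlers(
      mask_to_contour(coarse, n_points),
      ropseg_topology_warning = function(w) invokeRestart("muffleWarning"))
    ev <- evolve_snake(image, ct, params)
    m <- contour_to_mask(ev, dim(image))
    if (sum(m) < 8) rs_stop("contour collapsed", "ropseg_refinement_error")
    m <- largest_component(m)
    m <- matrix(as.numeric(EBImage::fillHull(m)), nrow(m), ncol(m))
    attr(m, "flagged") <- FALSE
    attr(m, "energy_trace") <- attr(ev, "energy_trace")
    m
  }, ropseg_error = function(e) {
    out <- coarse
    attr(out, "flagged") <- TRUE
    out
  })
  res
}
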