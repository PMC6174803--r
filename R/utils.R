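# Internal numeric helpers shared across modules.

rs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ropseg_error", "error", "condition")))
}

rs_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ropseg_warning", "warning", "condition")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded internals never
#' perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Replicate-pad a matrix by p pixels on every side.
pad_replicate <- function(m, p) {
  if (p <= 0L) return(m)
  r <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  cc <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[r, cc, drop = FALSE]
}

# Column-wise cumulative sums via one C-level cumsum over the full vector.
col_cumsum <- function(M) {
  n <- nrow(M); k <- ncol(M)
  cs <- cumsum(as.vector(M))
  CS <- matrix(cs, n, k)
  if (k > 1L) {
    offs <- cs[seq.int(n, by = n, length.out = k - 1L)]
    CS[, -1L] <- CS[, -1L, drop = FALSE] - matrix(offs, n, k - 1L, byrow = TRUE)
  }
  CS
}

# Windowed sum over a w x w neighbourhood (w odd), replicate boundary,
# computed from a 2D integral image.
box_sum <- function(m, w) {
  w <- as.integer(w)
  stopifnot(w %% 2L == 1L)
  h <- (w - 1L) %/% 2L
  n <- nrow(m); k <- ncol(m)
  p <- pad_replicate(m, h)
  ii <- t(col_cumsum(t(col_cumsum(p))))
  iz <- matrix(0, n + 2L * h + 1L, k + 2L * h + 1L)
  iz[-1L, -1L] <- ii
  iz[(w + 1L):(w + n), (w + 1L):(w + k), drop = FALSE] -
    iz[1L:n, (w + 1L):(w + k), drop = FALSE] -
    iz[(w + 1L):(w + n), 1L:k, drop = FALSE] +
    iz[1L:n, 1L:k, drop = FALSE]
}

box_mean <- function(m, w) box_sum(m, w) / (w * w)

# Shift a matrix by (dr, dc) with replicate boundary (content moves by +dr/+dc).
shift_replicate <- function(m, dr, dc) {
  n <- nrow(m); k <- ncol(m)
  r <- pmin(pmax(seq_len(n) - dr, 1L), n)
  cc <- pmin(pmax(seq_len(k) - dc, 1L), k)
  m[r, cc, drop = FALSE]
}

# Exact w x w median filter with replicate borders.
median_filter <- function(m, w = 5L) {
  w <- as.integer(w)
  if (nrow(m) < w || ncol(m) < w) {
    rs_stop(sprintf("image must be at least %dx%d for a %dx%d median filter",
                    w, w, w, w), "ropseg_parameter_error")
  }
  h <- (w - 1L) %/% 2L
  p <- pad_replicate(m, h)
  n <- nrow(m); k <- ncol(m)
  ww <- w * w
  npix <- n * k
  a <- matrix(0, npix, ww)
  t <- 0L
  for (dc in 0L:(w - 1L)) {
    for (dr in 0L:(w - 1L)) {
      t <- t + 1L
      a[, t] <- p[(1L + dr):(n + dr), (1L + dc):(k + dc)]
    }
  }
  rows <- rep.int(seq_len(npix), ww)
  v <- as.vector(a)[order(rows, as.vector(a))]
  med <- v[seq.int((ww + 1L) %/% 2L, by = ww, length.out = npix)]
  matrix(med, n, k)
}

# 2D correlation filtering with replicate boundary (EBImage FFT backend).
# filter2 performs true convolution (kernel flipped); flipping here restores
# correlation semantics so derivative kernels keep their sign convention.
conv2 <- function(m, kern) {
  flipped <- kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))), drop = FALSE]
  EBImage::filter2(m, flipped, boundary = "replicate")
}

# Separable Gaussian-derivative kernel; dx/dy in {0,1,2} are derivative
# orders along matrix rows (y) and columns (x).
gauss_deriv_kernel <- function(sigma, dy = 0L, dx = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  d1 <- -t / sigma^2 * g
  d2 <- (t^2 - sigma^2) / sigma^4 * g
  d2 <- d2 - mean(d2)  # truncated kernel must still annihilate constants
  pick <- function(ord) switch(ord + 1L, g, d1, d2)
  outer(pick(dy), pick(dx))
}

# Bilinear sampling of matrix `m` at 0-based (row, col) points; outside -> NA.
bilinear_sample <- function(m, r, c) {
  n <- nrow(m); k <- ncol(m)
  out <- rep(NA_real_, length(r))
  ok <- r >= 0 & r <= n - 1 & c >= 0 & c <= k - 1
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), n - 2); c0 <- pmin(floor(c), k - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + 1 + c0 * n
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + n] +
    fr * fc * m[i00 + n + 1]
  out[ok] <- v
  out
}

is_binary <- function(x) {
  all(x == 0 | x == 1)
}

# Largest connected component of a binary matrix (8-connectivity); ties broken
# by the component containing the lexicographically smallest (row, col) pixel.
largest_component <- function(bin) {
  if (!any(bin > 0)) return(bin * 0)
  lab <- label_components(bin)
  sizes <- tabulate(lab[lab > 0L])
  best <- max(sizes)
  cand <- which(sizes == best)
  if (length(cand) > 1L) {
    # first pixel in column-major order belonging to a tied component, ranked
    # by (row, col): scan rows within columns is column-major; we want
    # lexicographic (row, col), so order candidates by their minimal pixel.
    firsts <- vapply(cand, function(l) {
      idx <- which(lab == l)
      r <- (idx - 1L) %% nrow(bin)
      cc <- (idx - 1L) %/% nrow(bin)
      min(r * ncol(bin) + cc)
    }, numeric(1))
    cand <- cand[which.min(firsts)]
  }
  (lab == cand[1L]) * 1
}

# 8-connected labelling of a binary matrix. EBImage::bwlabel is 4-connected,
# so labels touching diagonally are merged with a union-find pass.
label_components <- function(bin) {
  lab <- as.integer(round(EBImage::bwlabel(bin)))
  dim(lab) <- dim(bin)
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  n <- nrow(lab); k <- ncol(lab)
  diag_pairs <- rbind(
    cbind(as.vector(lab[1:(n - 1), 1:(k - 1)]), as.vector(lab[2:n, 2:k])),
    cbind(as.vector(lab[1:(n - 1), 2:k]), as.vector(lab[2:n, 1:(k - 1)]))
  )
  diag_pairs <- diag_pairs[diag_pairs[, 1] > 0L & diag_pairs[, 2] > 0L &
                             diag_pairs[, 1] != diag_pairs[, 2], , drop = FALSE]
  if (nrow(diag_pairs) > 0L) {
    diag_pairs <- unique(diag_pairs)
    for (i in seq_len(nrow(diag_pairs))) {
      ra <- find_root(diag_pairs[i, 1]); rb <- find_root(diag_pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nl), find_root, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}
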