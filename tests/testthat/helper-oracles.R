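# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (explicit loops, no shared code with the package).

# Surface voxels by literal neighbour enumeration (face connectivity,
# out-of-grid = background). Returns k x 3 matrix of 0-based coords.
oracle_surface <- function(v) {
  d <- dim(v)
  use_z <- d[1] > 1L
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (v[i, j, k] == 0) next
    nb <- list(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    if (use_z) nb <- c(nb, list(c(1, 0, 0), c(-1, 0, 0)))
    is_surf <- FALSE
    for (o in nb) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          v[ii, jj, kk] == 0) {
        is_surf <- TRUE
        break
      }
    }
    if (is_surf) out <- rbind(out, c(i, j, k) - 1L)
  }
  if (is.null(out)) matrix(integer(0), 0, 3) else out
}

# All six metrics via set counting and an all-pairs double loop.
oracle_metrics <- function(A, B, spacing) {
  inter <- sum(A == 1 & B == 1)
  uni <- sum(A == 1 | B == 1)
  sa <- oracle_surface(A)
  sb <- oracle_surface(B)
  pa <- sweep(sa, 2, spacing, `*`)
  pb <- sweep(sb, 2, spacing, `*`)
  dmin <- function(p, q) {
    out <- numeric(nrow(p))
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        dd <- sqrt(sum((p[i, ] - q[j, ])^2))
        if (dd < best) best <- dd
      }
      out[i] <- best
    }
    out
  }
  dab <- dmin(pa, pb)
  dba <- dmin(pb, pa)
  list(
    voe = 100 * (1 - inter / uni),
    rvd = 100 * (sum(B) - sum(A)) / sum(A),
    asd = (sum(dab) + sum(dba)) / (length(dab) + length(dba)),
    rmsd = sqrt((sum(dab^2) + sum(dba^2)) / (length(dab) + length(dba))),
    msd = max(max(dab), max(dba)),
    dice = 100 * 2 * inter / (sum(A) + sum(B))
  )
}

# Random blob-ish binary mask: union of a few random boxes/balls.
random_mask <- function(dim3, n_blobs = 3) {
  v <- array(0, dim = dim3)
  for (b in seq_len(n_blobs)) {
    ctr <- sapply(dim3, function(n) runif(1, 1, n))
    rad <- runif(1, 1.5, max(2, min(dim3) / 3))
    g <- expand.grid(i = seq_len(dim3[1]), j = seq_len(dim3[2]), k = seq_len(dim3[3]))
    d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
    v[as.matrix(g)[d2 <= rad^2, , drop = FALSE]] <- 1
  }
  v
}
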