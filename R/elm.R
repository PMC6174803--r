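#' Extreme learning machine (single hidden layer, sine activation)
#'
#' An ELM is a single-hidden-layer feedforward network whose input weights
#' `W` and biases `b` are drawn at random and never trained; only the output
#' weights `beta` are solved, in closed form, as the minimum-norm
#' least-squares solution `beta = H^+ T` where `H_ij = sin(x_i . w_j + b_j)`
#' is the hidden-layer output matrix and `H^+` its Moore-Penrose generalized
#' inverse. With at least as many hidden units as distinct training samples
#' the system interpolates the training data exactly (the zero-error
#' property), which is what makes the closed-form solution attractive for
#' pixel classification.
#'
#' Inputs are standardized (per-dimension z-score, statistics saved in the
#' model) and scaled by `1/sqrt(d)` before the sine projection: the random
#' projection `x . w` then has unit-order variance for any input dimension
#' `d`, keeping the sine activation in its informative range (without this,
#' high-dimensional inputs wrap the sine through several periods and the
#' hidden units decorrelate from the data).
#'
#' @param X n x d matrix of training features (finite).
#' @param T n x m matrix (or length-n vector) of targets; for segmentation
#'   these are 0/1 pixel labels.
#' @param L number of hidden units (default 630).
#' @param seed RNG seed for the weight draw; the model is bit-reproducible
#'   given `(X, T, L, seed)`.
#' @return object of class `elm_model` with fields `W` (L x d), `b` (L),
#'   `beta` (L x m), `mu`/`sigma` (standardizer), `L`, `seed`, `signature`
#'   (feature-spec signature, set by callers that train on the feature bank).
#' @export
elm_train <- function(X, T, L = 630L, seed = 0L) {
  X <- as.matrix(X)
  if (is.null(dim(T))) T <- matrix(T, ncol = 1L)
  T <- as.matrix(T)
  if (!all(is.finite(X)) || !all(is.finite(T))) {
    rs_stop("ELM training requires finite inputs and targets",
            "ropseg_validation_error")
  }
  if (nrow(X) != nrow(T)) {
    rs_stop("X and T must have the same number of rows", "ropseg_validation_error")
  }
  if (L < 1L) rs_stop("L must be >= 1", "ropseg_parameter_error")
  d <- ncol(X)
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  sigma <- sigma * sqrt(d)  # unit-order projection variance at any d
  Xs <- sweep(sweep(X, 2L, mu), 2L, sigma, `/`)
  wb <- with_seed(seed, {
    W <- matrix(stats::runif(L * d, -1, 1), L, d)
    b <- stats::runif(L, -1, 1)
    list(W = W, b = b)
  })
  H <- elm_hidden(Xs, wb$W, wb$b)
  beta <- pinv_svd(H) %*% T
  structure(list(W = wb$W, b = wb$b, beta = beta, mu = mu, sigma = sigma,
                 L = as.integer(L), seed = as.integer(seed),
                 activation = "sin", signature = NULL),
            class = "elm_model")
}

# Hidden-layer output H_ij = sin(x_i . w_j + b_j); chunked over rows to keep
# the n x L intermediate within a bounded memory footprint.
elm_hidden <- function(Xs, W, b, chunk = 200000L %/% max(ncol(W), 1L)) {
  n <- nrow(Xs)
  L <- nrow(W)
  chunk <- max(chunk, 1024L)
  if (n <= chunk) return(sin(sweep(Xs %*% t(W), 2L, b, `+`)))
  H <- matrix(0, n, L)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    H[i:j, ] <- sin(sweep(Xs[i:j, , drop = FALSE] %*% t(W), 2L, b, `+`))
    i <- j + 1L
  }
  H
}

# Moore-Penrose pseudoinverse by SVD with relative truncation of small
# singular values.
pinv_svd <- function(H, rtol = 1e-10) {
  s <- svd(H)
  if (length(s$d) == 0L || s$d[1] <= 0) {
    return(matrix(0, ncol(H), nrow(H)))
  }
  keep <- s$d > rtol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Predict scores with a trained ELM
#'
#' @param model an `elm_model`.
#' @param X n x d feature matrix (same d as at training).
#' @return n x m matrix of real-valued scores `sin(X W' + b) beta`.
#' @export
elm_predict <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$W)) {
    rs_stop(sprintf("feature dimension %d does not match the model (%d)",
                    ncol(X), ncol(model$W)), "ropseg_validation_error")
  }
  Xs <- sweep(sweep(X, 2L, model$mu), 2L, model$sigma, `/`)
  elm_hidden(Xs, model$W, model$b) %*% model$beta
}

#' Binarize classifier scores
#'
#' Scores at or above the threshold map to 1 (ties go to the foreground).
#'
#' @param scores numeric vector/matrix.
#' @param threshold decision threshold (default 0.5).
#' @return integer 0/1 array of the same shape.
#' @export
binarize <- function(scores, threshold = 0.5) {
  out <- (scores >= threshold) * 1L
  dim(out) <- dim(scores)
  out
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("elm_model: %d hidden sine units, %d -> %d, seed %d\n",
              x$L, ncol(x$W), ncol(x$beta), x$seed))
  invisible(x)
}

#' Save / load an ELM model
#'
#' The archive is a directory with a JSON header (dimensions, seed,
#' feature-spec signature, standardizer) and the weight matrices as
#' plain-text CSV, so models are portable and diffable.
#'
#' @param model an `elm_model`.
#' @param path archive directory.
#' @return `path` (`write_elm`) or the restored `elm_model` (`read_elm`).
#' @export
write_elm <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  header <- list(L = model$L, d = ncol(model$W), m = ncol(model$beta),
                 seed = model$seed, activation = model$activation,
                 signature = model$signature, mu = model$mu, sigma = model$sigma)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(model$W, file.path(path, "W.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$b, file.path(path, "b.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$beta, file.path(path, "beta.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  h <- jsonlite::read_json(file.path(path, "header.json"), simplifyVector = TRUE)
  W <- as.matrix(utils::read.table(file.path(path, "W.csv"), sep = ","))
  dimnames(W) <- NULL
  b <- as.numeric(utils::read.table(file.path(path, "b.csv"), sep = ",")[[1]])
  beta <- as.matrix(utils::read.table(file.path(path, "beta.csv"), sep = ","))
  dimnames(beta) <- NULL
  structure(list(W = W, b = b, beta = beta, mu = h$mu, sigma = h$sigma,
                 L = h$L, seed = h$seed, activation = h$activation,
                 signature = if (is.null(h$signature)) NULL else h$signature),
            class = "elm_model")
}
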