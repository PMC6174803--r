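spec <- feature_spec()
block_cols <- function(name) {
  i <- which(spec$block == name)
  (cumsum(spec$dims)[i] - spec$dims[i] + 1L):cumsum(spec$dims)[i]
}

test_that("the feature spec is the fixed 126-dimensional table", {
  expect_equal(sum(spec$dims), 126)
  expect_equal(anyDuplicated(spec$block), 0)
  families <- c("gray", "gauss_d1", "gauss_d2", "local_sd", "bottom_hat",
                "phase_congruency", "canny", "harris", "lbp_hist", "gabor",
                "hessian_eig", "nbhd_mean_var", "entropy", "glcm", "laws",
                "sdh")
  expect_setequal(spec$block, families)
  # round trip through JSON preserves the table
  f <- file.path(tempdir(), "spec.json")
  jsonlite::write_json(spec, f, digits = NA)
  back <- as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE))
  expect_equal(back$block, spec$block)
  expect_equal(back$dims, spec$dims)
})

test_that("extraction returns one 126-d row per selected pixel", {
  set.seed(41)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  fm <- extract_features(img, bbox2d(10, 12, 30, 40))
  expect_equal(ncol(fm$values), 126)
  expect_equal(nrow(fm$values), 20 * 28)
  expect_true(all(is.finite(fm$values)))
  expect_equal(fm$pixel_index[1, ], c(row = 10, col = 12))
  # mask selection
  sel <- matrix(FALSE, 64, 64); sel[5, 7] <- TRUE
  one <- extract_features(img, sel * 1)
  expect_equal(nrow(one$values), 1)
  expect_equal(one$values[1, 1], img[5, 7])  # gray block is the raw intensity
  expect_equal(one$pixel_index[1, ], c(row = 4, col = 6))
  expect_error(extract_features(img, matrix(0, 64, 64)),
               class = "ropseg_parameter_error")
})

test_that("flat-field responses vanish for derivative-type blocks", {
  fm <- extract_features(matrix(77, 48, 48), bbox2d(8, 8, 40, 40))
  for (b in c("gauss_d1", "gauss_d2", "local_sd", "bottom_hat", "canny",
              "harris", "entropy")) {
    expect_lt(max(abs(fm$values[, block_cols(b)])), 1e-8)
  }
})

test_that("LBP codes and uniform-pattern binning follow the 8,1 convention", {
  centre_low <- matrix(5, 3, 3); centre_low[2, 2] <- 4
  expect_equal(ropseg:::lbp_codes(centre_low)[2, 2], 255)
  tbl <- ropseg:::lbp_riu2_table()
  expect_equal(tbl[0 + 1], 0)     # all-zero pattern: 0 bits
  expect_equal(tbl[255 + 1], 8)   # all-one pattern: 8 bits
  expect_equal(tbl[strtoi("00001111", base = 2) + 1], 4)  # one run: uniform
  expect_equal(tbl[strtoi("01010101", base = 2) + 1], 9)  # alternating: bin 9
  expect_equal(sort(unique(tbl)), 0:9)
})

test_that("features are deterministic and translation-covariant in the interior", {
  set.seed(42)
  base <- matrix(runif(96 * 96, 0, 255), 96, 96)
  # pin the global extremes deep inside the common interior so that the
  # global quantization ranges (entropy/glcm/sdh) are identical in both
  base[48, 48] <- 0; base[49, 49] <- 255
  sel <- bbox2d(40, 40, 56, 56)
  f1 <- extract_features(base, sel)
  f2 <- extract_features(base, sel)
  expect_identical(f1$values, f2$values)

  # shift the whole image content by (3, 2); compare interior windows far
  # from borders
  sh <- matrix(base[1, 1], 96, 96)
  sh[4:96, 3:96] <- base[1:93, 1:94]
  fs <- extract_features(sh, bbox2d(43, 42, 59, 58))
  loose <- c(block_cols("phase_congruency"),  # FFT-based, border-influenced
             block_cols("canny"))             # global quantile threshold
  strict <- setdiff(seq_len(126), loose)
  scale <- pmax(apply(abs(f1$values[, strict]), 2, max), 1)
  err <- apply(abs(fs$values[, strict] - f1$values[, strict]), 2, max) / scale
  expect_lt(max(err), 1e-6)
  expect_lt(mean(abs(fs$values[, loose] - f1$values[, loose])), 0.05)
})

test_that("local statistics blocks match direct windowed computation", {
  set.seed(43)
  img <- matrix(runif(32 * 32, 0, 10), 32, 32)
  fm <- extract_features(img, bbox2d(15, 15, 16, 16))  # single interior pixel
  win <- function(w) img[(16 - (w - 1) / 2):(16 + (w - 1) / 2),
                         (16 - (w - 1) / 2):(16 + (w - 1) / 2)]
  sd_cols <- block_cols("local_sd")
  for (k in 1:3) {
    w <- c(3, 5, 9)[k]
    v <- win(w)
    expect_equal(fm$values[1, sd_cols[k]],
                 sqrt(mean(v^2) - mean(v)^2), tolerance = 1e-8)
  }
  mv_cols <- block_cols("nbhd_mean_var")
  expect_equal(fm$values[1, mv_cols[1]], mean(win(3)), tolerance = 1e-10)
  expect_equal(fm$values[1, mv_cols[2]], mean(win(3)^2) - mean(win(3))^2,
               tolerance = 1e-8)
})
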