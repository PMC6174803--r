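test_that("surface voxels follow face-connectivity including grid edges", {
  cube <- array(0, dim = c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- 1
  s <- surface_voxels(cube)
  expect_equal(nrow(s), 26)  # all but the centre of a 3x3x3 solid
  expect_false(any(s[, 1] == 2 & s[, 2] == 2 & s[, 3] == 2))

  single <- array(0, dim = c(3, 3, 3)); single[2, 2, 2] <- 1
  expect_equal(unname(surface_voxels(single)), matrix(c(1L, 1L, 1L), 1))

  sheet <- array(0, dim = c(4, 6, 6)); sheet[2, , ] <- 1
  expect_equal(nrow(surface_voxels(sheet)), 36)

  # foreground touching the grid edge is surface even with no interior bg
  solid <- array(1, dim = c(3, 3, 3))
  expect_equal(nrow(surface_voxels(solid)), 26)
})

test_that("overlap metrics match hand-counted examples", {
  A <- array(0, dim = c(1, 4, 4)); B <- A
  A[1, 1, 1:2] <- 1            # two voxels
  B[1, 1, 2:3] <- 1            # two voxels sharing one
  expect_equal(voe(A, B), 100 * (1 - 1 / 3), tolerance = 1e-12)
  expect_equal(dice(A, B), 50)
  expect_equal(voe(A, A), 0)
  expect_equal(dice(A, A), 100)

  A2 <- array(0, dim = c(2, 3, 3)); B2 <- A2
  A2[1, , 1] <- 1; A2[2, 1, 1] <- 1          # |A| = 4
  B2[1, , 1] <- 1; B2[2, 1:2, 1] <- 1        # |B| = 5
  expect_equal(rvd(A2, B2), 25)
  expect_equal(rvd(A2, A2), 0)

  disjA <- array(0, dim = c(1, 3, 3)); disjB <- disjA
  disjA[1, 1, 1] <- 1; disjB[1, 3, 3] <- 1
  expect_equal(voe(disjA, disjB), 100)
  expect_equal(dice(disjA, disjB), 0)
})

test_that("rvd is asymmetric and empty masks raise metric errors", {
  A <- array(0, dim = c(1, 4, 4)); B <- A
  A[1, 1:2, 1] <- 1; B[1, 1, 1] <- 1
  expect_equal(rvd(A, B), -50)
  expect_equal(rvd(B, A), 100)
  expect_false(isTRUE(all.equal(rvd(B, A), -rvd(A, B))))
  empty <- array(0, dim = c(1, 4, 4))
  expect_error(voe(empty, empty), class = "ropseg_metric_error")
  expect_error(rvd(empty, A), class = "ropseg_metric_error")
  expect_error(asd(A, empty), class = "ropseg_metric_error")
})

test_that("surface distances respect anisotropic spacing on a single pair", {
  A <- array(0, dim = c(4, 4, 4)); B <- A
  A[2, 2, 2] <- 1; B[3, 2, 2] <- 1  # one slice apart
  sp <- c(3, 1, 1)
  expect_equal(asd(A, B, sp), 3)
  expect_equal(rmsd(A, B, sp), 3)
  expect_equal(msd(A, B, sp), 3)
  expect_equal(asd(A, A, sp), 0)
})

test_that("all metrics match the brute-force oracle on seeded random pairs", {
  set.seed(42)
  for (trial in 1:12) {
    d <- sample(6:12, 3, replace = TRUE)
    A <- random_mask(d); B <- random_mask(d)
    if (sum(A) == 0 || sum(B) == 0) next
    sp <- runif(3, 0.5, 3)
    o <- oracle_metrics(A, B, sp)
    expect_equal(voe(A, B), o$voe, tolerance = 1e-9)
    expect_equal(rvd(A, B), o$rvd, tolerance = 1e-9)
    expect_equal(dice(A, B), o$dice, tolerance = 1e-9)
    expect_equal(asd(A, B, sp), o$asd, tolerance = 1e-9)
    expect_equal(rmsd(A, B, sp), o$rmsd, tolerance = 1e-9)
    expect_equal(msd(A, B, sp), o$msd, tolerance = 1e-9)
  }
})

test_that("evaluate_all aggregates the individual metrics and flags", {
  set.seed(7)
  A <- random_mask(c(8, 8, 8)); B <- random_mask(c(8, 8, 8))
  sp <- c(1.6, 0.78, 0.78)
  r <- evaluate_all(A, B, sp)
  expect_equal(r$voe, voe(A, B))
  expect_equal(r$rvd, rvd(A, B))
  expect_equal(r$asd, asd(A, B, sp))
  expect_equal(r$rmsd, rmsd(A, B, sp))
  expect_equal(r$msd, msd(A, B, sp))
  expect_equal(r$dice, dice(A, B))
  expect_length(r$flags, 0)

  same <- evaluate_all(A, A, sp)
  expect_equal(unlist(same[c("voe", "rvd", "asd", "rmsd", "msd", "dice")]),
               c(voe = 0, rvd = 0, asd = 0, rmsd = 0, msd = 0, dice = 100))

  empty <- array(0, dim = c(8, 8, 8))
  flagged <- evaluate_all(A, empty, sp)
  expect_true(all(c("asd", "rmsd", "msd") %in% flagged$flags))
  expect_true(is.na(flagged$asd))
  expect_equal(flagged$rvd, -100)
})

test_that("growing the prediction toward the truth never decreases dice", {
  set.seed(9)
  A <- random_mask(c(10, 10, 10))
  B <- A * (array(runif(1000), dim = c(10, 10, 10)) < 0.3)
  if (sum(B) == 0) B[which(A == 1)[1]] <- 1
  missing <- which(A == 1 & B == 0)
  prev <- dice(A, B)
  for (i in missing[seq_len(min(30, length(missing)))]) {
    B[i] <- 1
    cur <- dice(A, B)
    expect_gte(cur, prev)
    prev <- cur
  }
})
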