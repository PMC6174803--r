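#' Parameters of the synthetic abdominal phantom
#'
#' The phantom emulates the intensity structure the segmentation pipeline
#' assumes: a liver whose gray values concentrate in the 130-150 window
#' (mean 140, sd 4 by default), darker tumors strictly inside the liver,
#' a spleen-like confounder organ whose intensity overlaps the liver window,
#' a soft-tissue body on an air background, additive Gaussian noise, and a
#' per-subject affine (scale/rotation/translation) emulating inter-patient
#' physical differences. The default 3D grid (64 slices of 128x128 at
#' spacing (4, 3, 3) mm) gives a default liver volume of about 1700 cm^3,
#' matching the average liver volume of an abdominal CT cohort.
#'
#' @param shape `(n_slices, n_rows, n_cols)`; use `(1, 128, 128)` for the 2D
#'   fast mode.
#' @param spacing `(z, y, x)` mm.
#' @param liver_mean,liver_sd liver gray statistics; the mean must lie inside
#'   the liver window `[130, 150]`.
#' @param tumor_mean,tumor_sd tumor gray statistics; the mean must fall below
#'   the low window edge so tumors are darker than liver.
#' @param n_tumors number of tumor blobs (0 or more).
#' @param organ_contrast gray offset of the confounder organ relative to the
#'   liver mean (default +5: inside the liver window, as in real data where
#'   neighbouring organs overlap the liver's gray range).
#' @param noise_sd additive Gaussian noise sd in gray units.
#' @param liver_axes_frac liver ellipsoid semi-axes as fractions of the grid
#'   half-extent `(z, y, x)`; defaults sized so the default grid yields a
#'   liver volume near 1720 cm^3.
#' @param deform_amp amplitude of the smooth radial deformation of the liver.
#' @param tumor_radius_frac range of tumor radii as a fraction of the
#'   smallest liver semi-axis.
#' @param affine_scale,affine_rot_deg,affine_shift_frac per-subject affine
#'   ranges: uniform per-axis scale, in-plane rotation (degrees), and
#'   translation as a fraction of grid extent. Zero-width ranges give
#'   identical anatomy across subjects.
#' @param seed RNG seed; the phantom is bit-deterministic given the seed.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(shape = c(64, 128, 128),
                           spacing = c(4, 3, 3),
                           liver_mean = 140, liver_sd = 4,
                           tumor_mean = 112, tumor_sd = 4,
                           n_tumors = 1,
                           organ_contrast = 5,
                           noise_sd = 2,
                           liver_axes_frac = c(0.47, 0.44, 0.42),
                           deform_amp = 0.05,
                           tumor_radius_frac = c(0.15, 0.30),
                           affine_scale = c(0.92, 1.08),
                           affine_rot_deg = c(-8, 8),
                           affine_shift_frac = c(-0.04, 0.04),
                           seed = 0) {
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            liver_mean = liver_mean, liver_sd = liver_sd,
            tumor_mean = tumor_mean, tumor_sd = tumor_sd,
            n_tumors = as.integer(n_tumors), organ_contrast = organ_contrast,
            noise_sd = noise_sd, liver_axes_frac = liver_axes_frac,
            deform_amp = deform_amp, tumor_radius_frac = tumor_radius_frac,
            affine_scale = affine_scale, affine_rot_deg = affine_rot_deg,
            affine_shift_frac = affine_shift_frac, seed = as.integer(seed))
  if (length(p$shape) != 3L || any(p$shape < 1L)) {
    rs_stop("shape must be three positive integers", "ropseg_parameter_error")
  }
  if (liver_mean < 130 || liver_mean > 150) {
    rs_stop("liver_mean must lie inside the liver window [130, 150]",
            "ropseg_parameter_error")
  }
  if (tumor_mean >= 130) {
    rs_stop("tumor_mean must fall below the liver window's low edge (130)",
            "ropseg_parameter_error")
  }
  if (noise_sd < 0) rs_stop("noise_sd must be >= 0", "ropseg_parameter_error")
  if (p$n_tumors < 0L) rs_stop("n_tumors must be >= 0", "ropseg_parameter_error")
  if (max(p$tumor_radius_frac) >= 0.6) {
    rs_stop("tumors must be strictly smaller than the liver (radius fraction < 0.6)",
            "ropseg_parameter_error")
  }
  class(p) <- "phantom_params"
  p
}

# Draw a per-subject affine from the parameter ranges.
draw_subject_affine <- function(p) {
  list(scale = c(runif(1, p$affine_scale[1], p$affine_scale[2]),
                 runif(1, p$affine_scale[1], p$affine_scale[2]),
                 runif(1, p$affine_scale[1], p$affine_scale[2])),
       rot = runif(1, p$affine_rot_deg[1], p$affine_rot_deg[2]) * pi / 180,
       shift = c(runif(1, p$affine_shift_frac[1], p$affine_shift_frac[2]),
                 runif(1, p$affine_shift_frac[1], p$affine_shift_frac[2]),
                 runif(1, p$affine_shift_frac[1], p$affine_shift_frac[2])))
}

#' Generate one synthetic abdominal phantom
#'
#' @param params a [phantom_params].
#' @param affine optional subject affine (internal use by [generate_cohort()]);
#'   by default drawn from the seeded generator.
#' @return list with elements `volume` ([ct_volume]), `liver` ([ct_mask]) and
#'   `tumor` ([ct_mask]); `tumor` is always a subset of `liver`.
#' @export
generate_phantom <- function(params = phantom_params(), affine = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, generate_phantom_impl(params, affine))
}

generate_phantom_impl <- function(p, affine = NULL) {
  d <- p$shape
  sp <- p$spacing
  if (is.null(affine)) affine <- draw_subject_affine(p)

  # physical coordinates, centred (mm); grids as 3 arrays via outer products
  zc <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  yc <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  xc <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  half <- c(max(abs(zc), sp[1]), max(abs(yc)), max(abs(xc)))

  Z <- array(rep(zc, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(yc, each = d[1]), times = d[3]), dim = d)
  X <- array(rep(xc, each = d[1] * d[2]), dim = d)

  # subject affine applied to coordinates (inverse mapping of anatomy):
  # rotate in-plane, scale per axis, shift by a fraction of the extent
  shift <- affine$shift * 2 * half
  Zs <- (Z - shift[1]) / affine$scale[1]
  cosr <- cos(affine$rot); sinr <- sin(affine$rot)
  Yr <- ((Y - shift[2]) * cosr + (X - shift[3]) * sinr) / affine$scale[2]
  Xr <- (-(Y - shift[2]) * sinr + (X - shift[3]) * cosr) / affine$scale[3]

  axes <- p$liver_axes_frac * half
  # liver sits slightly off-centre (toward -y, -x as the anatomical right)
  lc <- c(0, -0.08, -0.10) * 2 * half
  lr <- sqrt(((Zs - lc[1]) / axes[1])^2 + ((Yr - lc[2]) / axes[2])^2 +
               ((Xr - lc[3]) / axes[3])^2)

  # smooth low-frequency radial deformation of the liver boundary
  kz <- pi / half[1]; ky <- pi / half[2]; kx <- pi / half[3]
  n_modes <- 3L
  delta <- 0
  for (m in seq_len(n_modes)) {
    w <- runif(3, 0.3, 1.2) * c(kz, ky, kx)
    ph <- runif(1, 0, 2 * pi)
    delta <- delta + cos(w[1] * Zs + w[2] * Yr + w[3] * Xr + ph)
  }
  delta <- p$deform_amp * delta / n_modes
  liver <- (lr <= 1 + delta) * 1

  # spleen-like confounder: smaller ellipsoid on the opposite side, intensity
  # inside the liver window so FCM sees overlapping gray values
  sc <- c(0.05, 0.35, 0.42) * 2 * half
  sax <- axes * c(0.45, 0.35, 0.33)
  sr <- sqrt(((Zs - sc[1]) / sax[1])^2 + ((Yr - sc[2]) / sax[2])^2 +
               ((Xr - sc[3]) / sax[3])^2)
  spleen <- (sr <= 1) * 1
  spleen <- spleen * (1 - liver)

  # body soft tissue: large ellipse through all slices
  br <- sqrt((Zs / (1.1 * half[1]))^2 + (Yr / (0.92 * half[2]))^2 +
               (Xr / (0.92 * half[3]))^2)
  body <- (br <= 1) * 1

  # tumors strictly inside the liver (placed in the undeformed liver frame);
  # in 2D fast mode (single slice) tumors are in-plane disks
  is2d <- d[1] == 1L
  tumor <- array(0, dim = d)
  if (p$n_tumors > 0L) {
    placed <- 0L
    tries <- 0L
    while (placed < p$n_tumors && tries < 50L) {
      tries <- tries + 1L
      u <- runif(3, -0.45, 0.45)
      tc <- lc + u * axes
      trad <- runif(1, p$tumor_radius_frac[1], p$tumor_radius_frac[2]) *
        (if (is2d) min(axes[2:3]) else min(axes))
      tr <- if (is2d) sqrt((Yr - tc[2])^2 + (Xr - tc[3])^2) else
        sqrt((Zs - tc[1])^2 + (Yr - tc[2])^2 + (Xr - tc[3])^2)
      cand <- (tr <= trad) * 1
      cand <- cand * liver  # enforce containment
      if (sum(cand) >= 1) {
        tumor <- pmax(tumor, cand)
        placed <- placed + 1L
      }
    }
  }

  n <- prod(d)
  vox <- array(20, dim = d)                                  # air
  vox[body == 1] <- 100                                      # soft tissue
  nl <- sum(liver == 1)
  vox[liver == 1] <- rnorm(nl, p$liver_mean, p$liver_sd)     # liver texture
  ns <- sum(spleen == 1)
  vox[spleen == 1] <- rnorm(ns, p$liver_mean + p$organ_contrast, p$liver_sd)
  nt <- sum(tumor == 1)
  vox[tumor == 1] <- rnorm(nt, p$tumor_mean, p$tumor_sd)
  if (p$noise_sd > 0) vox <- vox + array(rnorm(n, 0, p$noise_sd), dim = d)

  id <- sprintf("phantom_seed%d", p$seed)
  list(volume = ct_volume(vox, spacing = sp, id = id),
       liver = ct_mask(liver, "liver", spacing = sp),
       tumor = ct_mask(tumor, "tumor", spacing = sp))
}

#' Generate a cohort of phantom subjects
#'
#' Each subject receives an independent random affine (and anatomy noise), so
#' liver shapes and volumes vary across the cohort; the whole cohort is
#' reproducible from `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param params shared [phantom_params]; its `seed` field is overridden
#'   per subject.
#' @param seed cohort-level seed.
#' @return list of `n_subjects` phantom lists (see [generate_phantom()]).
#' @export
generate_cohort <- function(n_subjects, params = phantom_params(), seed = 0) {
  if (n_subjects < 2L) {
    rs_stop("a cohort needs at least 2 subjects", "ropseg_parameter_error")
  }
  subj_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_subjects))
  lapply(seq_len(n_subjects), function(i) {
    p <- params
    p$seed <- subj_seeds[i]
    out <- generate_phantom(p)
    out$volume$id <- sprintf("subject%02d", i)
    out
  })
}
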