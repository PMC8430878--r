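#' Specify a synthetic DCE phantom
#'
#' Describes an ellipsoidal tumor embedded in a uniform background, the
#' ground-truth kinetic maps, and the SPGR acquisition. Defaults emulate a
#' 3T abdominal DCE protocol (TR/TE = 5.6/2.3 ms, flip angle 15 deg, frame
#' interval 12 s, 20 frames) and a pancreatic-tumor-like kinetic regime.
#'
#' @param shape Integer length-3 grid shape, voxels.
#' @param spacing Voxel spacing, mm (isotropic scalar or length-3).
#' @param center Tumor center, mm (default: grid center).
#' @param semiaxes Ellipsoid semi-axes, mm, length 3.
#' @param ktrans_tumor Tumor-mean ground-truth K^trans, 1/min.
#' @param ktrans_cv Multiplicative lognormal heterogeneity CV of the tumor
#'   K^trans field (0 disables).
#' @param ve_tumor,vp_tumor Tumor EES and plasma volume fractions.
#' @param vp_background Background plasma volume fraction (background has
#'   K^trans = 0: no extravasation outside the lesion).
#' @param t10 Pre-contrast T1, seconds (uniform).
#' @param tr Repetition time, s. @param te Echo time, s (recorded only).
#' @param fa Flip angle, degrees.
#' @param frame_interval Dynamic frame spacing, s. @param n_frames Frame count.
#' @param noise_sd Gaussian signal noise SD as a fraction of the baseline
#'   signal (0.05 corresponds to SNR 20).
#' @param relaxivity Contrast relaxivity r1, L mmol^-1 s^-1.
#' @param aif_args List of overrides passed to [generate_aif()].
#' @param seed Integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(40L, 40L, 40L), spacing = 1,
                         center = NULL, semiaxes = c(8, 7, 6),
                         ktrans_tumor = 0.14, ktrans_cv = 0.2,
                         ve_tumor = 0.3, vp_tumor = 0.04,
                         vp_background = 0.01, t10 = 0.8,
                         tr = 0.0056, te = 0.0023, fa = 15,
                         frame_interval = 12, n_frames = 20,
                         noise_sd = 0.05, relaxivity = 4.5,
                         aif_args = list(), seed = 1L) {
  spacing <- rep_len(spacing, 3)
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape / 2) * spacing
  stopifnot(all(shape >= 4L), all(spacing > 0), length(semiaxes) == 3,
            all(semiaxes > 0), ktrans_tumor >= 0, ktrans_cv >= 0,
            ve_tumor > 0, ve_tumor <= 1, vp_tumor >= 0, vp_tumor < 1,
            ve_tumor + vp_tumor <= 1, t10 > 0, tr > 0, fa > 0, fa < 90,
            frame_interval > 0, n_frames >= 4, noise_sd >= 0)
  if (any(center - semiaxes < 0) || any(center + semiaxes > shape * spacing))
    stop("tumor ellipsoid does not fit inside the grid")
  structure(list(shape = shape, spacing = spacing, center = center,
                 semiaxes = semiaxes, ktrans_tumor = ktrans_tumor,
                 ktrans_cv = ktrans_cv, ve_tumor = ve_tumor,
                 vp_tumor = vp_tumor, vp_background = vp_background,
                 t10 = t10, tr = tr, te = te, fa = fa,
                 frame_interval = frame_interval, n_frames = n_frames,
                 noise_sd = noise_sd, relaxivity = relaxivity,
                 aif_args = aif_args, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-center coordinates along one axis, mm (0-based indices)
.axis_coords <- function(n, h) (seq_len(n) - 0.5) * h

#' Rasterize an ellipsoid mask on a voxel grid
#'
#' A voxel belongs to the mask when its center lies inside the ellipsoid.
#'
#' @param shape Grid shape, voxels. @param spacing Spacing, mm (len 1 or 3).
#' @param center Ellipsoid center, mm. @param semiaxes Semi-axes, mm.
#' @return 3D logical array.
#' @export
ellipsoid_mask <- function(shape, spacing, center, semiaxes) {
  spacing <- rep_len(spacing, 3)
  x <- .axis_coords(shape[1], spacing[1])
  y <- .axis_coords(shape[2], spacing[2])
  z <- .axis_coords(shape[3], spacing[3])
  dx2 <- ((x - center[1]) / semiaxes[1])^2
  dy2 <- ((y - center[2]) / semiaxes[2])^2
  dz2 <- ((z - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Generate a synthetic DCE phantom dataset
#'
#' Forward-composes the extended Tofts model with the SPGR steady-state
#' signal equation on an ellipsoidal tumor, then adds Gaussian noise on the
#' magnitude signal. Identical spec + seed gives bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_dataset` list: `signal` (4D array), `t10` (3D, s),
#'   `mask` (3D logical), truth maps (`ktrans`, `ve`, `vp`), `aif`, `times`
#'   (s), and `provenance` (spec + seed).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  a <- do.call(generate_aif, c(list(timebase = times), spec$aif_args))
  mask <- ellipsoid_mask(spec$shape, spec$spacing, spec$center, spec$semiaxes)
  if (!any(mask)) stop("tumor mask is empty")
  kt <- array(0, spec$shape)
  idx <- which(mask)
  kt_t <- rep(spec$ktrans_tumor, length(idx))
  if (spec$ktrans_cv > 0 && spec$ktrans_tumor > 0) {
    sdlog <- sqrt(log(1 + spec$ktrans_cv^2))
    kt_t <- spec$ktrans_tumor *
      stats::rlnorm(length(idx), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  kt[idx] <- kt_t
  ve <- array(spec$ve_tumor, spec$shape)      # ve only acts where ktrans > 0
  vp <- array(spec$vp_background, spec$shape)
  vp[idx] <- spec$vp_tumor
  # tissue curves: all voxels share ve; ktrans and vp vary
  ct_tumor <- etm_forward(kt_t, spec$ve_tumor, spec$vp_tumor, a, times)
  if (is.null(dim(ct_tumor))) ct_tumor <- matrix(ct_tumor, nrow = 1)
  cp <- a$cp
  sig <- array(0, c(spec$shape, spec$n_frames))
  base <- spgr_signal(0, spec$t10, spec$tr, spec$fa, spec$relaxivity)
  for (f in seq_len(spec$n_frames)) {
    cf <- array(spec$vp_background * cp[f], spec$shape)
    cf[idx] <- ct_tumor[, f]
    sig[, , , f] <- spgr_signal(cf, spec$t10, spec$tr, spec$fa, spec$relaxivity)
  }
  if (spec$noise_sd > 0) {
    sig <- sig + stats::rnorm(length(sig), sd = spec$noise_sd * base)
    sig <- pmax(sig, 0)
  }
  structure(list(signal = sig, t10 = array(spec$t10, spec$shape),
                 mask = mask, ktrans = kt, ve = ve, vp = vp,
                 aif = a, times = times,
                 provenance = list(spec = unclass(spec), seed = spec$seed)),
            class = "phantom_dataset")
}

#' Specify a longitudinal synthetic cohort
#'
#' Each subject gets one phantom per time point (pre-TX, D1-TX, D2-TX) with
#' the subject's baseline K^trans scaled by per-timepoint multiplicative
#' effects. Default effects are the ratios of the published cohort means
#' (0.14, 0.27, 0.19 1/min), i.e. (1, 1.929, 1.357) — an emulation of the
#' observed shift, not ground truth. Tumor volumes are drawn log-uniformly
#' from `volume_range`; the default spans the reported pre-treatment range.
#' `missing` marks (subject, time point) pairs without an exam, emulating the
#' two dropped exams in the study cohort (n = 8, 8, 9).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effects Length-3 positive multiplicative K^trans effects.
#' @param volume_range Tumor-volume range, cm^3.
#' @param ktrans_baseline_mean,ktrans_baseline_sd Subject-level pre-TX
#'   K^trans distribution, 1/min (truncated at 0.02).
#' @param missing Integer matrix with columns (subject, timepoint), or NULL.
#'   Default drops subject 1 at time point 1 and subject 2 at time point 2
#'   when `n_subjects >= 9` (the study pattern), else nothing.
#' @param spacing Phantom voxel spacing, mm.
#' @param noise_sd Signal noise SD (fraction of baseline).
#' @param n_frames,frame_interval Acquisition timing.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 9L, effects = c(1, 0.27 / 0.14, 0.19 / 0.14),
                        volume_range = c(1.08, 68.53),
                        ktrans_baseline_mean = 0.14, ktrans_baseline_sd = 0.06,
                        missing = NULL, spacing = 2, noise_sd = 0.05,
                        n_frames = 20L, frame_interval = 12, seed = 1L) {
  stopifnot(n_subjects >= 2L, length(effects) == 3L, all(effects > 0),
            length(volume_range) == 2L, all(volume_range > 0),
            volume_range[1] <= volume_range[2], ktrans_baseline_mean > 0)
  if (is.null(missing) && n_subjects >= 9L)
    missing <- rbind(c(1L, 1L), c(2L, 2L))
  structure(list(n_subjects = as.integer(n_subjects), effects = effects,
                 volume_range = volume_range,
                 ktrans_baseline_mean = ktrans_baseline_mean,
                 ktrans_baseline_sd = ktrans_baseline_sd,
                 missing = missing, spacing = spacing, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a longitudinal phantom cohort
#'
#' @param spec A [cohort_spec()].
#' @param margin_mm Background margin around the tumor in each phantom, mm.
#' @return List with `subjects` — a list of per-subject lists holding
#'   `datasets` (length 3; NULL where the exam is missing), `volume_cm3`,
#'   `ktrans_true` (length-3 true tumor-mean K^trans, 1/min), `semiaxes` —
#'   and the `spec`. Time points are labeled pre-TX, D1-TX, D2-TX.
#' @export
generate_cohort <- function(spec, margin_mm = 12) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  tp_labels <- c("pre-TX", "D1-TX", "D2-TX")
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    v_cm3 <- exp(stats::runif(1, log(spec$volume_range[1]),
                              log(spec$volume_range[2])))
    # ellipsoid with mild random anisotropy, volume 4/3 pi abc = v
    ratios <- stats::runif(2, 0.7, 1)
    a3 <- v_cm3 * 1000 * 3 / (4 * pi) / prod(ratios)   # mm^3
    ax <- a3^(1 / 3)
    semi <- c(ax, ax * ratios[1], ax * ratios[2])
    kt0 <- max(0.02, stats::rnorm(1, spec$ktrans_baseline_mean,
                                  spec$ktrans_baseline_sd))
    side <- ceiling((2 * max(semi) + 2 * margin_mm) / spec$spacing)
    shape <- rep(as.integer(side), 3)
    kt_true <- kt0 * spec$effects
    seeds <- sample.int(2^30, 3)
    datasets <- vector("list", 3)
    for (tp in 1:3) {
      if (!is.null(spec$missing) &&
          any(spec$missing[, 1] == s & spec$missing[, 2] == tp)) next
      ps <- phantom_spec(shape = shape, spacing = spec$spacing,
                         semiaxes = semi, ktrans_tumor = kt_true[tp],
                         noise_sd = spec$noise_sd, n_frames = spec$n_frames,
                         frame_interval = spec$frame_interval,
                         seed = seeds[tp])
      datasets[[tp]] <- generate_phantom(ps)
    }
    names(datasets) <- tp_labels
    subjects[[s]] <- list(datasets = datasets, volume_cm3 = v_cm3,
                          ktrans_true = kt_true, semiaxes = semi)
  }
  list(subjects = subjects, spec = spec, timepoints = tp_labels)
}

#' Write a phantom dataset to NIfTI plus a JSON provenance sidecar
#'
#' @param ds A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(ds, dir, prefix = "phantom") {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- ds$provenance$spec$spacing
  wr <- function(img, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".nii.gz"))
    im <- RNifti::asNifti(img * 1)
    pd <- rep_len(sp, 3)
    if (length(dim(im)) == 4L) pd <- c(pd, ds$provenance$spec$frame_interval)
    im <- RNifti::`pixdim<-`(im, pd)
    RNifti::writeNifti(im, p)
    p
  }
  paths <- c(series = wr(ds$signal, "series"), t10 = wr(ds$t10, "t10"),
             mask = wr(ds$mask, "mask"), ktrans = wr(ds$ktrans, "ktrans_truth"),
             ve = wr(ds$ve, "ve_truth"), vp = wr(ds$vp, "vp_truth"))
  aif_path <- file.path(dir, paste0(prefix, "_aif.csv"))
  write_aif(ds$aif, aif_path)
  paths <- c(paths, aif = aif_path)
  side <- file.path(dir, paste0(prefix, "_provenance.json"))
  jsonlite::write_json(list(provenance = ds$provenance, times_s = ds$times,
                            units = list(t10 = "s", ktrans = "1/min",
                                         spacing = "mm")),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, provenance = side)
  invisible(paths)
}
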