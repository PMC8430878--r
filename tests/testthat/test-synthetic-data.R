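test_that("identical spec and seed give bit-identical phantoms", {
  ps <- phantom_spec(shape = c(14, 14, 14), spacing = 2, semiaxes = c(5, 4, 4),
                     noise_sd = 0.05, seed = 42)
  d1 <- generate_phantom(ps)
  d2 <- generate_phantom(ps)
  expect_identical(d1$signal, d2$signal)
  expect_identical(d1$ktrans, d2$ktrans)
})

test_that("no kinetics and no noise leave the signal at baseline", {
  ps <- phantom_spec(shape = c(12, 12, 12), spacing = 2, semiaxes = c(5, 4, 4),
                     ktrans_tumor = 0, ktrans_cv = 0, vp_tumor = 0,
                     vp_background = 0, noise_sd = 0, seed = 1)
  ds <- generate_phantom(ps)
  base <- ds$signal[, , , 1]
  for (f in seq_along(ds$times)) {
    expect_equal(ds$signal[, , , f], base, tolerance = 1e-12)
  }
})

test_that("noiseless phantom concentration is recovered exactly", {
  ps <- phantom_spec(shape = c(12, 12, 12), spacing = 2, semiaxes = c(5, 4, 4),
                     noise_sd = 0, ktrans_cv = 0.2, seed = 3)
  ds <- generate_phantom(ps)
  cv <- concentration_from_signal(ds$signal, ds$t10, tr = ps$tr, fa = ps$fa,
                                  baseline_frames = 3)
  idx <- which(ds$mask)
  cmat <- matrix(cv$conc, ncol = length(ds$times))[idx, , drop = FALSE]
  truth <- etm_forward(ds$ktrans[idx], ps$ve_tumor, ps$vp_tumor,
                       ds$aif, ds$times)
  expect_lt(max(abs(cmat - truth)) / max(truth), 1e-6)
})

test_that("fitted-parameter spread grows monotonically with signal noise", {
  sds <- c(0.01, 0.03, 0.06)
  spread <- vapply(seq_along(sds), function(i) {
    kt <- vapply(1:12, function(rep) {
      ps <- phantom_spec(shape = c(8, 8, 8), spacing = 2, semiaxes = c(4, 4, 4),
                         ktrans_cv = 0, noise_sd = sds[i],
                         seed = 1000 * i + rep)
      ds <- generate_phantom(ps)
      cv <- concentration_from_signal(ds$signal, ds$t10, tr = ps$tr,
                                      fa = ps$fa, baseline_frames = 3)
      ctm <- colMeans(matrix(cv$conc, ncol = length(ds$times))[which(ds$mask), ,
                                                               drop = FALSE])
      fit_etm(ctm, ds$aif, ds$times)$ktrans
    }, 0)
    stats::sd(kt)
  }, 0)
  expect_true(all(diff(spread) > 0))
})

test_that("cohort defaults emulate the study conditions", {
  cs <- cohort_spec()
  expect_equal(cs$volume_range, c(1.08, 68.53))
  expect_equal(cs$effects, c(1, 0.27 / 0.14, 0.19 / 0.14), tolerance = 1e-12)
  # default missingness reproduces the n = 8, 8, 9 exam pattern
  co_counts <- table(cs$missing[, 2])
  expect_equal(as.integer(co_counts[c("1", "2")]), c(1L, 1L))
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
})

test_that("null effects give identical true K^trans across time points", {
  cs <- cohort_spec(n_subjects = 3, effects = c(1, 1, 1),
                    volume_range = c(0.8, 0.8), missing = NULL, seed = 5)
  co <- generate_cohort(cs)
  for (s in co$subjects) {
    expect_equal(s$ktrans_true[1], s$ktrans_true[2])
    expect_equal(s$ktrans_true[1], s$ktrans_true[3])
  }
})

test_that("cohort-mean fitted K^trans ratios recover the generating effects", {
  eff <- c(1, 1.93, 1.36)
  cs <- cohort_spec(n_subjects = 5, effects = eff,
                    volume_range = c(0.6, 1.2), noise_sd = 0.01,
                    missing = NULL, seed = 7)
  co <- generate_cohort(cs)
  fitted <- sapply(co$subjects, function(s) {
    vapply(1:3, function(tp) {
      ds <- s$datasets[[tp]]
      cv <- concentration_from_signal(ds$signal, ds$t10,
                                      tr = ds$provenance$spec$tr,
                                      fa = ds$provenance$spec$fa,
                                      baseline_frames = 3)
      ctm <- colMeans(matrix(cv$conc,
                             ncol = length(ds$times))[which(ds$mask), ,
                                                      drop = FALSE])
      fit_etm(ctm, ds$aif, ds$times)$ktrans
    }, 0)
  })
  ratios <- rowMeans(fitted) / mean(fitted[1, ])
  expect_lt(abs(ratios[2] - eff[2]) / eff[2], 0.05)
  expect_lt(abs(ratios[3] - eff[3]) / eff[3], 0.05)
})

test_that("phantom NIfTI export round-trips and validates", {
  ps <- phantom_spec(shape = c(10, 10, 10), spacing = 2, semiaxes = c(4, 4, 4),
                     seed = 2)
  ds <- generate_phantom(ps)
  d <- withr::local_tempdir()
  paths <- write_phantom(ds, d, "ph")
  expect_true(all(file.exists(unlist(paths))))
  sig <- RNifti::readNifti(paths[["series"]])
  expect_equal(dim(sig), dim(ds$signal))
  expect_equal(as.array(sig), unclass(ds$signal), tolerance = 1e-6,
               ignore_attr = TRUE)
  rep <- validate_inputs(paths[c("series", "t10", "mask", "provenance")])
  expect_true(rep$ok)
})
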