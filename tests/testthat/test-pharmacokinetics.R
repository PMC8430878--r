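make_aif <- function(dt = 2, tmax = 300) {
  t <- seq(0, tmax, by = dt)
  list(t = t, a = generate_aif(t))
}

test_that("SPGR inversion is the exact inverse of the forward transform", {
  t <- seq(0, 300, 2)
  curve <- pmax(0, sin(t / 40)) * 2
  sig <- spgr_signal(c(rep(0, 3), curve[-(1:3)]), t10 = 1, tr = 0.0056, fa = 15)
  out <- concentration_from_signal(matrix(sig, 1), t10 = 1, tr = 0.0056,
                                   fa = 15, baseline_frames = 3)
  expect_lt(max(abs(out$conc[-(1:3)] - curve[-(1:3)])), 1e-9)
  expect_false(any(out$clamped))
})

test_that("baseline-identical signal maps to zero concentration", {
  sig <- matrix(rep(spgr_signal(0, 0.8), 30), 1)
  out <- concentration_from_signal(sig, 0.8, baseline_frames = 3)
  expect_equal(as.numeric(out$conc), rep(0, 30), tolerance = 1e-12)
})

test_that("signals beyond the SPGR-attainable range are clamped and flagged", {
  base <- spgr_signal(0, 0.8)
  smax <- spgr_signal(1e6, 0.8)      # asymptotic ceiling
  sig <- matrix(c(rep(base, 3), smax * 1.5), 1)
  out <- concentration_from_signal(sig, 0.8, baseline_frames = 3)
  expect_true(out$clamped[1, 4])
  expect_true(is.finite(out$conc[1, 4]))
})

test_that("vascular-only tissue reproduces the scaled AIF exactly", {
  m <- make_aif()
  ct <- etm_forward(0, 0.3, 0.04, m$a)
  expect_equal(ct, 0.04 * m$a$cp, tolerance = 1e-12)
})

test_that("constant plasma input gives the closed-form uptake curve", {
  t <- seq(0, 600, 2)
  a <- aif(t, rep(2.5, length(t)))
  ct <- etm_forward(0.27, 0.3, 0, a)
  kep_s <- 0.27 / (60 * 0.3)
  closed <- 0.3 * 2.5 * (1 - exp(-kep_s * t))
  expect_lt(max(abs(ct - closed)), 1e-10)
})

test_that("zero-kep kernel accumulates the trapezoidal integral of cp", {
  m <- make_aif()
  acc <- exp_conv(m$t, m$a$cp, 0)
  oracle <- c(0, cumsum(diff(m$t) * (utils::head(m$a$cp, -1) +
                                       utils::tail(m$a$cp, -1)) / 2))
  expect_equal(acc, oracle, tolerance = 1e-12)
})

test_that("recursive convolution agrees with a fine-grid trapezoidal oracle", {
  m <- make_aif(dt = 6)
  for (kep in c(0.002, 0.015, 0.08)) {
    rec <- exp_conv(m$t, m$a$cp, kep)
    ora <- conv_trapz(m$t, m$a$cp, kep)
    expect_lt(max(abs(rec - ora)) / max(ora), 1e-4)
  }
})

test_that("noiseless ETM fits recover the generating parameters", {
  m <- make_aif(dt = 2)
  truth <- c(ktrans = 0.27, ve = 0.3, vp = 0.04)
  ct <- etm_forward(truth[1], truth[2], truth[3], m$a)
  fit <- fit_etm(ct, m$a, m$t)
  expect_true(fit$converged)
  expect_lt(abs(fit$ktrans - truth[1]) / truth[1], 1e-3)
  expect_lt(abs(fit$ve - truth[2]) / truth[2], 1e-3)
  expect_lt(abs(fit$vp - truth[3]) / truth[3], 1e-3)
  expect_equal(fit$kep, fit$ktrans / fit$ve, tolerance = 1e-9)
})

test_that("fits are deterministic and null tissue yields null parameters", {
  m <- make_aif()
  ct <- etm_forward(0.14, 0.25, 0.03, m$a)
  f1 <- fit_etm(ct, m$a, m$t)
  f2 <- fit_etm(ct, m$a, m$t)
  expect_identical(f1, f2)
  f0 <- fit_etm(rep(0, length(m$t)), m$a, m$t)
  expect_equal(f0$ktrans, 0, tolerance = 1e-10)
  expect_equal(f0$vp, 0, tolerance = 1e-10)
  expect_error(fit_etm(ct[1:5], m$a, m$t[1:5]), "10 time points")
})

test_that("EES concentration derivation inverts the compartmental relation", {
  m <- make_aif()
  ce_true <- flux_forward(1e-3, 1e-4, 0.3, 0.82, m$a)
  ct <- 0.3 * ce_true + 0.05 * m$a$cp
  out <- derive_ce(ct, m$a$cp, ve = 0.3, vp = 0.05)
  expect_equal(out$ce, ce_true, tolerance = 1e-12)
  expect_equal(derive_ce(ct, m$a$cp, ve = 1, vp = 0)$ce, ct)
  expect_equal(derive_ce(0.04 * m$a$cp, m$a$cp, ve = 0.3, vp = 0.04)$ce,
               rep(0, length(m$t)), tolerance = 1e-12)
  expect_error(derive_ce(ct, m$a$cp, ve = 0, vp = 0), "positive")
})

test_that("flux-model fit recovers PS/V and Jv/V from a noiseless curve", {
  m <- make_aif()
  ce <- flux_forward(psv = 1e-3, jvv = 1e-4, ve = 0.3, sigma_t = 0.82, m$a)
  fx <- fit_flux_model(ce, m$a$cp, m$t, sigma_t = 0.82, ve = 0.3)
  expect_lt(abs(fx$psv - 1e-3) / 1e-3, 0.01)
  expect_lt(abs(fx$jvv - 1e-4) / 1e-4, 0.01)
  # deSolve integration of the governing ODE as an independent forward oracle
  ode_ce <- deSolve::ode(
    y = c(ce = 0), times = m$t,
    func = function(t, y, p) {
      cp <- stats::approx(m$t, m$a$cp, xout = t, rule = 2)$y
      list((p["psv"] * (cp - y[1]) + p["jvv"] * (1 - 0.82) * cp) / 0.3)
    }, parms = c(psv = 1e-3, jvv = 1e-4))[, "ce"]
  expect_lt(max(abs(ce - ode_ce)) / max(ce), 5e-3)
})

test_that("zero convection reduces to the nested pure-diffusion model", {
  m <- make_aif()
  ce <- flux_forward(1e-3, 0, 0.3, 0.82, m$a)
  full <- fit_flux_model(ce, m$a$cp, m$t, 0.82, ve = 0.3)
  diff_only <- fit_flux_model(ce, m$a$cp, m$t, 0.82, ve = 0.3,
                              diffusion_only = TRUE)
  expect_lt(abs(full$rss - diff_only$rss), 1e-10)
  expect_lt(full$jvv, 1e-8)
})

test_that("a dead plasma input is flagged as unidentifiable", {
  t <- seq(0, 300, 2)
  fx <- fit_flux_model(rep(0, length(t)), rep(0, length(t)), t, 0.82, ve = 0.3)
  expect_false(fx$identifiable)
  expect_true(is.na(fx$psv))
})

test_that("Lp rescaling preserves the tumor mean and is linear", {
  dims <- c(8, 8, 8)
  mask <- array(TRUE, dims)
  uni <- rescale_lp(array(2e-4, dims), mask)
  expect_equal(unique(as.numeric(uni$lp_sv)), 2.1e-11 * 2e4, tolerance = 1e-12)
  set.seed(1)
  jv <- array(stats::runif(prod(dims), 1e-5, 1e-3), dims)
  out <- rescale_lp(jv, mask)
  expect_lt(abs(mean(out$lp_sv) - 2.1e-11 * 2e4) / (2.1e-11 * 2e4), 1e-9)
  # a voxel at twice the mean filtration gets twice the baseline conductivity
  jv2 <- jv; jv2[1] <- 2 * out$mean_jv_over_v
  out2 <- rescale_lp(jv2, mask)
  expect_equal(out2$lp_sv[1],
               2 * 2.1e-11 * 2e4 * out$mean_jv_over_v / out2$mean_jv_over_v,
               tolerance = 1e-12)
  expect_error(rescale_lp(array(0, dims), mask), "zero")
})
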