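tc <- tissue_constants()

test_that("coefficient assembly reproduces the physiological table", {
  dom <- sphere_domain(r_mm = 6, shell_mm = 6, ktrans = 0.2)
  co <- assemble_coefficients(dom, tc)
  tum <- dom$labels == 2L; nor <- dom$labels == 1L
  # uniform K^trans: scaling factor 1, tumor conductance Lp0 * S/V
  expect_equal(unique(co$g_v[tum]), 2e-11 * 2e4, tolerance = 1e-12)
  expect_equal(unique(co$g_v[nor]), 3e-12 * 7e3, tolerance = 1e-12)
  expect_equal(unique(co$g_l[nor]), 1e-7, tolerance = 1e-15)
  expect_equal(unique(co$g_l[tum]), 0)
  expect_equal(unique(co$kh[tum]), 1.9e-12)
  # doubling one voxel's K^trans doubles its source conductance
  dom2 <- dom
  i <- which(tum)[1]
  dom2$ktrans[i] <- 2 * dom$ktrans_mean
  dom2$ktrans_mean <- mean(dom2$ktrans[tum])
  co2 <- assemble_coefficients(dom2, tc)
  expect_equal(co2$g_v[i],
               (2 * dom$ktrans_mean / dom2$ktrans_mean) * 4e-7,
               tolerance = 1e-9)
})

test_that("an all-tumor domain without sink relaxes to Starling equilibrium", {
  dom <- uniform_tumor_domain(10)
  pf <- solve_ifp(dom, tc)
  p_eq <- 2300 - 0.82 * (2670 - 3230)
  expect_equal(p_eq, 2759.2)
  expect_lt(max(abs(pf$p - p_eq)) / p_eq, 1e-3)
  # sources vanish at equilibrium
  expect_lt(max(abs(pf$phi_v), na.rm = TRUE), 1e-12)
})

test_that("without osmotic terms pressure equals microvascular pressure", {
  dom <- uniform_tumor_domain(8)
  tc0 <- tissue_constants(sigma_t = c(tumor = 0, normal = 0),
                          pi_v = 0, pi_i = c(tumor = 0, normal = 0))
  pf <- solve_ifp(dom, tc0)
  expect_equal(max(abs(pf$p - 2300)), 0, tolerance = 1e-6)
})

test_that("a source-free no-flux problem is rejected as singular", {
  dom <- uniform_tumor_domain(6)
  tc_dead <- tissue_constants(lp0 = c(tumor = 0, normal = 0))
  expect_error(solve_ifp(dom, tc_dead), "singular")
})

test_that("3D spherical solve matches the 1D radial reference", {
  dom <- sphere_domain(r_mm = 10, shell_mm = 10)
  pf <- solve_ifp(dom, tc)
  ref <- solve_ifp_radial(10, 10, tc)
  dr <- domain_radii(dom)
  bins <- floor(dr$r) + 0.5
  prof <- tapply(pf$p[dr$idx], bins, mean)
  rb <- as.numeric(names(prof))
  keep <- rb <= 20
  pref <- stats::approx(ref$r_mm, ref$p, xout = rb[keep], rule = 2)$y
  l2 <- sqrt(sum((prof[keep] - pref)^2) / sum(pref^2))
  expect_lt(l2, 0.02)
  # discrete conservation under the no-flux boundary
  expect_lt(pf$diagnostics$conservation, 1e-6)
  # maximum principle: bounded by the local equilibrium pressures
  lo <- starling_equilibrium(tc, "normal", with_sink = TRUE)
  hi <- starling_equilibrium(tc, "tumor")
  expect_gte(min(pf$p, na.rm = TRUE), lo * 0.99)
  expect_lte(max(pf$p, na.rm = TRUE), hi * 1.01)
})

test_that("strong coupling produces a core plateau at equilibrium pressure", {
  # alpha = R * sqrt(Lp S/V / K_H) >= 10 with an elevated vessel conductivity
  tc_hi <- tissue_constants(lp0 = c(tumor = 1e-10, normal = 3e-12))
  alpha <- 0.010 * sqrt(1e-10 * 2e4 / 1.9e-12)
  expect_gte(alpha, 10)
  dom <- sphere_domain(r_mm = 10, shell_mm = 10)
  pf <- solve_ifp(dom, tc_hi)
  ctr <- round(dim(dom$labels) / 2)
  p_eq <- starling_equilibrium(tc_hi, "tumor")
  expect_lt(abs(pf$p[ctr[1], ctr[2], ctr[3]] - p_eq) / p_eq, 0.01)
})

test_that("tumor-mean pressure is grid-converged at 1 mm", {
  dom1 <- sphere_domain(r_mm = 6, shell_mm = 6, spacing = 1)
  dom05 <- sphere_domain(r_mm = 6, shell_mm = 6, spacing = 0.5)
  p1 <- solve_ifp(dom1, tc)
  p05 <- solve_ifp(dom05, tc, tol = 1e-8)
  m1 <- mean(p1$p[dom1$labels == 2L])
  m05 <- mean(p05$p[dom05$labels == 2L])
  expect_lt(abs(m1 - m05) / m05, 0.01)
})

test_that("Darcy velocity reproduces hand-computed gradients", {
  dims <- c(10, 10, 10)
  lab <- array(2L, dims)
  p <- array(0, dims)
  for (i in 1:10) p[i, , ] <- 100 * i      # 100 Pa per mm along x
  pf <- structure(list(p = p, kh = array(1.9e-12, dims), spacing = 1,
                       labels = lab,
                       phi_v = p * 0, phi_l = p * 0,
                       diagnostics = list()), class = "pressure_field")
  vf <- compute_ifv(pf)
  # interior: |u| = K_H * 1e5 Pa/m, exactly
  expect_equal(vf$ux[5, 5, 5], -1.9e-12 * 1e5, tolerance = 1e-18)
  expect_equal(vf$uy[5, 5, 5], 0)
  expect_equal(vf$magnitude[5, 5, 5], 1.9e-12 * 1e5, tolerance = 1e-18)
  # uniform pressure: zero velocity everywhere
  pf$p <- array(500, dims)
  vf0 <- compute_ifv(pf)
  expect_true(all(vf0$magnitude == 0))
})

test_that("the fastest flow sits in the tumor boundary shell", {
  dom <- sphere_domain(r_mm = 8, shell_mm = 10)
  pf <- solve_ifp(dom, tc)
  vf <- compute_ifv(pf)
  dr <- domain_radii(dom)
  imax <- dr$idx[which.max(vf$magnitude[dr$idx])]
  r_max <- dr$r[match(imax, dr$idx)]
  expect_lt(abs(r_max - 8), 2)
})

test_that("field summaries agree with naive flat-array statistics", {
  dom <- sphere_domain(r_mm = 6, shell_mm = 6)
  pf <- solve_ifp(dom, tc)
  vf <- compute_ifv(pf)
  s <- summarize_fields(pf, vf, dom, "pre-TX", "sub01")
  tum <- dom$labels == 2L
  expect_equal(s$ifp_kpa_mean, mean(pf$p[tum]) / 1000, tolerance = 1e-12)
  expect_equal(s$ifp_kpa_sd, stats::sd(pf$p[tum]) / 1000, tolerance = 1e-12)
  expect_equal(s$ifv_ms_mean, mean(vf$magnitude[tum]), tolerance = 1e-15)
  expect_equal(s$vt_cm3, sum(tum) / 1000)
  # constant pressure: 2.63 kPa mean, zero SD
  pf$p[tum] <- 2630
  s2 <- summarize_fields(pf, vf, dom, "pre-TX")
  expect_equal(s2$ifp_kpa_mean, 2.63)
  expect_equal(s2$ifp_kpa_sd, 0)
})
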