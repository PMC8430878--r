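#' Forward diffusive-convective transcapillary flux model
#'
#' EES concentration dynamics
#' \eqn{v_e \, dC_e/dt = (PS/V)(C_p - C_e) + (J_v/V)(1-\sigma_T) C_p},
#' i.e. diffusive exchange plus convective delivery carried by plasma
#' concentration. The linear ODE is solved exactly (for piecewise-linear
#' C_p) via the exponential-kernel recursion:
#' \eqn{C_e(t) = A \int_0^t e^{-k(t-\tau)} C_p(\tau) d\tau} with
#' \eqn{k = (PS/V)/v_e} and \eqn{A = (PS/V + (J_v/V)(1-\sigma_T))/v_e}.
#'
#' @param psv Diffusive permeability-surface product per unit volume PS/V, 1/s.
#' @param jvv Filtration rate per unit volume J_v/V, 1/s.
#' @param ve EES volume fraction, > 0.
#' @param sigma_t Osmotic reflection coefficient in [0, 1].
#' @param aif A [aif()] object.
#' @param times Output sample times, seconds.
#' @return EES concentration curve, mM.
#' @export
flux_forward <- function(psv, jvv, ve, sigma_t, aif, times = aif$times) {
  stopifnot(psv >= 0, jvv >= 0, ve > 0, sigma_t >= 0, sigma_t <= 1)
  cp <- stats::approx(aif$times, aif$cp, xout = times, rule = 2)$y
  k <- psv / ve
  a <- (psv + jvv * (1 - sigma_t)) / ve
  a * exp_conv(times, cp, k)
}

#' Fit the diffusive-convective flux model to an EES curve
#'
#' Estimates PS/V and J_v/V by bounded nonlinear least squares with v_e and
#' sigma_T held fixed. v_e must be supplied (normally from the extended Tofts
#' fit): from a single C_e(t) curve the triple (v_e, PS/V, J_v/V) is not
#' identifiable, because the curve depends only on the rate PS/V / v_e and the
#' amplitude (PS/V + (J_v/V)(1-sigma_T)) / v_e; see the methods vignette.
#'
#' @param ce EES concentration curve, mM.
#' @param cp Plasma concentration at `times`, mM.
#' @param times Sample times, seconds.
#' @param sigma_t Osmotic reflection coefficient in [0, 1] (tissue constant,
#'   not fitted; tumor literature value 0.82).
#' @param ve EES volume fraction from the kinetic fit, > 0.
#' @param diffusion_only Logical; `TRUE` pins J_v/V = 0 (nested
#'   pure-diffusion model).
#' @return One-row tibble: `ve` (passed through), `psv` (1/s), `jvv` (1/s),
#'   `rss`, `converged`, `identifiable`. A degenerate, identically-zero
#'   plasma input yields `identifiable = FALSE` with NA parameters.
#' @export
fit_flux_model <- function(ce, cp, times, sigma_t = 0.82, ve, diffusion_only = FALSE) {
  stopifnot(length(ce) == length(times), length(cp) == length(times),
            sigma_t >= 0, sigma_t <= 1)
  if (missing(ve) || ve <= 0) stop("ve must be supplied and positive")
  if (all(abs(cp) < 1e-15)) {
    return(tibble::tibble(ve = ve, psv = NA_real_, jvv = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          identifiable = FALSE))
  }
  model <- function(p) {
    jv <- if (diffusion_only) 0 else p[2]
    k <- p[1] / ve
    ((p[1] + jv * (1 - sigma_t)) / ve) * exp_conv(times, cp, k)
  }
  resid_fn <- function(p) ce - model(p)
  start <- c(1e-3, 1e-4)
  lower <- c(1e-9, 0)
  upper <- c(1, 1)
  if (diffusion_only) { start <- start[1]; lower <- lower[1]; upper <- upper[1] }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            ftol = 1e-12,
                                                            ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble::tibble(ve = ve, psv = NA_real_, jvv = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          identifiable = TRUE))
  }
  tibble::tibble(ve = ve, psv = fit$par[1],
                 jvv = if (diffusion_only) 0 else fit$par[2],
                 rss = sum(fit$fvec^2), converged = fit$info %in% 1:4,
                 identifiable = TRUE)
}

#' Rescale capillary hydraulic conductivity by the filtration-rate map
#'
#' Spatially varying vessel-wall conductivity:
#' \eqn{L_p (S/V) = L_{p,0} (S/V) \cdot (J_v/V) / \langle J_v/V\rangle},
#' where the average is taken over the tumor mask, so the tumor mean of the
#' output equals \eqn{L_{p,0} (S/V)} by construction.
#'
#' @param jvv_map 3D array of J_v/V values, 1/s.
#' @param tumor_mask 3D logical/0-1 array, non-empty.
#' @param lp0 Baseline vessel hydraulic conductivity, m Pa^-1 s^-1 (literature
#'   tumor value 2.1e-11).
#' @param s_over_v Capillary surface-to-volume ratio, 1/m (tumor 2e4).
#' @return List: `lp_sv` (3D array, Pa^-1 s^-1, NA outside the tumor mask) and
#'   `mean_jv_over_v` (1/s).
#' @export
rescale_lp <- function(jvv_map, tumor_mask, lp0 = 2.1e-11, s_over_v = 2e4) {
  idx <- which(tumor_mask != 0)
  if (length(idx) == 0L) stop("tumor mask is empty")
  jv <- jvv_map[idx]
  if (any(!is.finite(jv)) || any(jv < 0)) stop("J_v/V map must be finite and non-negative")
  mj <- mean(jv)
  if (mj <= 0) stop("mean J_v/V over the tumor is zero; cannot rescale")
  lp_sv <- array(NA_real_, dim(jvv_map))
  lp_sv[idx] <- lp0 * s_over_v * jv / mj
  list(lp_sv = lp_sv, mean_jv_over_v = mj)
}
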