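#' Exponential-kernel convolution with a sampled input function
#'
#' Evaluates \eqn{I(t_n) = \int_0^{t_n} e^{-k (t_n - \tau)} c(\tau) d\tau}
#' by the recursive scheme that is exact when `c` is piecewise linear between
#' samples. This is preferred over FFT convolution because clinical DCE
#' sampling is coarse (5-15 s) and the recursion commits no quadrature error
#' on the linear interpolant.
#'
#' @param times Sample times, seconds, strictly increasing.
#' @param c Input concentration at `times` (mM).
#' @param k Decay-rate constant(s), 1/s; scalar or vector (one per voxel).
#' @return If `k` is scalar, a vector over `times`; else a matrix
#'   (length(k) x length(times)).
#' @export
exp_conv <- function(times, c, k) {
  nt <- length(times)
  stopifnot(length(c) == nt, nt >= 2L, all(diff(times) > 0), all(k >= 0))
  nv <- length(k)
  out <- matrix(0, nv, nt)
  acc <- numeric(nv)
  for (n in 2:nt) {
    dt <- times[n] - times[n - 1]
    b <- (c[n] - c[n - 1]) / dt
    kd <- k * dt
    e <- exp(-kd)
    small <- kd < 1e-6
    g1 <- ifelse(small, dt * (1 - kd / 2 + kd^2 / 6), (1 - e) / k)
    g2 <- ifelse(small, dt^2 * (0.5 - kd / 6 + kd^2 / 24), (dt - g1) / k)
    acc <- acc * e + c[n - 1] * g1 + b * g2
    out[, n] <- acc
  }
  if (nv == 1L) drop(out) else out
}

#' Forward extended Tofts model
#'
#' Tissue concentration
#' \eqn{C_t(t) = K^{trans}\int_0^t e^{-k_{ep}(t-\tau)} C_p(\tau)d\tau + v_p C_p(t)}
#' with \eqn{k_{ep} = K^{trans}/v_e}. Parameters are per-voxel vectors, so a
#' whole map can be simulated in one call.
#'
#' @param ktrans Volume transfer constant(s), 1/min.
#' @param ve Extravascular-extracellular volume fraction(s) in (0, 1].
#' @param vp Plasma volume fraction(s) in [0, 1).
#' @param aif A [aif()] object.
#' @param times Output sample times, seconds (default: the AIF time base).
#'   The AIF is interpolated linearly onto `times` if they differ.
#' @return Vector (single voxel) or matrix (voxels x times) of tissue
#'   concentration, mM.
#' @export
etm_forward <- function(ktrans, ve, vp, aif, times = aif$times) {
  stopifnot(inherits(aif, "dce_aif"), all(ktrans >= 0), all(ve > 0),
            all(ve <= 1), all(vp >= 0), all(vp < 1))
  nv <- max(length(ktrans), length(ve), length(vp))
  ktrans <- rep_len(ktrans, nv); ve <- rep_len(ve, nv); vp <- rep_len(vp, nv)
  cp <- stats::approx(aif$times, aif$cp, xout = times, rule = 2)$y
  kep_s <- ktrans / (60 * ve)        # 1/min -> 1/s
  conv <- exp_conv(times, cp, kep_s)
  kt_s <- ktrans / 60
  if (nv == 1L) {
    kt_s * conv + vp * cp
  } else {
    kt_s * conv + outer(vp, cp)
  }
}

.etm_bounds <- list(lower = c(ktrans = 0, ve = 1e-3, vp = 0),
                    upper = c(ktrans = 5, ve = 1, vp = 0.5))

# fixed multi-start grid (ktrans 1/min, ve, vp); spans slow-to-fast kinetics
.etm_starts <- list(c(0.05, 0.10, 0.01),
                    c(0.20, 0.30, 0.02),
                    c(1.00, 0.60, 0.05))

#' Fit the extended Tofts model to one tissue curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with a fixed
#' three-point multi-start grid; ties between starts are broken by lowest
#' residual norm, then lowest K^trans, so the fit is deterministic.
#' Bounds: K^trans in [0, 5] 1/min, v_e in [1e-3, 1], v_p in [0, 0.5].
#'
#' @param ct Tissue concentration curve, mM, at `times`.
#' @param aif A [aif()] object (must be non-zero somewhere).
#' @param times Sample times, seconds (>= 10 points).
#' @param start Optional single numeric start `c(ktrans, ve, vp)` replacing
#'   the multi-start grid (used for warm-started voxelwise map fitting).
#' @return A one-row [tibble::tibble()] with columns `ktrans`, `ve`, `vp`,
#'   `kep` (= ktrans/ve, 1/min), `rss`, `converged`. On non-convergence the
#'   parameters are `NA` and `converged` is `FALSE` (never silent).
#' @export
fit_etm <- function(ct, aif, times, start = NULL) {
  stopifnot(inherits(aif, "dce_aif"))
  if (length(times) < 10L) stop("need at least 10 time points to fit the ETM")
  if (all(abs(aif$cp) < 1e-15)) stop("AIF is identically zero; fit impossible")
  stopifnot(length(ct) == length(times))
  cp <- stats::approx(aif$times, aif$cp, xout = times, rule = 2)$y
  resid_fn <- function(p) {
    kep_s <- p[1] / (60 * p[2])
    ct - (p[1] / 60) * exp_conv(times, cp, kep_s) - p[3] * cp
  }
  starts <- if (is.null(start)) .etm_starts else list(as.numeric(start))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = .etm_bounds$lower, upper = .etm_bounds$upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14 ||
        (abs(rss - best$rss) <= 1e-14 && fit$par[1] < best$par[1])) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
                          kep = NA_real_, rss = NA_real_, converged = FALSE))
  }
  p <- best$par
  tibble::tibble(ktrans = p[1], ve = p[2], vp = p[3], kep = p[1] / p[2],
                 rss = best$rss, converged = best$info %in% 1:4)
}

#' Fit the extended Tofts model over a voxel map
#'
#' The tumor-mean curve is fitted first with the full multi-start grid; each
#' voxel is then fitted warm-started from the mean-curve solution (plus the
#' grid start closest to it), which keeps voxelwise map fitting tractable
#' without sacrificing determinism.
#'
#' @param conc 4D concentration array (x, y, z, t), mM.
#' @param mask 3D logical/0-1 array selecting voxels to fit.
#' @param aif A [aif()] object.
#' @param times Sample times, seconds.
#' @param multi_start Logical; `TRUE` runs the full grid at every voxel.
#' @return List of 3D maps `ktrans`, `ve`, `vp`, `kep` (NA outside mask),
#'   plus `fits` (tibble, one row per masked voxel, with voxel index) and
#'   `n_failed`.
#' @export
fit_etm_map <- function(conc, mask, aif, times, multi_start = FALSE) {
  dims <- dim(conc)
  stopifnot(length(dims) == 4L, all(dim(mask) == dims[1:3]))
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask is empty")
  cmat <- matrix(conc, ncol = dims[4])[idx, , drop = FALSE]
  mean_fit <- fit_etm(colMeans(cmat), aif, times)
  warm <- if (isTRUE(mean_fit$converged)) {
    c(mean_fit$ktrans, mean_fit$ve, mean_fit$vp)
  } else {
    .etm_starts[[2]]
  }
  rows <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    rows[[i]] <- if (multi_start) {
      fit_etm(cmat[i, ], aif, times)
    } else {
      fit_etm(cmat[i, ], aif, times, start = warm)
    }
  }
  fits <- do.call(rbind, rows)
  fits$voxel <- idx
  mk_map <- function(v) {
    m <- array(NA_real_, dims[1:3]); m[idx] <- v; m
  }
  list(ktrans = mk_map(fits$ktrans), ve = mk_map(fits$ve),
       vp = mk_map(fits$vp), kep = mk_map(fits$kep),
       fits = fits, n_failed = sum(!fits$converged))
}

#' Derive the EES concentration from the tissue curve
#'
#' Uses the compartmental relation \eqn{C_t = v_e C_e + v_p C_p}, i.e.
#' \eqn{C_e = (C_t - v_p C_p)/v_e}. Negative transients (noise-driven) are
#' floored at zero and counted.
#'
#' @param ct Tissue concentration curve, mM.
#' @param cp Plasma concentration at the same times, mM.
#' @param ve EES volume fraction, > 0.
#' @param vp Plasma volume fraction.
#' @return List with `ce` (mM) and `n_floored`.
#' @export
derive_ce <- function(ct, cp, ve, vp) {
  if (ve <= 0) stop("ve must be positive")
  stopifnot(length(ct) == length(cp))
  ce <- (ct - vp * cp) / ve
  n_neg <- sum(ce < 0)
  list(ce = pmax(ce, 0), n_floored = n_neg)
}
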