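#' Spoiled gradient-echo steady-state signal
#'
#' \eqn{S = M_0 \sin\alpha (1 - E_1) / (1 - E_1\cos\alpha)} with
#' \eqn{E_1 = \exp(-TR \cdot R_1)} and \eqn{R_1 = 1/T_{10} + r_1 C}.
#' T2*/TE weighting is treated as a constant factor absorbed into `m0`
#' (contrast-agent effects on T2* are neglected at short TE).
#'
#' @param conc Contrast concentration, mM (scalar, vector or array).
#' @param t10 Pre-contrast T1, seconds (recycled against `conc`).
#' @param tr Repetition time, seconds.
#' @param fa Flip angle, degrees.
#' @param relaxivity Longitudinal relaxivity r1, L mmol^-1 s^-1.
#' @param m0 Equilibrium-magnetization scale (arbitrary units).
#' @return Signal, same shape as `conc`.
#' @export
spgr_signal <- function(conc, t10, tr = 0.0056, fa = 15, relaxivity = 4.5,
                        m0 = 1000) {
  stopifnot(all(t10 > 0), tr > 0, fa > 0, fa < 90)
  r1 <- 1 / t10 + relaxivity * conc
  e1 <- exp(-tr * r1)
  a <- fa * pi / 180
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Convert a dynamic signal series to contrast concentration
#'
#' Inverts the SPGR steady-state equation per voxel. The pre-contrast baseline
#' signal S0 is the mean over the first `baseline_frames` frames; together with
#' the supplied T10 it fixes the voxel scale, so the inversion is exact on
#' noiseless input. Signals beyond the SPGR-attainable range (which would imply
#' a negative relaxation rate) are clamped and the voxel-frame is flagged.
#'
#' @param signal 4D numeric array (x, y, z, t) or matrix (voxels x t).
#' @param t10 3D array (or vector) of pre-contrast T1 values, seconds, > 0.
#' @param tr Repetition time, seconds.
#' @param fa Flip angle, degrees.
#' @param relaxivity Longitudinal relaxivity r1, L mmol^-1 s^-1 (contrast-agent
#'   specific; gadobutrol-like default).
#' @param baseline_frames Number of leading pre-bolus frames defining S0.
#' @return List with `conc` (same voxel layout as `signal`, mM) and `clamped`
#'   (logical array marking voxel-frames clamped to the attainable range).
#' @export
concentration_from_signal <- function(signal, t10, tr = 0.0056, fa = 15,
                                      relaxivity = 4.5, baseline_frames = 3) {
  dims <- dim(signal)
  if (is.null(dims) || length(dims) < 2L)
    stop("signal must be a matrix (voxels x t) or 4D array (x,y,z,t)")
  nt <- dims[length(dims)]
  if (baseline_frames < 1L || baseline_frames >= nt)
    stop("baseline_frames must be in [1, n_frames)")
  sig <- matrix(signal, ncol = nt)
  t10v <- as.numeric(t10)
  if (length(t10v) == 1L) t10v <- rep(t10v, nrow(sig))
  if (length(t10v) != nrow(sig)) stop("t10 does not match signal voxel count")
  if (any(t10v <= 0)) stop("t10 must be positive")
  stopifnot(fa > 0, fa < 90)
  a <- fa * pi / 180
  ca <- cos(a)
  s0 <- rowMeans(sig[, seq_len(baseline_frames), drop = FALSE])
  e10 <- exp(-tr / t10v)
  # relative enhancement rho = S/S0 * (1 - E10)/(1 - E10 cos a); then
  # E1 = (1 - rho)/(1 - rho cos a)
  base_ratio <- (1 - e10) / (1 - e10 * ca)
  rho <- sweep(sig, 1, s0, "/") * base_ratio
  # attainable range: E1 in (0, 1] <=> rho in [base_ratio at C=0 .. 1/... )
  rho_max <- 1 / (1 + 1e-12)  # rho -> 1 as R1 -> Inf
  clamped <- rho >= rho_max | rho < 0
  rho <- pmin(pmax(rho, 0), rho_max - 1e-9)
  e1 <- (1 - rho) / (1 - rho * ca)
  r1 <- -log(e1) / tr
  conc <- sweep(r1, 1, 1 / t10v, "-") / relaxivity
  dim(conc) <- dims
  dim(clamped) <- dims
  list(conc = conc, clamped = clamped)
}
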