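#' Physiological tissue constants for the fluid model
#'
#' Literature tumor/normal values used by the Starling-source Darcy
#' continuity model. All SI: conductivities in m Pa^-1 s^-1 (vessel wall,
#' `lp0`) or m^2 Pa^-1 s^-1 (tissue, `kh`), surface-to-volume `s_over_v` in
#' 1/m, lymphatic filtration coefficient `lymph_coeff` = L_pL S_L/V in
#' Pa^-1 s^-1 (zero in tumor: dysfunctional lymphatics), pressures in Pa,
#' and the dimensionless osmotic reflection coefficient `sigma_t`.
#'
#' @param ... Named overrides; each must be an existing field. Tumor/normal
#'   paired fields take a named vector `c(tumor = ..., normal = ...)`.
#' @return A `tissue_constants` list.
#' @export
tissue_constants <- function(...) {
  base <- list(
    lp0         = c(tumor = 2e-11,   normal = 3e-12),
    s_over_v    = c(tumor = 2e4,     normal = 7e3),
    lymph_coeff = c(tumor = 0,       normal = 1e-7),
    kh          = c(tumor = 1.9e-12, normal = 3.8e-13),
    pv          = 2300,
    pl          = 0,
    pi_v        = 2670,
    pi_i        = c(tumor = 3230,    normal = 1330),
    sigma_t     = c(tumor = 0.82,    normal = 0.91)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(base))
    if (length(bad)) stop("unknown tissue constant(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(ov)) {
      v <- ov[[nm]]
      if (length(base[[nm]]) == 2L && length(v) == 1L)
        v <- c(tumor = unname(v), normal = unname(v))
      base[[nm]] <- v
    }
  }
  stopifnot(all(base$kh > 0), all(base$sigma_t >= 0), all(base$sigma_t <= 1),
            base$lymph_coeff[["tumor"]] == 0)
  structure(base, class = "tissue_constants")
}

#' Local Starling equilibrium pressure
#'
#' Pressure at which the transcapillary source vanishes:
#' \eqn{p_V - \sigma_T (\pi_V - \pi_i)}. With a lymphatic sink present the
#' voxel-level equilibrium becomes the conductance-weighted mixture
#' \eqn{(g_v p_{eq} + g_L p_L) / (g_v + g_L)}.
#'
#' @param constants A [tissue_constants()] object.
#' @param tissue "tumor" or "normal".
#' @param with_sink Include the lymphatic sink in the balance.
#' @return Equilibrium pressure, Pa.
#' @export
starling_equilibrium <- function(constants, tissue = c("tumor", "normal"),
                                 with_sink = FALSE) {
  tissue <- match.arg(tissue)
  p_eq <- constants$pv -
    constants$sigma_t[[tissue]] * (constants$pi_v - constants$pi_i[[tissue]])
  if (!with_sink) return(p_eq)
  gv <- constants$lp0[[tissue]] * constants$s_over_v[[tissue]]
  gl <- constants$lymph_coeff[[tissue]]
  (gv * p_eq + gl * constants$pl) / (gv + gl)
}

#' Assemble per-voxel PDE coefficients on a labeled domain
#'
#' For every domain voxel: source conductance \eqn{g_v = f L_p S/V} with
#' \eqn{f = K^{trans}/\langle K^{trans}\rangle} in tumor and 1 in normal
#' tissue, sink conductance \eqn{g_L}, the Starling effective pressure
#' \eqn{p_{eff} = p_V - \sigma_T(\pi_V - \pi_i)}, and the tissue hydraulic
#' conductivity K_H.
#'
#' @param domain A `domain_grid` from [build_domain()].
#' @param constants A [tissue_constants()] object.
#' @param scaling_mode "ktrans_scaling" (normalized K^trans multiplies the
#'   baseline tumor L_p S/V; default), "lp_field" (use the spatially varying
#'   `domain$lp_sv` map from [rescale_lp()]), or "both" (their product).
#' @return List of 3D arrays `g_v`, `g_l`, `p_eff`, `kh` (NA outside the
#'   domain) plus `scaling_mode`.
#' @export
assemble_coefficients <- function(domain, constants = tissue_constants(),
                                  scaling_mode = c("ktrans_scaling",
                                                   "lp_field", "both")) {
  scaling_mode <- match.arg(scaling_mode)
  lab <- domain$labels
  tum <- lab == 2L; nor <- lab == 1L
  if (!any(tum)) stop("domain has no tumor voxels")
  dims <- dim(lab)
  g_v <- array(NA_real_, dims); g_l <- array(NA_real_, dims)
  p_eff <- array(NA_real_, dims); kh <- array(NA_real_, dims)
  # tumor source conductance
  if (scaling_mode %in% c("ktrans_scaling", "both")) {
    if (is.null(domain$ktrans) || anyNA(domain$ktrans[tum]))
      stop("K^trans is missing on tumor voxels; required by scaling_mode")
    if (!is.finite(domain$ktrans_mean) || domain$ktrans_mean <= 0)
      stop("tumor-mean K^trans must be positive for normalization")
    f <- domain$ktrans[tum] / domain$ktrans_mean
  } else {
    f <- rep(1, sum(tum))
  }
  if (scaling_mode %in% c("lp_field", "both")) {
    if (is.null(domain$lp_sv) || anyNA(domain$lp_sv[tum]))
      stop("domain$lp_sv is required for scaling_mode = 'lp_field'/'both'")
    base <- domain$lp_sv[tum]
  } else {
    base <- constants$lp0[["tumor"]] * constants$s_over_v[["tumor"]]
  }
  g_v[tum] <- f * base
  g_v[nor] <- constants$lp0[["normal"]] * constants$s_over_v[["normal"]]
  g_l[tum] <- constants$lymph_coeff[["tumor"]]
  g_l[nor] <- constants$lymph_coeff[["normal"]]
  p_eff[tum] <- constants$pv -
    constants$sigma_t[["tumor"]] * (constants$pi_v - constants$pi_i[["tumor"]])
  p_eff[nor] <- constants$pv -
    constants$sigma_t[["normal"]] * (constants$pi_v - constants$pi_i[["normal"]])
  kh[tum] <- constants$kh[["tumor"]]
  kh[nor] <- constants$kh[["normal"]]
  list(g_v = g_v, g_l = g_l, p_eff = p_eff, kh = kh,
       scaling_mode = scaling_mode)
}

# Jacobi-preconditioned conjugate gradients on a sparse SPD system;
# deterministic (fixed zero start, fixed ordering).
.pcg <- function(A, b, tol, maxit = 50000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, residual = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) return(list(x = x, iterations = it, residual = res))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = maxit, residual = sqrt(sum(r^2)) / bnorm)
}

#' Solve the stationary continuity equation for interstitial fluid pressure
#'
#' Seven-point finite differences on the labeled isotropic voxel domain:
#' \eqn{-\nabla\cdot(K_H \nabla p_i) + (g_v + g_L) p_i = g_v p_{eff} + g_L p_L}
#' with harmonic-mean K_H on faces between unlike tissues and a homogeneous
#' Neumann (no-flux) condition on the outer domain surface (faces to
#' unlabeled voxels carry no flux). The symmetric positive-definite system
#' is solved by deterministic Jacobi-preconditioned conjugate gradients.
#'
#' @param domain A `domain_grid`.
#' @param constants A [tissue_constants()] object.
#' @param scaling_mode See [assemble_coefficients()].
#' @param tol Relative-residual convergence tolerance.
#' @return A `pressure_field` list: `p` (3D array, Pa, NA outside domain),
#'   `phi_v`, `phi_l` (volumetric source/sink rates, 1/s), `kh` (map used),
#'   and `diagnostics` (iterations, residual, n_unknowns, conservation).
#' @export
solve_ifp <- function(domain, constants = tissue_constants(),
                      scaling_mode = "ktrans_scaling", tol = 1e-10) {
  stopifnot(tol > 0)
  co <- assemble_coefficients(domain, constants, scaling_mode)
  lab <- domain$labels
  dims <- dim(lab)
  idx <- which(lab > 0L)
  n <- length(idx)
  if (n == 0L) stop("empty domain")
  gv <- co$g_v[idx]; gl <- co$g_l[idx]
  if (max(gv + gl) <= 0)
    stop("all sources and sinks vanish: the no-flux problem is singular ",
         "(pressure level undetermined)")
  h <- domain$spacing * 1e-3                     # mm -> m
  map <- array(0L, dims); map[idx] <- seq_len(n)
  ii <- jj <- xx <- list(); ptr <- 0L
  diag_acc <- gv + gl
  arr_ind <- arrayInd(idx, dims)
  for (ax in 1:3) {
    shift <- arr_ind
    shift[, ax] <- shift[, ax] + 1L
    ok <- shift[, ax] <= dims[ax]
    nb_lin <- idx[ok] + c(1L, dims[1], dims[1] * dims[2])[ax]
    nb_id <- map[nb_lin]
    sel <- nb_id > 0L
    a_id <- seq_len(n)[ok][sel]
    b_id <- nb_id[sel]
    kh_a <- co$kh[idx][a_id]; kh_b <- co$kh[idx][b_id]
    w <- 2 * kh_a * kh_b / (kh_a + kh_b) / h^2   # harmonic mean face K_H
    ptr <- ptr + 1L
    ii[[ptr]] <- c(a_id, b_id); jj[[ptr]] <- c(b_id, a_id)
    xx[[ptr]] <- c(-w, -w)
    dd <- numeric(n)
    dd[a_id] <- dd[a_id] + w
    dd2 <- numeric(n)
    dd2[b_id] <- dd2[b_id] + w
    diag_acc <- diag_acc + dd + dd2
  }
  A <- Matrix::sparseMatrix(i = c(unlist(ii), seq_len(n)),
                            j = c(unlist(jj), seq_len(n)),
                            x = c(unlist(xx), diag_acc), dims = c(n, n))
  b <- gv * co$p_eff[idx] + gl * constants$pl
  sol <- .pcg(A, b, tol)
  if (sol$residual > tol)
    stop("linear solve failed to reach tolerance ", tol,
         " (residual ", signif(sol$residual, 3), ")")
  p <- array(NA_real_, dims); p[idx] <- sol$x
  phi_v <- array(NA_real_, dims); phi_l <- array(NA_real_, dims)
  phi_v[idx] <- gv * (co$p_eff[idx] - sol$x)
  phi_l[idx] <- gl * (sol$x - constants$pl)
  gross <- sum(abs(phi_v[idx]))
  cons <- if (gross > 0) abs(sum(phi_v[idx] - phi_l[idx])) / gross else 0
  structure(list(p = p, phi_v = phi_v, phi_l = phi_l, kh = co$kh,
                 spacing = domain$spacing, labels = lab,
                 diagnostics = list(iterations = sol$iterations,
                                    residual = sol$residual,
                                    n_unknowns = n,
                                    conservation = cons,
                                    scaling_mode = co$scaling_mode)),
            class = "pressure_field")
}

#' Spherically symmetric reference solution of the continuity equation
#'
#' Independent 1D finite-volume solve of the same two-region problem (tumor
#' sphere of radius `r_tumor_mm` inside a normal shell of thickness
#' `shell_mm`) on a fine radial grid, with zero-flux conditions at the center
#' and the outer radius. Used as a dimension-reduction oracle for the 3D
#' voxel solver.
#'
#' @param r_tumor_mm Tumor radius, mm.
#' @param shell_mm Normal-shell thickness, mm.
#' @param constants A [tissue_constants()] object.
#' @param n Number of radial cells.
#' @return List with `r_mm` (cell centers) and `p` (Pa).
#' @export
solve_ifp_radial <- function(r_tumor_mm, shell_mm = 10,
                             constants = tissue_constants(), n = 4000L) {
  r_out <- (r_tumor_mm + shell_mm) * 1e-3
  dr <- r_out / n
  rc <- (seq_len(n) - 0.5) * dr
  rf <- seq_len(n - 1) * dr                      # interior face radii
  tum <- rc <= r_tumor_mm * 1e-3
  kh <- ifelse(tum, constants$kh[["tumor"]], constants$kh[["normal"]])
  gv <- ifelse(tum, constants$lp0[["tumor"]] * constants$s_over_v[["tumor"]],
               constants$lp0[["normal"]] * constants$s_over_v[["normal"]])
  gl <- ifelse(tum, constants$lymph_coeff[["tumor"]],
               constants$lymph_coeff[["normal"]])
  peff <- ifelse(tum,
                 constants$pv - constants$sigma_t[["tumor"]] *
                   (constants$pi_v - constants$pi_i[["tumor"]]),
                 constants$pv - constants$sigma_t[["normal"]] *
                   (constants$pi_v - constants$pi_i[["normal"]]))
  kh_f <- 2 * kh[-n] * kh[-1] / (kh[-n] + kh[-1])
  w <- kh_f * rf^2 / dr                          # face conductance * area
  vol <- rc^2 * dr                               # cell volume / (4 pi)
  diag <- gv * vol + gl * vol
  diag[-n] <- diag[-n] + w
  diag[-1] <- diag[-1] + w
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(-w, diag, -w), symmetric = FALSE)
  b <- (gv * peff + gl * constants$pl) * vol
  p <- as.numeric(Matrix::solve(A, b))
  list(r_mm = rc * 1e3, p = p)
}

#' Darcy velocity field from the pressure solution
#'
#' \eqn{u = -K_H \nabla p_i}, with central differences on interior voxels and
#' one-sided differences where a neighbor lies outside the domain (the
#' gradient is taken as zero where no neighbor exists along an axis).
#'
#' @param pressure A `pressure_field` from [solve_ifp()].
#' @return A `velocity_field` list: `ux`, `uy`, `uz` and `magnitude`
#'   (3D arrays, m/s, NA outside the domain).
#' @export
compute_ifv <- function(pressure) {
  p <- pressure$p
  dims <- dim(p)
  h <- pressure$spacing * 1e-3
  inside <- !is.na(p)
  grad_axis <- function(ax) {
    g <- array(0, dims)
    stepl <- c(1L, dims[1], dims[1] * dims[2])[ax]
    idx <- which(inside)
    ai <- arrayInd(idx, dims)
    has_up <- ai[, ax] < dims[ax]
    up_ok <- rep(FALSE, length(idx))
    up_ok[has_up] <- inside[idx[has_up] + stepl]
    has_dn <- ai[, ax] > 1L
    dn_ok <- rep(FALSE, length(idx))
    dn_ok[has_dn] <- inside[idx[has_dn] - stepl]
    both <- up_ok & dn_ok
    g[idx[both]] <- (p[idx[both] + stepl] - p[idx[both] - stepl]) / (2 * h)
    uponly <- up_ok & !dn_ok
    g[idx[uponly]] <- (p[idx[uponly] + stepl] - p[idx[uponly]]) / h
    dnonly <- dn_ok & !up_ok
    g[idx[dnonly]] <- (p[idx[dnonly]] - p[idx[dnonly] - stepl]) / h
    g[!inside] <- NA_real_
    g
  }
  gx <- grad_axis(1); gy <- grad_axis(2); gz <- grad_axis(3)
  kh <- pressure$kh
  ux <- -kh * gx; uy <- -kh * gy; uz <- -kh * gz
  mag <- sqrt(ux^2 + uy^2 + uz^2)
  structure(list(ux = ux, uy = uy, uz = uz, magnitude = mag),
            class = "velocity_field")
}

#' Summarize a solved time point over the tumor label
#'
#' Tumor-label mean and SD of interstitial fluid pressure (reported in kPa),
#' Darcy-velocity magnitude (m/s), K^trans (1/min), and the tumor volume in
#' cm^3.
#'
#' @param pressure A `pressure_field`.
#' @param velocity A `velocity_field` from [compute_ifv()].
#' @param domain The `domain_grid` that was solved.
#' @param timepoint Label, e.g. "pre-TX", "D1-TX" or "D2-TX".
#' @param subject Optional subject identifier.
#' @return One-row tibble with means, SDs and the volume.
#' @export
summarize_fields <- function(pressure, velocity, domain,
                             timepoint = "pre-TX", subject = NA_character_) {
  tum <- which(domain$labels == 2L)
  if (length(tum) == 0L) stop("empty tumor label")
  stopifnot(all(dim(pressure$p) == dim(domain$labels)))
  pk <- pressure$p[tum] / 1000
  vm <- velocity$magnitude[tum]
  kt <- if (is.null(domain$ktrans)) rep(NA_real_, length(tum)) else
    domain$ktrans[tum]
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  tibble::tibble(subject = subject, timepoint = timepoint,
                 vt_cm3 = compute_tumor_volume(domain$labels == 2L,
                                               domain$spacing),
                 ktrans_mean = mean(kt), ktrans_sd = sd0(kt),
                 ifp_kpa_mean = mean(pk), ifp_kpa_sd = sd0(pk),
                 ifv_ms_mean = mean(vm), ifv_ms_sd = sd0(vm))
}
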