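# Independent oracles used across tests.

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n+m, n) group assignments (no ties assumed).
rank_sum_exact_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Fine-grid trapezoidal evaluation of the exponential-kernel convolution
# integral (independent of the recursion in the package).
conv_trapz <- function(times, cp, k, dt = 0.05) {
  tg <- seq(min(times), max(times), by = dt)
  cpg <- stats::approx(times, cp, xout = tg, rule = 2)$y
  vapply(times, function(tn) {
    sel <- tg <= tn + 1e-12
    integrand <- exp(-k * (tn - tg[sel])) * cpg[sel]
    if (sum(sel) < 2L) return(0)
    pracma::trapz(tg[sel], integrand)
  }, 0)
}

# small solid-tumor domain built directly (bypasses build_domain)
uniform_tumor_domain <- function(n = 8L, ktrans = 0.14, spacing = 1) {
  lab <- array(2L, c(n, n, n))
  structure(list(labels = lab, spacing = spacing,
                 ktrans = array(ktrans, dim(lab)), ktrans_mean = ktrans,
                 lp_sv = NULL, padded = FALSE), class = "domain_grid")
}

# spherical tumor + normal shell domain via the standard builder
sphere_domain <- function(r_mm = 10, shell_mm = 10, ktrans = 0.14,
                          spacing = 1) {
  side <- ceiling((2 * (r_mm + shell_mm) + 4) / spacing)
  ctr <- rep(side * spacing / 2, 3)
  mask <- ellipsoid_mask(rep(side, 3), spacing, ctr, rep(r_mm, 3))
  build_domain(mask, spacing, array(ktrans, dim(mask)),
               dilation_voxels = shell_mm / spacing, new_spacing = spacing)
}

# radial distance of every domain voxel from the grid center, mm
domain_radii <- function(domain) {
  dims <- dim(domain$labels)
  idx <- which(domain$labels > 0L)
  ai <- arrayInd(idx, dims)
  ctr <- dims * domain$spacing / 2
  list(idx = idx,
       r = sqrt(rowSums(sweep((ai - 0.5) * domain$spacing, 2, ctr, "-")^2)))
}
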