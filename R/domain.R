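#' Resample a 3D volume to isotropic spacing
#'
#' Samples the input at the voxel centers of the target grid, using
#' nearest-neighbor (labels/masks) or trilinear (continuous maps)
#' interpolation in world (mm) coordinates. Voxel centers sit at
#' (i - 0.5) * spacing, i = 1..n.
#'
#' @param vol 3D numeric array.
#' @param spacing Input voxel spacing, mm (length 1 or 3).
#' @param new_spacing Target isotropic spacing, mm (default 1).
#' @param method "nearest" or "trilinear".
#' @return 3D array on the target grid covering the same physical extent.
#' @export
resample_iso <- function(vol, spacing, new_spacing = 1,
                         method = c("nearest", "trilinear")) {
  method <- match.arg(method)
  spacing <- rep_len(spacing, 3)
  dims <- dim(vol)
  stopifnot(length(dims) == 3L, all(spacing > 0), new_spacing > 0)
  extent <- dims * spacing
  nd <- pmax(1L, as.integer(round(extent / new_spacing)))
  # world coords of target voxel centers -> fractional input indices
  fidx <- lapply(1:3, function(ax) {
    w <- (seq_len(nd[ax]) - 0.5) * new_spacing
    w / spacing[ax] + 0.5          # input index space (1-based centers)
  })
  if (method == "nearest") {
    ii <- lapply(1:3, function(ax) pmin(pmax(round(fidx[[ax]]), 1L), dims[ax]))
    return(vol[ii[[1]], ii[[2]], ii[[3]], drop = FALSE])
  }
  # trilinear
  lo <- lapply(1:3, function(ax) pmin(pmax(floor(fidx[[ax]]), 1L), dims[ax]))
  hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1L, dims[ax]))
  fr <- lapply(1:3, function(ax) pmin(pmax(fidx[[ax]] - lo[[ax]], 0), 1))
  out <- array(0, nd)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    iz <- if (cz) hi[[3]] else lo[[3]]
    wx <- if (cx) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy) fr[[2]] else 1 - fr[[2]]
    wz <- if (cz) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * vol[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Binary dilation with a spherical structuring element
#'
#' Exact Euclidean-ball dilation computed by FFT convolution of the mask with
#' a rasterized ball kernel (voxel centers within `radius`), thresholded at
#' half a count to absorb floating-point noise.
#'
#' @param mask 3D logical/0-1 array.
#' @param radius Ball radius in voxels (>= 0).
#' @return 3D logical array.
#' @export
dilate_ball <- function(mask, radius) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L, radius >= 0)
  if (radius == 0) return(mask != 0)
  r <- ceiling(radius)
  k <- 2L * r + 1L
  ax <- seq_len(k) - r - 1L
  kern <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= radius^2 + 1e-9
  pd <- dims + k - 1L
  pad <- function(a, d) {
    out <- array(0, d); out[seq_len(dim(a)[1]), seq_len(dim(a)[2]),
                            seq_len(dim(a)[3])] <- a; out
  }
  fm <- stats::fft(pad(mask * 1, pd))
  fk <- stats::fft(pad(kern * 1, pd))
  conv <- Re(stats::fft(fm * fk, inverse = TRUE)) / prod(pd)
  # kernel center is at offset (r, r, r) in the padded convolution
  sel <- lapply(1:3, function(i) r + seq_len(dims[i]))
  conv[sel[[1]], sel[[2]], sel[[3]]] > 0.5
}

#' Build the labeled isotropic simulation domain
#'
#' Reslices the tumor mask (nearest-neighbor) and the K^trans map (trilinear)
#' to isotropic 1 mm voxels, then dilates the tumor by a spherical margin of
#' `dilation_voxels` resliced voxels to add a surrounding normal-tissue
#' shell. The grid is padded automatically if the dilation would touch its
#' edge. Labels: 0 outside, 1 normal shell, 2 tumor.
#'
#' @param mask 3D tumor ROI mask on the native grid.
#' @param spacing Native voxel spacing, mm (length 1 or 3).
#' @param ktrans Optional K^trans map aligned with `mask`, 1/min.
#' @param dilation_voxels Margin radius in resliced voxels (default 10, i.e.
#'   10 mm at the default 1 mm reslicing).
#' @param new_spacing Target isotropic spacing, mm.
#' @return A `domain_grid` list: `labels` (3D integer array), `spacing` (mm),
#'   `ktrans` (3D array, NA outside tumor), `ktrans_mean` (1/min, tumor mean),
#'   `lp_sv` (NULL; attach via [rescale_lp()] output if used), `padded`.
#' @export
build_domain <- function(mask, spacing, ktrans = NULL, dilation_voxels = 10,
                         new_spacing = 1) {
  if (!any(mask != 0)) stop("ROI mask is empty")
  if (!is.null(ktrans)) stopifnot(all(dim(ktrans) == dim(mask)))
  tumor <- resample_iso(mask * 1, spacing, new_spacing, "nearest") != 0
  kt <- NULL
  if (!is.null(ktrans)) {
    # mask-weighted trilinear: K^trans is undefined outside the tumor, so
    # interpolate value*mask and renormalize by the interpolated mask weight
    kt0 <- ifelse(is.na(ktrans), 0, ktrans) * (mask != 0)
    w <- resample_iso((mask != 0) * 1, spacing, new_spacing, "trilinear")
    kv <- resample_iso(kt0, spacing, new_spacing, "trilinear")
    kt <- ifelse(w > 1e-6, kv / pmax(w, 1e-6), 0)
  }
  # pad so the dilated shell always fits
  r <- ceiling(dilation_voxels)
  dims <- dim(tumor)
  bb <- apply(which(tumor, arr.ind = TRUE), 2, range)
  pad_lo <- pmax(0L, r - (bb[1, ] - 1L))
  pad_hi <- pmax(0L, r - (dims - bb[2, ]))
  padded <- any(pad_lo > 0L) || any(pad_hi > 0L)
  if (padded) {
    nd <- dims + pad_lo + pad_hi
    grow <- function(a, fill) {
      out <- array(fill, nd)
      out[pad_lo[1] + seq_len(dims[1]), pad_lo[2] + seq_len(dims[2]),
          pad_lo[3] + seq_len(dims[3])] <- a
      out
    }
    tumor <- grow(tumor, FALSE)
    if (!is.null(kt)) kt <- grow(kt, 0)
  }
  region <- dilate_ball(tumor, dilation_voxels)
  labels <- array(0L, dim(tumor))
  labels[region] <- 1L
  labels[tumor] <- 2L
  kt_field <- NULL
  kt_mean <- NA_real_
  if (!is.null(kt)) {
    kt_field <- array(NA_real_, dim(tumor))
    kt_field[tumor] <- pmax(kt[tumor], 0)
    kt_mean <- mean(kt_field[tumor])
  }
  structure(list(labels = labels, spacing = new_spacing, ktrans = kt_field,
                 ktrans_mean = kt_mean, lp_sv = NULL, padded = padded),
            class = "domain_grid")
}

#' Tumor volume from a binary mask
#'
#' Voxel count times voxel volume, reported in cm^3.
#'
#' @param mask 3D binary mask.
#' @param spacing Voxel spacing, mm (length 1 or 3).
#' @return Volume in cm^3.
#' @export
compute_tumor_volume <- function(mask, spacing) {
  spacing <- rep_len(spacing, 3)
  sum(mask != 0) * prod(spacing) / 1000
}
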