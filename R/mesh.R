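# Surface extraction by marching tetrahedra at a fixed iso-level.
# Each grid cell (8 voxel centers) is split into 6 tetrahedra sharing the
# main diagonal; linear interpolation along tetrahedron edges places the
# surface vertices. The field is zero-padded so surfaces of masks touching
# the grid edge still close, and triangle orientation is fixed to point away
# from the interior, giving a watertight, consistently oriented mesh.

# corner offsets of a unit cell, rows = corners 1..8
.cell_corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                       c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))

# 6 tetrahedra on the diagonal corner1 -> corner8
.cell_tets <- rbind(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
                    c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))

#' Extract a triangulated iso-surface from a 3D mask or scalar field
#'
#' Marching tetrahedra at `iso` (default 0.5, the midpoint of a binary mask).
#' Coordinates are in mm, with voxel centers at (i - 0.5) * spacing.
#'
#' @param vol 3D numeric array (binary mask or scalar field).
#' @param spacing Voxel spacing, mm (length 1 or 3).
#' @param iso Iso-level.
#' @return A `surface_mesh` list: `vertices` (n x 9 matrix, one triangle per
#'   row: ax ay az bx by bz cx cy cz, mm) and `provenance`.
#' @export
extract_surface <- function(vol, spacing, iso = 0.5) {
  spacing <- rep_len(spacing, 3)
  dims <- dim(vol)
  stopifnot(length(dims) == 3L)
  if (!any(vol > iso)) stop("field never exceeds the iso-level; empty surface")
  # zero-pad one layer so the surface closes at the grid edge
  f <- array(0, dims + 2L)
  f[1 + seq_len(dims[1]), 1 + seq_len(dims[2]), 1 + seq_len(dims[3])] <- vol
  d <- dim(f)
  nc <- d - 1L
  cells <- as.matrix(expand.grid(i = seq_len(nc[1]), j = seq_len(nc[2]),
                                 k = seq_len(nc[3])))
  lin <- function(ijk) (ijk[, 1]) + (ijk[, 2] - 1L) * d[1] +
    (ijk[, 3] - 1L) * d[1] * d[2]
  # value and coordinate of every cell corner (cells x 8)
  vals <- matrix(0, nrow(cells), 8)
  for (c8 in 1:8) {
    off <- .cell_corners[c8, ]
    vals[, c8] <- f[lin(sweep(cells, 2, off, "+"))]
  }
  # quick reject: cells fully inside or outside
  keep <- rowSums(vals > iso) %in% 1:7
  cells <- cells[keep, , drop = FALSE]
  vals <- vals[keep, , drop = FALSE]
  if (nrow(cells) == 0L) stop("no surface cells found")
  # corner coordinates, mm: padded index i maps to center ((i-1) - 0.5)*h
  coord <- function(c8, ax) (cells[, ax] + .cell_corners[c8, ax] - 1.5) *
    spacing[ax]
  tris <- list()
  interp <- function(p, q, vp, vq) {
    t <- (iso - vp) / (vq - vp)
    p + t * (q - p)
  }
  for (tt in 1:6) {
    tet <- .cell_tets[tt, ]
    tv <- vals[, tet, drop = FALSE]
    inside <- tv > iso
    nin <- rowSums(inside)
    pos <- lapply(tet, function(c8)
      cbind(coord(c8, 1), coord(c8, 2), coord(c8, 3)))
    emit <- function(rows, a, b, c, pin) {
      # orient so the normal points away from the interior point pin
      u <- b - a; v <- c - a
      n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
      w <- a - pin
      flip <- rowSums(n * w) < 0
      b2 <- b; c2 <- c
      b2[flip, ] <- c[flip, ]; c2[flip, ] <- b[flip, ]
      tris[[length(tris) + 1L]] <<- cbind(a, b2, c2)
    }
    for (cin in 1:3) {
      combs <- utils::combn(4, cin)
      for (ci in seq_len(ncol(combs))) {
        ins <- combs[, ci]
        outs <- setdiff(1:4, ins)
        sel <- nin == cin &
          rowSums(inside[, ins, drop = FALSE]) == cin
        if (!any(sel)) next
        P <- lapply(1:4, function(m) pos[[m]][sel, , drop = FALSE])
        V <- tv[sel, , drop = FALSE]
        ev <- function(i1, i2) interp(P[[i1]], P[[i2]], V[, i1], V[, i2])
        if (cin == 1L) {
          a <- ev(ins, outs[1]); b <- ev(ins, outs[2]); c <- ev(ins, outs[3])
          emit(sel, a, b, c, P[[ins]])
        } else if (cin == 3L) {
          a <- ev(ins[1], outs); b <- ev(ins[2], outs); c <- ev(ins[3], outs)
          pin <- P[[ins[1]]]
          emit(sel, a, b, c, pin)
        } else {
          # two inside, two outside: quad split into two triangles
          e11 <- ev(ins[1], outs[1]); e12 <- ev(ins[1], outs[2])
          e21 <- ev(ins[2], outs[1]); e22 <- ev(ins[2], outs[2])
          pin <- P[[ins[1]]]
          emit(sel, e11, e12, e22, pin)
          emit(sel, e11, e22, e21, pin)
        }
      }
    }
  }
  verts <- do.call(rbind, tris)
  structure(list(vertices = verts,
                 provenance = list(iso = iso, spacing = spacing,
                                   source_dims = dims)),
            class = "surface_mesh")
}

#' Signed volume enclosed by a triangle mesh
#'
#' Sum of signed origin-tetrahedron volumes; positive for outward-oriented
#' closed meshes.
#'
#' @param mesh A `surface_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  a <- v[, 1:3, drop = FALSE]; b <- v[, 4:6, drop = FALSE]
  c <- v[, 7:9, drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Write a triangle mesh as binary STL
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  n <- nrow(v)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("voxel iso-surface", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  a <- v[, 1:3]; b <- v[, 4:6]; c <- v[, 7:9]
  u <- b - a; w <- c - a
  nr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nr^2)); len[len == 0] <- 1
  nr <- nr / len
  rec <- t(cbind(nr, a, b, c))     # 12 floats per triangle
  for (i in seq_len(n)) {
    writeBin(as.numeric(rec[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Export a mask surface as an STL mesh
#'
#' Iso-surface of the binary mask at level 0.5. A single-voxel mask is
#' degenerate for interpolation-based extraction and is flagged: its voxel
#' box surface is emitted instead.
#'
#' @param mask 3D binary mask, non-empty.
#' @param spacing Voxel spacing, mm.
#' @param path Optional STL output path.
#' @return A `surface_mesh` (with attribute `degenerate` if boxed); writes
#'   `path` when given.
#' @export
export_stl <- function(mask, spacing, path = NULL) {
  if (!any(mask != 0)) stop("mask is empty")
  spacing <- rep_len(spacing, 3)
  if (sum(mask != 0) == 1L) {
    warning("single-voxel mask: emitting its voxel box surface")
    ijk <- which(mask != 0, arr.ind = TRUE)[1, ]
    lo <- (ijk - 1) * spacing; hi <- ijk * spacing
    mesh <- .box_mesh(lo, hi)
    attr(mesh, "degenerate") <- TRUE
  } else {
    mesh <- extract_surface(mask * 1, spacing, iso = 0.5)
  }
  if (!is.null(path)) write_stl(mesh, path)
  mesh
}

.box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  quads <- rbind(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                 c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  tris <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(cbind(t(v[q[1], ]), t(v[q[2], ]), t(v[q[3], ])),
          cbind(t(v[q[1], ]), t(v[q[3], ]), t(v[q[4], ])))
  }))
  m <- structure(list(vertices = tris,
                      provenance = list(iso = NA, spacing = NA,
                                        source_dims = NA)),
                 class = "surface_mesh")
  if (mesh_volume(m) < 0) m$vertices <- m$vertices[, c(1:3, 7:9, 4:6)]
  m
}

#' Voxelize a closed triangle mesh onto a grid
#'
#' Parity-count ray casting along z: voxel centers between successive surface
#' crossings of their (x, y) column are inside. Used for round-trip checks
#' against the source mask.
#'
#' @param mesh A `surface_mesh`.
#' @param dims Grid shape, voxels.
#' @param spacing Voxel spacing, mm.
#' @return 3D logical array.
#' @export
voxelize_mesh <- function(mesh, dims, spacing) {
  spacing <- rep_len(spacing, 3)
  eps <- 1e-6
  xs <- (seq_len(dims[1]) - 0.5) * spacing[1] + eps
  ys <- (seq_len(dims[2]) - 0.5) * spacing[2] + eps * 2
  crossings <- vector("list", dims[1] * dims[2])
  v <- mesh$vertices
  for (t in seq_len(nrow(v))) {
    a <- v[t, 1:3]; b <- v[t, 4:6]; c <- v[t, 7:9]
    xr <- range(a[1], b[1], c[1]); yr <- range(a[2], b[2], c[2])
    ix <- which(xs >= xr[1] - eps & xs <= xr[2] + eps)
    iy <- which(ys >= yr[1] - eps & ys <= yr[2] + eps)
    if (!length(ix) || !length(iy)) next
    d1 <- b - a; d2 <- c - a
    det <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(det) < 1e-12) next      # triangle vertical in z: no z-crossing
    for (i in ix) for (j in iy) {
      px <- xs[i] - a[1]; py <- ys[j] - a[2]
      u <- (px * d2[2] - py * d2[1]) / det
      w <- (py * d1[1] - px * d1[2]) / det
      if (u >= 0 && w >= 0 && u + w <= 1) {
        z <- a[3] + u * d1[3] + w * d2[3]
        key <- i + (j - 1L) * dims[1]
        crossings[[key]] <- c(crossings[[key]], z)
      }
    }
  }
  out <- array(FALSE, dims)
  zs <- (seq_len(dims[3]) - 0.5) * spacing[3]
  for (key in which(lengths(crossings) > 0)) {
    z <- sort(crossings[[key]])
    # collapse duplicate hits on shared edges
    z <- z[c(TRUE, diff(z) > 1e-9)]
    if (length(z) %% 2L == 1L) next
    i <- ((key - 1L) %% dims[1]) + 1L
    j <- ((key - 1L) %/% dims[1]) + 1L
    for (p in seq(1, length(z), by = 2)) {
      out[i, j, zs > z[p] & zs < z[p + 1]] <- TRUE
    }
  }
  out
}
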