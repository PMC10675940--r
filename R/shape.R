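# 3D morphology of the tumor mask: mesh-based volume and surface area via a
# marching-tetrahedra triangulation of the (optionally smoothed) binary
# mask, principal-axis lengths from the physical voxel coordinates, and
# maximum diameters.  All 14 features depend only on the mask and spacing.

## Cube corners, unit offsets, numbered 0..7.
CUBE_CORNERS <- rbind(
  c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
  c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
## Six-tetrahedra decomposition around the 0-6 diagonal.
CUBE_TETS <- rbind(
  c(0,1,2,6), c(0,2,3,6), c(0,3,7,6),
  c(0,7,4,6), c(0,4,5,6), c(0,5,1,6)) + 1L

## Triangle area for rows of three xyz points.
tri_area <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

## Marching tetrahedra over a scalar field (iso-level 0.5).  Returns the
## total surface area and enclosed volume of the iso-surface.  The field is
## sampled at voxel centers, physical coordinates (index - 1) * spacing.
marching_tets <- function(field, spacing, iso = 0.5) {
  dm <- dim(field)
  ## pad with a zero shell so the surface closes
  pf <- array(0, dm + 2L)
  pf[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- field
  pd <- dim(pf)
  nx <- pd[1] - 1L; ny <- pd[2] - 1L; nz <- pd[3] - 1L
  corner_vals <- lapply(seq_len(8), function(cc) {
    o <- CUBE_CORNERS[cc, ]
    pf[(1:nx) + o[1], (1:ny) + o[2], (1:nz) + o[3], drop = FALSE]
  })
  ## cube base coordinates (physical), aligned with the un-padded grid
  bx <- ((1:nx) - 2) * spacing[1]
  by <- ((1:ny) - 2) * spacing[2]
  bz <- ((1:nz) - 2) * spacing[3]
  base <- cbind(rep(bx, times = ny * nz),
                rep(rep(by, each = nx), times = nz),
                rep(bz, each = nx * ny))
  area <- 0; volume <- 0
  for (t in seq_len(nrow(CUBE_TETS))) {
    ci <- CUBE_TETS[t, ]
    v <- sapply(ci, function(cc) as.vector(corner_vals[[cc]]))  # ncube x 4
    inside <- v >= iso
    n_in <- rowSums(inside)
    ## enclosed volume: fraction of each tetrahedron inside the midpoint
    ## surface is 0, 1/8, 1/2, 7/8, 1 for 0..4 inside corners (binary field)
    tet_vol <- prod(spacing) / 6
    volume <- volume + tet_vol *
      sum(c(0, 1/8, 1/2, 7/8, 1)[n_in + 1])
    corner_off <- CUBE_CORNERS[ci, , drop = FALSE] *
      matrix(spacing, 4, 3, byrow = TRUE)
    interp_pt <- function(rows, a, b, va, vb) {
      tt <- (iso - va) / (vb - va)
      p_a <- matrix(corner_off[a, ], length(rows), 3, byrow = TRUE)
      p_b <- matrix(corner_off[b, ], length(rows), 3, byrow = TRUE)
      base[rows, , drop = FALSE] + p_a + tt * (p_b - p_a)
    }
    for (case_mask in 1:14) {
      ins <- as.logical(bitwAnd(case_mask, c(1L, 2L, 4L, 8L)))
      rows <- which(inside[, 1] == ins[1] & inside[, 2] == ins[2] &
                    inside[, 3] == ins[3] & inside[, 4] == ins[4])
      if (!length(rows)) next
      if (sum(ins) %in% c(1, 3)) {
        ## one corner separated: single triangle on its three edges
        solo <- if (sum(ins) == 1) which(ins) else which(!ins)
        others <- setdiff(1:4, solo)
        p1 <- interp_pt(rows, solo, others[1], v[rows, solo], v[rows, others[1]])
        p2 <- interp_pt(rows, solo, others[2], v[rows, solo], v[rows, others[2]])
        p3 <- interp_pt(rows, solo, others[3], v[rows, solo], v[rows, others[3]])
        area <- area + sum(tri_area(p1, p2, p3))
      } else {
        ## two-two split: quad over the four crossing edges
        pin <- which(ins); pout <- which(!ins)
        q1 <- interp_pt(rows, pin[1], pout[1], v[rows, pin[1]], v[rows, pout[1]])
        q2 <- interp_pt(rows, pin[1], pout[2], v[rows, pin[1]], v[rows, pout[2]])
        q3 <- interp_pt(rows, pin[2], pout[2], v[rows, pin[2]], v[rows, pout[2]])
        q4 <- interp_pt(rows, pin[2], pout[1], v[rows, pin[2]], v[rows, pout[1]])
        area <- area + sum(tri_area(q1, q2, q3)) + sum(tri_area(q1, q3, q4))
      }
    }
  }
  list(area = area, volume = volume)
}

## Light separable Gaussian smoothing of the binary mask before meshing
## reduces voxelization faceting so the surface-area estimate tracks the
## underlying smooth boundary.
smooth_mask <- function(mask, sigma_vox = 0.7) {
  a <- mask * 1
  r <- max(1L, ceiling(2 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox); k <- k / sum(k)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    ## renormalize at the borders so a flat face keeps value 0.5 at the edge
    norm <- array(0, dim(a)); ones <- array(1, dim(a))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      d <- c(0L, 0L, 0L); d[ax] <- off
      out <- out + k[i] * shift_array(a, d[1], d[2], d[3], fill = 0)
      norm <- norm + k[i] * shift_array(ones, d[1], d[2], d[3], fill = 0)
    }
    a <- out / norm
  }
  a
}

max_pairwise_dist <- function(pts, chunk = 512L) {
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(pts^2), `+`) -
      2 * block %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

## boundary voxels: in-mask voxels with an out-of-mask 6-neighbor
boundary_voxels <- function(mask) {
  inner <- mask
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    inner <- inner & shift_array(mask, d[1], d[2], d[3], fill = FALSE)
  mask & !inner
}

#' 3D shape features of the tumor mask (14)
#'
#' Mesh volume and surface area from a marching-tetrahedra triangulation of
#' the lightly smoothed mask; sphericity
#' `pi^(1/3) (6 V)^(2/3) / A`; surface/volume ratio; voxel volume; maximum
#' 3D diameter and per-orientation maximum 2D diameters over boundary
#' voxels; principal-axis lengths (`4 sqrt(lambda)` from the covariance of
#' physical voxel coordinates), elongation `sqrt(l2/l1)` and flatness
#' `sqrt(l3/l1)`.
#'
#' @param mask Logical 3D tumor mask (non-empty).
#' @param spacing Voxel spacing (mm).
#' @return Named numeric vector of 14 features (mm-based units).
#' @export
shape3d <- function(mask, spacing) {
  mask <- mask != 0
  if (!any(mask)) stopf("shape features require a non-empty mask")
  ## volume from the binary midpoint mesh (the inside-fraction decomposition
  ## is exact there); area from the smoothed mesh (faceting-corrected)
  mesh <- list(volume = marching_tets(mask * 1, spacing)$volume,
               area = marching_tets(smooth_mask(mask), spacing)$area)
  n <- sum(mask)
  voxel_volume <- n * prod(spacing)
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2L, spacing, `*`)
  ## principal axes (population covariance); guard single-voxel masks
  lambda <- if (n > 1) {
    ev <- eigen(stats::cov(pts) * (n - 1) / n, symmetric = TRUE,
                only.values = TRUE)$values
    pmax(ev, 0)
  } else c(0, 0, 0)
  bidx <- which(boundary_voxels(mask), arr.ind = TRUE)
  bpts <- sweep(bidx - 1, 2L, spacing, `*`)
  max_2d <- function(drop_ax) {
    keep <- setdiff(1:3, drop_ax)
    best <- 0
    for (plane in unique(bidx[, drop_ax])) {
      sel <- bidx[, drop_ax] == plane
      best <- max(best, max_pairwise_dist(bpts[sel, keep, drop = FALSE]))
    }
    best
  }
  sphericity <- pi^(1/3) * (6 * mesh$volume)^(2/3) / mesh$area
  c(mesh_volume = mesh$volume,
    voxel_volume = voxel_volume,
    surface_area = mesh$area,
    surface_volume_ratio = mesh$area / mesh$volume,
    sphericity = sphericity,
    max_3d_diameter = max_pairwise_dist(bpts),
    max_2d_diameter_slice = max_2d(3),
    max_2d_diameter_column = max_2d(2),
    max_2d_diameter_row = max_2d(1),
    major_axis_length = 4 * sqrt(lambda[1]),
    minor_axis_length = 4 * sqrt(lambda[2]),
    least_axis_length = 4 * sqrt(lambda[3]),
    elongation = if (lambda[1] > 0) sqrt(lambda[2] / lambda[1]) else 0,
    flatness = if (lambda[1] > 0) sqrt(lambda[3] / lambda[1]) else 0)
}
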