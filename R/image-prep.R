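# DCE-MRI preprocessing: resampling to a common grid, parenchymal intensity
# normalization, subtraction-phase derivation, seeded spatial fuzzy c-means
# tumor segmentation, and the 20 mm peritumoral stroma band.

## ---- resampling -----------------------------------------------------------

## Trilinear interpolation of a 3D array at fractional voxel coordinates
## (1-based), clamped at the borders.
trilinear_at <- function(a, xi, yi, zi) {
  dm <- dim(a)
  xi <- pmin(pmax(xi, 1), dm[1]); yi <- pmin(pmax(yi, 1), dm[2])
  zi <- pmin(pmax(zi, 1), dm[3])
  x0 <- pmin(floor(xi), dm[1] - 1L); y0 <- pmin(floor(yi), dm[2] - 1L)
  z0 <- pmin(floor(zi), dm[3] - 1L)
  if (dm[1] == 1) x0 <- rep(1, length(xi))
  if (dm[2] == 1) y0 <- rep(1, length(yi))
  if (dm[3] == 1) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  g <- function(dx, dy, dz)
    a[cbind(pmin(x0 + dx, dm[1]), pmin(y0 + dy, dm[2]), pmin(z0 + dz, dm[3]))]
  v000 <- g(0,0,0); v100 <- g(1,0,0); v010 <- g(0,1,0); v110 <- g(1,1,0)
  v001 <- g(0,0,1); v101 <- g(1,0,1); v011 <- g(0,1,1); v111 <- g(1,1,1)
  (v000*(1-fx) + v100*fx)*(1-fy)*(1-fz) + (v010*(1-fx) + v110*fx)*fy*(1-fz) +
  (v001*(1-fx) + v101*fx)*(1-fy)*fz   + (v011*(1-fx) + v111*fx)*fy*fz
}

resample_grid <- function(dm_in, sp_in, sp_out) {
  pmax(1L, as.integer(round(dm_in * sp_in / sp_out)))
}

resample_one <- function(a, sp_in, sp_out, nearest = FALSE) {
  dm_in <- dim(a); dm_out <- resample_grid(dm_in, sp_in, sp_out)
  ## voxel i sits at world coordinate (i - 1) * spacing
  coords <- lapply(1:3, function(ax)
    (seq_len(dm_out[ax]) - 1) * sp_out[ax] / sp_in[ax] + 1)
  xi <- rep(coords[[1]], times = dm_out[2] * dm_out[3])
  yi <- rep(rep(coords[[2]], each = dm_out[1]), times = dm_out[3])
  zi <- rep(coords[[3]], each = dm_out[1] * dm_out[2])
  if (nearest) {
    dm <- dim(a)
    idx <- cbind(pmin(pmax(round(xi), 1), dm[1]),
                 pmin(pmax(round(yi), 1), dm[2]),
                 pmin(pmax(round(zi), 1), dm[3]))
    array(a[idx], dm_out)
  } else {
    array(trilinear_at(a, xi, yi, zi), dm_out)
  }
}

#' Resample a volume series and masks to a target spacing
#'
#' Intensities are interpolated trilinearly; masks with nearest-neighbour
#' interpolation. The default target (0.8 x 0.8 mm in plane, 2 mm slices)
#' harmonizes heterogeneous acquisition protocols.
#'
#' @param series A `volume_series` (list with `volumes`, `spacing`, and
#'   optionally `breast_mask`, `tumor_mask`).
#' @param target_spacing Output spacing (mm), default `c(0.8, 0.8, 2.0)`.
#' @return The series with all volumes/masks on the target grid and
#'   `spacing` set to `target_spacing`.
#' @export
resample_series <- function(series, target_spacing = c(0.8, 0.8, 2.0)) {
  if (any(target_spacing <= 0)) stopf("target spacing must be positive")
  sp <- series$spacing
  series$volumes <- lapply(series$volumes, resample_one, sp_in = sp,
                           sp_out = target_spacing)
  for (mk in c("breast_mask", "tumor_mask", "stroma_mask"))
    if (!is.null(series[[mk]]))
      series[[mk]] <- resample_one(series[[mk]] * 1, sp, target_spacing,
                                   nearest = TRUE) > 0.5
  if (!is.null(series$seed_point))
    series$seed_point <- pmax(1L, as.integer(round(
      (series$seed_point - 1) * sp / target_spacing) + 1L))
  series$spacing <- target_spacing
  series
}

## ---- normalization and phases --------------------------------------------

#' Normalize a volume by the mean parenchymal intensity
#'
#' Divides every voxel by the mean intensity over the parenchymal mask, so
#' the parenchyma has mean 1 and intensities are scanner-scale free.
#'
#' @param volume 3D array.
#' @param parenchyma_mask Logical mask of normal parenchyma (conventionally
#'   breast minus tumor minus stroma band; see [parenchyma_mask()]).
#' @return Normalized volume.
#' @export
normalize_volume <- function(volume, parenchyma_mask) {
  parenchyma_mask <- check_mask(parenchyma_mask, dim(volume), "parenchyma")
  if (!any(parenchyma_mask)) stopf("parenchyma mask is empty")
  mu <- mean(volume[parenchyma_mask])
  if (!is.finite(mu) || mu <= 0)
    stopf("parenchymal mean must be > 0 (got %g)", mu)
  volume / mu
}

#' Default parenchymal region: breast minus tumor and stroma band
#'
#' @param breast_mask,tumor_mask Logical masks.
#' @param stroma_mask Optional stroma-band mask, also excluded when given.
#' @return Logical parenchyma mask.
#' @export
parenchyma_mask <- function(breast_mask, tumor_mask, stroma_mask = NULL) {
  m <- breast_mask & !tumor_mask
  if (!is.null(stroma_mask)) m <- m & !stroma_mask
  m
}

#' Derive the subtraction phases S0 / S_I / S_L
#'
#' From a precontrast volume and k postcontrast volumes (3 <= k <= 6),
#' returns the precontrast volume S0, the intermediate subtraction
#' S_I = post[ceil(k/2)] - S0, and the last subtraction S_L = post[k] - S0.
#'
#' @param series A `volume_series` whose `volumes` list is S0 followed by the
#'   postcontrast volumes.
#' @return List of class `phase_set`: `S0`, `SI`, `SL` arrays plus `spacing`.
#' @export
derive_phases <- function(series) {
  vols <- series$volumes
  k <- length(vols) - 1L
  if (k < 3) stopf("need at least 3 postcontrast volumes (got %d)", k)
  if (k > 6) stopf("at most 6 postcontrast volumes supported (got %d)", k)
  mid <- ceiling(k / 2)
  structure(list(S0 = vols[[1]],
                 SI = vols[[mid + 1L]] - vols[[1]],
                 SL = vols[[k + 1L]] - vols[[1]],
                 intermediate_index = mid,
                 spacing = series$spacing),
            class = "phase_set")
}

## ---- spatial fuzzy c-means segmentation -----------------------------------

## 3x3 in-plane neighbourhood average of a 3D array (per slice).
neighborhood_mean_2d <- function(a) {
  s <- array(0, dim(a)); cnt <- array(0, dim(a))
  ones <- array(1, dim(a))
  for (dx in -1:1) for (dy in -1:1) {
    s <- s + shift_array(a, dx, dy, 0, fill = 0)
    cnt <- cnt + shift_array(ones, dx, dy, 0, fill = 0)
  }
  s / cnt
}

#' Seeded spatial fuzzy c-means tumor segmentation
#'
#' Two-class fuzzy c-means on the intensities inside the breast mask, with a
#' spatial membership regularizer: after each standard membership update, a
#' 3 x 3 in-plane neighbourhood average h of the membership is computed and
#' memberships are re-weighted as `u * h^spatial_weight` (renormalized over
#' classes). `spatial_weight = 0` reduces to plain FCM. The tumor class is
#' the class the seed voxel belongs to; the segmentation is the connected
#' component (6-connectivity) of the thresholded (> 0.5) tumor membership
#' that contains the seed.
#'
#' @param volume 3D array (a normalized subtraction phase works best).
#' @param breast_mask Logical breast mask.
#' @param seed_point Voxel index triple inside the breast.
#' @param c Number of classes (2).
#' @param m Fuzzifier (> 1), default 2.
#' @param spatial_weight Exponent of the spatial term, default 1.
#' @param tol Convergence tolerance on the max membership change.
#' @param max_iter Iteration cap; non-convergence returns the best iterate
#'   with a warning.
#' @return List of class `sfcm_fit`: `mask` (logical tumor mask),
#'   `membership` (tumor-class membership array), `centers`, `objective`
#'   (FCM cost trajectory, computed from the pre-regularization memberships),
#'   `iterations`, `converged`.
#' @export
segment_tumor_sfcm <- function(volume, breast_mask, seed_point, c = 2L,
                               m = 2, spatial_weight = 1, tol = 1e-4,
                               max_iter = 200L) {
  breast_mask <- check_mask(breast_mask, dim(volume), "breast")
  sp <- as.integer(seed_point)
  if (length(sp) != 3L || any(sp < 1) || any(sp > dim(volume)))
    stopf("seed_point must be a voxel index triple inside the volume")
  if (!breast_mask[sp[1], sp[2], sp[3]])
    stopf("seed point is outside the breast mask")
  x <- volume[breast_mask]
  n <- length(x)
  ## deterministic seeded init: the last center starts at the seed voxel's
  ## intensity (the tumor may be a small minority of the breast, so pure
  ## quantile inits can collapse onto the background mode)
  centers <- stats::quantile(x, probs = seq(0.1, 0.5, length.out = c),
                             names = FALSE)
  centers[c] <- volume[sp[1], sp[2], sp[3]]
  if (any(duplicated(centers)))
    centers <- centers + seq_len(c) * 1e-9 * (1 + abs(centers))
  u <- matrix(1 / c, n, c)
  expo <- 2 / (m - 1)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u_spatial <- u
  repeat {
    iter <- iter + 1L
    d2 <- outer(x, centers, function(a, b) (a - b)^2) + 1e-12
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    objective <- c(objective, sum(u_new^m * d2))
    u_spatial <- u_new
    if (spatial_weight > 0) {
      for (k in seq_len(c)) {
        memb <- array(0, dim(volume)); memb[breast_mask] <- u_new[, k]
        h <- neighborhood_mean_2d(memb)[breast_mask]
        u_spatial[, k] <- u_new[, k] * h^spatial_weight
      }
      u_spatial <- u_spatial / rowSums(u_spatial)
    }
    centers <- colSums(u_spatial^m * x) / colSums(u_spatial^m)
    if (max(abs(u_spatial - u)) < tol) { converged <- TRUE; break }
    u <- u_spatial
    if (iter >= max_iter) break
  }
  if (!converged)
    warnf("spatial FCM did not converge in %d iterations; returning best iterate",
          max_iter)
  memb_arr <- array(0, c(dim(volume), c))
  for (k in seq_len(c)) {
    tmp <- array(0, dim(volume)); tmp[breast_mask] <- u_spatial[, k]
    memb_arr[, , , k] <- tmp
  }
  seed_class <- which.max(memb_arr[sp[1], sp[2], sp[3], ])
  tumor_memb <- memb_arr[, , , seed_class, drop = TRUE]
  if (length(dim(volume)) == 3 && dim(volume)[3] == 1)
    tumor_memb <- array(tumor_memb, dim(volume))
  candidate <- tumor_memb > 0.5 & breast_mask
  mask <- connected_component(candidate, sp)
  structure(list(mask = mask, membership = tumor_memb, centers = centers,
                 objective = objective, iterations = iter,
                 converged = converged),
            class = "sfcm_fit")
}

## Connected component (6-connectivity) of `candidate` containing `seed`,
## grown by iterated binary propagation.
connected_component <- function(candidate, seed) {
  comp <- array(FALSE, dim(candidate))
  if (!candidate[seed[1], seed[2], seed[3]]) return(comp)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  offsets <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  repeat {
    grown <- comp
    for (i in seq_len(nrow(offsets)))
      grown <- grown | shift_array(comp, offsets[i,1], offsets[i,2],
                                   offsets[i,3], fill = FALSE)
    grown <- grown & candidate
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

## ---- peritumoral stroma band ----------------------------------------------

#' Peritumoral stroma band mask
#'
#' Per-slice 2D morphological dilation of the tumor by a Euclidean disk of
#' `width_px` pixels (default 25, i.e. 20 mm at 0.8 mm in-plane resolution),
#' minus the tumor, clipped to the breast. Dilation is 2D because the band
#' width is defined in in-plane units.
#'
#' @param tumor_mask,breast_mask Logical 3D masks on the resampled grid.
#' @param width_px Band width in pixels (default 25).
#' @return Logical stroma-band mask (disjoint from tumor, inside breast).
#' @export
stroma_band <- function(tumor_mask, breast_mask, width_px = 25) {
  tumor_mask <- check_mask(tumor_mask, dim(breast_mask), "tumor")
  breast_mask <- breast_mask != 0
  if (!any(tumor_mask)) stopf("tumor mask is empty")
  band <- array(FALSE, dim(tumor_mask))
  for (z in seq_len(dim(tumor_mask)[3])) {
    sl <- tumor_mask[, , z]
    if (!any(sl)) next
    ## EBImage::distmap: distance of foreground pixels to nearest background;
    ## on the complement it yields each pixel's distance to the tumor.
    d <- EBImage::distmap(1 - sl, metric = "euclidean")
    band[, , z] <- d > 0 & d <= width_px
  }
  band & breast_mask & !tumor_mask
}

#' Full preprocessing chain for one patient series
#'
#' Resample, segment the tumor on the chosen subtraction phase, build the
#' stroma band, normalize each acquired volume by its own parenchymal mean
#' (parenchyma = breast minus tumor minus band), and derive the subtraction
#' phases from the normalized volumes.
#'
#' @param series `volume_series` with `breast_mask` and `seed_point`.
#' @param target_spacing Resampling target (mm).
#' @param segment_on Phase used for segmentation: "SI" (default, strongest
#'   tumor contrast), "S0" or "SL".
#' @param band_width_px Stroma band width in pixels.
#' @param ... Passed to [segment_tumor_sfcm()].
#' @return List: `phases` (normalized `phase_set`), `tumor_mask`,
#'   `stroma_mask`, `breast_mask`, `spacing`, `sfcm` (segmentation fit).
#' @export
prep_patient <- function(series, target_spacing = c(0.8, 0.8, 2.0),
                         segment_on = c("SI", "S0", "SL"),
                         band_width_px = 25, ...) {
  segment_on <- match.arg(segment_on)
  series <- resample_series(series, target_spacing)
  phases_raw <- derive_phases(series)
  fit <- segment_tumor_sfcm(phases_raw[[segment_on]], series$breast_mask,
                            series$seed_point, ...)
  tumor <- fit$mask
  stroma <- stroma_band(tumor, series$breast_mask, band_width_px)
  par_mask <- parenchyma_mask(series$breast_mask, tumor, stroma)
  series$volumes <- lapply(series$volumes, normalize_volume, par_mask)
  phases <- derive_phases(series)
  list(phases = phases, tumor_mask = tumor, stroma_mask = stroma,
       breast_mask = series$breast_mask, spacing = series$spacing, sfcm = fit)
}
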