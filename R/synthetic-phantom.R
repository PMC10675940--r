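# Multi-phase DCE-MRI phantoms with known tumor/breast masks.
#
# The phantom is an ellipsoidal tumor inside an ellipsoidal breast on a
# regular grid.  Each tissue has a per-phase enhancement curve (precontrast
# plus k postcontrast values); intra-tissue texture is a smoothed Gaussian
# random field so texture features are non-degenerate, plus independent
# voxel noise.  Everything needed downstream is returned: the volume series,
# ground-truth masks, and a tumor seed voxel.

#' Configuration for a synthetic DCE-MRI phantom
#'
#' @param grid_shape Integer length-3 voxel grid (x, y, z).
#' @param spacing Voxel spacing in mm, default `c(0.8, 0.8, 2.0)`.
#' @param tumor_center_mm Tumor ellipsoid centre (mm, grid coordinates);
#'   default grid centre.
#' @param tumor_radii_mm Tumor ellipsoid semi-axes (mm).
#' @param breast_margin_vox Margin (voxels) between grid edge and the breast
#'   ellipsoid.
#' @param n_postcontrast Number of postcontrast volumes, in 3..6.
#' @param enhancement Named list of per-tissue enhancement curves, each of
#'   length `n_postcontrast + 1` (precontrast first). Defaults: tumor rises
#'   steeply to 2x the breast plateau; breast enhances mildly.
#' @param base_intensity Named `c(breast =, tumor =)` precontrast means; the
#'   default gives the tumor twice the background contrast once enhanced.
#' @param texture_amplitude SD of the smoothed random texture field, as a
#'   fraction of the tumor-background contrast.
#' @param texture_scale_vox Gaussian smoothing sigma (voxels) of the texture
#'   field.
#' @param noise_sd Independent voxel noise SD as a fraction of the
#'   tumor-background contrast (default 0.05 = 5%).
#' @param seed Integer seed.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 14L),
                           spacing = c(0.8, 0.8, 2.0),
                           tumor_center_mm = NULL,
                           tumor_radii_mm = c(6.5, 5.5, 5),
                           breast_margin_vox = 2L,
                           n_postcontrast = 4L,
                           enhancement = NULL,
                           base_intensity = c(breast = 50, tumor = 50),
                           texture_amplitude = 0.1,
                           texture_scale_vox = 1.5,
                           noise_sd = 0.05,
                           seed = 1L) {
  if (n_postcontrast < 3 || n_postcontrast > 6)
    stopf("n_postcontrast must be in [3, 6]")
  if (is.null(tumor_center_mm))
    tumor_center_mm <- (grid_shape - 1) / 2 * spacing
  if (is.null(enhancement)) {
    t_rel <- seq_len(n_postcontrast) / n_postcontrast
    enhancement <- list(
      tumor = c(1, 1 + 1.2 * pmin(1, 2 * t_rel)),  # fast wash-in, plateau 2.2
      breast = c(1, 1 + 0.1 * t_rel)               # mild parenchymal uptake
    )
  }
  for (nm in names(enhancement))
    if (length(enhancement[[nm]]) != n_postcontrast + 1)
      stopf("enhancement curve '%s' must have length n_postcontrast + 1", nm)
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = spacing,
              tumor_center_mm = tumor_center_mm,
              tumor_radii_mm = tumor_radii_mm,
              breast_margin_vox = as.integer(breast_margin_vox),
              n_postcontrast = as.integer(n_postcontrast),
              enhancement = enhancement, base_intensity = base_intensity,
              texture_amplitude = texture_amplitude,
              texture_scale_vox = texture_scale_vox,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

## Smoothed Gaussian random field: white noise convolved with a separable
## Gaussian kernel, rescaled to unit SD.
smooth_field <- function(dm, sigma_vox) {
  f <- array(stats::rnorm(prod(dm)), dm)
  if (sigma_vox > 0) {
    r <- max(1L, ceiling(2 * sigma_vox))
    k <- stats::dnorm(-r:r, sd = sigma_vox); k <- k / sum(k)
    conv_axis <- function(a, axis) {
      out <- array(0, dim(a))
      for (i in seq_along(k)) {
        off <- i - r - 1L
        d <- c(0L, 0L, 0L); d[axis] <- off
        out <- out + k[i] * shift_array(a, d[1], d[2], d[3], fill = 0)
      }
      out
    }
    for (ax in 1:3) f <- conv_axis(f, ax)
  }
  f / stats::sd(f)
}

ellipsoid_mask <- function(dm, spacing, center_mm, radii_mm) {
  x <- ((seq_len(dm[1]) - 1) * spacing[1] - center_mm[1]) / radii_mm[1]
  y <- ((seq_len(dm[2]) - 1) * spacing[2] - center_mm[2]) / radii_mm[2]
  z <- ((seq_len(dm[3]) - 1) * spacing[3] - center_mm[3]) / radii_mm[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Generate a multi-phase phantom with ground-truth masks
#'
#' @param config A [phantom_config()].
#' @return List of class `volume_series` plus ground truth: `volumes` (list
#'   `S0`, `post1..postk` of 3D arrays), `spacing`, `breast_mask`,
#'   `tumor_mask` (ground truth), `seed_point` (voxel index triple at the
#'   tumor centre), `config`.
#' @export
generate_phantom <- function(config) {
  set.seed(config$seed)
  dm <- config$grid_shape; sp <- config$spacing
  center_mm <- (dm - 1) / 2 * sp
  breast_radii <- (dm / 2 - config$breast_margin_vox) * sp
  breast <- ellipsoid_mask(dm, sp, center_mm, breast_radii)
  tumor <- ellipsoid_mask(dm, sp, config$tumor_center_mm,
                          config$tumor_radii_mm)
  if (any(tumor & !breast)) stopf("tumor does not fit inside the breast mask")
  if (!any(tumor)) stopf("tumor mask is empty; enlarge tumor_radii_mm")

  contrast <- config$base_intensity["tumor"] *
    (max(config$enhancement$tumor) - 1)
  if (contrast <= 0) contrast <- config$base_intensity["tumor"]
  ## one static texture field per tissue, shared across phases (tissue
  ## architecture does not change between acquisitions)
  tex_breast <- smooth_field(dm, config$texture_scale_vox) *
    config$texture_amplitude * contrast
  tex_tumor <- smooth_field(dm, config$texture_scale_vox) *
    config$texture_amplitude * contrast

  k <- config$n_postcontrast
  vols <- vector("list", k + 1)
  names(vols) <- c("S0", paste0("post", seq_len(k)))
  for (ph in seq_len(k + 1)) {
    v <- array(0, dm)
    v[breast] <- config$base_intensity["breast"] *
      config$enhancement$breast[ph] + tex_breast[breast]
    v[tumor] <- config$base_intensity["tumor"] *
      config$enhancement$tumor[ph] + tex_tumor[tumor]
    v <- v + array(stats::rnorm(prod(dm), 0, config$noise_sd * contrast), dm)
    v[!breast] <- 0
    vols[[ph]] <- v
  }
  seed_point <- round(config$tumor_center_mm / sp) + 1L
  structure(list(volumes = vols, spacing = sp, breast_mask = breast,
                 tumor_mask = tumor, seed_point = as.integer(seed_point),
                 config = config),
            class = "volume_series")
}
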