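# Gray-level texture matrices and their feature panels: GLCM (24), GLRLM
# (16), GLSZM (16), GLDM (14), NGTDM (5).  All matrices are built in 3D over
# the 26-neighborhood: pairwise/run/dependence statistics use the 13 unique
# direction vectors (symmetrically), zones use 26-connected components.
# Direction-dependent matrices are averaged over directions before feature
# computation.

log2p <- function(p) ifelse(p > 0, log2(p), 0)

## ---- GLCM -----------------------------------------------------------------

#' Gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence counts at the given voxel distance, averaged over
#' the 13 unique 3D directions and normalized to probabilities.
#'
#' @param droi A [discretize()]d ROI.
#' @param distance Neighbor distance in voxels (default 1).
#' @return Ng x Ng probability matrix.
#' @export
glcm_matrix <- function(droi, distance = 1L) {
  lv <- droi$levels; ng <- droi$ng
  dirs <- unique_directions_3d() * distance
  acc <- matrix(0, ng, ng)
  for (i in seq_len(nrow(dirs))) {
    sh <- shift_array(lv, dirs[i, 1], dirs[i, 2], dirs[i, 3])
    ok <- !is.na(lv) & !is.na(sh)
    if (!any(ok)) next
    counts <- tabulate((lv[ok] - 1L) * ng + sh[ok], nbins = ng * ng)
    m <- matrix(counts, ng, ng, byrow = TRUE)
    acc <- acc + m + t(m)     # symmetric
  }
  s <- sum(acc)
  if (s == 0) { acc[1, 1] <- 1; s <- 1 }  # single isolated voxel
  acc / s
}

#' GLCM features (24)
#'
#' The standard 24-feature co-occurrence panel, including IDMN
#' `sum p(i,j) / (1 + (i - j)^2 / Ng^2)`. Degenerate (single-level) ROIs
#' take analytic limits (e.g. correlation and MCC 1, IMC terms 0).
#'
#' @param droi A [discretize()]d ROI.
#' @param distance Neighbor distance (voxels).
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(droi, distance = 1L) {
  p <- glcm_matrix(droi, distance)
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  ## difference / sum marginals
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  hxy <- -sum(p * log2p(p))
  hx <- -sum(px * log2p(px)); hy <- -sum(py * log2p(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2p(pxy))
  hxy2 <- -sum(pxy * log2p(pxy))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y) else 1
  ## maximal correlation coefficient: sqrt of the 2nd eigenvalue of Q
  nz <- which(px > 0)
  mcc <- if (length(nz) < 2) 1 else {
    psub <- p[nz, nz, drop = FALSE]
    q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz))
      q[a, b] <- sum(psub[a, ] * psub[b, ] / (px[nz][a] * py[nz]))
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }
  c(autocorrelation = sum(i * j * p),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(p_diff * log2p(p_diff)),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    id = sum(p / (1 + abs(i - j))),
    idm = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    idn = sum(p / (1 + abs(i - j) / ng)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    joint_average = mu_x,
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    maximum_probability = max(p),
    mcc = mcc,
    sum_average = sum(k_sum * p_sum),
    sum_entropy = -sum(p_sum * log2p(p_sum)),
    sum_squares = sum((i - mu_x)^2 * p))
}

## ---- GLRLM ----------------------------------------------------------------

## Runs of equal level along one direction; returns counts per (level, length).
glrlm_one_direction <- function(lv, d, ng, max_len) {
  dm <- dim(lv)
  ## line start voxels: those whose predecessor along d is out of bounds
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  prev <- sweep(idx, 2L, d, `-`)
  is_start <- prev[, 1] < 1 | prev[, 1] > dm[1] |
              prev[, 2] < 1 | prev[, 2] > dm[2] |
              prev[, 3] < 1 | prev[, 3] > dm[3]
  starts <- idx[is_start, , drop = FALSE]
  n_lines <- nrow(starts)
  ## walk all lines in lockstep, collecting values column-per-step
  vals <- list()
  pos <- starts
  step <- 0L
  repeat {
    inb <- pos[, 1] >= 1 & pos[, 1] <= dm[1] & pos[, 2] >= 1 &
           pos[, 2] <= dm[2] & pos[, 3] >= 1 & pos[, 3] <= dm[3]
    if (!any(inb)) break
    v <- rep(NA_integer_, n_lines)
    v[inb] <- lv[pos[inb, , drop = FALSE]]
    vals[[step + 1L]] <- v
    pos <- sweep(pos, 2L, d, `+`)
    step <- step + 1L
  }
  ## serialize line-by-line with NA separators, then one rle pass
  vm <- do.call(cbind, vals)                 # lines x steps
  flat <- as.vector(t(cbind(vm, NA_integer_)))
  r <- rle(ifelse(is.na(flat), -1L, flat))
  keep <- r$values > 0
  lev <- r$values[keep]; len <- pmin(r$lengths[keep], max_len)
  counts <- tabulate((lev - 1L) * max_len + len, nbins = ng * max_len)
  matrix(counts, ng, max_len, byrow = TRUE)
}

#' Gray-level run-length matrix
#'
#' Run counts per (gray level, run length), averaged over the 13 unique 3D
#' directions. Out-of-mask voxels break runs.
#'
#' @param droi A [discretize()]d ROI.
#' @return Ng x max-run-length count matrix (direction-averaged).
#' @export
glrlm_matrix <- function(droi) {
  lv <- droi$levels; ng <- droi$ng
  max_len <- max(dim(lv)) * 2L  # diagonal runs cannot exceed this
  dirs <- unique_directions_3d()
  acc <- matrix(0, ng, max_len)
  for (k in seq_len(nrow(dirs)))
    acc <- acc + glrlm_one_direction(lv, dirs[k, ], ng, max_len)
  acc <- acc / nrow(dirs)
  acc[, seq_len(max(which(colSums(acc) > 0), 1)), drop = FALSE]
}

## Shared feature shapes for run-length-style matrices (rows = gray level,
## columns = size/length/dependence).
size_matrix_features <- function(mat, n_vox, prefix_small, prefix_large,
                                 size_name, normalizer = sum(mat)) {
  i <- row(mat); j <- col(mat)
  nr <- normalizer
  if (nr == 0) { mat[1, 1] <- 1; nr <- 1 }
  p <- mat / nr
  r_i <- rowSums(mat); r_j <- colSums(mat)
  lev <- seq_len(nrow(mat)); siz <- seq_len(ncol(mat))
  mu_i <- sum(row(p) * p); mu_j <- sum(col(p) * p)
  out <- c(
    sum(r_j / siz^2) / nr,                    # small emphasis
    sum(r_j * siz^2) / nr,                    # large emphasis
    sum(r_i^2) / nr,                          # gray-level non-uniformity
    sum(r_i^2) / nr^2,                        # GLN normalized
    sum(r_j^2) / nr,                          # size non-uniformity
    sum(r_j^2) / nr^2,                        # SN normalized
    nr / n_vox,                               # percentage
    sum((row(p) - mu_i)^2 * p),               # gray-level variance
    sum((col(p) - mu_j)^2 * p),               # size variance
    -sum(p * log2p(p)),                       # entropy
    sum(r_i / lev^2) / nr,                    # low gray-level emphasis
    sum(r_i * lev^2) / nr,                    # high gray-level emphasis
    sum(mat / (i^2 * j^2)) / nr,              # small + low
    sum(mat * i^2 / j^2) / nr,                # small + high
    sum(mat * j^2 / i^2) / nr,                # large + low
    sum(mat * i^2 * j^2) / nr                 # large + high
  )
  names(out) <- c(
    paste0(prefix_small, "_emphasis"), paste0(prefix_large, "_emphasis"),
    "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
    paste0(size_name, "_nonuniformity"),
    paste0(size_name, "_nonuniformity_normalized"),
    paste0(size_name, "_percentage"),
    "gray_level_variance", paste0(size_name, "_variance"),
    paste0(size_name, "_entropy"),
    "low_gray_level_emphasis", "high_gray_level_emphasis",
    paste0(prefix_small, "_low_gray_level_emphasis"),
    paste0(prefix_small, "_high_gray_level_emphasis"),
    paste0(prefix_large, "_low_gray_level_emphasis"),
    paste0(prefix_large, "_high_gray_level_emphasis"))
  out
}

#' GLRLM features (16)
#'
#' Standard run-length panel including long-run high gray-level emphasis
#' `sum R(i,l) i^2 l^2 / Nr`.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(droi) {
  mat <- glrlm_matrix(droi)
  size_matrix_features(mat, n_vox = sum(droi$mask),
                       prefix_small = "short_run",
                       prefix_large = "long_run", size_name = "run")
}

## ---- GLSZM ----------------------------------------------------------------

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level; the matrix counts
#' zones per (gray level, zone size).
#'
#' @param droi A [discretize()]d ROI.
#' @return Ng x max-zone-size count matrix.
#' @export
glszm_matrix <- function(droi) {
  lv <- droi$levels; ng <- droi$ng
  dm <- dim(lv)
  vox <- which(!is.na(lv))
  id_of <- integer(prod(dm)); id_of[vox] <- seq_along(vox)
  dirs <- unique_directions_3d()
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    sh <- shift_array(lv, dirs[k, 1], dirs[k, 2], dirs[k, 3])
    ## linear index of the voxel that moved here: p - d
    src <- which(!is.na(lv) & !is.na(sh) & lv == sh)
    if (!length(src)) next
    d <- dirs[k, ]
    src_idx <- arrayInd(src, dm)
    nb_idx <- sweep(src_idx, 2L, d, `-`)
    nb <- (nb_idx[, 3] - 1L) * dm[1] * dm[2] + (nb_idx[, 2] - 1L) * dm[1] +
      nb_idx[, 1]
    from <- c(from, id_of[src]); to <- c(to, id_of[nb])
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(vox) - igraph::vcount(g)))
    comp <- igraph::components(g)
    zone_level <- lv[vox][match(seq_len(comp$no), comp$membership)]
    zone_size <- comp$csize
  } else {  # no same-level adjacencies: every voxel is its own zone
    zone_level <- lv[vox]
    zone_size <- rep(1L, length(vox))
  }
  max_size <- max(zone_size)
  counts <- tabulate((zone_level - 1L) * max_size + zone_size,
                     nbins = ng * max_size)
  matrix(counts, ng, max_size, byrow = TRUE)
}

#' GLSZM features (16)
#'
#' Standard size-zone panel including gray-level non-uniformity.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(droi) {
  mat <- glszm_matrix(droi)
  size_matrix_features(mat, n_vox = sum(droi$mask),
                       prefix_small = "small_area",
                       prefix_large = "large_area", size_name = "zone")
}

## ---- GLDM -----------------------------------------------------------------

#' Gray-level dependence matrix
#'
#' For each in-mask voxel, the dependence size is 1 (the voxel itself) plus
#' the number of 26-neighbors within `distance` whose gray level differs by
#' at most `alpha`. The matrix counts voxels per (gray level, dependence
#' size).
#'
#' @param droi A [discretize()]d ROI.
#' @param alpha Gray-level difference tolerance (default 0).
#' @param distance Neighborhood Chebyshev radius (default 1).
#' @return Ng x max-dependence-size count matrix.
#' @export
gldm_matrix <- function(droi, alpha = 0, distance = 1L) {
  lv <- droi$levels; ng <- droi$ng
  dep <- array(0L, dim(lv))
  offs <- all_directions_3d() * distance
  for (k in seq_len(nrow(offs))) {
    sh <- shift_array(lv, offs[k, 1], offs[k, 2], offs[k, 3])
    dep <- dep + (!is.na(lv) & !is.na(sh) & abs(lv - sh) <= alpha)
  }
  size <- dep[!is.na(lv)] + 1L
  level <- lv[!is.na(lv)]
  max_size <- max(size)
  counts <- tabulate((level - 1L) * max_size + size, nbins = ng * max_size)
  matrix(counts, ng, max_size, byrow = TRUE)
}

#' GLDM features (14)
#'
#' Dependence panel: the 16 run-length-style shapes minus the two normalized
#' non-uniformity duplicates that the 14-feature convention omits
#' (gray-level non-uniformity normalized and dependence percentage, which is
#' identically 1 since every voxel contributes).
#'
#' @param droi A [discretize()]d ROI.
#' @param alpha Gray-level difference tolerance.
#' @param distance Neighborhood radius.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(droi, alpha = 0, distance = 1L) {
  mat <- gldm_matrix(droi, alpha, distance)
  full <- size_matrix_features(mat, n_vox = sum(droi$mask),
                               prefix_small = "small_dependence",
                               prefix_large = "large_dependence",
                               size_name = "dependence")
  full[!names(full) %in% c("gray_level_nonuniformity_normalized",
                           "dependence_percentage")]
}

## ---- NGTDM ----------------------------------------------------------------

#' Neighborhood gray-tone difference matrix components
#'
#' For each gray level i: `n_i` (voxel count), `p_i = n_i / N`, and
#' `s_i = sum |i - A_i|` where `A_i` is the mean level of the in-mask
#' 26-neighbors of each level-i voxel (voxels with no in-mask neighbor are
#' excluded).
#'
#' @param droi A [discretize()]d ROI.
#' @param distance Neighborhood Chebyshev radius (default 1).
#' @return data.frame: level, n, p, s.
#' @export
ngtdm_matrix <- function(droi, distance = 1L) {
  lv <- droi$levels; ng <- droi$ng
  s_sum <- array(0, dim(lv)); s_cnt <- array(0L, dim(lv))
  offs <- all_directions_3d() * distance
  for (k in seq_len(nrow(offs))) {
    sh <- shift_array(lv, offs[k, 1], offs[k, 2], offs[k, 3])
    ok <- !is.na(sh)
    s_sum[ok] <- s_sum[ok] + sh[ok]
    s_cnt <- s_cnt + ok
  }
  use <- !is.na(lv) & s_cnt > 0
  avg <- s_sum[use] / s_cnt[use]
  level <- lv[use]
  dev <- abs(level - avg)
  n_i <- tabulate(level, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(dev[level == i]), numeric(1))
  data.frame(level = seq_len(ng), n = n_i, p = n_i / sum(n_i), s = s_i)
}

#' NGTDM features (5)
#'
#' Coarseness, contrast, busyness, complexity, and strength.
#'
#' @param droi A [discretize()]d ROI.
#' @param distance Neighborhood radius.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(droi, distance = 1L) {
  m <- ngtdm_matrix(droi, distance)
  nz <- m[m$p > 0, ]
  n_vox <- sum(m$n)
  ngp <- nrow(nz)
  coars_den <- sum(nz$p * nz$s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(nz$p, nz$p) * outer(nz$level, nz$level, `-`)^2) /
      (ngp * (ngp - 1)) * sum(nz$s) / n_vox
  } else 0
  busy_den <- sum(abs(outer(nz$level * nz$p, nz$level * nz$p, `-`)))
  busyness <- if (busy_den > 0) sum(nz$p * nz$s) / busy_den else 0
  complexity <- if (ngp > 1) {
    pi_ <- nz$p; si_ <- nz$s; li <- nz$level
    sum(abs(outer(li, li, `-`)) *
          (outer(pi_ * si_, pi_ * si_, `+`) / outer(pi_, pi_, `+`))) / n_vox
  } else 0
  strength <- if (sum(nz$s) > 0 && ngp > 1) {
    sum(outer(nz$p, nz$p, `+`) * outer(nz$level, nz$level, `-`)^2) / sum(nz$s)
  } else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
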