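# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## The ten cell populations scored by the marker-set estimator: eight immune
## lineages plus two stromal populations.
CELL_TYPES <- c(
  "T cells", "CD8 T cells", "Cytotoxic lymphocytes", "NK cells",
  "B lineage", "Monocytic lineage", "Myeloid dendritic cells",
  "Neutrophils", "Endothelial cells", "Fibroblasts"
)

#' Names of the ten scored cell populations
#'
#' Eight immune populations (CD3+ T cells, CD8+ T cells, cytotoxic
#' lymphocytes, NK cells, B lineage, monocytic lineage, myeloid dendritic
#' cells, neutrophils) and two stromal populations (endothelial cells,
#' fibroblasts).
#'
#' @return Character vector of length 10.
#' @export
cell_types <- function() CELL_TYPES

## 13 unique displacement vectors covering the 26-neighborhood up to sign.
## Ordered lexicographically on (dz, dy, dx) with the first nonzero positive.
unique_directions_3d <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- apply(d, 1L, function(v) {
    nz <- v[v != 0]
    nz[length(nz)] > 0  # canonical sign: last nonzero (slowest axis) positive
  })
  as.matrix(d[keep, , drop = FALSE])
}

all_directions_3d <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), , drop = FALSE])
}

## Shift a 3D array by (dx, dy, dz), padding with `fill`.  shift_array(a, d)
## at voxel p equals a at p - d (i.e. contents move in the +d direction).
shift_array <- function(a, dx, dy, dz, fill = NA_real_) {
  dm <- dim(a)
  out <- array(fill, dm)
  lo <- pmax(1, 1 - c(dx, dy, dz))
  hi <- pmin(dm, dm - c(dx, dy, dz))
  if (any(lo > hi)) return(out)
  src_x <- lo[1]:hi[1]; src_y <- lo[2]:hi[2]; src_z <- lo[3]:hi[3]
  out[src_x + dx, src_y + dy, src_z + dz] <- a[src_x, src_y, src_z]
  out
}

## Population variance (divide by n), the convention used by the texture and
## network heterogeneity formulas.
pop_var <- function(x) mean((x - mean(x))^2)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Validate a 3D logical/0-1 mask against a reference dim.
check_mask <- function(mask, dm, what = "mask") {
  if (!identical(dim(mask), dm))
    stopf("%s dimensions %s do not match volume dimensions %s",
          what, paste(dim(mask), collapse = "x"), paste(dm, collapse = "x"))
  mask <- mask != 0
  mask
}
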