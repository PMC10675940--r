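# The radiomic feature engine: discretization, first-order statistics,
# shape, the five texture families (against brute-force enumeration
# oracles), and the 572-feature orchestration.

test_that("discretization bins equal-width and flags constant ROIs", {
  vol <- array(seq(0, 1, length.out = 64), c(4, 4, 4))
  msk <- array(TRUE, c(4, 4, 4))
  dr <- discretize(vol, msk, n_bins = 32)
  expect_true(all(dr$levels %in% 1:32))
  ## uniform ramp -> every level hit twice (64 voxels / 32 bins)
  expect_true(all(tabulate(dr$levels, 32) == 2))

  two <- discretize(array(c(0, 5), c(2, 1, 1)), array(TRUE, c(2, 1, 1)),
                    n_bins = 2)
  expect_equal(sort(unique(as.vector(two$levels))), c(1L, 2L))

  expect_warning(cst <- discretize(array(3, c(2, 2, 1)),
                                   array(TRUE, c(2, 2, 1))), "constant ROI")
  expect_true(cst$degenerate)
  expect_true(all(cst$levels == 1))
  expect_error(discretize(vol, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("first-order features match direct computation", {
  vol <- array(1:100, c(10, 10, 1))
  msk <- array(TRUE, c(10, 10, 1))
  fo <- first_order(discretize(vol, msk, spacing = c(1, 1, 1)))
  expect_length(fo, 18)
  expect_equal(unname(fo["median"]), 50.5)
  expect_equal(unname(fo["iqr"]), 49.5)
  expect_equal(unname(fo["mean"]), 50.5)
  expect_equal(unname(fo["range"]), 99)
  expect_equal(unname(fo["energy"]), sum((1:100)^2))
  expect_equal(unname(fo["skewness"]), 0, tolerance = 1e-12)

  cst <- suppressWarnings(discretize(array(5, c(10, 1, 1)),
                                     array(TRUE, c(10, 1, 1))))
  fc <- first_order(cst)
  expect_equal(unname(fc[c("mean", "variance", "range")]), c(5, 0, 0))

  ## shift covariance: mean shifts, variance does not
  set.seed(1)
  v <- array(rnorm(60), c(5, 4, 3)); m <- array(TRUE, c(5, 4, 3))
  f1 <- first_order(discretize(v, m))
  f2 <- first_order(discretize(v + 10, m))
  expect_equal(unname(f2["mean"] - f1["mean"]), 10)
  expect_equal(unname(f2["variance"]), unname(f1["variance"]))
  ## voxel-order invariance
  vp <- array(sample(as.vector(v)), dim(v))
  f3 <- first_order(discretize(vp, m))
  expect_equal(unname(f3["variance"]), unname(f1["variance"]))
})

test_that("texture matrices agree with brute-force enumeration", {
  for (s in 1:12) {
    dr <- random_droi(seed = 1000 + s)
    expect_equal(glcm_matrix(dr), oracle_glcm(dr$levels, dr$ng),
                 tolerance = 1e-12, info = paste("glcm seed", s))
    expect_equal(glrlm_matrix(dr), oracle_glrlm(dr$levels, dr$ng),
                 tolerance = 1e-12, info = paste("glrlm seed", s))
    expect_equal(glszm_matrix(dr), oracle_glszm(dr$levels, dr$ng),
                 tolerance = 1e-12, info = paste("glszm seed", s))
    expect_equal(gldm_matrix(dr), oracle_gldm(dr$levels, dr$ng),
                 tolerance = 1e-12, info = paste("gldm seed", s))
    expect_equal(as.matrix(ngtdm_matrix(dr)),
                 as.matrix(oracle_ngtdm(dr$levels, dr$ng)),
                 tolerance = 1e-12, info = paste("ngtdm seed", s))
  }
})

test_that("texture feature panels have the published family sizes", {
  dr <- random_droi(seed = 77)
  expect_length(glcm_features(dr), 24)
  expect_length(glrlm_features(dr), 16)
  expect_length(glszm_features(dr), 16)
  expect_length(gldm_features(dr), 14)
  expect_length(ngtdm_features(dr), 5)
})

test_that("texture features hit their closed forms on degenerate inputs", {
  cst <- suppressWarnings(discretize(array(4, c(3, 3, 2)),
                                     array(TRUE, c(3, 3, 2))))
  g <- glcm_features(cst)
  expect_equal(unname(g["idmn"]), 1)
  expect_equal(unname(g["contrast"]), 0)
  expect_equal(unname(g["joint_energy"]), 1)
  expect_true(unname(g["idmn"]) <= 1 && unname(g["idmn"]) > 0)
  expect_equal(unname(ngtdm_features(cst)["contrast"]), 0)

  ## single run the length of a line
  line <- structure(list(levels = array(2L, c(6, 1, 1)),
                         intensities = rep(2, 6),
                         mask = array(TRUE, c(6, 1, 1)),
                         spacing = c(1, 1, 1), ng = 4L, n_bins = 4L,
                         degenerate = FALSE), class = "droi")
  rl <- glrlm_matrix(line)
  ## the x-axis direction sees one run of length 6; other 12 directions see
  ## 6 runs of length 1
  expect_equal(rl[2, 6], 1 / 13)
  expect_equal(rl[2, 1], 12 * 6 / 13)
  lrhgle <- glrlm_features(line)["long_run_high_gray_level_emphasis"]
  nr <- (1 + 12 * 6) / 13
  expect_equal(unname(lrhgle), (4 * 36 * 1 / 13 + 4 * 1 * 72 / 13) / nr)

  ## alternating line: every run (in every direction) has length 1
  alt <- structure(list(levels = array(rep(c(1L, 2L), 4), c(8, 1, 1)),
                        intensities = rep(c(1, 2), 4),
                        mask = array(TRUE, c(8, 1, 1)),
                        spacing = c(1, 1, 1), ng = 2L, n_bins = 2L,
                        degenerate = FALSE), class = "droi")
  expect_equal(unname(glrlm_features(alt)["short_run_emphasis"]), 1)

  ## two same-level zones of sizes 3 and 5 (isolated by NA gaps)
  lv <- array(NA_integer_, c(11, 1, 1))
  lv[1:3] <- 1L; lv[5:9] <- 1L; lv[11] <- 2L
  zz <- structure(list(levels = lv, intensities = lv[!is.na(lv)],
                       mask = !is.na(lv), spacing = c(1, 1, 1),
                       ng = 2L, n_bins = 2L, degenerate = FALSE),
                  class = "droi")
  zm <- glszm_matrix(zz)
  expect_equal(zm[1, 3], 1)
  expect_equal(zm[1, 5], 1)
  expect_equal(zm[2, 1], 1)

  ## isolated bright voxel has dependence size 1 (no dependent neighbors)
  dv <- array(1L, c(3, 3, 1)); dv[2, 2, 1] <- 2L
  dd <- structure(list(levels = dv, intensities = as.vector(dv),
                       mask = array(TRUE, c(3, 3, 1)), spacing = c(1, 1, 1),
                       ng = 2L, n_bins = 2L, degenerate = FALSE),
                  class = "droi")
  dm <- gldm_matrix(dd)
  expect_equal(dm[2, 1], 1)   # the bright voxel, alone at size 1
  expect_equal(sum(dm), 9)
})

test_that("direction-averaged texture features are rotation invariant in plane", {
  set.seed(41)
  lv <- array(sample.int(4, 5 * 5 * 2, TRUE), c(5, 5, 2))
  mk <- array(TRUE, c(5, 5, 2))
  mk_droi <- function(lv) structure(
    list(levels = lv, intensities = lv[mk], mask = mk, spacing = c(1, 1, 1),
         ng = 4L, n_bins = 4L, degenerate = FALSE), class = "droi")
  rot <- array(NA_integer_, dim(lv))
  for (z in 1:2) rot[, , z] <- t(lv[5:1, , z])  # 90-degree in-plane rotation
  f1 <- glcm_features(mk_droi(lv)); f2 <- glcm_features(mk_droi(rot))
  expect_equal(f1, f2, tolerance = 1e-10)
  r1 <- glrlm_features(mk_droi(lv)); r2 <- glrlm_features(mk_droi(rot))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("IDMN lies in (0, 1] and orders heterogeneity", {
  set.seed(55)
  for (s in 1:5) {
    dr <- random_droi(seed = 300 + s)
    v <- glcm_features(dr)["idmn"]
    expect_gt(unname(v), 0)
    expect_lte(unname(v), 1)
  }
  ## smooth ROI (gentle bands along x, constant in y/z) scores higher IDMN
  ## than a noisy one
  smooth_lv <- array(rep(rep(1:4, each = 2), times = 16), c(8, 8, 2))
  rough_lv <- array(sample.int(4, 128, TRUE), c(8, 8, 2))
  mk <- array(TRUE, c(8, 8, 2))
  as_droi <- function(lv) structure(
    list(levels = lv, intensities = lv[mk], mask = mk, spacing = c(1, 1, 1),
         ng = 4L, n_bins = 4L, degenerate = FALSE), class = "droi")
  expect_gt(unname(glcm_features(as_droi(smooth_lv))["idmn"]),
            unname(glcm_features(as_droi(rough_lv))["idmn"]))
})

test_that("NGTDM coarseness falls as checkerboard frequency rises", {
  mk <- array(TRUE, c(8, 8, 2))
  as_droi <- function(lv) structure(
    list(levels = lv, intensities = lv[mk], mask = mk, spacing = c(1, 1, 1),
         ng = 2L, n_bins = 2L, degenerate = FALSE), class = "droi")
  coarse <- array(1L + (((row(matrix(0, 8, 8)) - 1) %/% 4 +
                           (col(matrix(0, 8, 8)) - 1) %/% 4) %% 2), c(8, 8, 2))
  fine <- array(1L + ((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2),
                c(8, 8, 2))
  expect_gt(unname(ngtdm_features(as_droi(coarse))["coarseness"]),
            unname(ngtdm_features(as_droi(fine))["coarseness"]))
})

test_that("shape features match analytic solids", {
  r <- 12
  dm <- c(2 * r + 5, 2 * r + 5, 2 * r + 5)
  cc <- (dm + 1) / 2
  g <- expand.grid(x = 1:dm[1], y = 1:dm[2], z = 1:dm[3])
  ball <- array((g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2 <= r^2, dm)
  sh <- shape3d(ball, c(1, 1, 1))
  expect_length(sh, 14)
  expect_gt(unname(sh["sphericity"]), 0.95)
  expect_lt(unname(sh["sphericity"]), 1.05)
  expect_gt(unname(sh["flatness"]), 0.97)
  expect_lte(unname(sh["flatness"]), 1)
  expect_equal(unname(sh["max_3d_diameter"]), 2 * r, tolerance = 0.05)
  expect_equal(unname(sh["mesh_volume"]), 4 / 3 * pi * r^3, tolerance = 0.05)

  rod <- array(FALSE, c(5, 5, 9)); rod[3, 3, 3:7] <- TRUE
  shr <- shape3d(rod, c(1, 1, 1))
  expect_lt(unname(shr["flatness"]), 0.4)

  ## doubling the spacing scales volume by 8, sphericity unchanged
  sh2 <- shape3d(ball, c(2, 2, 2))
  expect_equal(unname(sh2["mesh_volume"] / sh["mesh_volume"]), 8)
  expect_equal(unname(sh2["sphericity"]), unname(sh["sphericity"]),
               tolerance = 1e-10)
})

test_that("extract_all produces the full named 572-feature layout", {
  ph <- small_phantom(seed = 10)
  pr <- prep_patient(ph)
  fv <- extract_all(pr$phases, pr$tumor_mask, pr$stroma_mask)
  expect_length(fv, 572)
  expect_true(all(is.finite(fv)))
  expect_equal(sum(grepl("^tumor_shape_", names(fv))), 14)
  for (region in c("tumor", "stroma")) for (phase in c("S0", "SI", "SL"))
    expect_equal(sum(grepl(paste0("^", region, "_", phase, "_"), names(fv))),
                 93)
  counts <- feature_family_counts()
  expect_equal(unname(counts[c("firstorder", "shape", "glcm", "glrlm",
                               "glszm", "gldm", "ngtdm")]),
               c(18L, 14L, 24L, 16L, 16L, 14L, 5L))
  for (fam in c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"))
    expect_equal(sum(grepl(paste0("^tumor_S0_", fam, "_"), names(fv))),
                 unname(counts[fam]))

  ## swapping the masks permutes region blocks but shape follows the
  ## tumor-mask argument
  fv_sw <- extract_all(pr$phases, pr$stroma_mask, pr$tumor_mask)
  expect_equal(unname(fv_sw["stroma_S0_firstorder_mean"]),
               unname(fv["tumor_S0_firstorder_mean"]))
  expect_false(isTRUE(all.equal(unname(fv_sw["tumor_shape_mesh_volume"]),
                                unname(fv["tumor_shape_mesh_volume"]))))
})
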