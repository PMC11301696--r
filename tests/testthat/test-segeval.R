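mask3d <- function(dims, idx) {
  m <- array(FALSE, dims); m[idx] <- TRUE; m
}

test_that("overlap metrics reproduce hand-computed values", {
  dims <- c(10, 10, 1)
  a <- mask3d(dims, 1:8)
  expect_equal(unlist(overlap_metrics(a, a)),
               c(dsc = 1, tpr = 1, precision = 1, mcc = 1, vs = 1))
  # TP=8, FP=2, FN=1, TN=89 -> MCC = 710/sqrt(737100)
  a2 <- mask3d(dims, 1:9)            # 9 reference voxels
  b2 <- mask3d(dims, c(1:8, 10, 11)) # 8 overlap, 2 extra
  m <- overlap_metrics(a2, b2, mcc_full_volume = TRUE)
  expect_equal(m$mcc, 710 / sqrt(737100), tolerance = 1e-9)
  # |a|=8, |b|=10, overlap 6 -> DSC = 12/18, VS = 1 - 1/9
  a3 <- mask3d(dims, 1:8)
  b3 <- mask3d(dims, c(3:8, 20:23))
  m3 <- overlap_metrics(a3, b3)
  expect_equal(m3$dsc, 12 / 18, tolerance = 1e-9)
  expect_equal(m3$vs, 1 - 1 / 9, tolerance = 1e-9)
  # symmetry for DSC/MCC/VS, and TPR(a,b) = precision(b,a)
  mf <- overlap_metrics(b3, a3)
  expect_equal(mf$dsc, m3$dsc)
  expect_equal(mf$vs, m3$vs)
  expect_equal(mf$precision, m3$tpr)
  expect_equal(mf$tpr, m3$precision)
  expect_error(overlap_metrics(mask3d(dims, c()), mask3d(dims, c())),
               "empty")
})

test_that("STAPLE recovers unanimous and majority truths", {
  dims <- c(2, 2, 1)
  m <- mask3d(dims, c(1, 2))
  st <- staple(list(m, m, m))
  expect_identical(st$consensus, m)
  expect_true(all(st$sensitivity > 0.999) && all(st$specificity > 0.999))
  # 2 identical raters + 1 complement -> consensus equals the majority mask
  st2 <- staple(list(m, m, !m))
  expect_identical(st2$consensus, m)
  expect_true(all(st2$probability >= 0 & st2$probability <= 1))
  # invariance under rater reordering
  st3 <- staple(list(!m, m, m))
  expect_identical(st3$consensus, st2$consensus)
  expect_equal(sort(st3$sensitivity), sort(st2$sensitivity),
               tolerance = 1e-12)
  # posterior is monotone in the number of agreeing raters
  dims2 <- c(4, 4, 2)
  set.seed(21)
  base <- array(stats::runif(32) < 0.4, dims2)
  raters <- lapply(1:5, function(k) {
    flip <- stats::runif(32) < 0.15
    xor(base, array(flip, dims2))
  })
  st4 <- staple(raters)
  votes <- Reduce(`+`, lapply(raters, function(r) array(as.numeric(r), dims2)))
  for (v in 0:4) {
    lo <- st4$probability[votes == v]
    hi <- st4$probability[votes == v + 1]
    if (length(lo) && length(hi)) expect_gt(min(hi), max(lo) - 1e-9)
  }
  expect_error(staple(list(m)), "2")
})

test_that("shape features of a digitized sphere match analytic values", {
  grid <- voxel_grid(40, 40, 40, 1.65, 1.65, 1.65)
  m <- ball_mask(grid, c(0, 0, 0), 30)
  f <- shape_features(m, grid)
  expect_lt(abs(f$volume_ml - 14.137) / 14.137, 0.03)
  expect_lt(abs(f$surface_area_cm2 - 28.274) / 28.274, 0.05)
  for (ax in c(f$major_axis_mm, f$minor_axis_mm, f$least_axis_mm))
    expect_lt(abs(ax - 30) / 30, 0.05)
  expect_true(f$major_axis_mm >= f$minor_axis_mm)
  expect_true(f$minor_axis_mm >= f$least_axis_mm)
  # doubling the grid spacing doubles axes, x4 area, x8 volume
  grid2 <- voxel_grid(40, 40, 40, 3.3, 3.3, 3.3)
  f2 <- shape_features(m, grid2)
  expect_equal(f2$volume_ml, 8 * f$volume_ml, tolerance = 1e-9)
  expect_equal(f2$surface_area_cm2, 4 * f$surface_area_cm2,
               tolerance = 1e-9)
  expect_equal(f2$major_axis_mm, 2 * f$major_axis_mm, tolerance = 1e-9)
  # axis ordering holds for an anisotropic shape too
  me <- array(FALSE, c(40, 40, 40)); me[10:30, 15:25, 18:22] <- TRUE
  fe <- shape_features(me, grid)
  expect_true(fe$major_axis_mm >= fe$minor_axis_mm &&
                fe$minor_axis_mm >= fe$least_axis_mm)
  single <- array(FALSE, c(40, 40, 40)); single[5, 5, 5] <- TRUE
  expect_warning(shape_features(single, grid), "single")
})

test_that("Lin's concordance correlation: worked examples and inequality", {
  expect_equal(ccc(1:10, 1:10), 1)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(ccc(x, -x), -1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  # |CCC| <= |Pearson r| on random pairs
  set.seed(8)
  for (k in 1:20) {
    a <- stats::rnorm(15); b <- 0.5 * a + stats::rnorm(15)
    expect_lte(abs(ccc(a, b)), abs(stats::cor(a, b)) + 1e-12)
  }
  expect_error(ccc(rep(1, 4), rep(1, 4)), "undefined")
})
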