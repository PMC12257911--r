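mk <- function(m, sp = c(1, 1, 1)) binary_mask(m, sp)

test_that("vDSC counts voxels and handles empties per convention", {
  g <- array(FALSE, c(4, 4, 2)); g[1:2, 1, 1] <- TRUE
  p <- array(FALSE, c(4, 4, 2)); p[2:3, 1, 1] <- TRUE
  expect_equal(vdsc(mk(g), mk(p)), 0.5)  # overlap 1 of 2+2
  expect_equal(vdsc(mk(g), mk(g)), 1)
  empty <- array(FALSE, c(4, 4, 2))
  expect_equal(vdsc(mk(g), mk(empty)), 0)
  expect_error(vdsc(mk(empty), mk(empty)), "both masks are empty")
})

test_that("surface extraction counts faces and areas", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  s <- extract_surface(mk(one))
  expect_equal(nrow(s$points), 6)
  expect_equal(sum(s$areas), 6)
  bar <- array(FALSE, c(4, 3, 3)); bar[2:3, 2, 2] <- TRUE
  expect_equal(nrow(extract_surface(mk(bar))$points), 10)
  block <- array(FALSE, c(5, 5, 5)); block[2:4, 2:4, 2:4] <- TRUE
  sb <- extract_surface(mk(block))
  expect_equal(nrow(sb$points), 54)  # 6 faces x 9, no interior faces
  # anisotropic areas: single voxel at (1,1,3) spacing
  sa <- extract_surface(mk(one, c(1, 1, 3)))
  expect_equal(sum(sa$areas), 2 * 3 + 2 * 3 + 2 * 1)
  expect_error(extract_surface(mk(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("hd95 on separated single voxels equals their gap", {
  g <- array(FALSE, c(8, 3, 3)); g[2, 2, 2] <- TRUE
  p <- array(FALSE, c(8, 3, 3)); p[7, 2, 2] <- TRUE
  expect_equal(hd95(mk(g), mk(p)), 5)
  expect_equal(hd95(mk(g), mk(g)), 0)
  expect_error(hd95(mk(g), mk(array(FALSE, c(8, 3, 3)))), "empty")
})

test_that("hd95 never exceeds the plain Hausdorff distance", {
  for (seed in 1:5) {
    g <- random_blob(c(8, 8, 4), seed = seed)
    p <- random_blob(c(8, 8, 4), seed = seed + 50)
    expect_lte(hd95(mk(g), mk(p)), hd95(mk(g), mk(p), probs = 1) + 1e-12)
  }
})

test_that("assd is bounded by a pure translation", {
  g <- array(FALSE, c(6, 6, 6)); g[2:4, 2:4, 2:4] <- TRUE
  p <- array(FALSE, c(6, 6, 6)); p[3:5, 2:4, 2:4] <- TRUE  # shift 1 mm in x
  expect_lte(assd(mk(g), mk(p)), 1)
  expect_equal(assd(mk(g), mk(g)), 0)
})

test_that("sdsc saturates at its limits", {
  g <- array(FALSE, c(10, 4, 4)); g[2, 2, 2] <- TRUE
  p <- array(FALSE, c(10, 4, 4)); p[9, 2, 2] <- TRUE
  expect_equal(sdsc(mk(g), mk(p), tol = 1), 0)    # farther apart than tol
  expect_equal(sdsc(mk(g), mk(p), tol = 100), 1)  # saturation
  expect_equal(sdsc(mk(g), mk(g)), 1)
  expect_error(sdsc(mk(g), mk(p), tol = 0), "positive")
})

test_that("surface metrics match brute-force oracles on random blobs", {
  for (seed in 1:8) {
    sp <- list(c(1, 1, 1), c(1, 1, 2))[[(seed %% 2) + 1]]
    g <- random_blob(c(7, 7, 5), seed = seed, radius = 2)
    p <- random_blob(c(7, 7, 5), seed = seed + 100, radius = 2)
    bf <- bf_surface_metrics(g, p, sp)
    expect_equal(hd95(mk(g, sp), mk(p, sp)), bf$hd95, tolerance = 1e-9)
    expect_equal(assd(mk(g, sp), mk(p, sp)), bf$assd, tolerance = 1e-9)
    expect_equal(sdsc(mk(g, sp), mk(p, sp)), bf$sdsc, tolerance = 1e-9)
    expect_equal(vdsc(mk(g, sp), mk(p, sp)), bf_vdsc(g, p),
                 tolerance = 1e-12)
    expect_equal(apl(mk(g, sp), mk(p, sp)), bf_apl(g, p, sp),
                 tolerance = 1e-12)
  }
})

test_that("apl follows the GT-referenced set difference", {
  g <- array(FALSE, c(6, 6, 1)); g[2:4, 2:4, 1] <- TRUE  # 3x3 square: 8 contour px
  expect_equal(apl(mk(g), mk(g)), 0)
  empty <- array(FALSE, c(6, 6, 1))
  expect_equal(apl(mk(g), mk(empty)), 8 * 1 / 10)  # full GT contour remains
  p <- array(FALSE, c(6, 6, 1)); p[3:5, 2:4, 1] <- TRUE  # shifted by one
  expect_equal(apl(mk(g), mk(p)), bf_apl(g, p, c(1, 1, 1)))
  expect_error(apl(mk(empty), mk(g)), "empty")
})

test_that("symmetry and asymmetry conventions hold", {
  g <- random_blob(c(8, 8, 4), seed = 11)
  p <- random_blob(c(8, 8, 4), seed = 222)
  expect_equal(vdsc(mk(g), mk(p)), vdsc(mk(p), mk(g)))
  expect_equal(sdsc(mk(g), mk(p)), sdsc(mk(p), mk(g)))
  expect_equal(hd95(mk(g), mk(p)), hd95(mk(p), mk(g)))
  expect_equal(assd(mk(g), mk(p)), assd(mk(p), mk(g)))
})

test_that("growing the prediction error degrades metrics monotonically", {
  g <- array(FALSE, c(10, 10, 6)); g[3:8, 3:8, 2:5] <- TRUE
  errs <- c(0, 1, 2, 3)
  vd <- sd_ <- as_ <- numeric(length(errs))
  for (i in seq_along(errs)) {
    p <- g
    if (errs[i] > 0) p[3:(2 + errs[i]), 3:8, 2:5] <- FALSE  # peel layers
    vd[i] <- vdsc(mk(g), mk(p))
    sd_[i] <- sdsc(mk(g), mk(p))
    as_[i] <- assd(mk(g), mk(p))
  }
  expect_true(all(diff(vd) <= 0))
  expect_true(all(diff(sd_) <= 0))
  expect_true(all(diff(as_) >= 0))
})

test_that("metric_report degrades gracefully with an empty prediction", {
  g <- array(FALSE, c(5, 5, 3)); g[2:4, 2:4, 2] <- TRUE
  p <- array(FALSE, c(5, 5, 3))
  r <- metric_report(mk(g), mk(p), organ = "bladder")
  expect_equal(r$vdsc, 0)
  expect_equal(r$sdsc, 0)
  expect_true(is.na(r$hd95) && is.na(r$assd))
  expect_gt(r$apl, 0)
  full <- metric_report(mk(g), mk(g))
  expect_equal(full$vdsc, 1)
  expect_equal(full$hd95, 0)
})
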