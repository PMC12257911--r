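test_that("phantom generation is deterministic per seed", {
  a <- generate_phantom(phantom_spec(seed = 5))
  b <- generate_phantom(phantom_spec(seed = 5))
  expect_identical(a$volume$labels, b$volume$labels)
  c_ <- generate_phantom(phantom_spec(seed = 6))
  expect_false(identical(a$volume$labels, c_$volume$labels))
})

test_that("phantom structures are disjoint, named, and sized to spec", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  vol <- ph$volume
  expect_setequal(unname(vol$label_names),
                  c("CTV_HR", "bladder", "rectum", "sigmoid", "small_bowel"))
  # exclusive labels: every voxel carries exactly one structure or none
  expect_true(all(vol$labels %in% 0:5))
  spec <- ph$spec
  vv <- voxel_volume(vol)
  for (i in seq_along(spec$organs)) {
    org <- spec$organs[[i]]
    got <- sum(vol$labels == i + 1) * vv
    target <- brachymetrics:::primitive_volume(org)
    expect_lt(abs(got - target) / target, 0.2)
  }
  # all organs exceed the 2 cm^3 needed for a meaningful D2cm3
  for (l in 2:5) expect_gt(sum(vol$labels == l) * vv, 2000)
})

test_that("abutting organs hug the target and distant ones keep away", {
  for (seed in c(1, 9, 33)) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    dmap <- euclidean_distance_map(extract_binary(ph$volume, 1L))
    mind <- function(org)
      min(dmap$dist[extract_binary(ph$volume, org)$mask])
    expect_lte(mind("bladder"), 6)
    expect_lte(mind("rectum"), 6)
    expect_gte(mind("sigmoid"), 8)
    expect_gte(mind("small_bowel"), 12)
    expect_gt(mind("small_bowel"), mind("rectum"))
  }
})

test_that("dwells line up inside the target along its axis", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  ctv <- ph$spec$ctv
  for (dw in ph$dwells) {
    expect_equal(dw$position[1:2], ctv$center[1:2])
    expect_lte(abs(dw$position[3] - ctv$center[3]), ctv$semi_axes[3])
  }
  expect_length(ph$dwells, ph$spec$n_dwells)
})

test_that("zero error fraction reproduces the ground truth exactly", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  ps <- perturb_spec(0, band = "near", mode = "erode", seed = 1)
  out <- perturb_prediction(ph$volume, "rectum", ps)
  expect_identical(out$prediction$labels, ph$volume$labels)
  expect_equal(out$n_flipped, 0)
  g <- extract_binary(ph$volume, "rectum")
  p <- extract_binary(out$prediction, "rectum")
  expect_equal(vdsc(g, p), 1)
})

test_that("perturbations flip the requested volume in the requested band", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  dmap <- euclidean_distance_map(extract_binary(ph$volume, 1L))
  n_org <- sum(ph$volume$labels == 3)  # rectum
  for (mode in c("erode", "dilate", "transfer")) {
    ps <- perturb_spec(0.05, band = "uniform", mode = mode, seed = 21)
    out <- perturb_prediction(ph$volume, "rectum", ps, dmap)
    expect_lte(abs(out$n_flipped - round(0.05 * n_org)), 1)
    # only the requested organ changed
    diff_idx <- which(out$prediction$labels != ph$volume$labels)
    expect_true(all(ph$volume$labels[diff_idx] %in% c(0L, 3L)))
    expect_true(all(out$prediction$labels[diff_idx] %in% c(0L, 3L)))
  }
  # erode removes only organ voxels
  ps <- perturb_spec(0.05, band = "near", mode = "erode", seed = 5)
  out <- perturb_prediction(ph$volume, "rectum", ps, dmap)
  changed <- which(out$prediction$labels != ph$volume$labels)
  expect_true(all(ph$volume$labels[changed] == 3L))
  expect_true(all(out$prediction$labels[changed] == 0L))
  # near-band errors really sit closer to the target than far-band ones
  ps_far <- perturb_spec(0.05, band = "far", mode = "erode", seed = 5)
  out_far <- perturb_prediction(ph$volume, "rectum", ps_far, dmap)
  expect_lt(out$mean_error_dist, out_far$mean_error_dist)
})

test_that("near and far errors of equal size split wDSC but not vDSC", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  dmap <- euclidean_distance_map(extract_binary(ph$volume, 1L))
  g <- extract_binary(ph$volume, "sigmoid")
  res <- lapply(c("near", "far"), function(band) {
    ps <- perturb_spec(0.06, band = band, mode = "erode", seed = 77)
    out <- perturb_prediction(ph$volume, "sigmoid", ps, dmap)
    p <- extract_binary(out$prediction, "sigmoid")
    list(v = vdsc(g, p), w = wdsc(g, p, dmap)$wdsc, n = out$n_flipped)
  })
  expect_equal(res[[1]]$n, res[[2]]$n)
  expect_equal(res[[1]]$v, res[[2]]$v)
  expect_lt(res[[1]]$w, res[[2]]$w)
})

test_that("an oversized error request fails with the achievable maximum", {
  # organ fills the grid except the target and 2 background voxels, so a
  # dilation needing more than 2 voxels cannot be placed
  lab <- array(2L, c(4, 4, 2))
  lab[1, 1, 1] <- 1L
  lab[4, 4, 1] <- 0L; lab[4, 4, 2] <- 0L
  gt <- labeled_volume(lab, c(1, 1, 1), c("1" = "CTV_HR", "2" = "organ"))
  ps <- perturb_spec(0.3, band = "near", mode = "dilate", seed = 1)
  expect_error(perturb_prediction(gt, 2L, ps), "achievable maximum")
})

test_that("phantom grids validate against their own perturbations", {
  ph <- generate_phantom(phantom_spec(seed = 10))
  ps <- perturb_spec(0.04, band = "uniform", mode = "transfer", seed = 2)
  out <- perturb_prediction(ph$volume, "bladder", ps)
  expect_true(validate_pair(ph$volume, out$prediction))
})
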