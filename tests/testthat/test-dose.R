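grid131 <- list(shape = c(21, 3, 3), spacing = c(1, 1, 1))

test_that("a single point source follows the inverse-square law", {
  dw <- source_dwell(c(0, 0, 0), 100)
  dose <- compute_dose(list(dw), grid131, r_clamp = 0.5)
  expect_equal(dose$dose[11, 1, 1], 100 / 10^2)  # 1 Gy at 10 mm
  expect_equal(dose$dose[6, 1, 1], 100 / 25)
  # clamp saturation at the source voxel
  expect_equal(dose$dose[1, 1, 1], 100 / 0.25)
  # monotone fall-off along the axis beyond the clamp
  expect_true(all(diff(dose$dose[, 1, 1]) < 0))
  expect_error(compute_dose(list(), grid131), "at least one")
  expect_error(source_dwell(c(0, 0, 0), -1), "positive")
})

test_that("dose superposes linearly over sources", {
  d1 <- compute_dose(list(source_dwell(c(0, 0, 0), 100)), grid131)
  d2 <- compute_dose(list(source_dwell(c(5, 0, 0), 40)), grid131)
  both <- compute_dose(list(source_dwell(c(0, 0, 0), 100),
                            source_dwell(c(5, 0, 0), 40)), grid131)
  expect_equal(both$dose, d1$dose + d2$dose, tolerance = 1e-12)
  twice <- compute_dose(list(source_dwell(c(0, 0, 0), 100),
                             source_dwell(c(0, 0, 0), 100)), grid131)
  expect_equal(twice$dose, 2 * d1$dose, tolerance = 1e-12)
})

test_that("cumulative DVH is a valid survival curve of dose", {
  shape <- c(10, 10, 4)
  set.seed(8)
  dose <- structure(list(dose = array(runif(prod(shape), 0, 10), shape),
                         spacing = c(1, 1, 1)), class = "dose_grid")
  organ <- binary_mask(random_blob(shape, seed = 3, radius = 3), c(1, 1, 1))
  dvh <- cumulative_dvh(dose, organ, n_bins = 40)
  expect_equal(dvh$volume_cm3[1], sum(organ$mask) / 1000)  # DVH(0) = volume
  expect_true(all(diff(dvh$volume_cm3) <= 0))
  # brute-force threshold counting at every bin edge
  od <- dose$dose[organ$mask]
  for (i in seq_len(nrow(dvh))) {
    expect_equal(dvh$volume_cm3[i], sum(od >= dvh$dose_gy[i]) / 1000)
  }
  # uniform dose: a step function at d
  du <- structure(list(dose = array(5, shape), spacing = c(1, 1, 1)),
                  class = "dose_grid")
  dvh2 <- cumulative_dvh(du, organ, n_bins = 10)
  expect_true(all(dvh2$volume_cm3 == sum(organ$mask) / 1000))
  expect_error(cumulative_dvh(dose, binary_mask(array(FALSE, shape),
                                                c(1, 1, 1))), "empty")
})

test_that("D2cm3 is the minimum dose of the hottest 2 cm^3", {
  # 4 voxels of 1 cm^3 each (10 x 10 x 10 mm)
  shape <- c(4, 1, 1)
  dose <- structure(list(dose = array(c(8, 6, 4, 2), shape),
                         spacing = c(10, 10, 10)), class = "dose_grid")
  organ <- binary_mask(array(TRUE, shape), c(10, 10, 10))
  expect_equal(d2cc(dose, organ), 6)  # hottest 2 cm^3 = {8, 6}
  # shrinking the organ to its hottest 2 cm^3 leaves the value unchanged
  hot <- binary_mask(array(c(TRUE, TRUE, FALSE, FALSE), shape),
                     c(10, 10, 10))
  expect_equal(d2cc(dose, hot), 6)
  # uniform dose on a 4 cm^3 organ
  du <- structure(list(dose = array(10, shape), spacing = c(10, 10, 10)),
                  class = "dose_grid")
  expect_equal(d2cc(du, organ), 10)
  # sub-2-cm^3 organ falls back to its minimum dose, with a warning
  small <- binary_mask(array(c(TRUE, FALSE, FALSE, FALSE), shape),
                       c(10, 10, 10))
  expect_warning(v <- d2cc(dose, small), "below")
  expect_equal(v, 8)
})

test_that("d2cc matches the accumulate-and-threshold oracle", {
  for (seed in 1:8) {
    shape <- c(8, 8, 4)
    set.seed(seed)
    dg <- structure(list(dose = array(rexp(prod(shape), 0.2), shape),
                         spacing = c(2, 2, 4)), class = "dose_grid")
    organ <- binary_mask(random_blob(shape, seed = seed + 7, radius = 3),
                         c(2, 2, 4))
    if (sum(organ$mask) * 16 < 2000) next
    expect_equal(d2cc(dg, organ),
                 bf_d2cc(dg$dose[organ$mask], 16), tolerance = 1e-12)
    # bounded by the organ dose range; shifts with a uniform offset
    od <- dg$dose[organ$mask]
    expect_gte(d2cc(dg, organ), min(od))
    expect_lte(d2cc(dg, organ), max(od))
    dg2 <- dg; dg2$dose <- dg$dose + 3
    expect_equal(d2cc(dg2, organ), d2cc(dg, organ) + 3, tolerance = 1e-12)
  }
})

test_that("d2cc agrees with the DVH crossing at 2 cm^3", {
  shape <- c(12, 12, 6)
  set.seed(5)
  dg <- structure(list(dose = array(rexp(prod(shape), 0.1), shape),
                       spacing = c(3, 3, 5)), class = "dose_grid")
  organ <- binary_mask(random_blob(shape, seed = 12, radius = 4), c(3, 3, 5))
  v <- d2cc(dg, organ)
  dvh <- cumulative_dvh(dg, organ, n_bins = 400)
  # at the D2cm3 dose the DVH still covers >= 2 cm^3; just above it doesn't
  vol_at <- dvh$volume_cm3[max(which(dvh$dose_gy <= v))]
  expect_gte(vol_at + 1e-9, 2)
  expect_lt(sum(dg$dose[organ$mask] > v) * voxel_volume(organ) / 1000, 2)
})

test_that("absolute D2cm3 difference follows its definition", {
  shape <- c(4, 1, 1)
  dose <- structure(list(dose = array(c(8, 6, 4, 2), shape),
                         spacing = c(10, 10, 10)), class = "dose_grid")
  ref <- binary_mask(array(TRUE, shape), c(10, 10, 10))
  expect_equal(abs_d2cc_diff(ref, ref, dose)$abs_diff, 0)
  # prediction missing the hottest voxel: D2cm3 drops from 6 to 4
  pred <- binary_mask(array(c(FALSE, TRUE, TRUE, TRUE), shape),
                      c(10, 10, 10))
  r <- abs_d2cc_diff(pred, ref, dose, organ = "rectum")
  expect_equal(r$d2cc_pred, 4)
  expect_equal(r$d2cc_ref, 6)
  expect_equal(r$abs_diff, 2)
  # symmetric under swapping prediction and reference
  expect_equal(abs_d2cc_diff(ref, pred, dose)$abs_diff, 2)
})
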