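test_that("distance transform matches simple geometric cases", {
  v <- array(FALSE, c(5, 5, 5))
  v[3, 3, 3] <- TRUE
  m <- structure_mask(v, c(2.5, 2.5, 2.5))
  d <- distance_from_mask(m)
  expect_equal(d$distances[3, 3, 3], 0)
  expect_equal(d$distances[4, 3, 3], 2.5)
  expect_equal(d$distances[1, 1, 3],
               sqrt((2 * 2.5)^2 + (2 * 2.5)^2))

  v <- array(FALSE, c(6, 6, 3))
  v[1, 1, 1] <- TRUE
  m <- structure_mask(v, c(1, 1, 1))
  d <- distance_from_mask(m)
  expect_equal(d$distances[4, 5, 1], 5)  # (3,4,0) triangle
  expect_error(distance_from_mask(structure_mask(array(FALSE, c(2, 2, 2)),
                                                 c(1, 1, 1))),
               "no structure")
})

test_that("distance transform equals all-pairs brute force, anisotropic included", {
  set.seed(99)
  for (rep in 1:12) {
    dm <- sample(3:14, 3, replace = TRUE)
    sp <- sample(c(1, 1.5, 2.5, 3), 3, replace = TRUE)
    m <- random_mask(dm, spacing = sp, p = stats::runif(1, 0.02, 0.4))
    d <- distance_from_mask(m)
    expect_equal(d$distances, brute_distance_field(m), tolerance = 1e-10)
  }
})

test_that("conformality index and R50 are isodose-to-PTV volume ratios", {
  g <- uniform_grid(0, dim = c(10, 10, 10), spacing = c(10, 10, 10))
  ptv <- full_mask(g)
  ptv$voxels[] <- FALSE
  ptv$voxels[1:100] <- TRUE                  # 100 voxels
  g$values[1:115] <- 60                      # 115 voxels at Rx
  expect_equal(conformality_index(g, ptv, 60), 1.15)
  g2 <- uniform_grid(0.6 * 60, dim = c(10, 10, 10), spacing = c(10, 10, 10))
  expect_equal(r50(g2, ptv, 60), 10)         # whole grid >= 50% Rx
  expect_equal(conformality_index(g2, ptv, 60), 0)
  expect_gte(r50(g, ptv, 60), conformality_index(g, ptv, 60))
})

test_that("d2cm takes the maximum dose strictly beyond the margin", {
  vals <- array(0, c(7, 1, 1))
  vals[, 1, 1] <- c(10, 20, 30, 40, 50, 60, 70) * 0.6  # % of 60 Gy
  g <- dose_grid(vals, c(10, 10, 10))
  pv <- array(FALSE, c(7, 1, 1)); pv[4, 1, 1] <- TRUE
  ptv <- structure_mask(pv, c(10, 10, 10))
  expect_equal(d2cm(g, ptv, 60), 70)

  u <- uniform_grid(0.48 * 60, dim = c(9, 9, 9), spacing = c(10, 10, 10))
  pu <- array(FALSE, c(9, 9, 9)); pu[5, 5, 5] <- TRUE
  expect_equal(d2cm(u, structure_mask(pu, c(10, 10, 10)), 60), 48)
  expect_error(d2cm(g, full_mask(g), 60), "grid too small")
})

test_that("d2cm is monotone in margin and shrinks when the PTV grows", {
  set.seed(31)
  g <- random_grid(c(12, 12, 12), spacing = c(4, 4, 4))
  pv <- array(FALSE, c(12, 12, 12)); pv[6:7, 6:7, 6:7] <- TRUE
  ptv <- structure_mask(pv, c(4, 4, 4))
  d_small <- d2cm(g, ptv, 60, margin_mm = 12)
  d_big <- d2cm(g, ptv, 60, margin_mm = 20)
  expect_gte(d_small, d_big)
  grown <- ptv
  grown$voxels[5:8, 5:8, 5:8] <- TRUE
  expect_lte(d2cm(g, grown, 60, margin_mm = 12), d_small)
})

test_that("island classification is inclusive at the threshold", {
  cw <- array(FALSE, c(20, 4, 4)); cw[1, , ] <- TRUE
  pv <- array(FALSE, c(20, 4, 4))
  sp <- c(5, 5, 5)
  pv[1, 2, 2] <- TRUE   # touching (distance 0)
  expect_false(classify_island(structure_mask(pv, sp),
                               structure_mask(cw, sp)))
  pv[] <- FALSE; pv[4, 2, 2] <- TRUE  # 15 mm
  expect_true(classify_island(structure_mask(pv, sp),
                              structure_mask(cw, sp)))
  pv[] <- FALSE; pv[3, 2, 2] <- TRUE  # exactly 10 mm
  expect_true(classify_island(structure_mask(pv, sp),
                              structure_mask(cw, sp)))
  expect_true(is.na(classify_island(structure_mask(pv, sp), NULL)))
})
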