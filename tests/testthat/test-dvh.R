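sample_of <- function(doses, voxel_cc = 1) {
  n <- max(length(doses), 1L)
  g <- dose_grid(array(c(doses, numeric(n - length(doses))), c(n, 1, 1)),
                 rep((voxel_cc * 1000)^(1 / 3), 3))
  m <- structure_mask(array(seq_len(n) <= length(doses), c(n, 1, 1)),
                      g$spacing)
  dose_sample(g, m)
}

test_that("dose_at_volume_pct picks the exact voxel quantile", {
  expect_equal(dose_at_volume_pct(sample_of(rep(60, 50)), 95), 60)
  expect_equal(dose_at_volume_pct(sample_of(c(10, 20, 30, 40)), 75), 20)
  expect_equal(dose_at_volume_pct(sample_of(c(10, 20, 30, 40)), 100), 10)
  expect_equal(dose_at_volume_pct(sample_of(c(10, 20, 30, 40)), 25), 40)
  expect_error(dose_at_volume_pct(sample_of(numeric(0)), 95), "no structure")
})

test_that("volume_pct_at_dose uses an inclusive threshold", {
  expect_equal(volume_pct_at_dose(sample_of(rep(60, 10)), 60), 100)
  expect_equal(volume_pct_at_dose(sample_of(c(10, 20, 30, 40)), 25), 50)
  expect_equal(volume_pct_at_dose(sample_of(c(10, 20, 30, 40)), 0), 100)
})

test_that("coverage duality: D at V(x) covers at least x", {
  set.seed(11)
  for (rep in 1:25) {
    s <- sample_of(round(stats::runif(sample(3:40, 1), 0, 70), 2))
    for (x in c(5, 37.5, 50, 95, 100)) {
      d <- dose_at_volume_pct(s, x)
      expect_gte(volume_pct_at_dose(s, d), x)
    }
  }
})

test_that("near_min_dose excludes at most the coldest cold_cc", {
  s <- sample_of(c(50, 55, 60, 65), voxel_cc = 0.02)
  expect_equal(near_min_dose(s, 0.03), 55)
  expect_equal(near_min_dose(s, 0), 50)
  expect_equal(near_min_dose(sample_of(rep(60, 9), 0.02), 0.05), 60)
  expect_error(near_min_dose(s, 1), "invalid volume")
})

test_that("max dose and isodose volumes", {
  g <- uniform_grid(60, dim = c(5, 5, 4))
  expect_equal(max_dose(g), 60)
  g$values[3, 3, 2] <- 72
  expect_equal(max_dose(g), 72)
  expect_equal(60 / max_dose(g), 0.8333, tolerance = 1e-4)

  expect_equal(isodose_volume_cc(g, 0), 100)      # 100 voxels at 1 cc
  expect_equal(isodose_volume_cc(g, 100), 0)
  expect_equal(isodose_volume_cc(g, 72), 1)
})

test_that("hot volume outside the PTV uses a strict threshold", {
  g <- uniform_grid(60, dim = c(10, 10, 1), spacing = c(5, 5, 5))
  ptv <- full_mask(g)
  ptv$voxels[] <- FALSE
  ptv$voxels[1:10, 1:10, 1][1:100] <- TRUE
  # all inside PTV: nothing outside
  expect_equal(hot_volume_outside_pct(g, ptv, 63), 0)
  ptv$voxels[] <- FALSE
  ptv$voxels[1:10, 1:10, 1][1:100] <- c(rep(TRUE, 90), rep(FALSE, 10))
  g$values[1:10, 1:10, 1][91:100] <- 70
  expect_equal(hot_volume_outside_pct(g, ptv, 63), 100 * 10 / 90)
  expect_equal(hot_volume_outside_pct(g, ptv, 70), 0)  # strict >
})

test_that("DVH operations agree with brute-force oracles on random grids", {
  set.seed(2024)
  for (rep in 1:60) {
    dm <- sample(2:12, 3, replace = TRUE)
    g <- random_grid(dm)
    m <- random_mask(dm)
    s <- dose_sample(g, m)
    doses <- g$values[m$voxels]
    x <- stats::runif(1, 1, 100)
    lev <- stats::runif(1, 0, 85)
    expect_identical(dose_at_volume_pct(s, x), brute_dose_at_volume(doses, x))
    expect_equal(volume_pct_at_dose(s, lev), brute_volume_at_dose(doses, lev))
    expect_equal(isodose_volume_cc(g, lev, m),
                 brute_isodose_cc(doses, voxel_volume_cc(g), lev))
    cold <- stats::runif(1, 0, length(doses) * s$voxel_cc * 0.9)
    expect_identical(near_min_dose(s, cold),
                     brute_near_min(doses, s$voxel_cc, cold))
  }
})

test_that("isodose volume is monotone non-increasing in level", {
  set.seed(5)
  g <- random_grid(c(9, 7, 8))
  levels <- seq(0, 85, by = 5)
  vols <- vapply(levels, function(l) isodose_volume_cc(g, l), numeric(1))
  expect_true(all(diff(vols) <= 0))
})
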