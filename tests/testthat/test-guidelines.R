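test_that("threshold interpolation reproduces the protocol table and clamps", {
  set <- rtog_guidelines()
  # exact at every tabulated volume
  for (i in seq_len(nrow(set$rows))) {
    row <- interpolate_thresholds(set, set$rows$ptv_cc[i])
    for (cl in c("ci_none", "ci_minor_upper", "r50_none", "r50_minor_upper",
                 "d2cm_none", "d2cm_minor_upper"))
      expect_equal(row[[cl]], set$rows[[cl]][i])
  }
  expect_equal(interpolate_thresholds(set, 10)$d2cm_none, 50)
  expect_equal(interpolate_thresholds(set, 28)$r50_none, 4.4)
  # clamped outside the tabulated range
  expect_equal(unclass(interpolate_thresholds(set, 0.5))[1:6],
               unclass(interpolate_thresholds(set, 1.8))[1:6])
  expect_equal(unclass(interpolate_thresholds(set, 500))[1:6],
               unclass(interpolate_thresholds(set, 163))[1:6])
})

test_that("normalised metrics divide by the none/minor boundary", {
  expect_equal(d2cm_prime(48, 50), 0.96)
  expect_equal(d2cm_prime(50, 50), 1.0)
  expect_equal(d2cm_prime(57, 50), 1.14)
  expect_equal(r50_prime(4.5, 5), 0.90)
  expect_equal(r50_prime(4.66, 4.7), 0.99148936, tolerance = 1e-8)
  expect_error(d2cm_prime(48, 0), "invalid threshold")
})

test_that("banded classification follows the printed boundary conventions", {
  set <- rtog_guidelines()
  expect_equal(classify_plan(metrics_stub(d2cm_pct = 48), set)$banded$d2cm,
               "none")
  expect_equal(classify_plan(metrics_stub(d2cm_pct = 50), set)$banded$d2cm,
               "minor")
  expect_equal(classify_plan(metrics_stub(d2cm_pct = 58), set)$banded$d2cm,
               "minor")  # minor band closed at its upper end (58 at 10 cc)
  expect_equal(classify_plan(metrics_stub(d2cm_pct = 60), set)$banded$d2cm,
               "major")
  expect_equal(classify_plan(metrics_stub(ci = 1.2), set)$banded$ci, "minor")
  expect_equal(classify_plan(metrics_stub(ci = 1.19), set)$banded$ci, "none")
  expect_equal(classify_plan(metrics_stub(ci = 1.51), set)$banded$ci, "major")
})

test_that("volume-specific and volume-independent classes stay in their vocabularies", {
  set.seed(77)
  set <- rtog_guidelines()
  for (rep in 1:200) {
    m <- metrics_stub(ptv_cc = stats::runif(1, 1, 200),
                      ci = stats::runif(1, 0.8, 1.8),
                      r50 = stats::runif(1, 2, 9),
                      d2cm_pct = stats::runif(1, 30, 100),
                      v100_pct = stats::runif(1, 80, 100),
                      v90_pct = stats::runif(1, 95, 100),
                      v105_pct_of_ptv = stats::runif(1, 0, 25),
                      rx_over_dmax = stats::runif(1, 0.4, 1))
    rep_ <- classify_plan(m, set)
    expect_true(all(unlist(rep_$banded) %in% c("none", "minor", "major")))
    expect_true(all(unlist(rep_$pass_fail) %in% c("none", "deviation")))
    # class none iff normalised metric < 1 (both directions)
    expect_identical(rep_$banded$d2cm == "none", rep_$d2cm_prime < 1)
    expect_identical(rep_$banded$r50 == "none", rep_$r50_prime < 1)
  }
})

test_that("classification is monotone in the metric value", {
  set <- rtog_guidelines()
  rank <- c(none = 1, minor = 2, major = 3)
  set.seed(13)
  for (rep in 1:50) {
    v <- stats::runif(1, 1.8, 163)
    vals <- sort(stats::runif(2, 30, 100))
    c1 <- classify_plan(metrics_stub(ptv_cc = v, d2cm_pct = vals[1]),
                        set)$banded$d2cm
    c2 <- classify_plan(metrics_stub(ptv_cc = v, d2cm_pct = vals[2]),
                        set)$banded$d2cm
    expect_lte(rank[c1], rank[c2])
  }
})

test_that("missing metrics are flagged, not fatal", {
  m <- metrics_stub()
  m$ci <- NA_real_
  rep_ <- classify_plan(m)
  expect_true("ci" %in% rep_$missing)
  expect_true(is.na(rep_$banded$ci))
  expect_error(classify_plan(list(ci = 1.0)), "PTV volume")
})

test_that("guideline sets round trip through JSON", {
  set <- rtog_guidelines()
  f <- tempfile(fileext = ".json")
  write_guidelines_json(set, f)
  back <- read_guidelines_json(f)
  expect_equal(back$rows, set$rows)
  expect_equal(back$rx_over_dmax_range, set$rx_over_dmax_range)
})
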