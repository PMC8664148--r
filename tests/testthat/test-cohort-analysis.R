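test_that("paired t matches the closed form and the stats oracle", {
  r <- paired_t(c(0, 0, 0, 0), c(-1, 1, -1, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- paired_t(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(r$t, 3.873, tolerance = 1e-3)
  expect_equal(r$df, 3)
  expect_equal(r$p, 0.0305, tolerance = 1e-2)

  set.seed(8)
  for (rep in 1:30) {
    n <- sample(2:10, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    ours <- paired_t(x, y)
    ref <- stats::t.test(y, x, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and unpaired inputs are flagged", {
  r <- paired_t(c(1, 2, 3), c(3, 4, 5))  # all differences equal
  expect_true(r$degenerate)
  expect_true(is.na(r$p))
  expect_error(paired_t(1:3, 1:4), "pairing error")
})

test_that("relative difference and its guard", {
  expect_equal(relative_difference(95, 91.4), -0.0379, tolerance = 1e-3)
  expect_equal(relative_difference(7, 7), 0)
  expect_error(relative_difference(0, 1), "undefined ratio")
})

test_that("deviation counts: zeros when all pass, boundaries count as minor", {
  good <- cbind(data.frame(patient_id = c("a", "b"), arm = "plan",
                           island = c(TRUE, FALSE)),
                as.data.frame(metrics_stub()))
  counts <- deviation_count_table(good)
  expect_equal(counts$total_minor[counts$subgroup == "all"], 0)
  expect_equal(counts$total_major[counts$subgroup == "all"], 0)

  one <- good
  one$d2cm_pct[1] <- 50  # exactly at the none/minor boundary (10 cc PTV)
  counts <- deviation_count_table(one)
  all_row <- counts[counts$subgroup == "all", ]
  expect_equal(all_row$d2cm_minor, 1)
  expect_equal(all_row$d2cm_major, 0)
  # totals equal the sum of per-metric counts
  expect_equal(all_row$total_minor,
               all_row$ci_minor + all_row$r50_minor + all_row$d2cm_minor)
})

test_that("volume stratification splits at the cutoff and tests relative differences", {
  mk <- function(id, arm, vol, ci) {
    cbind(data.frame(patient_id = id, arm = arm),
          as.data.frame(metrics_stub(ptv_cc = vol, ci = ci)))
  }
  tab <- rbind(mk("a", "plan", 7.58, 1.2), mk("b", "plan", 74.06, 1.1),
               mk("c", "plan", 12, 1.15), mk("d", "plan", 30, 1.05),
               mk("a", "recalculated", 7.58, 1.1),
               mk("b", "recalculated", 74.06, 1.05),
               mk("c", "recalculated", 12, 1.04),
               mk("d", "recalculated", 30, 1.0))
  st <- stratify_by_volume(tab, metrics = "ci")
  expect_setequal(st$small_ids, c("a", "c"))
  expect_setequal(st$large_ids, c("b", "d"))
  expect_false(st$stratum_empty)
  expect_true(all(c("t", "p") %in% names(st$tests)))

  small_only <- tab[tab$ptv_cc < 20, ]
  st2 <- stratify_by_volume(small_only, metrics = "ci")
  expect_true(st2$stratum_empty)
  expect_null(st2$tests)
})

test_that("compare_cohort reports paired tests per metric", {
  set.seed(21)
  n <- 8
  base <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(data.frame(patient_id = sprintf("p%d", i), arm = "plan",
                     mu_total = 2000),
          as.data.frame(metrics_stub(ci = 1.1 + stats::rnorm(1, 0, 0.02))))))
  rec <- base
  rec$arm <- "recalculated"
  rec$ci <- base$ci - 0.08 + stats::rnorm(n, 0, 0.005)
  cmp <- compare_cohort(rbind(base, rec))
  ci_row <- cmp[cmp$metric == "ci", ]
  expect_lt(ci_row$p, 0.01)
  expect_equal(ci_row$mean_diff, mean(rec$ci) - mean(base$ci))
  expect_true(ci_row$significant)
})
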