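test_that("blank collection keeps quantifications strictly below the threshold", {
  records <- specimen_table(mm_events = c(0, 5, 30)) # fractions 0, 5e-7, 3e-6
  expect_equal(collect_blanks(records, 2e-6), c(0, 5e-7))
  expect_equal(collect_blanks(records, 2e-6, exclude_zeros = TRUE), 5e-7)
  expect_length(collect_blanks(specimen_table(mm_events = c(30, 40)), 2e-6), 0)
  expect_error(collect_blanks(records[0, ], 2e-6), "empty")

  bm <- generate_cohort(cohort_config(n_specimens = 300, seed = 13))
  fracs <- bm$mm_pc_events / (bm$acquired_events_tube_a + bm$acquired_events_tube_b)
  expect_equal(sort(collect_blanks(bm, 2e-6)), sort(fracs[fracs < 2e-6]))
})

test_that("blank statistics reproduce printed detection-limit pairs", {
  # invert lod = m + 3s, lloq = m + 10s for each printed pair, then recompute
  pair2 <- solve_blank_moments(percent_to_fraction(0.00019), percent_to_fraction(0.00057))
  bs2 <- compute_blank_stats(blanks_with_moments(pair2$m, pair2$s), threshold = 2e-6)
  expect_equal(bs2$lod, 1.9e-6, tolerance = 1e-12)
  expect_equal(bs2$lloq, 5.7e-6, tolerance = 1e-12)

  pair1 <- solve_blank_moments(percent_to_fraction(0.00009), percent_to_fraction(0.00027))
  bs1 <- compute_blank_stats(blanks_with_moments(pair1$m, pair1$s), threshold = 1e-6)
  expect_equal(bs1$lod, 9e-7, tolerance = 1e-12)
  expect_equal(bs1$lloq, 2.7e-6, tolerance = 1e-12)

  zero <- compute_blank_stats(rep(0, 10))
  expect_equal(c(zero$lob, zero$lod, zero$lloq), c(0, 0, 0))
  expect_error(compute_blank_stats(1e-6), "at least 2")
})

test_that("LOB < LOD < LLOQ whenever the blank SD is positive; scaling is equivariant", {
  withr::with_seed(14, {
    for (rep in 1:15) {
      blanks <- rlnorm(sample(3:50, 1), log(3e-7), 1)
      bs <- compute_blank_stats(blanks)
      expect_true(bs$lob < bs$lod && bs$lod < bs$lloq)
      c_ <- runif(1, 0.1, 10)
      sc <- compute_blank_stats(blanks * c_)
      expect_equal(c(sc$lob, sc$lod, sc$lloq), c_ * c(bs$lob, bs$lod, bs$lloq))
    }
  })
  # degenerate blank set collapses all three limits onto the mean
  flat <- compute_blank_stats(rep(2e-7, 5))
  expect_equal(c(flat$lob, flat$lod, flat$lloq), rep(2e-7, 3))
})

test_that("blank statistics match a two-pass mean/SD oracle", {
  withr::with_seed(15, {
    for (rep in 1:15) {
      x <- runif(sample(2:30, 1), 0, 5e-6)
      bs <- compute_blank_stats(x, lob_z = 1.645)
      n <- length(x)
      m <- sum(x) / n
      s <- sqrt(sum((x - m)^2) / (n - 1))
      expect_equal(bs$v_mean, m)
      expect_equal(bs$v_sd, s)
      expect_equal(bs$lob, m + 1.645 * s)
      expect_equal(bs$lod, m + 3 * s)
      expect_equal(bs$lloq, m + 10 * s)
    }
  })
})

test_that("scan closed forms: all-zero blanks give vLOD 0 and RMSE equal to the target", {
  records <- specimen_table(mm_events = rep(0, 30))
  scan <- sensitivity_scan(records, bootstrap_reps = 25, seed = 5)
  expect_true(all(scan$results$vlod == 0))
  expect_equal(scan$results$rmse, scan$results$threshold)
})

test_that("without resampling the RMSE is the single-cohort deviation |vLOD - t|", {
  bm <- generate_cohort(cohort_config(n_specimens = 200, seed = 23))
  scan <- sensitivity_scan(bm, grid = c(1e-5, 5e-6, 2e-6), seed = 1, resample = FALSE)
  expect_equal(scan$results$rmse, abs(scan$results$vlod - scan$results$threshold))
  expect_equal(scan$bootstrap_reps, 1L)
})

test_that("scan is deterministic under a fixed seed and validates its grid", {
  bm <- generate_cohort(cohort_config(n_specimens = 250, seed = 31))
  s1 <- sensitivity_scan(bm, bootstrap_reps = 40, seed = 9)
  s2 <- sensitivity_scan(bm, bootstrap_reps = 40, seed = 9)
  expect_identical(s1$results, s2$results)
  expect_identical(s1$achievable_sensitivity, s2$achievable_sensitivity)
  s3 <- sensitivity_scan(bm, bootstrap_reps = 40, seed = 10)
  expect_false(identical(s1$results$rmse, s3$results$rmse))

  expect_error(sensitivity_scan(bm, grid = c(1e-6, 2e-6)), "decreasing")
  expect_error(sensitivity_scan(bm, bootstrap_reps = 0), "bootstrap_reps")
})

test_that("grid points with fewer than 2 blanks are skipped with a warning", {
  # fractions: 0, 1.5e-6, 1.7e-6, 3e-6, 4e-6 -> only one blank below 1e-6
  records <- specimen_table(mm_events = c(0, 15, 17, 30, 40))
  warns <- testthat::capture_warnings(
    scan <- sensitivity_scan(records, grid = c(5e-6, 2e-6, 1e-6), bootstrap_reps = 20, seed = 2)
  )
  expect_true(any(grepl("Skipping", warns)))
  expect_true(is.na(scan$results$rmse[scan$results$threshold == 1e-6]))
  expect_equal(scan$results$n_blank, c(5, 3, 1))
  # with < 3 usable points no achievable sensitivity can be located
  expect_true(any(grepl("3 usable", warns)))
  expect_true(is.na(scan$achievable_sensitivity))
})

test_that("achievable sensitivity sits just before the RMSE break", {
  # RMSE flat through 1e-6, dropping by >2% at 0.9e-6 and decreasing after
  seq_paper <- tibble::tibble(
    threshold = c(5e-6, 2e-6, 1e-6, 0.9e-6, 0.8e-6, 0.7e-6),
    rmse = c(1.72e-7, 1.75e-7, 1.705e-7, 1.660e-7, 1.63e-7, 1.60e-7)
  )
  expect_identical(select_achievable_sensitivity(seq_paper), 1e-6)

  rising <- tibble::tibble(threshold = c(5e-6, 2e-6, 1e-6, 5e-7), rmse = 1:4 * 1e-7)
  expect_identical(select_achievable_sensitivity(rising), 5e-7)

  flat <- tibble::tibble(threshold = c(5e-6, 2e-6, 1e-6, 5e-7), rmse = rep(1e-7, 4))
  expect_identical(select_achievable_sensitivity(flat), 5e-7)

  expect_error(
    select_achievable_sensitivity(flat[1:2, ]),
    "3 usable"
  )
})

test_that("tidy and glance summarise performance objects", {
  bs <- compute_blank_stats(c(0, 0, 5e-7, 1e-6), threshold = 2e-6)
  td <- generics::tidy(bs)
  expect_equal(td$term, c("v_mean", "v_sd", "lob", "lod", "lloq"))
  gl <- generics::glance(bs)
  expect_equal(gl$n_blank, 4L)
  expect_equal(gl$lod, bs$lod)

  bm <- generate_cohort(cohort_config(n_specimens = 200, seed = 4))
  scan <- sensitivity_scan(bm, grid = c(1e-5, 5e-6, 2e-6), bootstrap_reps = 20, seed = 3)
  expect_s3_class(generics::tidy(scan), "tbl_df")
  expect_equal(generics::glance(scan)$n_thresholds, 3L)
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})
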