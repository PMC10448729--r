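cohort_213_209_134 <- function() {
  # mast fractions chosen to land in each adequacy band at 1e7 events
  specimen_table(
    mm_events = 0,
    mast_events = c(rep(830, 213), rep(300, 209), rep(190, 134))
  )
}

test_that("adequacy accounting recovers category counts and the suboptimal rate", {
  records <- cohort_213_209_134()
  qc <- assess_specimens(records)
  calls <- call_mrd_cohort(records, qc)
  s <- summarize_cohort(records, qc, calls)
  counts <- stats::setNames(s$adequacy_counts$n, s$adequacy_counts$category)
  expect_equal(counts[["adequate"]], 213)
  expect_equal(counts[["marginal"]], 209)
  expect_equal(counts[["suboptimal"]], 134)
  expect_equal(s$n_specimens, 556)
  expect_equal(round(s$pct_suboptimal), 24)
  expect_equal(sum(s$adequacy_counts$n), s$n_specimens)
})

test_that("cohort summary rejects empty or misaligned inputs", {
  records <- specimen_table(mm_events = c(0, 5))
  qc <- assess_specimens(records)
  calls <- call_mrd_cohort(records, qc)
  expect_error(summarize_cohort(records[0, ], qc[0, ], calls[0, ]), "empty")
  qc_bad <- qc
  qc_bad$specimen_id[1] <- "GHOST"
  expect_error(summarize_cohort(records, qc_bad, calls), "GHOST")
})

test_that("degenerate cohorts give boundary rates", {
  records <- specimen_table(mm_events = rep(5000, 8)) # fraction 5e-4 everywhere
  qc <- assess_specimens(records)
  calls <- call_mrd_cohort(records, qc)
  s <- summarize_cohort(records, qc, calls)
  expect_true(all(s$positivity_by_threshold$positivity_rate == 100))
})

test_that("summary counts match brute-force recounts of the input tables", {
  bm <- generate_cohort(cohort_config(n_specimens = 300, seed = 19))
  qc <- assess_specimens(bm)
  calls <- call_mrd_cohort(bm, qc)
  s <- summarize_cohort(bm, qc, calls)
  expect_equal(
    stats::setNames(s$adequacy_counts$n, s$adequacy_counts$category),
    table(qc$hemodilution_category)[levels(qc$hemodilution_category)],
    ignore_attr = TRUE
  )
  for (t in unique(calls$threshold)) {
    sub <- calls[calls$threshold == t, ]
    expect_equal(
      s$positivity_by_threshold$positivity_rate[s$positivity_by_threshold$threshold == t],
      100 * sum(sub$status == "positive") / nrow(sub)
    )
  }
  expect_true(all(s$positivity_by_threshold$positivity_rate >= 0 &
    s$positivity_by_threshold$positivity_rate <= 100))
  # tidy/glance/autoplot surfaces
  expect_s3_class(generics::tidy(s), "tbl_df")
  expect_equal(generics::glance(s)$n_specimens, 300)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  expect_s3_class(plot_mast_by_timepoint(bm, qc), "ggplot")
})

test_that("reports apply the adequacy-qualified clinical rules", {
  records <- specimen_table(
    mm_events = c(50, 0, 0), # fractions 5e-6, 0, 0
    mast_events = c(150, 830, 830), # suboptimal, adequate, adequate
    analytical_input = c(1e7, 4e6, 1e7)
  )
  qc <- assess_specimens(records)
  calls <- call_mrd_cohort(records, qc, thresholds = 1e-6)
  rep_ <- render_report(records, qc, calls)

  # positive on a hemodiluted specimen: reported positive, caveated
  expect_equal(as.character(rep_$mrd_status[1]), "positive")
  expect_match(rep_$qc_caveats[1], "hemodiluted")
  expect_true(rep_$evaluable[1])

  # negative with revised LOD 2.5e-6 coarser than 1e-6: reduced sensitivity
  expect_equal(as.character(rep_$mrd_status[2]), "negative_reduced_sensitivity")
  expect_false(rep_$evaluable[2])
  expect_equal(rep_$reported_sensitivity[2], 2.5e-6)
  expect_match(rep_$qc_caveats[2], "low analytical input")

  # clean negative: nominal sensitivity, no caveats
  expect_equal(as.character(rep_$mrd_status[3]), "negative")
  expect_true(rep_$evaluable[3])
  expect_equal(rep_$reported_sensitivity[3], 1e-6)
  expect_identical(rep_$qc_caveats[3], "")

  # laboratory policy switch for unevaluable negatives
  rep_ne <- render_report(records, qc, calls, negative_policy = "not_evaluable")
  expect_equal(as.character(rep_ne$mrd_status[2]), "not_evaluable")
})

test_that("report logic is total over the status x adequacy product", {
  grid <- expand.grid(
    status = c("positive", "negative", "not_evaluable"),
    hemo = c("adequate", "marginal", "suboptimal"),
    stringsAsFactors = FALSE
  )
  mm <- ifelse(grid$status == "positive", 50, 0)
  input <- ifelse(grid$status == "not_evaluable", 4e6, 1e7)
  mast <- c(adequate = 830, marginal = 300, suboptimal = 150)[grid$hemo]
  records <- specimen_table(
    mm_events = mm, mast_events = round(mast * input / 1e7),
    analytical_input = input
  )
  qc <- assess_specimens(records)
  calls <- call_mrd_cohort(records, qc, thresholds = 1e-6)
  expect_equal(as.character(calls$status), grid$status) # construction worked
  rep_ <- render_report(records, qc, calls)
  expect_false(anyNA(rep_$mrd_status))
  expect_false(anyNA(rep_$reported_sensitivity))
  # every suboptimal specimen carries the hemodilution caveat
  expect_true(all(grepl("hemodiluted", rep_$qc_caveats[grid$hemo == "suboptimal"])))
  # a positive is always reported positive whatever the adequacy
  expect_true(all(rep_$mrd_status[grid$status == "positive"] == "positive"))
})

test_that("pipeline runs end to end, writes artifacts, and reruns byte-identically", {
  cfg <- cohort_config(n_specimens = 120, seed = 29)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  b1 <- run_pipeline(cfg, bootstrap_reps = 20, out_dir = out1)
  b2 <- run_pipeline(cfg, bootstrap_reps = 20, out_dir = out2)
  files <- c(
    "cohort.csv", "truth.csv", "qc.csv", "calls.csv", "scan.csv",
    "reports.csv", "summary.json", "manifest.json"
  )
  expect_true(all(file.exists(file.path(out1, files))))
  expect_identical(b1$manifest$files, b2$manifest$files)
  expect_equal(nrow(b1$reports), 120)
  expect_s3_class(b1$summary, "mrd_cohort_summary")

  expect_warning(
    run_pipeline(cohort_config(n_specimens = 60, seed = 1),
      thresholds = c(1e-6, 4e-7), bootstrap_reps = 5, grid = c(1e-5, 5e-6, 2e-6)
    ),
    "reproducibly resolved"
  )
})
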