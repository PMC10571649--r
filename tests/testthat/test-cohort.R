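test_that("follow-up windows are half-open, disjoint and exhaustive", {
  expect_equal(assign_window(45), "W1")
  expect_equal(assign_window(90), "W1")
  expect_equal(assign_window(91), "W2")
  expect_equal(assign_window(400), "W5")
  expect_error(assign_window(0), "baseline")
  expect_error(assign_window(-10), "baseline")

  days <- 1:1200
  w <- assign_window(days)
  expect_true(all(w %in% paste0("W", 1:5)))
  wins <- follow_up_windows()
  for (i in seq_len(nrow(wins))) {
    inw <- days > wins$lower[i] & days <= wins$upper[i]
    expect_true(all(w[inw] == wins$label[i]))
  }
})

test_that("the earliest of several scans in a window is analyzed", {
  df <- make_lesion_df(days = c(0, 40, 80, 100, 170),
                       ld = c(14, 12, 11, 10, 9), perp = 6)
  s <- build_lesion_series(df)[[1]]
  expect_equal(select_window_measurement(s, "W1")$days_from_srt, 40L)
  expect_equal(select_window_measurement(s, "W2")$days_from_srt, 100L)
  expect_null(select_window_measurement(s, "W3"))
})

test_that("relative size is percent of baseline with flagged degenerate baselines", {
  expect_equal(relative_size(3.0, 8.1), 37.03704, tolerance = 1e-6)
  expect_equal(relative_size(8.1, 8.1), 100)
  expect_equal(relative_size(0, 5), 0)
  expect_warning(out <- relative_size(4, 0), "undefined")
  expect_true(is.na(out))
})

test_that("nadir is the running minimum of baseline and prior follow-up LDs", {
  df <- make_lesion_df(days = c(0, 60, 150), ld = c(14, 10, 12), perp = 6)
  s <- build_lesion_series(df)[[1]]
  expect_equal(nadir_ld(s, 150), 10)
  expect_equal(nadir_ld(s, 30), 14)   # no follow-ups yet

  df2 <- make_lesion_df(days = c(0, 60, 150), ld = c(14, 15, 13), perp = 6)
  s2 <- build_lesion_series(df2)[[1]]
  expect_equal(nadir_ld(s2, 200), 13)

  # non-increasing in the horizon
  horizons <- c(10, 60, 100, 150, 400)
  nads <- vapply(horizons, function(h) nadir_ld(s, h), numeric(1))
  expect_true(all(diff(nads) <= 0))

  # CR timepoints count as 0 only on request
  df3 <- rbind(make_lesion_df(days = c(0, 60), ld = c(14, 10), perp = 6),
               make_lesion_df(days = 150, ld = NA, core_present = FALSE))
  s3 <- build_lesion_series(df3)[[1]]
  expect_equal(nadir_ld(s3, 200), 10)
  expect_equal(nadir_ld(s3, 200, include_cr = TRUE), 0)
})

test_that("baselines come from the day-0 scan and the latest pre-SRT edema scan", {
  df <- rbind(
    make_lesion_df(days = -25, edema = 9.0),
    make_lesion_df(days = -7, edema = 8.1),
    make_lesion_df(days = 0, ld = 14, perp = 7),
    make_lesion_df(days = 50, ld = 10, perp = 5, edema = 3))
  s <- build_lesion_series(df)[[1]]
  expect_equal(s$baseline_ld_mm, 14)
  expect_equal(s$baseline_perp_mm, 7)
  expect_equal(s$baseline_edema_cm3, 8.1)   # closest to day 0
  expect_equal(s$baseline_edema_day, -7L)
  expect_false(s$is_new_lesion)
})

test_that("a lesion with no baseline scan is a new lesion seeded by first appearance", {
  df <- make_lesion_df(days = c(120, 200), ld = c(8, 11), perp = 4,
                       edema = c(2, 4))
  s <- build_lesion_series(df)[[1]]
  expect_true(s$is_new_lesion)
  expect_equal(s$baseline_ld_mm, 8)
  expect_equal(s$baseline_edema_cm3, 2)
})

test_that("exclusion rules fire in order with one rule per lesion", {
  ok <- make_lesion_df("P1", "L1", days = c(0, 50), ld = c(14, 10), perp = 6)
  small <- make_lesion_df("P1", "L2", days = c(0, 50), ld = c(9, 8), perp = 4)
  thick <- make_lesion_df("P2", "L1", days = c(0, 50), ld = c(15, 12),
                          perp = 7, thickness = 3.0)
  thick_small <- make_lesion_df("P2", "L2", days = c(0, 50), ld = c(9, 9),
                                perp = 4, thickness = 3.5)
  nosclc <- make_lesion_df("P3", "L1", days = c(0, 50), ld = c(15, 12),
                           perp = 7, histology = "melanoma")
  confl <- make_lesion_df("P4", "L1", days = c(0, 50), ld = c(16, 12),
                          perp = 8, edema = c(NA, 30), confluent = TRUE)
  res <- apply_exclusions(rbind(ok, small, thick, thick_small, nosclc, confl))

  expect_equal(res$log$rule[res$log$patient_id == "P1"], "5")
  expect_equal(res$log$rule[res$log$patient_id == "P2" &
                              res$log$lesion_id == "L1"], "3")
  # first matching rule wins: thickness outranks small baseline LD
  expect_equal(res$log$rule[res$log$patient_id == "P2" &
                              res$log$lesion_id == "L2"], "3")
  expect_equal(res$log$rule[res$log$patient_id == "P3"], "4")

  kept <- unique(paste(res$cohort$patient_id, res$cohort$lesion_id))
  expect_setequal(kept, c("P1 L1", "P4 L1"))
  # confluent lesion stays for LD analyses but is edema-excluded
  expect_equal(res$edema_excluded$patient_id, "P4")

  # idempotent
  res2 <- apply_exclusions(res$cohort)
  expect_equal(nrow(res2$log), 0)
  expect_identical(res2$cohort, res$cohort)
})

test_that("the cohort CSV round-trips losslessly with empty cells as NA", {
  sim <- simulate_cohort(4, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(sim$cohort, f)
  back <- read_cohort_csv(f)
  expect_equal(back, validate_cohort(sim$cohort), tolerance = 1e-12)
})

test_that("schema violations are reported with row numbers", {
  df <- make_lesion_df(days = c(0, 50), ld = c(14, 12), perp = 6)
  expect_error(validate_cohort(df[, -3]), "missing columns")
  bad <- df
  bad$core_present[2] <- FALSE
  expect_error(validate_cohort(bad), "rows 2")
  bad2 <- df
  bad2$edema_cm3[1] <- 5
  bad2$edema_resolved[1] <- TRUE
  expect_error(validate_cohort(bad2), "rows 1")
})
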