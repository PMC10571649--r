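test_that("RANO-BM categories follow the printed thresholds, inclusive", {
  # exactly 30% decrease from baseline is partial response
  expect_equal(classify_rano_bm(14, 14, 9.8), "PR")
  expect_equal(classify_rano_bm(14, 14, 9.9), "SD")
  # exactly 20% increase from nadir is progression
  expect_equal(classify_rano_bm(14, 10, 12), "PD")
  expect_equal(classify_rano_bm(14, 10, 11.9), "SD")
  # disappearance is complete response; absence on prior scans is new
  expect_equal(classify_rano_bm(14, 10, NA, core_present = FALSE), "CR")
  expect_equal(classify_rano_bm(NA, NA, 8, previously_present = FALSE), "NEW")
  expect_equal(classify_rano_bm(14, 14, 12), "SD")
  # no scan is no classification
  expect_true(is.na(classify_rano_bm(14, 14, NA)))
})

test_that("progression from a deep nadir trumps response, and recurrence after CR is PD", {
  # 40% below baseline but 20% above nadir: PD, not PR
  expect_equal(classify_rano_bm(14, 7, 8.4), "PD")
  # reappearance at any size after complete response
  expect_equal(classify_rano_bm(14, 0, 3), "PD")
  expect_error(classify_rano_bm(14, 15, 12), "nadir")
})

test_that("sweeping relative LD change switches category only at the thresholds", {
  baseline <- 14
  dec <- seq(0, 50, by = 0.1)
  cats <- vapply(dec, function(d)
    classify_rano_bm(baseline, baseline, baseline * (1 - d / 100)),
    character(1))
  expect_equal(sort(unique(cats)), c("PR", "SD"))
  expect_equal(min(dec[cats == "PR"]), 30)
  expect_equal(max(dec[cats == "SD"]), 29.9)

  nadir <- 10
  inc <- seq(0, 40, by = 0.1)
  cats2 <- vapply(inc, function(d)
    classify_rano_bm(14, nadir, nadir * (1 + d / 100)), character(1))
  expect_equal(min(inc[cats2 == "PD"]), 20)
})

test_that("edema grading uses a strict 25% stable band with resolution on top", {
  expect_equal(classify_edema_grade(1.1, 10), "decreased")   # -89%
  expect_equal(classify_edema_grade(11.4, 10), "stable")     # +14%
  expect_equal(classify_edema_grade(12.5, 10), "increased")  # boundary +25%
  expect_equal(classify_edema_grade(7.5, 10), "decreased")   # boundary -25%
  expect_equal(classify_edema_grade(12.49, 10), "stable")
  expect_equal(classify_edema_grade(7.51, 10), "stable")
  expect_equal(classify_edema_grade(5, 10, edema_resolved = TRUE), "resolved")
  expect_equal(classify_edema_grade(0, 10), "resolved")
  expect_warning(out <- classify_edema_grade(4, 0), "baseline")
  expect_true(is.na(out))
})

test_that("direction labels respect the dead-band and remission", {
  expect_equal(change_direction(10, 12), "increasing")
  expect_equal(change_direction(10, 8), "decreasing")
  expect_equal(change_direction(10, 10), "unchanged")
  expect_equal(change_direction(5, 0, now_remitted = TRUE), "remitted")
  expect_equal(change_direction(5, 0), "remitted")
  expect_equal(change_direction(10, 10.5, epsilon_pct = 10), "unchanged")
  expect_equal(change_direction(0, 2), "increasing")   # regrowth after remission
})

test_that("congruence is symmetric and strict about unchanged pairs", {
  expect_equal(congruence("decreasing", "decreasing"), "congruent")
  expect_equal(congruence("remitted", "remitted"), "congruent")
  expect_equal(congruence("decreasing", "increasing"), "incongruent")
  expect_equal(congruence("unchanged", "unchanged"), "incongruent")
  expect_equal(congruence("unchanged", "unchanged", stable_congruent = TRUE),
               "congruent")
  dirs <- c("increasing", "decreasing", "remitted", "unchanged")
  for (a in dirs) for (b in dirs) {
    expect_equal(congruence(a, b), congruence(b, a))
  }
  expect_true(is.na(congruence("increasing", NA)))
})

test_that("trajectory patterns are labeled by precedence with first match winning", {
  expect_equal(as.character(pattern_label(c(100, 40, 20, 8))),
               "continuous_decrease")
  expect_equal(as.character(pattern_label(c(100, 30, 60, 25))),
               "waxing_waning")
  expect_equal(as.character(pattern_label(c(100, 114, 130, 396))),
               "continuous_increase")
  expect_equal(as.character(pattern_label(c(100, 50, 20, 0))),
               "complete_remission")
  expect_equal(as.character(pattern_label(c(100, 130, 80, 60))),
               "paradoxical_then_decrease")
  # regrowth above baseline is not waxing-waning
  expect_equal(as.character(pattern_label(c(100, 60, 120, 80))), "other")
  short <- pattern_label(c(100, 50))
  expect_equal(as.character(short), "other")
  expect_equal(attr(short, "note"), "insufficient timepoints")
})

test_that("patient-level sum of LD caps targets at the five largest measurable lesions", {
  lds <- c(14, 12, 11, 10, 10, 9)
  df <- do.call(rbind, lapply(seq_along(lds), function(i) {
    make_lesion_df("P1", paste0("L", i), days = c(0, 50),
                   ld = c(lds[i], lds[i] - 1), perp = c(6, 5))
  }))
  series <- build_lesion_series(df)
  # the 9 mm lesion is not measurable; the five largest sum to 57 at baseline
  expect_equal(patient_sum_ld(series, "baseline"), 57)
  expect_equal(patient_sum_ld(series, "W1"), 57 - 5)

  # a target in complete response contributes 0
  cr <- rbind(make_lesion_df("P2", "L1", days = 0, ld = 14, perp = 6),
              make_lesion_df("P2", "L1", days = 50, ld = NA,
                             core_present = FALSE),
              make_lesion_df("P2", "L2", days = c(0, 50), ld = c(12, 11),
                             perp = 6))
  expect_equal(patient_sum_ld(build_lesion_series(cr), "W1"), 11)

  # three measurable lesions sum over three
  three <- do.call(rbind, lapply(1:3, function(i)
    make_lesion_df("P3", paste0("L", i), days = 0, ld = 10 + i, perp = 6)))
  expect_equal(patient_sum_ld(build_lesion_series(three), "baseline"), 36)

  # a missing target scan leaves the window sum undefined
  expect_true(is.na(patient_sum_ld(build_lesion_series(three), "W1")))

  # no measurable lesions at all
  none <- make_lesion_df("P4", "L1", days = 0, ld = 8, perp = 4)
  expect_warning(out <- patient_sum_ld(build_lesion_series(none), "baseline"),
                 "no measurable")
  expect_true(is.na(out))
})

test_that("assess_lesion composes window labels, directions and patterns", {
  df <- rbind(
    make_lesion_df(days = -10, edema = 10),
    make_lesion_df(days = 0, ld = 14, perp = 7),
    make_lesion_df(days = 50, ld = 12, perp = 6, edema = 14),
    make_lesion_df(days = 140, ld = 9, perp = 5, edema = 6),
    make_lesion_df(days = 230, ld = 8, perp = 5, edema = 4))
  s <- build_lesion_series(df)[[1]]
  a <- assess_lesion(s)
  expect_equal(a$labels$window, c("W1", "W2", "W3"))
  # W1: core decreasing, edema increasing -> incongruent, early flag set
  expect_equal(a$labels$core_direction[1], "decreasing")
  expect_equal(a$labels$edema_direction[1], "increasing")
  expect_equal(a$labels$congruence[1], "incongruent")
  expect_true(a$incongruent_first_followup)
  # later windows both decreasing -> congruent
  expect_equal(a$labels$congruence[2:3], c("congruent", "congruent"))
  expect_equal(a$labels$rano, c("SD", "PR", "PR"))
  expect_equal(a$labels$edema_grade, c("increased", "decreased", "decreased"))
  expect_equal(a$edema_pattern, "paradoxical_then_decrease")
  expect_equal(a$core_pattern, "continuous_decrease")
})

test_that("a constant series is stable disease, stable edema, unchanged and incongruent", {
  df <- rbind(
    make_lesion_df(days = -5, edema = 8),
    make_lesion_df(days = 0, ld = 14, perp = 7),
    make_lesion_df(days = c(60, 150, 250), ld = 14, perp = 7, edema = 8))
  a <- assess_lesion(build_lesion_series(df)[[1]])
  expect_true(all(a$labels$rano == "SD"))
  expect_true(all(a$labels$edema_grade == "stable"))
  expect_true(all(a$labels$core_direction == "unchanged"))
  expect_true(all(a$labels$congruence == "incongruent"))
  # the configurable lenient reading instead calls the flat pair congruent
  a2 <- assess_lesion(build_lesion_series(df)[[1]],
                      analysis_config(stable_congruent = TRUE))
  expect_true(all(a2$labels$congruence == "congruent"))
})

test_that("empty follow-up gives an empty assessment; confluent lesions keep LD only", {
  df <- make_lesion_df(days = 0, ld = 14, perp = 7)
  a <- assess_lesion(build_lesion_series(df)[[1]])
  expect_equal(nrow(a$labels), 0)

  df2 <- rbind(
    make_lesion_df(days = -5, edema = 20, confluent = TRUE),
    make_lesion_df(days = 0, ld = 14, perp = 7, confluent = TRUE),
    make_lesion_df(days = c(60, 150, 250), ld = c(12, 10, 9), perp = 6,
                   edema = c(25, 18, 12), confluent = TRUE))
  a2 <- assess_lesion(build_lesion_series(df2)[[1]], edema_excluded = TRUE)
  expect_true(all(!is.na(a2$labels$rano)))
  expect_true(all(is.na(a2$labels$edema_grade)))
  expect_true(all(is.na(a2$labels$congruence)))
  expect_true(is.na(a2$edema_pattern))
  expect_equal(a2$core_pattern, "continuous_decrease")
})

test_that("a new lesion is NEW at first appearance and tracked thereafter", {
  df <- make_lesion_df(days = c(120, 200, 300), ld = c(8, 11, 14), perp = 5,
                       edema = c(2, 4, 7))
  s <- build_lesion_series(df)[[1]]
  a <- assess_lesion(s)
  expect_equal(a$labels$rano[1], "NEW")
  expect_equal(a$labels$rano[2], "PD")   # 11 vs nadir 8 is +37.5%
})
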