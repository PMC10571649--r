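# Per-lesion response classification: RANO-BM categories from LD, the
# proposed 25%-band edema-volume grading, direction/congruence labels for
# core-versus-edema response curves, and trajectory pattern labeling.

.rano_levels <- c("CR", "PR", "SD", "PD", "NEW")
.edema_levels <- c("stable", "decreased", "increased", "resolved")
.direction_levels <- c("increasing", "decreasing", "remitted", "unchanged")
.pattern_levels <- c("continuous_decrease", "waxing_waning",
                     "paradoxical_then_decrease", "continuous_increase",
                     "complete_remission", "other")

#' RANO-BM category of one lesion at one timepoint
#'
#' Evaluation order (first match wins): new lesion (not previously present);
#' complete response (core disappeared); progressive disease (LD increase
#' >= 20% from nadir -- checked before PR, so a lesion regrowing from a deep
#' nadir is progressive even while still >= 30% below baseline); partial
#' response (LD decrease >= 30% from baseline); otherwise stable disease.
#' Both thresholds are inclusive. After a complete response the nadir is 0,
#' so any reappearance of the core is progression.
#'
#' @param baseline_ld Baseline LD, mm (> 0 unless the lesion is new).
#' @param nadir Smallest LD recorded so far, mm (see [nadir_ld()]); 0 after a
#'   complete response.
#' @param ld_mm Current LD, mm; `NA` when no LD was measured.
#' @param core_present Is the enhancing core visible on the current scan?
#' @param previously_present Was the lesion present on any prior MRI?
#' @param pr_pct,pd_pct Response/progression thresholds in percent
#'   (defaults 30 and 20).
#' @return One of `"CR", "PR", "SD", "PD", "NEW"`, or `NA` when the
#'   timepoint carries no usable measurement (no scan is not a response).
#' @export
classify_rano_bm <- function(baseline_ld, nadir, ld_mm, core_present = TRUE,
                             previously_present = TRUE,
                             pr_pct = 30, pd_pct = 20) {
  if (!previously_present) return("NEW")
  if (!core_present) return("CR")
  if (is.na(ld_mm)) return(NA_character_)
  if (is.na(baseline_ld) || baseline_ld <= 0) {
    stop("baseline LD must be positive for an established lesion")
  }
  if (nadir > baseline_ld) stop("nadir cannot exceed the baseline LD")
  if (nadir <= 0) {
    # recurrence after complete response: progression at any size
    return(if (ld_mm > 0) "PD" else "CR")
  }
  if (.geq(100 * (ld_mm - nadir) / nadir, pd_pct)) return("PD")
  if (.geq(100 * (baseline_ld - ld_mm) / baseline_ld, pr_pct)) return("PR")
  "SD"
}

#' Grade the change in peritumoral edema volume
#'
#' The proposed grading: stable (absolute change below 25%), decreased
#' (>= 25% decrease), increased (>= 25% increase), and resolved (edema no
#' longer present). "Less than 25%" is strict, so the exact 25% boundary is
#' assigned to the directional grade.
#'
#' @param current_cm3 Edema volume at the timepoint, cm^3.
#' @param baseline_cm3 Baseline edema volume, cm^3 (> 0).
#' @param edema_resolved Flag that the edema has fully resolved.
#' @param band_pct Width of the stable band in percent (default 25).
#' @return One of `"stable", "decreased", "increased", "resolved"`; `NA`
#'   (with a warning) when the baseline is zero or missing.
#' @export
classify_edema_grade <- function(current_cm3, baseline_cm3,
                                 edema_resolved = FALSE, band_pct = 25) {
  if (isTRUE(edema_resolved) ||
      (!is.na(current_cm3) && current_cm3 == 0)) {
    return("resolved")
  }
  if (is.na(current_cm3)) return(NA_character_)
  if (is.na(baseline_cm3) || baseline_cm3 <= 0) {
    warning("edema grade undefined without a positive baseline volume")
    return(NA_character_)
  }
  delta <- 100 * (current_cm3 - baseline_cm3) / baseline_cm3
  if (.geq(delta, band_pct)) return("increased")
  if (.geq(-delta, band_pct)) return("decreased")
  "stable"
}

#' Direction of change between two timepoints
#'
#' Used to read response curves: increasing / decreasing when the relative
#' change exceeds `epsilon_pct` in magnitude, remitted when the quantity has
#' disappeared, unchanged otherwise. The default epsilon of 0 makes any
#' strict change directional.
#'
#' @param previous Value at the previous available timepoint (> 0; 0 means
#'   the quantity had already remitted, so any positive value now is
#'   increasing).
#' @param current Value at the current timepoint.
#' @param now_remitted Has the quantity disappeared at this timepoint?
#' @param epsilon_pct Dead-band in percent for "unchanged".
#' @return One of `"increasing", "decreasing", "remitted", "unchanged"`.
#' @export
change_direction <- function(previous, current, now_remitted = FALSE,
                             epsilon_pct = 0) {
  if (isTRUE(now_remitted) || (!is.na(current) && current == 0)) {
    return("remitted")
  }
  if (is.na(previous) || is.na(current)) return(NA_character_)
  if (previous <= 0) return("increasing")
  ch <- 100 * (current - previous) / previous
  if (ch > epsilon_pct) return("increasing")
  if (ch < -epsilon_pct) return("decreasing")
  "unchanged"
}

#' Congruence of core and edema response directions
#'
#' A timepoint is congruent iff the tumor-core diameter and the edema volume
#' are concurrently increasing, decreasing, or completely remitted; any other
#' pairing -- including any pair involving "unchanged" under the strict
#' reading -- is incongruent. Set `stable_congruent = TRUE` to additionally
#' treat (unchanged, unchanged) as congruent.
#'
#' @param core_dir,edema_dir Direction labels (see [change_direction()]);
#'   vectorized.
#' @param stable_congruent Count a jointly unchanged pair as congruent?
#' @return `"congruent"` / `"incongruent"` (NA where either side is absent).
#' @export
congruence <- function(core_dir, edema_dir, stable_congruent = FALSE) {
  ok <- c("increasing", "decreasing", "remitted")
  if (stable_congruent) ok <- c(ok, "unchanged")
  ifelse(is.na(core_dir) | is.na(edema_dir), NA_character_,
         ifelse(core_dir == edema_dir & core_dir %in% ok,
                "congruent", "incongruent"))
}

#' Trajectory pattern of a relative-size series
#'
#' Labels a lesion's whole course from its time-ordered relative sizes (in
#' percent of baseline; the first element is the baseline itself, i.e. 100).
#' Evaluation order, first match wins:
#'
#' 1. `complete_remission` -- the final value is 0;
#' 2. `continuous_decrease` -- every successive change <= 0;
#' 3. `continuous_increase` -- every successive change >= 0 and the final
#'    value exceeds baseline;
#' 4. `paradoxical_then_decrease` -- an increase at the first follow-up, a
#'    decrease at the second, and no later increase;
#' 5. `waxing_waning` -- a decrease followed by at least one regrowth and a
#'    later decrease, the series never exceeding its pretreatment baseline;
#' 6. `other`.
#'
#' @param rel_sizes Numeric vector of relative sizes (percent), baseline
#'   first; `NA` values are dropped.
#' @param baseline_pct The baseline reference (default the first value).
#' @return A pattern label; with fewer than two follow-up values, `"other"`
#'   with attribute `note = "insufficient timepoints"`.
#' @examples
#' pattern_label(c(100, 40, 20, 8))     # continuous_decrease
#' pattern_label(c(100, 30, 60, 25))    # waxing_waning
#' pattern_label(c(100, 114, 130, 396)) # continuous_increase
#' @export
pattern_label <- function(rel_sizes, baseline_pct = rel_sizes[1L]) {
  v <- rel_sizes[!is.na(rel_sizes)]
  if (length(v) < 3L) {
    return(structure("other", note = "insufficient timepoints"))
  }
  ch <- diff(v)
  if (v[length(v)] == 0) return("complete_remission")
  if (all(ch <= 0)) return("continuous_decrease")
  if (all(ch >= 0) && v[length(v)] > baseline_pct) return("continuous_increase")
  if (ch[1L] > 0 && ch[2L] < 0 && all(ch[-(1:2)] <= 0)) {
    return("paradoxical_then_decrease")
  }
  pos <- which(ch > 0)
  waxing <- any(vapply(pos, function(u) {
    any(ch[seq_len(u - 1L)] < 0) && any(ch[-seq_len(u)] < 0)
  }, logical(1L)))
  if (waxing && max(v) <= baseline_pct + 1e-9) return("waxing_waning")
  "other"
}

#' Patient-level sum of longest diameters
#'
#' RANO-BM sums the LDs of up to five target lesions. Targets are the up-to-
#' five largest lesions that are measurable at baseline (LD >= 10 mm and
#' perpendicular >= 5 mm), fixed thereafter. Lesions in complete response
#' contribute 0; a target without a scan in the window makes the sum
#' undefined for that window.
#'
#' @param series_list List of `lesion_series` for one patient.
#' @param window Window label (`"W1"` ...), or `"baseline"` for the
#'   treatment-day sum.
#' @param max_targets Cap on the number of target lesions (default 5).
#' @param min_ld_mm,min_perp_mm Measurability thresholds.
#' @param breaks Window boundaries.
#' @return Sum of LDs in mm; `NA` (with a warning when no lesion is
#'   measurable) if undefined.
#' @export
patient_sum_ld <- function(series_list, window, max_targets = 5,
                           min_ld_mm = 10, min_perp_mm = 5,
                           breaks = c(0, 90, 180, 270, 365, Inf)) {
  meas <- vapply(series_list, function(s) {
    isTRUE(is_measurable(s$baseline_ld_mm, s$baseline_perp_mm,
                         min_ld_mm, min_perp_mm))
  }, logical(1L))
  targets <- series_list[meas]
  if (!length(targets)) {
    warning("no measurable lesions at baseline; sum of LD undefined")
    return(NA_real_)
  }
  bld <- vapply(targets, function(s) s$baseline_ld_mm, numeric(1L))
  targets <- targets[order(-bld)][seq_len(min(max_targets, length(targets)))]
  if (identical(window, "baseline")) {
    return(sum(vapply(targets, function(s) s$baseline_ld_mm, numeric(1L))))
  }
  vals <- vapply(targets, function(s) {
    m <- select_window_measurement(s, window, breaks)
    if (is.null(m)) return(NA_real_)
    if (!m$core_present) return(0)
    m$ld_mm
  }, numeric(1L))
  if (anyNA(vals)) return(NA_real_)
  sum(vals)
}

#' Assess one lesion over its follow-up windows
#'
#' Composes the per-timepoint classifiers along a lesion series: for every
#' window holding a scan (the earliest, if several) it reports the RANO-BM
#' category, the edema grade versus the edema baseline, the core/edema
#' direction pair versus the previous analyzed timepoint (the baseline before
#' the first follow-up), and the congruence label. Series-level results are
#' the trajectory pattern of core and edema (computed on the full
#' time-ordered measurement series) and the congruence-at-first-follow-up
#' flag, the candidate early marker of subsequent progression.
#'
#' @param series A `lesion_series`.
#' @param config An [analysis_config()].
#' @param edema_excluded Set `TRUE` for confluent-edema lesions: edema
#'   grades, directions and patterns are withheld, LD analyses retained.
#' @return Object of class `lesion_assessment`: `labels` (one row per
#'   assessed window), `core_pattern`, `edema_pattern`,
#'   `incongruent_first_followup`.
#' @export
assess_lesion <- function(series, config = analysis_config(),
                          edema_excluded = FALSE) {
  stopifnot(inherits(series, "lesion_series"))
  breaks <- config$window_breaks
  m <- series$measurements
  fu <- m[m$days_from_srt > 0L, , drop = FALSE]
  empty <- data.frame(window = character(0), days_from_srt = integer(0),
                      ld_mm = numeric(0), rel_ld_pct = numeric(0),
                      edema_cm3 = numeric(0), rel_edema_pct = numeric(0),
                      rano = character(0), edema_grade = character(0),
                      core_direction = character(0),
                      edema_direction = character(0),
                      congruence = character(0))
  out <- list(patient_id = series$patient_id, lesion_id = series$lesion_id,
              labels = empty, core_pattern = NA_character_,
              edema_pattern = NA_character_,
              incongruent_first_followup = NA)
  class(out) <- "lesion_assessment"
  if (!nrow(fu)) return(out)

  b_ld <- series$baseline_ld_mm
  b_ed <- if (edema_excluded) NA_real_ else series$baseline_edema_cm3
  wins <- assign_window(fu$days_from_srt, breaks)
  worder <- unique(wins[order(fu$days_from_srt)])
  prev_ld <- b_ld
  prev_ed <- b_ed
  seen_cr <- FALSE
  first_appearance_day <- if (series$is_new_lesion)
    min(fu$days_from_srt) else -1L
  rows <- vector("list", length(worder))
  for (i in seq_along(worder)) {
    w <- worder[i]
    r <- fu[wins == w, , drop = FALSE]
    r <- r[which.min(r$days_from_srt), , drop = FALSE]
    day <- r$days_from_srt
    prior <- fu[fu$days_from_srt < day, , drop = FALSE]
    nad <- if (seen_cr) 0 else {
      suppressWarnings(min(c(b_ld, prior$ld_mm[!is.na(prior$ld_mm)]),
                           na.rm = TRUE))
    }
    rano <- if (is.na(b_ld) && !series$is_new_lesion) NA_character_ else {
      classify_rano_bm(if (series$is_new_lesion && day == first_appearance_day)
                         NA_real_ else b_ld,
                       nad, r$ld_mm, r$core_present,
                       previously_present = !(series$is_new_lesion &&
                                                day == first_appearance_day),
                       pr_pct = config$pr_pct, pd_pct = config$pd_pct)
    }
    if (!r$core_present) seen_cr <- TRUE
    ed_val <- if (edema_excluded) NA_real_ else r$edema_cm3
    ed_rem <- !edema_excluded &&
      (isTRUE(r$edema_resolved) || (!is.na(ed_val) && ed_val == 0))
    egrade <- if (edema_excluded) NA_character_ else {
      if (is.na(b_ed) && !ed_rem) NA_character_ else
        suppressWarnings(classify_edema_grade(ed_val, b_ed, ed_rem,
                                              config$edema_band_pct))
    }
    core_dir <- change_direction(prev_ld, r$ld_mm,
                                 now_remitted = !r$core_present,
                                 epsilon_pct = config$direction_epsilon_pct)
    edema_dir <- if (edema_excluded) NA_character_ else {
      change_direction(prev_ed, ed_val, now_remitted = ed_rem,
                       epsilon_pct = config$direction_epsilon_pct)
    }
    cong <- congruence(core_dir, edema_dir, config$stable_congruent)
    rel_ld <- if (!is.na(b_ld) && b_ld > 0 && !is.na(r$ld_mm))
      100 * r$ld_mm / b_ld else if (!r$core_present) 0 else NA_real_
    rel_ed <- if (!is.na(b_ed) && b_ed > 0 && !is.na(ed_val))
      100 * ed_val / b_ed else NA_real_
    rows[[i]] <- data.frame(window = w, days_from_srt = day,
                            ld_mm = if (is.na(r$ld_mm)) NA_real_ else r$ld_mm,
                            rel_ld_pct = rel_ld,
                            edema_cm3 = ed_val, rel_edema_pct = rel_ed,
                            rano = rano, edema_grade = egrade,
                            core_direction = core_dir,
                            edema_direction = edema_dir,
                            congruence = cong)
    prev_ld <- if (!r$core_present) 0 else
      if (is.na(r$ld_mm)) prev_ld else r$ld_mm
    if (!edema_excluded) {
      prev_ed <- if (ed_rem) 0 else if (is.na(ed_val)) prev_ed else ed_val
    }
  }
  out$labels <- do.call(rbind, rows)

  # series-level patterns over the full measurement sequence
  if (!is.na(b_ld) && b_ld > 0) {
    ld_seq <- ifelse(!fu$core_present, 0, fu$ld_mm)
    rel <- 100 * ld_seq / b_ld
    out$core_pattern <- as.character(pattern_label(c(100, rel)))
  }
  if (!edema_excluded && !is.na(series$baseline_edema_cm3) &&
      series$baseline_edema_cm3 > 0) {
    ed_seq <- ifelse(fu$edema_resolved %in% TRUE, 0, fu$edema_cm3)
    rel <- 100 * ed_seq / series$baseline_edema_cm3
    out$edema_pattern <- as.character(pattern_label(c(100, rel)))
  }
  out$incongruent_first_followup <-
    if (is.na(out$labels$congruence[1L])) NA else
      out$labels$congruence[1L] == "incongruent"
  out
}

#' @export
print.lesion_assessment <- function(x, ...) {
  cat(sprintf("<lesion_assessment %s/%s> core pattern: %s, edema pattern: %s\n",
              x$patient_id, x$lesion_id, x$core_pattern, x$edema_pattern))
  if (nrow(x$labels)) print(x$labels, row.names = FALSE)
  invisible(x)
}
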