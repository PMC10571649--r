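# Longitudinal cohort data model: the long-format measurement table, lesion
# series with baselines, follow-up windows, and the study exclusion rules.
#
# Table schema (one row per lesion-timepoint, empty cell = absent):
#   patient_id, lesion_id, days_from_srt, ld_mm, perp_mm, edema_cm3,
#   core_present, edema_resolved, confluent_edema, on_steroids,
#   slice_thickness_mm, flair_available, histology
# Baselines: tumor-core LD on the treatment-day scan (day 0); edema volume on
# a scan 0-30 days pre-treatment (the one closest to day 0 if several).

#' Column names of the long-format cohort table
#' @return Character vector of the required column names, in order.
#' @export
cohort_columns <- function() {
  c("patient_id", "lesion_id", "days_from_srt", "ld_mm", "perp_mm",
    "edema_cm3", "core_present", "edema_resolved", "confluent_edema",
    "on_steroids", "slice_thickness_mm", "flair_available", "histology")
}

#' Validate (and normalize) a cohort measurement table
#'
#' Checks the schema and the row-level invariants: a row without a visible
#' core cannot carry an LD, and a row flagged edema-resolved cannot carry a
#' positive edema volume. Violations are reported with their row numbers.
#'
#' @param df A data frame in the cohort schema.
#' @return The data frame with columns coerced to their canonical types.
#' @export
validate_cohort <- function(df) {
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing)) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[cohort_columns()]
  df$patient_id <- as.character(df$patient_id)
  df$lesion_id <- as.character(df$lesion_id)
  df$days_from_srt <- as.integer(df$days_from_srt)
  for (col in c("ld_mm", "perp_mm", "edema_cm3", "slice_thickness_mm")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("core_present", "edema_resolved", "confluent_edema",
                "on_steroids", "flair_available")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df$histology <- as.character(df$histology)
  bad <- character(0)
  r <- which(!df$core_present & !is.na(df$ld_mm))
  if (length(r)) {
    bad <- c(bad, paste0("rows ", paste(r, collapse = ","),
                         ": ld_mm present but core_present is FALSE"))
  }
  r <- which(df$edema_resolved & !is.na(df$edema_cm3) & df$edema_cm3 > 0)
  if (length(r)) {
    bad <- c(bad, paste0("rows ", paste(r, collapse = ","),
                         ": edema_resolved with positive edema_cm3"))
  }
  r <- which(is.na(df$days_from_srt))
  if (length(r)) {
    bad <- c(bad, paste0("rows ", paste(r, collapse = ","),
                         ": days_from_srt missing"))
  }
  neg <- which(!is.na(df$ld_mm) & df$ld_mm < 0 |
                 !is.na(df$edema_cm3) & df$edema_cm3 < 0)
  if (length(neg)) {
    bad <- c(bad, paste0("rows ", paste(neg, collapse = ","),
                         ": negative measurement"))
  }
  if (length(bad)) stop("invalid cohort table:\n  ", paste(bad, collapse = "\n  "))
  df
}

#' Read / write the long-format cohort CSV
#'
#' Empty cells are absent values. `read_cohort_csv` validates the schema and
#' row invariants; `write_cohort_csv` writes absent values as empty cells.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv`: the validated data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort CSV: ", path)
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_csv
#' @param df Cohort data frame in the schema of [cohort_columns()].
#' @export
write_cohort_csv <- function(df, path) {
  df <- validate_cohort(df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Post-treatment follow-up windows
#'
#' The five analysis windows in days after treatment, half-open on the left:
#' (0,90], (90,180], (180,270], (270,365], (365, Inf). The half-open
#' convention keeps the windows disjoint and exhaustive for all positive
#' days (day 90 belongs to W1, day 91 to W2).
#'
#' @param breaks Window boundaries, ascending, starting at 0 and ending in
#'   `Inf`.
#' @return Data frame with `label`, `lower` (exclusive), `upper` (inclusive).
#' @export
follow_up_windows <- function(breaks = c(0, 90, 180, 270, 365, Inf)) {
  k <- length(breaks) - 1L
  data.frame(label = paste0("W", seq_len(k)),
             lower = breaks[-length(breaks)],
             upper = breaks[-1L])
}

#' Assign follow-up days to their window
#'
#' @param days_from_srt Integer days after treatment; must be strictly
#'   positive (day 0 and pre-treatment scans are baselines, not follow-up).
#' @param breaks As in [follow_up_windows()].
#' @return Character vector of window labels (`"W1"` ... ).
#' @examples
#' assign_window(c(45, 90, 91, 400))
#' @export
assign_window <- function(days_from_srt, breaks = c(0, 90, 180, 270, 365, Inf)) {
  if (anyNA(days_from_srt) || any(days_from_srt <= 0)) {
    stop("days_from_srt must be > 0: baseline/pre-SRT scans are not follow-up")
  }
  i <- findInterval(days_from_srt, breaks[-length(breaks)], left.open = TRUE)
  paste0("W", i)
}

#' Relative size versus baseline, in percent
#'
#' @param current,baseline Nonnegative measurements (same units).
#' @return `100 * current / baseline`; `NA` with a warning where the baseline
#'   is zero or missing (such records are excluded from relative analyses).
#' @export
relative_size <- function(current, baseline) {
  out <- ifelse(!is.na(baseline) & baseline > 0, 100 * current / baseline,
                NA_real_)
  if (any(!is.na(current) & (is.na(baseline) | baseline <= 0))) {
    warning("relative size undefined for nonpositive/missing baseline; NA returned")
  }
  out
}

#' Assemble per-lesion series from a cohort table
#'
#' Orders each lesion's measurements in time and derives its baselines: the
#' LD (and perpendicular) from the day-0 scan, and the edema volume from the
#' pre-treatment scan in \[-30, 0\] days closest to day 0. Lesions with no
#' baseline scan at all are new lesions: their first appearance becomes their
#' baseline and they are flagged `is_new_lesion`.
#'
#' @param df Validated cohort data frame.
#' @return Named list of `lesion_series` objects (names `patient/lesion`).
#' @export
build_lesion_series <- function(df) {
  df <- validate_cohort(df)
  key <- paste(df$patient_id, df$lesion_id, sep = "/")
  lapply(split(df, factor(key, levels = unique(key))), function(m) {
    m <- m[order(m$days_from_srt), , drop = FALSE]
    bl <- m[m$days_from_srt == 0L & !is.na(m$ld_mm), , drop = FALSE]
    ed <- m[m$days_from_srt >= -30L & m$days_from_srt <= 0L &
              !is.na(m$edema_cm3), , drop = FALSE]
    is_new <- !any(m$days_from_srt <= 0L)
    baseline_ld <- if (nrow(bl)) bl$ld_mm[1L] else NA_real_
    baseline_perp <- if (nrow(bl)) bl$perp_mm[1L] else NA_real_
    baseline_edema <- if (nrow(ed)) ed$edema_cm3[nrow(ed)] else NA_real_
    baseline_edema_day <- if (nrow(ed)) ed$days_from_srt[nrow(ed)] else NA_integer_
    if (is_new) {
      fld <- m[!is.na(m$ld_mm), , drop = FALSE]
      fed <- m[!is.na(m$edema_cm3), , drop = FALSE]
      if (nrow(fld)) baseline_ld <- fld$ld_mm[1L]
      if (nrow(fld)) baseline_perp <- fld$perp_mm[1L]
      if (nrow(fed)) {
        baseline_edema <- fed$edema_cm3[1L]
        baseline_edema_day <- fed$days_from_srt[1L]
      }
    }
    structure(list(patient_id = m$patient_id[1L],
                   lesion_id = m$lesion_id[1L],
                   measurements = m,
                   baseline_ld_mm = baseline_ld,
                   baseline_perp_mm = baseline_perp,
                   baseline_edema_cm3 = baseline_edema,
                   baseline_edema_day = baseline_edema_day,
                   is_new_lesion = is_new,
                   confluent = any(m$confluent_edema, na.rm = TRUE)),
              class = "lesion_series")
  })
}

#' @export
print.lesion_series <- function(x, ...) {
  cat(sprintf(
    "<lesion_series %s/%s> %d timepoints, baseline LD %s mm, baseline edema %s cm^3%s\n",
    x$patient_id, x$lesion_id, nrow(x$measurements),
    format(x$baseline_ld_mm), format(x$baseline_edema_cm3),
    if (x$is_new_lesion) " [new lesion]" else ""))
  invisible(x)
}

#' Pick the analyzed measurement of a window
#'
#' At 6-12 week scan intervals a window usually holds at most one scan; if
#' several fall into it, the earliest is analyzed (a declared convention).
#'
#' @param series A `lesion_series`.
#' @param window Window label (`"W1"` ...).
#' @param breaks Window boundaries, as in [assign_window()].
#' @return A one-row data frame, or `NULL` if the window has no scan.
#' @export
select_window_measurement <- function(series, window,
                                      breaks = c(0, 90, 180, 270, 365, Inf)) {
  stopifnot(inherits(series, "lesion_series"))
  m <- series$measurements
  m <- m[m$days_from_srt > 0L, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  m <- m[assign_window(m$days_from_srt, breaks) == window, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  m[which.min(m$days_from_srt), , drop = FALSE]
}

#' Smallest LD recorded up to a given day (the nadir)
#'
#' The nadir is the minimum of the baseline LD and all follow-up LDs at or
#' before `up_to_day`. Timepoints where the core had disappeared carry no LD;
#' they count as 0 only when `include_cr = TRUE` (the complete-response ->
#' recurrence logic of the response classifier) and are skipped otherwise.
#'
#' @param series A `lesion_series` with a baseline LD.
#' @param up_to_day Day horizon (inclusive).
#' @param include_cr Treat disappeared-core timepoints as LD 0.
#' @return The nadir LD in mm.
#' @export
nadir_ld <- function(series, up_to_day, include_cr = FALSE) {
  stopifnot(inherits(series, "lesion_series"))
  if (is.na(series$baseline_ld_mm)) stop("series has no baseline LD")
  m <- series$measurements
  m <- m[m$days_from_srt > 0L & m$days_from_srt <= up_to_day, , drop = FALSE]
  vals <- m$ld_mm[!is.na(m$ld_mm)]
  if (include_cr && any(!m$core_present)) vals <- c(vals, 0)
  min(c(series$baseline_ld_mm, vals))
}

#' Apply the study exclusion rules to a cohort table
#'
#' Rules, checked in the study's order with the first match logged:
#' * rule 3: T1c+ slice thickness >= 3 mm at any timepoint, or FLAIR missing;
#' * rule 4: histology other than NSCLC;
#' * rule 5: baseline (treatment-day) LD below 10 mm.
#'
#' Lesions with confluent peritumoral edema are retained for the 2-D (LD)
#' analyses but flagged for exclusion from edema-volume analyses, since
#' confluent edema cannot be attributed to a single core.
#'
#' @param df Cohort data frame (validated on entry).
#' @param min_ld_mm Baseline LD threshold, default 10.
#' @return List with `cohort` (retained rows), `log` (one row per excluded
#'   lesion: patient_id, lesion_id, rule, detail) and `edema_excluded`
#'   (data frame of confluent lesions kept for LD analyses only).
#'   The operation is idempotent.
#' @export
apply_exclusions <- function(df, min_ld_mm = 10) {
  df <- validate_cohort(df)
  key <- paste(df$patient_id, df$lesion_id, sep = "/")
  log <- data.frame(patient_id = character(0), lesion_id = character(0),
                    rule = character(0), detail = character(0))
  drop_keys <- character(0)
  edema_excl <- data.frame(patient_id = character(0), lesion_id = character(0))
  for (k in unique(key)) {
    m <- df[key == k, , drop = FALSE]
    rule <- detail <- NULL
    if (any(m$slice_thickness_mm >= 3, na.rm = TRUE) ||
        any(!m$flair_available, na.rm = TRUE)) {
      rule <- "3"
      detail <- "slice thickness >= 3 mm or FLAIR missing"
    } else if (any(!is.na(m$histology) & m$histology != "NSCLC")) {
      rule <- "4"
      detail <- "non-NSCLC histology"
    } else {
      bl <- m$ld_mm[m$days_from_srt == 0L & !is.na(m$ld_mm)]
      if (length(bl) && !.geq(bl[1L], min_ld_mm)) {
        rule <- "5"
        detail <- sprintf("baseline LD %.1f mm < %g mm", bl[1L], min_ld_mm)
      }
    }
    if (!is.null(rule)) {
      drop_keys <- c(drop_keys, k)
      log <- rbind(log, data.frame(patient_id = m$patient_id[1L],
                                   lesion_id = m$lesion_id[1L],
                                   rule = rule, detail = detail))
    } else if (any(m$confluent_edema, na.rm = TRUE)) {
      edema_excl <- rbind(edema_excl,
                          data.frame(patient_id = m$patient_id[1L],
                                     lesion_id = m$lesion_id[1L]))
    }
  }
  list(cohort = df[!key %in% drop_keys, , drop = FALSE],
       log = log, edema_excluded = edema_excl)
}
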