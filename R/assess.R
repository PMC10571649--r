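# The central pipeline: exclusions -> series assembly -> per-lesion
# assessment -> cohort tables (congruence ratios, window summaries, rank
# tests, pooled correlation, patient-level sums of LD).

#' Assess a cohort of irradiated brain metastases
#'
#' Runs the full response-assessment pipeline on a long-format measurement
#' table: applies the study exclusion rules, assembles per-lesion series with
#' their baselines, classifies every lesion-window (RANO-BM category, edema
#' grade, direction pair, congruence), labels trajectory patterns, and
#' compiles the cohort statistics -- per-window congruence ratios, median/IQR
#' summaries of relative LD and relative edema volume, paired signed-rank
#' tests of baseline versus first follow-up and of consecutive windows,
#' the pooled Spearman correlation of LD versus edema volume over all
#' lesion-timepoints, and patient-level sums of target-lesion LDs.
#'
#' @param cohort Data frame in the cohort schema (see [cohort_columns()]) or
#'   a path to such a CSV.
#' @param config An [analysis_config()].
#' @return Object of class `bm_response` with elements `labels` (one row per
#'   lesion-window), `patterns`, `congruence_by_window`, `window_summaries`,
#'   `tests`, `correlation`, `sum_ld`, `first_followup`, `exclusions`,
#'   `edema_excluded`, `series`, `config`, `n_patients`, `n_lesions`.
#'   Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' sim <- simulate_cohort(5, seed = 1)
#' fit <- assess_cohort(sim$cohort)
#' fit
#' head(as.data.frame(fit))
#' @export
assess_cohort <- function(cohort, config = analysis_config()) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  stopifnot(inherits(config, "analysis_config"))
  excl <- apply_exclusions(cohort, min_ld_mm = config$measurable_ld_mm)
  series <- build_lesion_series(excl$cohort)
  ee_keys <- paste(excl$edema_excluded$patient_id,
                   excl$edema_excluded$lesion_id, sep = "/")
  assessments <- lapply(series, function(s) {
    assess_lesion(s, config,
                  edema_excluded = paste(s$patient_id, s$lesion_id,
                                         sep = "/") %in% ee_keys)
  })

  labels <- do.call(rbind, lapply(assessments, function(a) {
    if (!nrow(a$labels)) return(NULL)
    cbind(patient_id = a$patient_id, lesion_id = a$lesion_id, a$labels)
  }))
  if (is.null(labels)) {
    labels <- data.frame(patient_id = character(0), lesion_id = character(0),
                         window = character(0), days_from_srt = integer(0),
                         ld_mm = numeric(0), rel_ld_pct = numeric(0),
                         edema_cm3 = numeric(0), rel_edema_pct = numeric(0),
                         rano = character(0), edema_grade = character(0),
                         core_direction = character(0),
                         edema_direction = character(0),
                         congruence = character(0))
  }
  rownames(labels) <- NULL

  patterns <- data.frame(
    patient_id = vapply(assessments, `[[`, "", "patient_id"),
    lesion_id = vapply(assessments, `[[`, "", "lesion_id"),
    core_pattern = vapply(assessments, `[[`, "", "core_pattern"),
    edema_pattern = vapply(assessments, `[[`, "", "edema_pattern"),
    incongruent_first_followup = vapply(assessments, function(a)
      as.logical(a$incongruent_first_followup), logical(1L)))
  rownames(patterns) <- NULL

  wlabs <- follow_up_windows(config$window_breaks)$label
  cong <- do.call(rbind, lapply(wlabs, function(w) {
    v <- labels$congruence[labels$window == w & !is.na(labels$congruence)]
    data.frame(window = w, n = length(v),
               n_congruent = sum(v == "congruent"),
               n_incongruent = sum(v == "incongruent"),
               pct_incongruent = if (length(v))
                 100 * sum(v == "incongruent") / length(v) else NA_real_)
  }))

  wsum <- do.call(rbind, lapply(wlabs, function(w) {
    rows <- labels[labels$window == w, , drop = FALSE]
    out <- NULL
    if (any(!is.na(rows$rel_ld_pct))) {
      out <- rbind(out, cbind(variable = "rel_ld_pct",
                              window_summary(rows$rel_ld_pct, w)))
    }
    if (any(!is.na(rows$rel_edema_pct))) {
      out <- rbind(out, cbind(variable = "rel_edema_pct",
                              window_summary(rows$rel_edema_pct, w)))
    }
    out
  }))

  lw <- function(var) {
    data.frame(lesion = paste(labels$patient_id, labels$lesion_id, sep = "/"),
               window = labels$window, value = labels[[var]])
  }
  tests <- list()
  for (var in c("rel_ld_pct", "rel_edema_pct")) {
    d <- lw(var)
    w1 <- d[d$window == wlabs[1L] & !is.na(d$value), ]
    if (nrow(w1) > 0L) {
      tests[[paste0(var, "_baseline_vs_W1")]] <-
        paired_signed_rank(rep(100, nrow(w1)), w1$value)
    }
    for (i in seq_len(length(wlabs) - 1L)) {
      nm <- paste0(var, "_", wlabs[i], "_vs_", wlabs[i + 1L])
      res <- tryCatch(
        suppressWarnings(compare_windows_paired(d, wlabs[i], wlabs[i + 1L])),
        error = function(e) NULL)
      if (!is.null(res)) tests[[nm]] <- res
    }
  }

  # pooled correlation over all lesion-timepoints with both measurements
  ok <- !is.na(labels$ld_mm) & !is.na(labels$edema_cm3)
  correlation <- if (sum(ok) >= 3L) {
    rank_correlation(labels$ld_mm[ok], labels$edema_cm3[ok])
  } else NULL

  # first-follow-up stratification: relative edema change for lesions whose
  # edema is increasing versus decreasing at W1
  fu1 <- labels[labels$window == wlabs[1L] &
                  labels$edema_direction %in% c("increasing", "decreasing") &
                  !is.na(labels$rel_edema_pct), , drop = FALSE]
  first_followup <- if (nrow(fu1) &&
                        length(unique(fu1$edema_direction)) == 2L) {
    stratified_summaries(fu1$rel_edema_pct, fu1$edema_direction, wlabs[1L])
  } else NULL

  sum_ld <- do.call(rbind, lapply(split(series,
                                        vapply(series, `[[`, "", "patient_id")),
                                  function(sl) {
    sums <- vapply(c("baseline", wlabs), function(w) {
      suppressWarnings(
        patient_sum_ld(sl, w, config$max_target_lesions,
                       config$measurable_ld_mm, config$measurable_perp_mm,
                       config$window_breaks))
    }, numeric(1L))
    data.frame(patient_id = sl[[1L]]$patient_id,
               window = c("baseline", wlabs), sum_ld_mm = sums)
  }))
  rownames(sum_ld) <- NULL

  structure(list(labels = labels, patterns = patterns,
                 congruence_by_window = cong, window_summaries = wsum,
                 tests = tests, correlation = correlation,
                 first_followup = first_followup, sum_ld = sum_ld,
                 exclusions = excl$log, edema_excluded = excl$edema_excluded,
                 series = series, config = config,
                 n_patients = length(unique(excl$cohort$patient_id)),
                 n_lesions = length(series)),
            class = "bm_response")
}

#' @export
print.bm_response <- function(x, ...) {
  cat(sprintf("<bm_response> %d patients, %d lesions (%d excluded, %d edema-excluded)\n",
              x$n_patients, x$n_lesions, nrow(x$exclusions),
              nrow(x$edema_excluded)))
  cat("Congruence of core vs edema response by window:\n")
  print(x$congruence_by_window, row.names = FALSE, digits = 3)
  if (!is.null(x$correlation)) {
    cat(sprintf("Pooled Spearman LD vs edema volume: rho = %.2f (p = %.3g, n = %d)\n",
                x$correlation$rho, x$correlation$p_value, x$correlation$n))
  }
  invisible(x)
}

#' @export
summary.bm_response <- function(object, ...) {
  structure(list(fit = object), class = "summary.bm_response")
}

#' @export
print.summary.bm_response <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nWindow summaries (median [IQR] of relative size, %):\n")
  print(f$window_summaries, row.names = FALSE, digits = 3)
  cat("\nEdema trajectory patterns:\n")
  print(table(f$patterns$edema_pattern, useNA = "ifany"))
  cat("\nIncongruent at first follow-up:",
      sum(f$patterns$incongruent_first_followup, na.rm = TRUE), "of",
      sum(!is.na(f$patterns$incongruent_first_followup)), "lesions\n")
  if (length(f$tests)) {
    cat("\nRank tests:\n")
    for (nm in names(f$tests)) {
      t <- f$tests[[nm]]
      cat(sprintf("  %-34s p = %.4g (n = %s)\n", nm, t$p_value,
                  paste(t$n, collapse = "/")))
    }
  }
  invisible(x)
}

#' Plot response curves of a fitted assessment
#'
#' Spaghetti plot of per-lesion relative size (percent of baseline) against
#' days from treatment: tumor-core LD in the left panel, peritumoral edema
#' volume in the right, both on a log scale with the baseline at 100%.
#'
#' @param x A `bm_response`.
#' @param max_lesions Cap on the number of lesion curves drawn per panel.
#' @param ... Passed to [graphics::matplot()]-style internals (unused).
#' @export
plot.bm_response <- function(x, max_lesions = 40, ...) {
  lab <- x$labels
  keys <- unique(paste(lab$patient_id, lab$lesion_id, sep = "/"))
  keys <- keys[seq_len(min(length(keys), max_lesions))]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(var, main) {
    ok <- lab[!is.na(lab[[var]]) & lab[[var]] > 0, , drop = FALSE]
    if (!nrow(ok)) {
      graphics::plot.new()
      graphics::title(main = paste(main, "(no data)"))
      return(invisible())
    }
    graphics::plot(NA, xlim = c(0, max(ok$days_from_srt)),
                   ylim = range(ok[[var]]), log = "y",
                   xlab = "days from SRT", ylab = "% of baseline",
                   main = main)
    graphics::abline(h = 100, lty = 3)
    for (k in keys) {
      r <- ok[paste(ok$patient_id, ok$lesion_id, sep = "/") == k, ,
              drop = FALSE]
      if (nrow(r)) {
        graphics::lines(c(0, r$days_from_srt), c(100, r[[var]]),
                        col = grDevices::adjustcolor("steelblue", 0.5))
      }
    }
  }
  panel("rel_ld_pct", "Tumor core LD")
  panel("rel_edema_pct", "Peritumoral edema volume")
  invisible(x)
}

#' @export
as.data.frame.bm_response <- function(x, ...) x$labels
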