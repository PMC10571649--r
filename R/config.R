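# Analysis configuration: every threshold of the pipeline in one place, with
# the published defaults, serializable to JSON so a report can state exactly
# what produced it.

#' Analysis configuration
#'
#' All tunable thresholds with their published defaults: partial response
#' at a >= 30% LD decrease from baseline, progression at a >= 20% LD increase
#' from nadir, the 25% stable band of the edema grading, measurability at
#' LD >= 10 mm with perpendicular >= 5 mm, the five follow-up windows, the
#' direction dead-band (0: any strict change is directional) and the strict
#' congruence reading (a jointly unchanged pair is incongruent unless
#' `stable_congruent`).
#'
#' @param pr_pct Partial-response threshold, percent decrease from baseline.
#' @param pd_pct Progression threshold, percent increase from nadir.
#' @param edema_band_pct Stable-band half-width of the edema grading, percent.
#' @param measurable_ld_mm,measurable_perp_mm Measurability thresholds, mm.
#' @param window_breaks Follow-up window boundaries in days, ending in `Inf`.
#' @param direction_epsilon_pct Dead-band for direction labels, percent.
#' @param stable_congruent Treat (unchanged, unchanged) as congruent?
#' @param max_target_lesions Cap for the patient-level sum of LDs.
#' @param seed Optional integer seed recorded with reports.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(pr_pct = 30, pd_pct = 20, edema_band_pct = 25,
                            measurable_ld_mm = 10, measurable_perp_mm = 5,
                            window_breaks = c(0, 90, 180, 270, 365, Inf),
                            direction_epsilon_pct = 0,
                            stable_congruent = FALSE,
                            max_target_lesions = 5, seed = NULL) {
  stopifnot(pr_pct > 0, pd_pct > 0, edema_band_pct > 0,
            measurable_ld_mm > 0, measurable_perp_mm > 0,
            direction_epsilon_pct >= 0, max_target_lesions >= 1)
  window_breaks <- as.numeric(window_breaks)
  if (window_breaks[1L] != 0 || is.finite(window_breaks[length(window_breaks)]) ||
      is.unsorted(window_breaks, strictly = TRUE)) {
    stop("window_breaks must be strictly increasing, start at 0 and end in Inf")
  }
  structure(list(pr_pct = pr_pct, pd_pct = pd_pct,
                 edema_band_pct = edema_band_pct,
                 measurable_ld_mm = measurable_ld_mm,
                 measurable_perp_mm = measurable_perp_mm,
                 window_breaks = window_breaks,
                 direction_epsilon_pct = direction_epsilon_pct,
                 stable_congruent = stable_congruent,
                 max_target_lesions = as.integer(max_target_lesions),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  PR >= %g%% decrease from baseline; PD >= %g%% increase from nadir\n",
              x$pr_pct, x$pd_pct))
  cat(sprintf("  edema stable band: |change| < %g%%\n", x$edema_band_pct))
  cat(sprintf("  measurable: LD >= %g mm, perpendicular >= %g mm\n",
              x$measurable_ld_mm, x$measurable_perp_mm))
  cat(sprintf("  windows (days): %s\n",
              paste(x$window_breaks, collapse = ", ")))
  cat(sprintf("  direction epsilon %g%%; unchanged pair congruent: %s\n",
              x$direction_epsilon_pct, x$stable_congruent))
  invisible(x)
}

#' Write / read an analysis configuration as JSON
#'
#' The round trip is lossless; the open upper window bound is stored as the
#' list of finite boundaries and restored to `Inf` on read.
#'
#' @param config An [analysis_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  lst <- unclass(config)
  lst$window_breaks <- lst$window_breaks[is.finite(lst$window_breaks)]
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config`: the restored `analysis_config`.
#' @export
read_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, c(
    lst[setdiff(names(lst), "window_breaks")],
    list(window_breaks = c(lst$window_breaks, Inf))))
}
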