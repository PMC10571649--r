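# Cohort statistics: median/IQR window summaries, Wilcoxon signed-rank and
# Mann-Whitney rank-sum tests (exact where small, normal approximation with
# tie correction otherwise), Spearman rank correlation, and stratified
# descriptive comparisons. Test machinery is base R's; the conventions
# (zero-difference dropping, exactness cutoffs, quartile type) are declared
# here and mirrored by the enumeration oracles in the test suite.

#' Median and interquartile range of a window's values
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile(type = 7)`, the widespread default convention).
#'
#' @param values Numeric values (NAs dropped); must leave at least one.
#' @param window Optional window label carried into the output.
#' @return One-row data frame: `window`, `n`, `median`, `q1`, `q3`.
#' @export
window_summary <- function(values, window = NA_character_) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("window_summary: no values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(window = window, n = length(values),
             median = q[2L], q1 = q[1L], q3 = q[3L])
}

.rank_test_result <- function(statistic, p_value, n, method,
                              degenerate = FALSE, rho = NULL) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n = n, method = method, alpha = 0.05,
                 degenerate = degenerate, rho = rho),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$rho)) cat(sprintf("  rho = %.4f\n", x$rho))
  cat(sprintf("  statistic = %s, p = %.4g, n = %s%s\n",
              format(x$statistic), x$p_value, paste(x$n, collapse = "/"),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired pre/post values (pairs aligned by lesion).
#' Zero differences are dropped (a declared convention -- it changes n);
#' the null distribution is exact for n <= 25 without tied absolute
#' differences, otherwise the normal approximation with tie correction is
#' used. All differences zero gives a degenerate result with p = 1.
#'
#' @param pre,post Equal-length numeric vectors; pairs with an NA are dropped.
#' @return A `rank_test` object (statistic = V, `n` = pairs after dropping
#'   zeros, `n_zero` attribute in `n` reporting).
#' @export
paired_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be equal length")
  keep <- !(is.na(pre) | is.na(post))
  d <- post[keep] - pre[keep]
  nz <- d != 0
  n <- sum(nz)
  if (n == 0L) {
    return(.rank_test_result(NA_real_, 1, 0,
                             "Wilcoxon signed-rank (two-sided)",
                             degenerate = TRUE))
  }
  d <- d[nz]
  exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  .rank_test_result(wt$statistic, wt$p.value, n,
                    sprintf("Wilcoxon signed-rank (two-sided, %s, %d zero pairs dropped)",
                            if (exact) "exact" else "normal approx.",
                            sum(!nz)))
}

#' Two-sample Mann-Whitney rank-sum test
#'
#' Two-tailed rank-sum comparison of two independent groups; exact when the
#' smaller sample has at most 8 observations and there are no ties across
#' groups, normal approximation with tie correction otherwise.
#'
#' @param a,b Numeric vectors (NAs dropped); both non-empty.
#' @return A `rank_test` object (statistic = U of the first group).
#' @export
two_sample_rank <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- min(length(a), length(b)) <= 8 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  degenerate <- is.nan(p)   # zero rank variance: every pooled value tied
  if (degenerate) p <- 1
  .rank_test_result(wt$statistic, p, c(length(a), length(b)),
                    sprintf("Mann-Whitney rank-sum (two-tailed, %s)",
                            if (exact) "exact" else "normal approx."),
                    degenerate = degenerate)
}

# all permutations of 1..n as an (n!) x n integer matrix, built recursively
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    vals <- seq_len(n)[-k]
    cbind(rep(k, nrow(p)), matrix(vals[p], nrow(p)))
  }))
}

#' Spearman rank correlation between core LD and edema volume
#'
#' Spearman's rho with average ranks for ties. The two-sided p-value comes
#' from full permutation enumeration for n <= 10 and from the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom otherwise. Pairs are typically pooled across all lesion-timepoints
#' (the study's convention; within-lesion dependence is ignored and flagged
#' in reports).
#'
#' @param x,y Paired numeric vectors (pairs with an NA dropped); at least 3
#'   complete pairs.
#' @return A `rank_test` with `rho`; a constant input on either axis yields
#'   `rho = NA` and a degenerate flag.
#' @export
rank_correlation <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("rank correlation needs at least 3 pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(.rank_test_result(NA_real_, NA_real_, n,
                             "Spearman rank correlation (degenerate: constant input)",
                             degenerate = TRUE, rho = NA_real_))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    perms <- .all_perms(n)
    s <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    rho_all <- (s - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "Spearman rank correlation (t approximation)"
  }
  .rank_test_result(rho, min(p, 1), n, method, rho = rho)
}

#' Stratified window summaries with a rank-sum comparison
#'
#' Purely descriptive group comparison (e.g. by steroid exposure or vital
#' status): per-group n/median/IQR and, when exactly two non-empty groups are
#' present, a two-tailed rank-sum test. No causal claims.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (same length).
#' @param window Optional label carried through.
#' @return List with `summaries` (data frame, one row per group) and `test`
#'   (`rank_test`, or `NULL` with a `note` when not comparable).
#' @export
stratified_summaries <- function(values, group, window = NA_character_) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group[keep])
  if (!length(values)) stop("no values to summarize")
  gs <- split(values, group)
  summ <- do.call(rbind, lapply(names(gs), function(g) {
    s <- window_summary(gs[[g]], window)
    cbind(group = g, s)
  }))
  if (length(gs) == 2L) {
    list(summaries = summ, test = two_sample_rank(gs[[1L]], gs[[2L]]))
  } else {
    list(summaries = summ, test = NULL,
         note = sprintf("%d group(s); rank-sum comparison needs exactly 2",
                        length(gs)))
  }
}

#' Paired comparison of one variable across two follow-up windows
#'
#' The study compares e.g. the 91-180 and 181-270 day windows although
#' different lesion subsets are present in each; the pairing here is on the
#' intersection of lesions carrying a value in both windows (a declared
#' convention).
#'
#' @param df Data frame with columns `lesion`, `window`, `value` (one row per
#'   lesion-window).
#' @param w1,w2 The two window labels.
#' @return A `rank_test` from [paired_signed_rank()]; `NULL` with a warning
#'   when no lesion appears in both windows.
#' @export
compare_windows_paired <- function(df, w1, w2) {
  a <- df[df$window == w1 & !is.na(df$value), c("lesion", "value")]
  b <- df[df$window == w2 & !is.na(df$value), c("lesion", "value")]
  common <- intersect(a$lesion, b$lesion)
  if (!length(common)) {
    warning("no lesions present in both windows; comparison skipped")
    return(NULL)
  }
  paired_signed_rank(a$value[match(common, a$lesion)],
                     b$value[match(common, b$lesion)])
}
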