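## ---------------------------------------------------------------------------
## Group comparisons (signed-rank / Kolmogorov-Smirnov), time-course
## summaries with edge segments, rest-vs-task shift analysis, box-plot
## statistics under the w = 2 fence rule, and report rendering.
## ---------------------------------------------------------------------------

#' Nonparametric group comparison
#'
#' Dispatches the Wilcoxon signed-rank test for paired groups (zero
#' differences dropped, the standard convention) and the two-sample
#' Kolmogorov-Smirnov test for unpaired ones; two-sided p-values.
#'
#' @param a,b numeric samples; for `paired = TRUE` they must be matched
#'   by subject order and of equal length.
#' @param paired logical.
#' @return a `group_comparison` list with `test`, `statistic`, `p`,
#'   `paired`, `n`, and `degenerate` (all paired differences zero).
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stopf("paired comparison requires matched, equal-length samples")
  if (min(length(a), length(b)) < 5)
    warnf("fewer than 5 observations per group")
  if (paired) {
    d <- a - b
    if (all(d == 0)) {
      out <- list(test = "wilcoxon-signed-rank", statistic = 0, p = 1,
                  paired = TRUE, n = length(a), degenerate = TRUE)
      class(out) <- "group_comparison"
      return(out)
    }
    ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
  } else {
    ht <- suppressWarnings(ks.test(a, b))
  }
  out <- list(test = if (paired) "wilcoxon-signed-rank" else "kolmogorov-smirnov",
              statistic = unname(ht$statistic), p = ht$p.value,
              paired = paired, n = c(length(a), length(b)),
              degenerate = FALSE)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g%s\n",
              x$test, x$statistic, x$p,
              if (x$degenerate) " (all differences zero)" else ""))
  invisible(x)
}

#' Cross-subject time-course summary with edge segments
#'
#' Smooths each subject's series with a centred moving average, aligns
#' subjects to the episode start (leading segment) and separately to the
#' episode end (trailing segment), and returns the cross-subject mean and
#' standard deviation on the common grid. Task episodes differ in length
#' across subjects, so only the first and last `edge_s` seconds are
#' aggregated.
#'
#' @param series_list list of numeric per-subject series (one episode
#'   each, uniform rate).
#' @param rate sampling rate (Hz).
#' @param smooth_s moving-average window (s), default 10.
#' @param edge_s edge-segment length (s), default 40.
#' @return a `timecourse_summary` list with `t_start`, `mean_start`,
#'   `sd_start`, `t_end`, `mean_end`, `sd_end` (times relative to episode
#'   start / end).
#' @export
timecourse_summary <- function(series_list, rate, smooth_s = 10, edge_s = 40) {
  if (length(series_list) < 2) stopf("need at least 2 subjects")
  ns <- round(edge_s * rate)
  if (any(vapply(series_list, length, integer(1)) < ns))
    stopf("a subject's series is shorter than the edge segment")
  sm <- lapply(series_list, smooth_timecourse, rate = rate, window_s = smooth_s)
  lead <- do.call(rbind, lapply(sm, function(x) x[seq_len(ns)]))
  trail <- do.call(rbind, lapply(sm, function(x) x[(length(x) - ns + 1):length(x)]))
  structure(list(
    t_start = (seq_len(ns) - 1) / rate,
    mean_start = colMeans(lead), sd_start = apply(lead, 2, sd),
    t_end = (seq_len(ns) - ns) / rate,
    mean_end = colMeans(trail), sd_end = apply(trail, 2, sd),
    n_subjects = length(series_list)
  ), class = "timecourse_summary")
}

#' Rest-vs-task shift analysis
#'
#' How the change of a metric from rest to task depends on its resting
#' value: returns the (rest, task) scatter pairs, the correlation between
#' rest and task values, and the regression of the change (task - rest)
#' on the resting value. A near-zero slope means the shift is independent
#' of the starting point; a slope near -1 with strongly negative r is the
#' regression-to-the-mean signature of a floor-limited metric.
#'
#' @param rest,task numeric per-subject values, matched by position.
#' @return a `rest_task_shift` list with `pairs`, `r_rest_task`,
#'   `delta_slope`, `delta_intercept`, `delta_r`.
#' @export
rest_task_shift <- function(rest, task) {
  if (length(rest) != length(task))
    stopf("rest and task must be matched per subject")
  ok <- is.finite(rest) & is.finite(task)
  rest <- rest[ok]; task <- task[ok]
  if (length(rest) < 3) stopf("need at least 3 matched subjects")
  d <- task - rest
  fit <- lm(d ~ rest)
  structure(list(
    pairs = data.frame(rest = rest, task = task, delta = d),
    r_rest_task = if (sd(rest) > 0 && sd(task) > 0) cor(rest, task) else NA_real_,
    delta_slope = unname(coef(fit)[2]),
    delta_intercept = unname(coef(fit)[1]),
    delta_r = if (sd(rest) > 0 && sd(d) > 0) cor(rest, d) else NA_real_
  ), class = "rest_task_shift")
}

#' Box-plot statistics with the w = 2 fence rule
#'
#' Median, quartiles (linear interpolation of order statistics), whiskers
#' (most extreme values within `q1 - w IQR` and `q3 + w IQR`) and the
#' flagged outliers.
#'
#' @param x numeric vector.
#' @param w fence constant, default 2.
#' @return list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `n`.
#' @export
boxplot_stats <- function(x, w = 2) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - w * iqr; hi <- q[3] + w * iqr
  inside <- x >= lo & x <= hi
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = if (any(inside)) min(x[inside]) else NA_real_,
       whisker_hi = if (any(inside)) max(x[inside]) else NA_real_,
       outliers = sort(x[!inside]), n = length(x))
}

#' Render a report directory
#'
#' Writes CSV tables (the prediction-performance table, per-group
#' box-plot summaries, group comparisons), plus a markdown summary and a
#' JSON manifest with the MD5 hash of every file, so that every reported
#' number is traceable to its inputs. Deterministic: regeneration from
#' identical inputs is byte-identical.
#'
#' @param results named list; recognised elements are
#'   `prediction_table` (from [build_prediction_table()]),
#'   `features`, `targets` (aligned data.frames), `comparisons` (named
#'   list of `group_comparison`s), and `boxplots` (named list of numeric
#'   vectors summarised under the w = 2 rule).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list. Missing inputs are listed in the
#'   manifest and a partial report is produced.
#' @export
render_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  missing <- setdiff(c("prediction_table", "features", "targets"),
                     names(results))
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, name)
  }
  if (!is.null(results$prediction_table))
    wcsv(results$prediction_table, "prediction_table.csv")
  if (!is.null(results$features)) wcsv(results$features, "features.csv")
  if (!is.null(results$targets)) wcsv(results$targets, "targets.csv")
  if (!is.null(results$comparisons)) {
    cmp <- do.call(rbind, lapply(names(results$comparisons), function(nm) {
      x <- results$comparisons[[nm]]
      data.frame(comparison = nm, test = x$test,
                 statistic = x$statistic, p = x$p, paired = x$paired)
    }))
    wcsv(cmp, "group_comparisons.csv")
  }
  if (!is.null(results$boxplots)) {
    bx <- do.call(rbind, lapply(names(results$boxplots), function(nm) {
      b <- boxplot_stats(results$boxplots[[nm]])
      data.frame(group = nm, median = b$median, q1 = b$q1, q3 = b$q3,
                 whisker_lo = b$whisker_lo, whisker_hi = b$whisker_hi,
                 n_outliers = length(b$outliers), n = b$n)
    }))
    wcsv(bx, "boxplot_stats.csv")
  }
  md <- c("# Analysis report", "",
          sprintf("Tables written: %s",
                  if (length(written)) paste(written, collapse = ", ") else "none"),
          if (length(missing))
            sprintf("Missing inputs: %s", paste(missing, collapse = ", ")))
  writeLines(md, file.path(dir, "report.md"))
  written <- c(written, "report.md")
  manifest <- list(
    files = as.list(tools::md5sum(file.path(dir, written))),
    missing_inputs = missing
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
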