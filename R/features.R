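## ---------------------------------------------------------------------------
## Per-episode feature summarisation, behavioural metrics, outlier rule,
## and assembly of aligned feature / target tables.
## ---------------------------------------------------------------------------

#' Per-episode physiological features
#'
#' Mean, standard deviation, maximum and minimum of heart rate and of the
#' windowed HRV series within the episode, plus the episode-mean blink
#' rate (blinks are too sparse for within-episode statistics beyond the
#' mean).
#'
#' @param hr a `heart_rate_series`.
#' @param hrv an `hrv_series` (window-centre timestamps).
#' @param blinks a `blink_events` or `NULL`.
#' @param episode one row of a [session_layout()] (or a list with
#'   `episode`, `label`, `start`, `end`).
#' @param subject_id subject identifier.
#' @param removed_intervals excised EEG fragments, passed to
#'   [blink_rate()].
#' @return one-row data.frame with columns `subject`, `episode`, `label`,
#'   `hr_mean`, `hr_std`, `hr_max`, `hr_min`, `hrv_mean`, `hrv_std`,
#'   `hrv_max`, `hrv_min`, `br_mean`. Features whose series do not cover
#'   the episode are `NA`.
#' @export
episode_summary_features <- function(hr, hrv, blinks, episode,
                                     subject_id = "S01",
                                     removed_intervals = NULL) {
  span <- c(episode$start, episode$end)
  hsel <- hr$t >= span[1] & hr$t < span[2]
  vsel <- hrv$t >= span[1] & hrv$t < span[2]
  stat4 <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(mean(x), sd(x), max(x), min(x))
  }
  h <- stat4(hr$hr[hsel])
  v <- stat4(hrv$hrv[vsel])
  data.frame(
    subject = subject_id, episode = episode$episode, label = episode$label,
    hr_mean = h[1], hr_std = h[2], hr_max = h[3], hr_min = h[4],
    hrv_mean = v[1], hrv_std = v[2], hrv_max = v[3], hrv_min = v[4],
    br_mean = blink_rate(blinks, span, removed_intervals)
  )
}

#' Secondary-task reaction time and non-response rate
#'
#' A stimulus counts as responded only when its response arrives before
#' the next stimulus onset (the final stimulus has no successor and only
#' needs any response). Reaction time is aggregated over responded
#' stimuli.
#'
#' @param log secondary-task log: data.frame with `onset` (s) and
#'   `response_time` (absolute s, `NA` for no response).
#' @param episode `c(start, end)` in seconds, or a layout row.
#' @param aggregate `"mean"` (default) or `"median"` reaction-time
#'   aggregate.
#' @return list with `reaction_time` (s), `non_response_rate` (fraction),
#'   `n_stimuli`; `NA` values when the episode has no stimuli.
#' @export
secondary_task_metrics <- function(log, episode, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (is.list(episode) && !is.null(episode$start))
    episode <- c(episode$start, episode$end)
  sel <- log$onset >= episode[1] & log$onset < episode[2]
  if (!any(sel))
    return(list(reaction_time = NA_real_, non_response_rate = NA_real_,
                n_stimuli = 0L))
  onset <- log$onset[sel]
  resp <- log$response_time[sel]
  o <- order(onset); onset <- onset[o]; resp <- resp[o]
  nxt <- c(onset[-1], Inf)
  responded <- !is.na(resp) & resp < nxt
  rt <- resp[responded] - onset[responded]
  agg <- if (aggregate == "mean") mean else median
  list(
    reaction_time = if (length(rt)) agg(rt) else NA_real_,
    non_response_rate = mean(!responded),
    n_stimuli = length(onset)
  )
}

#' Moving-average smoothing of a uniformly sampled series
#'
#' Centred moving average over `window_s` seconds, with the window
#' shrinking symmetrically at the edges.
#'
#' @param x numeric series.
#' @param rate sampling rate (Hz).
#' @param window_s window length (s), default 10.
#' @return smoothed series, same length as `x`.
#' @export
smooth_timecourse <- function(x, rate, window_s = 10) {
  if (window_s <= 0) stopf("window_s must be positive")
  n <- length(x)
  half <- max(0, floor(window_s * rate / 2))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Quartile-fence outlier rule
#'
#' Flags values outside `[q1 - w * IQR, q3 + w * IQR]`, with quartiles by
#' linear interpolation of order statistics and the box-whisker constant
#' `w = 2`.
#'
#' @param values numeric vector.
#' @param w whisker constant, default 2.
#' @return logical mask (`TRUE` = outlier). With fewer than 4 finite
#'   values, an all-`FALSE` mask with a warning.
#' @export
detect_outliers <- function(values, w = 2) {
  ok <- is.finite(values)
  if (sum(ok) < 4) {
    warnf("fewer than 4 values; no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values > q[2] + w * iqr | values < q[1] - w * iqr
  out & ok
}

#' Assemble aligned feature and target tables
#'
#' Pools the task episodes (one row per subject x task episode) and joins
#' physiological features with workload targets on exact subject/episode
#' keys. The predictor source is selectable: the task episodes themselves
#' (default), the subject's first rest episode (replicated across task
#' rows), or the task-minus-first-rest change.
#'
#' @param features data.frame of per-episode features (rows from
#'   [episode_summary_features()], all episodes).
#' @param targets data.frame of per-task-episode targets with `subject`,
#'   `label` and target columns.
#' @param pooling task labels to pool, default `Task1`, `Task2`, `Task1R`.
#' @param predictor_source `"task"`, `"rest"` or `"delta"`.
#' @param feature_cols feature column names used as predictors.
#' @return list with aligned `features` and `targets` data.frames (equal
#'   row counts, matching `subject`/`label` keys). Rows with a missing
#'   episode on either side are dropped with a warning.
#' @export
assemble_feature_target_tables <- function(features, targets,
                                           pooling = c("Task1", "Task2", "Task1R"),
                                           predictor_source = c("task", "rest", "delta"),
                                           feature_cols = c("hr_mean", "hr_std",
                                                            "hr_max", "hr_min",
                                                            "hrv_mean", "hrv_std",
                                                            "hrv_max", "hrv_min",
                                                            "br_mean")) {
  predictor_source <- match.arg(predictor_source)
  ft <- features[features$label %in% pooling, , drop = FALSE]
  tg <- targets[targets$label %in% pooling, , drop = FALSE]
  fkey <- paste(ft$subject, ft$label)
  tkey <- paste(tg$subject, tg$label)
  common <- intersect(fkey, tkey)
  missing <- union(setdiff(fkey, tkey), setdiff(tkey, fkey))
  if (length(missing))
    warnf("dropping %d unmatched subject/episode row(s): %s",
          length(missing), paste(head(missing, 5), collapse = ", "))
  ft <- ft[match(common, fkey), , drop = FALSE]
  tg <- tg[match(common, tkey), , drop = FALSE]
  if (predictor_source != "task") {
    rest <- features[features$label %in% c("Rest", "Baseline"), , drop = FALSE]
    rest <- rest[order(rest$subject, rest$episode), , drop = FALSE]
    first_rest <- rest[rest$label == "Rest", , drop = FALSE]
    first_rest <- first_rest[!duplicated(first_rest$subject), , drop = FALSE]
    ridx <- match(ft$subject, first_rest$subject)
    if (anyNA(ridx)) stopf("missing first rest episode for subject(s): %s",
                           paste(unique(ft$subject[is.na(ridx)]), collapse = ", "))
    rmat <- first_rest[ridx, feature_cols, drop = FALSE]
    if (predictor_source == "rest") {
      ft[feature_cols] <- rmat
    } else {
      ft[feature_cols] <- ft[feature_cols] - rmat
    }
  }
  rownames(ft) <- rownames(tg) <- NULL
  list(features = ft, targets = tg)
}

#' Per-subject feature extraction from a simulated bundle
#'
#' Runs the fNIRS cardiac chain, summarises every episode, and computes
#' the behavioural metrics from the secondary-task log. Blink events come
#' either from the full EEG chain (when `eeg_events` is supplied) or from
#' the bundle's ground-truth blink times.
#'
#' @param bundle one subject bundle from [simulate_cohort()].
#' @param eeg_events optional `blink_events` from [eeg_blinks_chain()].
#' @param hrv_window_s,hrv_step_s HRV sliding-window parameters.
#' @param use_truth logical; with `TRUE` the physiological features are
#'   computed from the ground-truth heart rate (no optical extraction),
#'   which isolates the statistical pathway from recovery noise.
#' @return list with `features` (one row per episode) and `targets` (one
#'   row per task episode, including reaction time and non-response rate).
#' @export
extract_subject_features <- function(bundle, eeg_events = NULL,
                                     hrv_window_s = 30, hrv_step_s = 1,
                                     use_truth = FALSE) {
  lay <- bundle$layout
  rate <- if (!is.null(bundle$optical)) bundle$optical$rate
          else round(1 / (bundle$truth$t[2] - bundle$truth$t[1]))
  if (use_truth) {
    hr <- structure(list(t = bundle$truth$t, hr = bundle$truth$true_hr,
                         rate = rate), class = "heart_rate_series")
    hrv <- compute_hrv_series(hr, window_s = hrv_window_s, step_s = hrv_step_s)
  } else {
    chain <- fnirs_cardiac_chain(bundle$optical, hrv_window_s = hrv_window_s,
                                 hrv_step_s = hrv_step_s)
    hr <- chain$hr; hrv <- chain$hrv
  }
  blinks <- eeg_events %||%
    structure(list(times = bundle$truth$true_blink_times, component = NA_integer_),
              class = "blink_events")
  feats <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i)
    episode_summary_features(hr, hrv, blinks, lay[i, ],
                             subject_id = bundle$subject_id)))
  tg <- bundle$targets
  if (!is.null(tg) && nrow(tg)) {
    stm <- lapply(seq_len(nrow(tg)), function(i) {
      row <- lay[lay$episode == tg$episode[i], ]
      secondary_task_metrics(bundle$task_log, row)
    })
    tg$reaction_time <- vapply(stm, `[[`, numeric(1), "reaction_time")
    tg$non_response_rate <- vapply(stm, `[[`, numeric(1), "non_response_rate")
    tg$subject <- bundle$subject_id
  }
  list(features = feats, targets = tg)
}
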