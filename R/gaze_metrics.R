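# Dynamic area-of-interest gaze analysis: quality-based exclusions, glance
# detection against circular AOI tracks, and the four per-participant
# summary statistics (percentage of targets looked at, glance frequency,
# first-glance latency, total dwell per looked-at target).

#' Effective sample rate of a gaze stream
#'
#' `(n_samples - 1) / (t_last - t_first)` in Hz.
#'
#' @param samples Data.frame with a `t_s` column.
#' @return Rate in Hz (NA for fewer than 2 samples).
#' @export
effective_sample_rate <- function(samples) {
  n <- nrow(samples)
  if (n < 2L) return(NA_real_)
  span <- samples$t_s[n] - samples$t_s[1]
  if (span <= 0) return(NA_real_)
  (n - 1) / span
}

#' Apply the gaze quality exclusion rules
#'
#' Drops a participant whose nine-point calibration error exceeds
#' `max_calibration_error` (or who carries a manual-inspection flag), and
#' drops individual clips whose effective sample rate is below
#' `min_sample_rate`. Never raises; every drop is logged with its reason.
#'
#' @param quality Data.frame with `participant_id`, `calibration_error`,
#'   `clip_id` (or `target_id`), `effective_rate`, and optionally
#'   `manual_exclude`.
#' @param max_calibration_error Degrees; default 2.
#' @param min_sample_rate Hz; default 5.
#' @return List with `retained` (quality rows kept) and `log` (data.frame
#'   `participant_id`, `clip_id`, `reason`).
#' @export
apply_exclusions <- function(quality, max_calibration_error = 2,
                             min_sample_rate = 5) {
  log <- data.frame(participant_id = character(0), clip_id = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  q <- quality
  bad_cal <- q$calibration_error > max_calibration_error
  if ("manual_exclude" %in% names(q))
    bad_cal <- bad_cal | isTRUE_vec(q$manual_exclude)
  bad_pid <- unique(q$participant_id[bad_cal])
  if (length(bad_pid)) {
    log <- rbind(log, data.frame(
      participant_id = bad_pid, clip_id = NA_character_,
      reason = sprintf("calibration error > %g degrees (or manual flag)",
                       max_calibration_error),
      stringsAsFactors = FALSE))
    q <- q[!(q$participant_id %in% bad_pid), ]
  }
  slow <- !is.na(q$effective_rate) & q$effective_rate < min_sample_rate
  if (any(slow)) {
    log <- rbind(log, data.frame(
      participant_id = q$participant_id[slow],
      clip_id = if ("clip_id" %in% names(q)) q$clip_id[slow] else NA_character_,
      reason = sprintf("effective sample rate < %g Hz", min_sample_rate),
      stringsAsFactors = FALSE))
    q <- q[!slow, ]
  }
  list(retained = q, log = log)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# circle of a track at time t (linear interpolation between keyframes)
track_at <- function(track, t) {
  kf <- track$keyframes
  if (is.null(kf)) {           # constant-circle track row
    return(list(x = rep(track$x, length(t)), y = rep(track$y, length(t)),
                radius = rep(track$radius, length(t))))
  }
  list(x = stats::approx(kf$t_s, kf$x, t, rule = 2)$y,
       y = stats::approx(kf$t_s, kf$y, t, rule = 2)$y,
       radius = stats::approx(kf$t_s, kf$radius, t, rule = 2)$y)
}

#' Detect glances to a dynamic AOI
#'
#' A glance is a maximal run of valid in-circle samples lasting at least
#' `min_glance` seconds; runs separated by gaps of at most `max_gap`
#' seconds are merged first. Samples before the target appears or after
#' the mask are ignored; invalid samples break runs but count toward gap
#' duration.
#'
#' @param samples Gaze stream (`t_s`, `x`, `y`, `valid`).
#' @param track One AOI track: list/row with `appear_time`, `end_time`,
#'   `x`, `y`, `radius` (constant circle) or a `keyframes` data.frame.
#' @param min_glance Minimum glance duration (s), default 0.1.
#' @param max_gap Maximum merged gap (s), default 0.075.
#' @return Data.frame of glance events: `onset`, `offset`, `dwell`.
#' @export
detect_glances <- function(samples, track, min_glance = 0.1,
                           max_gap = 0.075) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      dwell = numeric(0))
  keep <- samples$t_s >= track$appear_time & samples$t_s <= track$end_time
  s <- samples[keep, , drop = FALSE]
  if (nrow(s) == 0L) return(empty)
  circ <- track_at(track, s$t_s)
  inside <- s$valid &
    (s$x - circ$x)^2 + (s$y - circ$y)^2 <= circ$radius^2
  if (!any(inside)) return(empty)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(onset = s$t_s[starts[r$values]],
                     offset = s$t_s[ends[r$values]])
  # merge runs split by short gaps; the interruption starts one sample
  # period after the last in-AOI sample, so discount one period
  period <- stats::median(diff(s$t_s))
  if (!is.finite(period)) period <- 0
  if (nrow(runs) > 1L) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap <- runs$onset[i] - merged$offset[nrow(merged)] - period
      if (gap <= max_gap) {
        merged$offset[nrow(merged)] <- runs$offset[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs$dwell <- runs$offset - runs$onset
  runs <- runs[runs$dwell >= min_glance, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Per-participant gaze summary over the analysed targets
#'
#' Computes the four glance statistics: the percentage of retained targets
#' glanced at least once, and — over looked-at targets only — the mean
#' number of glances, the mean first-glance latency from target appearance,
#' and the mean total dwell.
#'
#' @param glances_by_target Named list (one entry per retained target) of
#'   [detect_glances()] outputs.
#' @param tracks The corresponding `"aoi_tracks"` (for appearance times);
#'   only targets present in `glances_by_target` are used.
#' @return One-row data.frame: `n_targets`, `n_looked`,
#'   `pct_targets_looked` (percent), `avg_glance_freq`,
#'   `avg_first_glance_latency` (s), `avg_dwell_time` (s); the three
#'   averages are `NA` when no target was looked at.
#' @export
participant_gaze_summary <- function(glances_by_target, tracks) {
  ids <- names(glances_by_target)
  if (length(ids) == 0L)
    stop("no retained targets for this participant", call. = FALSE)
  looked <- vapply(glances_by_target, function(g) nrow(g) > 0L, logical(1))
  appear <- tracks$targets$appear_time[match(ids, tracks$targets$target_id)]
  n_looked <- sum(looked)
  if (n_looked > 0L) {
    freq <- mean(vapply(glances_by_target[looked], nrow, integer(1)))
    lat <- mean(vapply(which(looked), function(i)
      glances_by_target[[i]]$onset[1] - appear[i], numeric(1)))
    dwell <- mean(vapply(glances_by_target[looked], function(g)
      sum(g$dwell), numeric(1)))
  } else {
    freq <- lat <- dwell <- NA_real_
  }
  data.frame(n_targets = length(ids), n_looked = n_looked,
             pct_targets_looked = 100 * n_looked / length(ids),
             avg_glance_freq = freq, avg_first_glance_latency = lat,
             avg_dwell_time = dwell)
}

#' Gaze summaries for a simulated cohort
#'
#' Applies the exclusion rules to each participant's gaze quality records,
#' detects glances on the retained targets and summarizes per participant.
#'
#' @param cohort An `"sa_cohort"` whose sessions carry gaze streams.
#' @param tracks The `"aoi_tracks"` used in simulation.
#' @param ... Passed to [detect_glances()].
#' @return List with `summaries` (one row per usable participant, with
#'   `participant_id` and `group`) and `exclusion_log`.
#' @export
cohort_gaze_summary <- function(cohort, tracks, ...) {
  rows <- list(); logs <- list()
  for (sess in cohort) {
    if (is.null(sess$gaze)) next
    excl <- apply_exclusions(sess$gaze_quality)
    logs[[length(logs) + 1L]] <- excl$log
    if (nrow(excl$retained) == 0L) next
    kept <- excl$retained$target_id
    glances <- lapply(kept, function(tid) {
      tr <- as.list(tracks$targets[tracks$targets$target_id == tid, ])
      detect_glances(sess$gaze[[tid]], tr, ...)
    })
    names(glances) <- kept
    row <- participant_gaze_summary(glances, tracks)
    row <- cbind(data.frame(participant_id = sess$participant_id,
                            group = sess$profile$group), row)
    rows[[length(rows) + 1L]] <- row
  }
  list(summaries = do.call(rbind, rows),
       exclusion_log = do.call(rbind, logs))
}

#' Predict accuracy from the gaze parameters
#'
#' One simple linear regression of logit accuracy on each of the four gaze
#' parameters, as in the study's eye-movement analysis.
#'
#' @param gaze_summaries Output rows of [cohort_gaze_summary()].
#' @param accuracy_tbl Data.frame with `participant_id` and
#'   `logit_accuracy`.
#' @return Named list of `"regression_result"` objects, one per parameter.
#' @export
gaze_accuracy_regression <- function(gaze_summaries, accuracy_tbl) {
  m <- merge(gaze_summaries, accuracy_tbl, by = "participant_id")
  params <- c("pct_targets_looked", "avg_glance_freq",
              "avg_first_glance_latency", "avg_dwell_time")
  out <- lapply(params, function(p) {
    keep <- stats::complete.cases(m[, c(p, "logit_accuracy")])
    ols_regression(m$logit_accuracy[keep],
                   stats::setNames(m[keep, p, drop = FALSE], p))
  })
  stats::setNames(out, params)
}
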