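# Performance measures: confusion counts, log-linear corrected rates,
# equal-variance SDT sensitivity and criteria, response bias, accuracy and
# its logit, and partial-credit-unit scoring of the counting span.
#
# Sign convention: criteria are measured from the noise-distribution mean,
# so the observed criterion is the *negative* normal quantile of the
# false-alarm rate. A liberal observer (high FA) has a low criterion.

#' Tally a confusion matrix from binary location responses
#'
#' Overt and covert targets both count as signal. Use `clips` to window
#' the tally (e.g. to one phase's clips); practice clips are included only
#' if their ids are passed explicitly.
#'
#' @param responses Response records (`target_present`, `selected`,
#'   `clip_id`).
#' @param clips Optional clip ids to restrict to; default: all game clips
#'   present (rows with `role == "game"` when a `role` column exists,
#'   otherwise all rows).
#' @return Object of class `"confusion_counts"`: `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, `n_signal`, `n_noise`.
#' @export
tally_counts <- function(responses, clips = NULL) {
  r <- responses
  if (!is.null(clips)) {
    r <- r[r$clip_id %in% clips, ]
  } else if ("role" %in% names(r)) {
    r <- r[r$role == "game", ]
  }
  if (nrow(r) == 0L) stop("empty response window", call. = FALSE)
  hits <- sum(r$target_present & r$selected)
  misses <- sum(r$target_present & !r$selected)
  fas <- sum(!r$target_present & r$selected)
  crs <- sum(!r$target_present & !r$selected)
  structure(list(hits = hits, misses = misses, false_alarms = fas,
                 correct_rejections = crs, n_signal = hits + misses,
                 n_noise = fas + crs),
            class = "confusion_counts")
}

#' Log-linear corrected hit and false-alarm rates
#'
#' Adds 0.5 to the hit and false-alarm counts and 1 to the signal and noise
#' trial counts, so rates can never be exactly 0 or 1 and the normal
#' quantile stays finite.
#'
#' @param counts A `"confusion_counts"` object (or compatible list).
#' @return Named numeric: `hit_rate`, `fa_rate`, both strictly in (0, 1).
#' @export
loglinear_rates <- function(counts) {
  if (counts$n_signal < 1L || counts$n_noise < 1L)
    stop("log-linear rates need at least one signal and one noise trial",
         call. = FALSE)
  c(hit_rate = (counts$hits + 0.5) / (counts$n_signal + 1),
    fa_rate = (counts$false_alarms + 0.5) / (counts$n_noise + 1))
}

check_rate <- function(p, what) {
  if (any(p <= 0 | p >= 1))
    stop(what, " must lie strictly in (0, 1); apply the log-linear ",
         "correction to boundary rates", call. = FALSE)
}

#' Sensitivity index d'
#'
#' Difference of standard-normal quantiles of the hit and false-alarm
#' rates: the distance, in sd units, between the signal and noise evidence
#' distributions of an equal-variance SDT observer.
#'
#' @param hit_rate,fa_rate Proportions strictly in (0, 1).
#' @return d' in sd units.
#' @export
#' @examples
#' dprime(0.84, 0.16)
dprime <- function(hit_rate, fa_rate) {
  check_rate(hit_rate, "hit rate"); check_rate(fa_rate, "false-alarm rate")
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Observed decision criterion
#'
#' The criterion on the evidence axis, measured from the noise-distribution
#' mean: `-qnorm(fa_rate)`. Positive values mean a conservative observer
#' (few false alarms).
#'
#' @param fa_rate False-alarm proportion strictly in (0, 1).
#' @return Criterion in sd units.
#' @export
observed_criterion <- function(fa_rate) {
  check_rate(fa_rate, "false-alarm rate")
  -stats::qnorm(fa_rate)
}

#' Accuracy-optimal decision criterion under unequal prevalence
#'
#' For sensitivity `d_prime` and target prevalence `s`, the criterion that
#' maximizes accuracy is `0.5 * d_prime - logit(s) / d_prime`. When targets
#' outnumber empties (`s > 0.5`) the optimal criterion shifts liberal.
#'
#' @param d_prime Sensitivity (nonzero).
#' @param prevalence_s Probability a probed location holds a target, in
#'   (0, 1).
#' @return Optimal criterion in sd units.
#' @export
optimal_criterion <- function(d_prime, prevalence_s) {
  if (any(d_prime == 0))
    stop("optimal criterion is undefined at zero sensitivity", call. = FALSE)
  check_rate(prevalence_s, "prevalence")
  0.5 * d_prime - log(prevalence_s / (1 - prevalence_s)) / d_prime
}

#' Response bias
#'
#' Observed minus optimal criterion. Negative values indicate a bias to
#' select locations; positive values a bias to leave them unselected.
#'
#' @param lambda_obs,lambda_opt Criteria in sd units.
#' @return Bias in sd units.
#' @export
response_bias <- function(lambda_obs, lambda_opt) lambda_obs - lambda_opt

#' Accuracy and its logit
#'
#' Accuracy is the uncorrected proportion of locations answered correctly
#' (hits plus correct rejections over all locations). `logit_accuracy`
#' requires an interior proportion; summaries produced from counts shrink
#' boundary values log-linearly (`(k + 0.5) / (n + 1)`) before the logit.
#'
#' @param counts A `"confusion_counts"` object.
#' @return `accuracy`: proportion in \[0, 1\].
#' @export
accuracy <- function(counts) {
  total <- counts$n_signal + counts$n_noise
  if (total < 1L) stop("no locations to score", call. = FALSE)
  (counts$hits + counts$correct_rejections) / total
}

#' @rdname accuracy
#' @param p Proportion strictly in (0, 1).
#' @export
logit_accuracy <- function(p) {
  check_rate(p, "accuracy")
  log(p / (1 - p))
}

# logit of accuracy from counts, shrinking only boundary values
logit_accuracy_counts <- function(counts) {
  p <- accuracy(counts)
  if (p <= 0 || p >= 1) {
    n <- counts$n_signal + counts$n_noise
    p <- (counts$hits + counts$correct_rejections + 0.5) / (n + 1)
  }
  log(p / (1 - p))
}

#' Partial-credit-unit score of a counting-span transcript
#'
#' For every administered trial, the proportion of tallies recalled in the
#' correct position; the PCU score is the mean of those proportions (trials
#' never reached because of an early stop are excluded).
#'
#' @param transcript A `"counting_span_transcript"`.
#' @return Object of class `"counting_span_score"`: `pcu`,
#'   `tallies_presented`, `tallies_correct`, `n_trials`.
#' @export
pcu_score <- function(transcript) {
  trials <- transcript$trials
  if (length(trials) == 0L) stop("empty counting-span transcript",
                                 call. = FALSE)
  props <- vapply(trials, function(tr) {
    mean(tr$recalled_tallies == tr$true_tallies)
  }, numeric(1))
  correct <- sum(vapply(trials, function(tr)
    sum(tr$recalled_tallies == tr$true_tallies), numeric(1)))
  presented <- sum(vapply(trials, function(tr) tr$set_size, numeric(1)))
  structure(list(pcu = mean(props), tallies_presented = presented,
                 tallies_correct = correct, n_trials = length(trials)),
            class = "counting_span_score")
}

sdt_summary_row <- function(counts, prevalence_s) {
  rates <- loglinear_rates(counts)
  d <- dprime(rates["hit_rate"], rates["fa_rate"])
  lobs <- observed_criterion(rates["fa_rate"])
  # the optimal criterion is undefined at zero sensitivity; a participant
  # whose corrected rates coincide gets NA criteria rather than aborting
  # the whole summary
  lopt <- if (d != 0) optimal_criterion(d, prevalence_s) else NA_real_
  data.frame(
    hit_rate = unname(rates["hit_rate"]), fa_rate = unname(rates["fa_rate"]),
    d_prime = unname(d), lambda_obs = unname(lobs), lambda_opt = unname(lopt),
    bias = unname(response_bias(lobs, lopt)),
    accuracy = accuracy(counts),
    logit_accuracy = logit_accuracy_counts(counts),
    prevalence_s = prevalence_s,
    n_signal = counts$n_signal, n_noise = counts$n_noise
  )
}

#' Per-phase and overall SDT summary for one participant
#'
#' Windows the game clips by the participant's own phase partition
#' (practice excluded), pools counts within each window, applies the
#' log-linear correction, and computes d', observed and optimal criteria
#' (prevalence taken from the window's realized location composition),
#' bias, accuracy and mean response time.
#'
#' @param session A `"participant_session"`.
#' @param bank The stimulus bank played.
#' @return Data.frame with rows start, middle, end, overall.
#' @export
per_phase_summary <- function(session, bank) {
  resp <- session$responses[session$responses$role == "game", ]
  windows <- list(start = 1L, middle = 2L, end = 3L,
                  overall = 1:3)
  out <- lapply(names(windows), function(w) {
    rw <- resp[resp$phase %in% windows[[w]], ]
    counts <- tally_counts(rw, clips = unique(rw$clip_id))
    s <- mean(rw$target_present)
    row <- sdt_summary_row(counts, s)
    rt <- session$clip_rt
    rtw <- rt$rt_s[rt$role == "game" & rt$phase %in% windows[[w]]]
    cbind(data.frame(participant_id = session$participant_id,
                     group = session$profile$group, window = w),
          row, data.frame(mean_rt = mean(rtw)))
  })
  do.call(rbind, out)
}

#' Tidy SDT summary table for a whole cohort
#'
#' @param cohort An `"sa_cohort"` (list of sessions).
#' @param bank The stimulus bank played.
#' @return Data.frame: one row per participant and window
#'   (start/middle/end/overall).
#' @export
summarize_cohort <- function(cohort, bank) {
  do.call(rbind, lapply(cohort, per_phase_summary, bank = bank))
}
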