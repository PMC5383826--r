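# Synthetic observers: equal-variance SDT responders with phase-wise
# learning, lognormal response times, AOI-directed gaze traces and
# set-size-limited counting-span recall. The generator exists so that every
# downstream estimator can be tested by parameter recovery.

#' Observer profile
#'
#' Generative parameters for one simulated player. Sensitivity and decision
#' criterion are given per game phase (start/middle/end, 10 clips each);
#' learning is modelled as phase-wise constant d' that never decreases.
#'
#' @param group `"child"` or `"adult"`.
#' @param d_prime_by_phase Three non-decreasing sensitivities (sd units).
#' @param criterion Decision threshold on the evidence axis, measured from
#'   the noise mean (sd units); length 1 or 3 (per phase).
#' @param rt_mean_by_phase Mean clip response time per phase (seconds).
#' @param rt_sigma Lognormal shape (sdlog) of response times.
#' @param p_look Probability of glancing at an analysed gaze target.
#' @param glance_latency_mean Mean latency of the first glance after the
#'   target becomes identifiable (seconds).
#' @param glance_dwell_mean Mean dwell per glance (seconds).
#' @param glance_rate Expected glances per looked-at target (Poisson, min 1).
#' @param wm_capacity Largest counting-span set size recalled reliably.
#' @param wm_noise Per-tally recall error probability below capacity.
#' @param lapse_rate Probability a selection is replaced by a fair coin.
#' @return An object of class `"observer_profile"`.
#' @export
observer_profile <- function(group = c("child", "adult"),
                             d_prime_by_phase,
                             criterion,
                             rt_mean_by_phase = c(4.82, 4.15, 3.47),
                             rt_sigma = 0.4,
                             p_look = 0.5,
                             glance_latency_mean = 2.0,
                             glance_dwell_mean = 0.5,
                             glance_rate = 1.5,
                             wm_capacity = 4L,
                             wm_noise = 0.05,
                             lapse_rate = 0) {
  group <- match.arg(group)
  d_prime_by_phase <- rep(d_prime_by_phase, length.out = 3L)
  criterion <- rep(criterion, length.out = 3L)
  rt_mean_by_phase <- rep(rt_mean_by_phase, length.out = 3L)
  stopifnot(all(d_prime_by_phase >= 0), !is.unsorted(d_prime_by_phase),
            all(rt_mean_by_phase > 0), rt_sigma > 0,
            p_look >= 0, p_look <= 1, lapse_rate >= 0, lapse_rate <= 1,
            glance_latency_mean > 0, glance_dwell_mean > 0, glance_rate > 0,
            wm_capacity >= 0, wm_noise >= 0, wm_noise <= 1)
  structure(list(group = group, d_prime_by_phase = d_prime_by_phase,
                 criterion = criterion, rt_mean_by_phase = rt_mean_by_phase,
                 rt_sigma = rt_sigma, p_look = p_look,
                 glance_latency_mean = glance_latency_mean,
                 glance_dwell_mean = glance_dwell_mean,
                 glance_rate = glance_rate,
                 wm_capacity = as.integer(wm_capacity), wm_noise = wm_noise,
                 lapse_rate = lapse_rate),
            class = "observer_profile")
}

#' Default child and adult observer profiles
#'
#' Sensitivities and criteria follow the study's printed per-phase group
#' means; gaze parameters follow the printed group glance statistics (dwell
#' is per glance, so that glances-per-target times per-glance dwell matches
#' the printed total dwell per target).
#'
#' @return An `"observer_profile"`.
#' @export
child_profile <- function() {
  observer_profile("child",
                   d_prime_by_phase = c(0.88, 1.06, 1.43),
                   criterion = c(0.24, 0.28, 0.50),
                   p_look = 0.35, glance_latency_mean = 2.48,
                   glance_dwell_mean = 0.37, glance_rate = 2.01,
                   wm_capacity = 2L)
}

#' @rdname child_profile
#' @export
adult_profile <- function() {
  observer_profile("adult",
                   d_prime_by_phase = c(1.74, 1.82, 2.04),
                   criterion = c(0.68, 0.76, 0.88),
                   p_look = 0.55, glance_latency_mean = 1.97,
                   glance_dwell_mean = 0.78, glance_rate = 1.49,
                   wm_capacity = 6L)
}

# phase (1..3) of each position among game clips; practice clips get phase 1
phase_of_position <- function(order, roles) {
  phase <- integer(length(order))
  game_pos <- cumsum(roles == "game")
  n_game <- sum(roles == "game")
  brk <- ceiling(n_game / 3)
  phase[roles == "game"] <- pmin(3L, (game_pos[roles == "game"] - 1L) %/% brk + 1L)
  phase[roles != "game"] <- 1L
  phase
}

#' Simulate one participant's game responses and response times
#'
#' Each location draws evidence from N(0, 1) if empty or N(d', 1) if it
#' holds a target (overt or covert alike); the location is selected when
#' evidence exceeds the phase's criterion. With probability `lapse_rate`
#' the selection is replaced by a fair coin. Clip response times are
#' lognormal with phase-dependent mean. Game phases are positions 1-10,
#' 11-20 and 21-30 of the participant's own randomized order.
#'
#' @param profile An [observer_profile()].
#' @param bank A valid [generate_bank()] output.
#' @param order Clip-id presentation order from [randomize_order()].
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the records.
#' @return A list of class `"participant_session"` with `responses`
#'   (participant_id, clip_id, location_id, kind, target_present, selected,
#'   role, phase), `clip_rt` (clip_id, phase, rt_s), the `order`, `profile`
#'   and `participant_id`. Gaze and counting-span slots are filled by
#'   [simulate_cohort()] or manually.
#' @export
simulate_responses <- function(profile, bank, order, seed = 1L,
                               participant_id = "P1") {
  stopifnot(inherits(profile, "observer_profile"))
  if (!setequal(order, bank$clips$clip_id) ||
      length(order) != nrow(bank$clips))
    stop("presentation order does not cover the bank's clips exactly",
         call. = FALSE)
  with_seed(derive_seed(seed, paste0("responses-", participant_id)), {
    roles <- bank$clips$role[match(order, bank$clips$clip_id)]
    phases <- phase_of_position(order, roles)
    loc <- bank$locations
    idx <- order(match(loc$clip_id, order))
    loc <- loc[idx, ]
    loc$phase <- phases[match(loc$clip_id, order)]
    target <- loc$kind != "empty"
    dp <- profile$d_prime_by_phase[loc$phase]
    lam <- profile$criterion[loc$phase]
    evidence <- stats::rnorm(nrow(loc), mean = ifelse(target, dp, 0), sd = 1)
    selected <- evidence > lam
    if (profile$lapse_rate > 0) {
      lapse <- stats::runif(nrow(loc)) < profile$lapse_rate
      selected[lapse] <- stats::runif(sum(lapse)) < 0.5
    }
    responses <- data.frame(
      participant_id = participant_id,
      clip_id = loc$clip_id, location_id = loc$location_id,
      kind = loc$kind, target_present = target, selected = selected,
      role = loc$role, phase = loc$phase, stringsAsFactors = FALSE
    )
    rt_mean <- profile$rt_mean_by_phase[phases]
    meanlog <- log(rt_mean) - profile$rt_sigma^2 / 2
    clip_rt <- data.frame(
      participant_id = participant_id, clip_id = order, role = roles,
      phase = phases,
      rt_s = stats::rlnorm(length(order), meanlog, profile$rt_sigma),
      stringsAsFactors = FALSE
    )
    structure(list(participant_id = participant_id, profile = profile,
                   order = order, responses = responses, clip_rt = clip_rt,
                   gaze = NULL, gaze_quality = NULL, counting_span = NULL),
              class = "participant_session")
  })
}

#' Simulate a gaze trace for one clip and one AOI track
#'
#' Samples run from clip start to mask at an effective rate drawn uniformly
#' in `rate_range`. With probability `p_look` the trace enters the AOI:
#' the number of glances is Poisson(`glance_rate`) truncated at 1, the first
#' begins a lognormal latency after the target appears, and each dwells a
#' lognormal time (truncated at the mask). Outside glances the trace follows
#' a centre-biased random walk kept out of the AOI circle.
#'
#' @param profile An [observer_profile()].
#' @param clip One row of `bank$clips`.
#' @param track AOI track for a target in this clip (see
#'   [generate_aoi_tracks()]); a list with `clip_id`, `target_id`,
#'   `appear_time`, `end_time`, `x`, `y`, `radius`.
#' @param seed Integer seed.
#' @param calibration_error Recorded nine-point calibration error (degrees),
#'   passed through to the quality record.
#' @param rate_range Effective sampling-rate range (Hz).
#' @return List with `samples` (t_s, x, y, valid) and `quality`
#'   (calibration_error, effective_rate).
#' @export
simulate_gaze <- function(profile, clip, track, seed = 1L,
                          calibration_error = 1.0, rate_range = c(10, 30)) {
  stopifnot(track$clip_id == clip$clip_id)
  with_seed(derive_seed(seed, paste0("gaze-", clip$clip_id, "-", track$target_id)), {
    rate <- stats::runif(1, rate_range[1], rate_range[2])
    t <- seq(0, clip$mask_time_s, by = 1 / rate)
    n <- length(t)
    # glance windows
    windows <- NULL
    if (stats::runif(1) < profile$p_look) {
      n_gl <- max(1L, stats::rpois(1, profile$glance_rate))
      lat <- stats::rlnorm(1, log(profile$glance_latency_mean) - 0.3^2 / 2, 0.3)
      onset1 <- min(track$appear_time + lat, track$end_time - 0.15)
      onsets <- sort(c(onset1,
                       if (n_gl > 1)
                         stats::runif(n_gl - 1, onset1, track$end_time)))
      dwells <- stats::rlnorm(n_gl, log(profile$glance_dwell_mean) - 0.3^2 / 2, 0.3)
      ends <- pmin(onsets + dwells, track$end_time)
      windows <- cbind(onsets, ends)
    }
    in_glance <- rep(FALSE, n)
    if (!is.null(windows)) {
      for (w in seq_len(nrow(windows)))
        in_glance <- in_glance | (t >= windows[w, 1] & t <= windows[w, 2])
    }
    # background: centre-biased random walk
    x <- numeric(n); y <- numeric(n)
    x[1] <- 0.5; y[1] <- 0.5
    step <- stats::rnorm(2 * n, 0, 0.03)
    for (i in seq_len(n)[-1]) {
      x[i] <- x[i - 1] + 0.15 * (0.5 - x[i - 1]) + step[i]
      y[i] <- y[i - 1] + 0.15 * (0.5 - y[i - 1]) + step[n + i]
    }
    x <- pmin(pmax(x, 0), 1); y <- pmin(pmax(y, 0), 1)
    # push non-glance samples out of the AOI circle
    d <- sqrt((x - track$x)^2 + (y - track$y)^2)
    bg_in <- !in_glance & d < track$radius * 1.2
    if (any(bg_in)) {
      scale <- (track$radius * 1.3) / pmax(d[bg_in], 1e-6)
      x[bg_in] <- track$x + (x[bg_in] - track$x) * scale
      y[bg_in] <- track$y + (y[bg_in] - track$y) * scale
    }
    # glance samples: inside the circle with small jitter
    if (any(in_glance)) {
      k <- sum(in_glance)
      r <- track$radius * 0.5 * sqrt(stats::runif(k))
      a <- stats::runif(k, 0, 2 * pi)
      x[in_glance] <- track$x + r * cos(a)
      y[in_glance] <- track$y + r * sin(a)
    }
    samples <- data.frame(t_s = t, x = pmin(pmax(x, 0), 1),
                          y = pmin(pmax(y, 0), 1), valid = TRUE)
    list(samples = samples,
         quality = list(calibration_error = calibration_error,
                        effective_rate = rate))
  })
}

#' Simulate a counting-span transcript
#'
#' The schedule presents set sizes 2 through 8, three trials each (at most
#' 21 trials, 105 tallies). True tallies are uniform on 2-8. A tally is
#' recalled correctly with probability `1 - noise` when the trial's set
#' size is within `wm_capacity`, dropping by `overload_penalty` per item
#' beyond capacity (floored at 0). The task stops early after three
#' consecutive trials in which no tally was recalled correctly.
#'
#' @param wm_capacity Capacity in tallies (set sizes above this overload).
#' @param noise Per-tally error probability below capacity.
#' @param seed Integer seed.
#' @param overload_penalty Added error probability per item over capacity.
#' @return An object of class `"counting_span_transcript"`: list with
#'   `trials` (each: `set_size`, `true_tallies`, `recalled_tallies`) and
#'   `stopped_early`.
#' @export
simulate_counting_span <- function(wm_capacity, noise = 0.05, seed = 1L,
                                   overload_penalty = 0.2) {
  stopifnot(wm_capacity >= 0, noise >= 0, noise <= 1)
  with_seed(derive_seed(seed, "counting-span"), {
    trials <- list()
    consec_fail <- 0L
    stopped <- FALSE
    for (set_size in 2:8) {
      for (rep_i in 1:3) {
        truth <- sample(2:8, set_size, replace = TRUE)
        p_ok <- if (set_size <= wm_capacity) 1 - noise else
          max(0, 1 - noise - overload_penalty * (set_size - wm_capacity))
        ok <- stats::runif(set_size) < p_ok
        recalled <- truth
        if (any(!ok)) {
          # a wrong recall is a different digit in 2..8
          recalled[!ok] <- vapply(truth[!ok], function(tt)
            sample(setdiff(2:8, tt), 1L), integer(1))
        }
        trials[[length(trials) + 1L]] <-
          list(set_size = set_size, true_tallies = truth,
               recalled_tallies = recalled)
        consec_fail <- if (!any(ok)) consec_fail + 1L else 0L
        if (consec_fail >= 3L) stopped <- TRUE
        if (stopped) break
      }
      if (stopped) break
    }
    structure(list(trials = trials, stopped_early = stopped),
              class = "counting_span_transcript")
  })
}

#' Between-subject jitter settings for a simulated cohort
#'
#' Gaussian jitter applied per participant to the profile's d' (one shared
#' offset across phases, so learning stays monotone), criterion and p_look.
#' Defaults are calibrated so that the *measured* between-subject spread,
#' after adding the estimation noise from the finite number of probed
#' locations, is close to the study's printed between-subject sds.
#'
#' @param d_prime_sd,criterion_sd,p_look_sd Jitter standard deviations.
#' @return A list of class `"cohort_jitter"`.
#' @export
cohort_jitter <- function(d_prime_sd = 0.5, criterion_sd = 0.4,
                          p_look_sd = 0.1) {
  structure(list(d_prime_sd = d_prime_sd, criterion_sd = criterion_sd,
                 p_look_sd = p_look_sd), class = "cohort_jitter")
}

jitter_profile <- function(profile, jitter) {
  d_off <- stats::rnorm(1, 0, jitter$d_prime_sd)
  c_off <- stats::rnorm(1, 0, jitter$criterion_sd)
  p_off <- stats::rnorm(1, 0, jitter$p_look_sd)
  profile$d_prime_by_phase <- pmax(profile$d_prime_by_phase + d_off, 0.05)
  profile$criterion <- profile$criterion + c_off
  profile$p_look <- min(max(profile$p_look + p_off, 0.02), 0.98)
  profile
}

#' Simulate a cohort of participants
#'
#' Each participant gets an independent presentation order and a seed
#' derived from the root seed, a jittered copy of the group profile, game
#' responses and response times, optionally gaze traces for the analysed
#' AOI targets, and a counting-span transcript.
#'
#' @param n_children,n_adults Group sizes (study defaults: 36 and 22).
#' @param bank A valid stimulus bank.
#' @param seed Root seed.
#' @param child_profile,adult_profile Group [observer_profile()]s.
#' @param jitter A [cohort_jitter()]; use sds of 0 for identical observers.
#' @param tracks AOI tracks from [generate_aoi_tracks()], or `NULL` to skip
#'   gaze simulation.
#' @return List of `"participant_session"` objects (class `"sa_cohort"`).
#' @export
simulate_cohort <- function(n_children, n_adults, bank, seed = 1L,
                            child_profile = sagame::child_profile(),
                            adult_profile = sagame::adult_profile(),
                            jitter = cohort_jitter(),
                            tracks = NULL) {
  stopifnot(n_children >= 0, n_adults >= 0)
  groups <- rep(c("child", "adult"), c(n_children, n_adults))
  sessions <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    pid <- sprintf("%s%02d", ifelse(groups[i] == "child", "C", "A"),
                   if (groups[i] == "child") i else i - n_children)
    pseed <- derive_seed(seed, paste0("participant-", pid))
    base <- if (groups[i] == "child") child_profile else adult_profile
    prof <- with_seed(derive_seed(pseed, "jitter"),
                      jitter_profile(base, jitter))
    ord <- randomize_order(bank, seed = pseed)
    sess <- simulate_responses(prof, bank, ord, seed = pseed,
                               participant_id = pid)
    sess$counting_span <- simulate_counting_span(
      prof$wm_capacity, noise = prof$wm_noise, seed = pseed)
    if (!is.null(tracks)) {
      gz <- vector("list", nrow(tracks$targets))
      rates <- numeric(nrow(tracks$targets))
      for (k in seq_len(nrow(tracks$targets))) {
        tr <- as.list(tracks$targets[k, ])
        clip <- bank$clips[bank$clips$clip_id == tr$clip_id, ]
        g <- simulate_gaze(prof, clip, tr, seed = pseed)
        g$samples$participant_id <- pid
        g$samples$clip_id <- tr$clip_id
        gz[[k]] <- g$samples
        rates[k] <- g$quality$effective_rate
      }
      names(gz) <- tracks$targets$target_id
      sess$gaze <- gz
      sess$gaze_quality <- data.frame(
        participant_id = pid, calibration_error = 1.0,
        target_id = tracks$targets$target_id,
        clip_id = tracks$targets$clip_id,
        effective_rate = rates, stringsAsFactors = FALSE)
    }
    sessions[[i]] <- sess
  }
  structure(sessions, class = "sa_cohort")
}

#' Build dynamic AOI tracks for the analysed gaze targets
#'
#' Picks `n_targets` target locations from distinct game clips, preferring
#' off-centre locations and long clips, and gives each a dynamic circular
#' AOI running from the moment the target is first identifiable until the
#' mask. Keyframes (here: constant circles) are stored so tracks can be
#' serialized as a keyframe table.
#'
#' @param bank A valid stimulus bank.
#' @param n_targets Number of analysed targets (study default: 10).
#' @param seed Integer seed.
#' @return An object of class `"aoi_tracks"`: list with `targets` (one row
#'   per target: clip_id, target_id, appear_time, end_time, x, y, radius)
#'   and `keyframes` (clip_id, target_id, t_s, x, y, radius).
#' @export
generate_aoi_tracks <- function(bank, n_targets = 10L, seed = 1L) {
  loc <- bank$locations
  cand <- loc[loc$role == "game" & loc$kind != "empty", ]
  cand$dist_center <- sqrt((cand$x - 0.5)^2 + (cand$y - 0.5)^2)
  cand <- cand[cand$dist_center > 0.12, ]
  cand <- merge(cand, bank$clips[, c("clip_id", "mask_time_s")], by = "clip_id")
  with_seed(derive_seed(seed, "aoi"), {
    # one target per clip; prefer longer clips so the AOI window is wide
    cand <- cand[sample.int(nrow(cand)), ]
    cand <- cand[!duplicated(cand$clip_id), ]
    cand <- cand[order(-cand$mask_time_s), ]
    if (nrow(cand) < n_targets)
      stop("bank has only ", nrow(cand),
           " eligible off-centre targets in distinct clips", call. = FALSE)
    sel <- cand[seq_len(n_targets), ]
    targets <- data.frame(
      clip_id = sel$clip_id,
      target_id = sprintf("T%02d", seq_len(n_targets)),
      appear_time = pmax(0.2, sel$mask_time_s - 8),
      end_time = sel$mask_time_s,
      x = sel$x, y = sel$y, radius = pmax(sel$radius, 0.06),
      stringsAsFactors = FALSE
    )
    keyframes <- rbind(
      data.frame(clip_id = targets$clip_id, target_id = targets$target_id,
                 t_s = targets$appear_time, x = targets$x, y = targets$y,
                 radius = targets$radius, stringsAsFactors = FALSE),
      data.frame(clip_id = targets$clip_id, target_id = targets$target_id,
                 t_s = targets$end_time, x = targets$x, y = targets$y,
                 radius = targets$radius, stringsAsFactors = FALSE)
    )
    keyframes <- keyframes[order(keyframes$target_id, keyframes$t_s), ]
    structure(list(targets = targets, keyframes = keyframes),
              class = "aoi_tracks")
  })
}
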