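# Game scoring: +5 for a hit, -5 for a miss, +1 for a correct rejection,
# 0 for a false alarm; the on-screen running total is clamped at zero after
# every clip. Covert-target feedback carries the view-blocker note.

POINTS_DELTA <- c(hit = 5L, miss = -5L, correct_rejection = 1L,
                  false_alarm = 0L)

#' Score one clip's responses
#'
#' Classifies each probed location as hit, miss, correct rejection or false
#' alarm, attaches the points delta and the feedback category shown to the
#' player (covert targets get the view-blocker note).
#'
#' @param responses Response records for exactly this clip's locations:
#'   a data.frame with `location_id`, `target_present`, `selected` (and
#'   optionally `kind`, used for the covert feedback note).
#' @param clip_locations The clip's rows of `bank$locations`.
#' @return A data.frame of score events: `clip_id`, `location_id`,
#'   `outcome`, `points_delta`, `feedback_label`.
#' @export
score_clip <- function(responses, clip_locations) {
  missing_loc <- setdiff(clip_locations$location_id, responses$location_id)
  extra_loc <- setdiff(responses$location_id, clip_locations$location_id)
  if (length(missing_loc) || length(extra_loc))
    stop("responses do not cover the clip's locations exactly: ",
         if (length(missing_loc))
           paste0("missing ", paste(missing_loc, collapse = ", ")),
         if (length(missing_loc) && length(extra_loc)) "; ",
         if (length(extra_loc))
           paste0("unknown ", paste(extra_loc, collapse = ", ")),
         call. = FALSE)
  m <- match(clip_locations$location_id, responses$location_id)
  target <- clip_locations$kind != "empty"
  selected <- responses$selected[m]
  outcome <- ifelse(target,
                    ifelse(selected, "hit", "miss"),
                    ifelse(selected, "false_alarm", "correct_rejection"))
  feedback <- c(hit = "detected", miss = "missed",
                correct_rejection = "empty_correct",
                false_alarm = "empty_selected")[outcome]
  covert <- clip_locations$kind == "covert"
  feedback[covert & outcome %in% c("hit", "miss")] <- "view_blocker_note"
  data.frame(
    clip_id = clip_locations$clip_id,
    location_id = clip_locations$location_id,
    outcome = outcome,
    points_delta = unname(POINTS_DELTA[outcome]),
    feedback_label = unname(feedback),
    stringsAsFactors = FALSE
  )
}

#' Accumulate clip scores into the on-screen points total
#'
#' The running total starts at zero and after each clip is clamped at zero:
#' `total_k = max(0, total_{k-1} + clip_delta_k)`.
#'
#' @param events Score events ([score_clip()] output, possibly several
#'   clips' worth).
#' @param order Clip-id presentation order; clips absent from `events`
#'   contribute nothing.
#' @return A list of class `"score_board"`: `running_total` (named by
#'   clip id, in presentation order) and `final_points`.
#' @export
accumulate_points <- function(events, order = unique(events$clip_id)) {
  deltas <- vapply(order, function(id)
    sum(events$points_delta[events$clip_id == id]), numeric(1))
  running <- numeric(length(order))
  total <- 0
  for (i in seq_along(order)) {
    total <- max(0, total + deltas[i])
    running[i] <- total
  }
  names(running) <- order
  structure(list(running_total = running,
                 final_points = if (length(running)) running[[length(running)]]
                 else 0),
            class = "score_board")
}

#' Score a whole session
#'
#' Convenience wrapper: scores every clip of a session against the bank and
#' accumulates the points board in presentation order.
#'
#' @param session A `"participant_session"`.
#' @param bank The stimulus bank the session was played on.
#' @return List with `events` (all score events) and `board`
#'   (a `"score_board"`).
#' @export
score_session <- function(session, bank) {
  events <- do.call(rbind, lapply(session$order, function(id) {
    score_clip(session$responses[session$responses$clip_id == id, ],
               bank$locations[bank$locations$clip_id == id, ])
  }))
  list(events = events, board = accumulate_points(events, session$order))
}

#' Partition the game clips of an order into three phases
#'
#' Practice clips are dropped; the 30 remaining game clips are labelled
#' start/middle/end by position (1-10, 11-20, 21-30).
#'
#' @param order Clip-id presentation order.
#' @param roles Optional role vector aligned with `order`; ids starting
#'   with `"p"` are treated as practice when `roles` is missing.
#' @return Factor (levels start/middle/end) named by game clip id.
#' @export
partition_phases <- function(order, roles = NULL) {
  if (is.null(roles)) roles <- ifelse(grepl("^p", order), "practice", "game")
  game <- order[roles == "game"]
  if (length(game) != 30L)
    stop("expected exactly 30 game clips, found ", length(game),
         call. = FALSE)
  phase <- rep(c("start", "middle", "end"), each = 10L)
  factor(stats::setNames(phase, game), levels = c("start", "middle", "end"))
}
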