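# Synthetic stimulus bank: masked video clips, each probing 2-3 screen
# locations that held an overt hazard (visible road user), a covert hazard
# (an occluder someone could emerge from) or nothing.

#' Stimulus bank configuration
#'
#' Describes the clip counts, the location-kind composition of the game
#' clips, and the clip-duration distribution. Defaults reproduce the study
#' conditions: 30 game clips probing 79 locations (33 overt, 12 covert,
#' 34 empty), plus 3 practice clips, with durations between 4.81 and
#' 24.19 s and mean 11.47 s.
#'
#' @param n_game Number of game clips.
#' @param n_practice Number of practice clips (fixed composition, see
#'   [generate_bank()]).
#' @param n_overt,n_covert,n_empty Game-clip location composition.
#' @param duration_mean,duration_sd,duration_min,duration_max Truncated-normal
#'   duration distribution (seconds); generated game durations are recentred
#'   so their mean is exactly `duration_mean`.
#' @param radius Probe-circle radius in normalized screen units.
#' @return A list of class `"bank_config"`.
#' @export
bank_config <- function(n_game = 30L, n_practice = 3L,
                        n_overt = 33L, n_covert = 12L, n_empty = 34L,
                        duration_mean = 11.47, duration_sd = 5.08,
                        duration_min = 4.81, duration_max = 24.19,
                        radius = 0.05) {
  cfg <- list(
    n_game = as.integer(n_game), n_practice = as.integer(n_practice),
    n_overt = as.integer(n_overt), n_covert = as.integer(n_covert),
    n_empty = as.integer(n_empty),
    duration_mean = duration_mean, duration_sd = duration_sd,
    duration_min = duration_min, duration_max = duration_max,
    radius = radius
  )
  stopifnot(cfg$n_game >= 0, cfg$n_practice >= 0,
            cfg$n_overt >= 0, cfg$n_covert >= 0, cfg$n_empty >= 0,
            duration_min > 0, duration_min <= duration_mean,
            duration_mean <= duration_max)
  class(cfg) <- "bank_config"
  cfg
}

# Solve the per-clip location/target layout for the game clips.
# Returns a data.frame (n_locations, n_targets) with one row per clip, or
# stops with the violated constraint. Clips have 2 or 3 locations; every
# game clip holds 1 or 2 targets; a 3-location clip never holds 3 targets;
# among 2-location clips, one-target clips must outnumber two-target clips.
solve_layout <- function(cfg) {
  C <- cfg$n_game
  L <- cfg$n_overt + cfg$n_covert + cfg$n_empty
  T_ <- cfg$n_overt + cfg$n_covert
  t3 <- L - 2L * C                      # number of 3-location clips
  t2 <- C - t3
  if (t3 < 0L || t3 > C) {
    stop("infeasible bank configuration: ", L, " locations cannot be split ",
         "into ", C, " clips of 2-3 locations each", call. = FALSE)
  }
  n2 <- T_ - C                          # number of two-target clips needed
  if (n2 < 0L) {
    stop("infeasible bank configuration: fewer targets (", T_, ") than game ",
         "clips (", C, "); every clip must contain at least one target",
         call. = FALSE)
  }
  # b2 two-target clips among the 2-location clips, a2 among the 3-location
  b2_max <- min(t2, n2, if (t2 > 0L) (t2 - 1L) %/% 2L else 0L)
  b2_min <- max(0L, n2 - t3)
  if (b2_min > b2_max) {
    stop("infeasible bank configuration: cannot place ", n2, " two-target ",
         "clips while keeping at most two targets in any three-location clip ",
         "and a one-target majority among two-location clips", call. = FALSE)
  }
  b2 <- if (b2_min == b2_max) b2_min else sample(b2_min:b2_max, 1L)
  a2 <- n2 - b2
  n_loc <- c(rep(3L, t3), rep(2L, t2))
  n_tgt <- c(rep(2L, a2), rep(1L, t3 - a2), rep(2L, b2), rep(1L, t2 - b2))
  layout <- data.frame(n_locations = n_loc, n_targets = n_tgt)
  layout[sample.int(nrow(layout)), , drop = FALSE]
}

# Truncated-normal durations recentred to an exact mean without leaving
# [min, max]: deviations from the mean are shrunk just enough.
draw_durations <- function(n, cfg) {
  if (n == 0L) return(numeric(0))
  d <- numeric(0)
  while (length(d) < n) {
    x <- stats::rnorm(2L * n, cfg$duration_mean, cfg$duration_sd)
    d <- c(d, x[x >= cfg$duration_min & x <= cfg$duration_max])
  }
  d <- d[seq_len(n)]
  dev <- d - mean(d)
  s <- 1
  if (any(dev > 0)) s <- min(s, (cfg$duration_max - cfg$duration_mean) / max(dev))
  if (any(dev < 0)) s <- min(s, (cfg$duration_mean - cfg$duration_min) / -min(dev))
  cfg$duration_mean + dev * max(s, 0)
}

draw_center <- function(n) {
  # keep probe circles away from screen edges
  cbind(x = stats::runif(n, 0.1, 0.9), y = stats::runif(n, 0.1, 0.9))
}

#' Generate a synthetic stimulus bank
#'
#' Constructs a bank of practice and game clips satisfying the study's
#' structural constraints: each clip probes 2-3 locations, every game clip
#' holds one or two targets (never three), and among two-location game
#' clips those with a single target outnumber those with two. The game-clip
#' composition is exactly the configured overt/covert/empty totals, and
#' game-clip durations average exactly `duration_mean`. Practice clips use
#' a fixed composition (overt+empty, covert+empty, overt+covert when
#' `n_practice = 3`).
#'
#' @param config A [bank_config()].
#' @param seed Integer seed; the same seed always yields the same bank.
#' @return An object of class `"stimulus_bank"`: a list with
#'   `clips` (one row per clip: `clip_id`, `role`, `duration_s`,
#'   `mask_time_s`, `n_locations`), `locations` (one row per location:
#'   `clip_id`, `role`, `location_id`, `kind`, `x`, `y`, `radius`),
#'   `prevalence` (fraction of game locations holding a target) and the
#'   `config` and `seed` used.
#' @export
#' @examples
#' bank <- generate_bank(seed = 1)
#' table(bank$locations$kind[bank$locations$role == "game"])
generate_bank <- function(config = bank_config(), seed = 1L) {
  stopifnot(inherits(config, "bank_config"))
  with_seed(derive_seed(seed, "bank"), {
    layout <- solve_layout(config)
    n_game <- config$n_game
    game_ids <- sprintf("g%02d", seq_len(n_game))
    durations <- draw_durations(n_game, config)

    loc <- NULL
    if (n_game > 0L) {
      # per-clip kinds: targets first, then empties; covert labels are
      # sprinkled over the target slots
      n_tgt_total <- sum(layout$n_targets)
      covert_slot <- rep(FALSE, n_tgt_total)
      covert_slot[sample.int(n_tgt_total, config$n_covert)] <- TRUE
      kinds <- vector("list", n_game)
      k <- 0L
      for (i in seq_len(n_game)) {
        nt <- layout$n_targets[i]
        tk <- ifelse(covert_slot[k + seq_len(nt)], "covert", "overt")
        k <- k + nt
        kinds[[i]] <- sample(c(tk, rep("empty", layout$n_locations[i] - nt)))
      }
      loc <- data.frame(
        clip_id = rep(game_ids, layout$n_locations),
        role = "game",
        location_id = unlist(lapply(seq_len(n_game), function(i) {
          sprintf("%s_L%d", game_ids[i], seq_len(layout$n_locations[i]))
        })),
        kind = unlist(kinds),
        stringsAsFactors = FALSE
      )
    }

    practice_kinds <- list(c("overt", "empty"), c("covert", "empty"),
                           c("overt", "covert"))
    n_prac <- config$n_practice
    prac_ids <- sprintf("p%02d", seq_len(n_prac))
    if (n_prac > 0L) {
      pk <- rep(practice_kinds, length.out = n_prac)
      ploc <- data.frame(
        clip_id = rep(prac_ids, lengths(pk)),
        role = "practice",
        location_id = unlist(lapply(seq_len(n_prac), function(i) {
          sprintf("%s_L%d", prac_ids[i], seq_along(pk[[i]]))
        })),
        kind = unlist(pk),
        stringsAsFactors = FALSE
      )
      loc <- rbind(ploc, loc)
    }

    xy <- draw_center(nrow(loc))
    loc$x <- xy[, "x"]; loc$y <- xy[, "y"]
    loc$radius <- config$radius

    prac_dur <- if (n_prac > 0L) {
      d <- numeric(0)
      while (length(d) < n_prac) {
        x <- stats::rnorm(2L * n_prac, config$duration_mean, config$duration_sd)
        d <- c(d, x[x >= config$duration_min & x <= config$duration_max])
      }
      d[seq_len(n_prac)]
    } else numeric(0)

    clips <- data.frame(
      clip_id = c(prac_ids, game_ids),
      role = rep(c("practice", "game"), c(n_prac, n_game)),
      duration_s = c(prac_dur, durations),
      stringsAsFactors = FALSE
    )
    clips$mask_time_s <- clips$duration_s   # mask at clip end by default
    clips$n_locations <- as.integer(table(factor(loc$clip_id,
                                                 levels = clips$clip_id)))

    n_game_loc <- sum(loc$role == "game")
    bank <- list(
      clips = clips,
      locations = loc[order(match(loc$clip_id, clips$clip_id)), ],
      prevalence = if (n_game_loc > 0)
        sum(loc$role == "game" & loc$kind != "empty") / n_game_loc else NA_real_,
      config = config,
      seed = as.integer(seed)
    )
    rownames(bank$locations) <- NULL
    class(bank) <- "stimulus_bank"
    bank
  })
}

#' Validate a stimulus bank against its structural invariants
#'
#' Never raises: returns a character vector of violation descriptions,
#' empty when the bank is valid. Each violation names the offending clip
#' (where applicable) and the rule broken.
#'
#' @param bank A `"stimulus_bank"` object.
#' @return Character vector of violations (empty if valid).
#' @export
validate_bank <- function(bank) {
  v <- character(0)
  note <- function(...) v <<- c(v, sprintf(...))
  cfg <- bank$config
  clips <- bank$clips; loc <- bank$locations

  if (sum(clips$role == "game") != cfg$n_game)
    note("bank: expected %d game clips, found %d", cfg$n_game,
         sum(clips$role == "game"))
  if (sum(clips$role == "practice") != cfg$n_practice)
    note("bank: expected %d practice clips, found %d", cfg$n_practice,
         sum(clips$role == "practice"))
  if (!all(loc$kind %in% c("overt", "covert", "empty")))
    note("bank: unknown location kind(s): %s",
         paste(setdiff(unique(loc$kind), c("overt", "covert", "empty")),
               collapse = ", "))
  if (any(loc$x < 0 | loc$x > 1 | loc$y < 0 | loc$y > 1))
    note("bank: location centers outside the unit square")
  if (any(loc$radius <= 0))
    note("bank: non-positive probe radius")

  for (i in seq_len(nrow(clips))) {
    id <- clips$clip_id[i]
    lc <- loc[loc$clip_id == id, ]
    n <- nrow(lc)
    if (n < 2L || n > 3L)
      note("%s: location-count rule violated (%d locations, expected 2-3)",
           id, n)
    nt <- sum(lc$kind != "empty")
    if (n == 3L && nt > 2L)
      note("%s: three-location clip with %d targets (at most 2 allowed)",
           id, nt)
    if (clips$role[i] == "game" && (nt < 1L || nt > 2L))
      note("%s: game clip with %d targets (expected 1 or 2)", id, nt)
    if (!(clips$mask_time_s[i] > 0 && clips$mask_time_s[i] <= clips$duration_s[i]))
      note("%s: mask time %.2f outside (0, duration %.2f]",
           id, clips$mask_time_s[i], clips$duration_s[i])
  }

  gl <- loc[loc$role == "game", ]
  comp <- c(overt = sum(gl$kind == "overt"), covert = sum(gl$kind == "covert"),
            empty = sum(gl$kind == "empty"))
  want <- c(overt = cfg$n_overt, covert = cfg$n_covert, empty = cfg$n_empty)
  if (!identical(unname(comp), unname(as.integer(want))))
    note("bank: game composition %s does not match configured %s",
         paste(comp, collapse = "/"), paste(want, collapse = "/"))

  # one-target majority among two-location game clips
  two_loc <- clips$clip_id[clips$role == "game" & clips$n_locations == 2L]
  if (length(two_loc)) {
    nt2 <- vapply(two_loc, function(id)
      sum(loc$kind[loc$clip_id == id] != "empty"), integer(1))
    if (sum(nt2 == 1L) <= sum(nt2 == 2L))
      note("bank: two-location game clips with one target (%d) do not outnumber those with two (%d)",
           sum(nt2 == 1L), sum(nt2 == 2L))
  }
  v
}

#' Randomize the clip presentation order
#'
#' Practice clips come first in a fixed order; the game clips follow in a
#' seeded random permutation, as in the study protocol.
#'
#' @param bank A valid `"stimulus_bank"`.
#' @param seed Integer seed.
#' @return Character vector of clip ids (practice first, then permuted game).
#' @export
randomize_order <- function(bank, seed = 1L) {
  prac <- bank$clips$clip_id[bank$clips$role == "practice"]
  game <- bank$clips$clip_id[bank$clips$role == "game"]
  with_seed(derive_seed(seed, "order"), c(prac, sample(game)))
}

#' @export
print.stimulus_bank <- function(x, ...) {
  gl <- x$locations[x$locations$role == "game", ]
  cat(sprintf(
    "<stimulus_bank> %d game + %d practice clips, %d game locations (%d overt / %d covert / %d empty), prevalence %.3f\n",
    sum(x$clips$role == "game"), sum(x$clips$role == "practice"), nrow(gl),
    sum(gl$kind == "overt"), sum(gl$kind == "covert"), sum(gl$kind == "empty"),
    x$prevalence))
  invisible(x)
}

#' Write / read a stimulus bank as delimited text
#'
#' The bank is stored as a TSV of locations joined with clip metadata, plus
#' a JSON sidecar holding the configuration, seed and schema version.
#'
#' @param bank A `"stimulus_bank"`.
#' @param dir Directory to write into (created if missing).
#' @return `write_bank` returns the directory invisibly; `read_bank`
#'   returns the reconstructed `"stimulus_bank"`.
#' @export
write_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- merge(bank$locations,
               bank$clips[, c("clip_id", "duration_s", "mask_time_s")],
               by = "clip_id", sort = FALSE)
  tab <- tab[order(match(tab$clip_id, bank$clips$clip_id)), ]
  utils::write.table(tab, file.path(dir, "bank.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(schema_version = BANK_SCHEMA_VERSION, seed = bank$seed,
               config = unclass(bank$config))
  jsonlite::write_json(side, file.path(dir, "bank.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

BANK_SCHEMA_VERSION <- "1"

#' @rdname write_bank
#' @export
read_bank <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "bank.json"), simplifyVector = TRUE)
  if (!identical(as.character(side$schema_version), BANK_SCHEMA_VERSION))
    stop("bank schema version mismatch: file has ",
         side$schema_version %||% "<none>", ", expected ",
         BANK_SCHEMA_VERSION, call. = FALSE)
  tab <- utils::read.table(file.path(dir, "bank.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  clips <- unique(tab[, c("clip_id", "role", "duration_s", "mask_time_s")])
  clips$n_locations <- as.integer(table(factor(tab$clip_id,
                                               levels = clips$clip_id)))
  loc <- tab[, c("clip_id", "role", "location_id", "kind", "x", "y", "radius")]
  n_game_loc <- sum(loc$role == "game")
  cfg <- do.call(bank_config, side$config)
  bank <- list(clips = clips, locations = loc,
               prevalence = if (n_game_loc > 0)
                 sum(loc$role == "game" & loc$kind != "empty") / n_game_loc
               else NA_real_,
               config = cfg, seed = as.integer(side$seed))
  rownames(bank$clips) <- rownames(bank$locations) <- NULL
  class(bank) <- "stimulus_bank"
  bank
}

`%||%` <- function(a, b) if (is.null(a)) b else a
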