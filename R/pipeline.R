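# Orchestration: one seeded run from bank generation through cohort
# simulation, scoring, SDT and gaze metrics, to the inferential analyses,
# producing report tables shaped like the study's Tables 1-3.

#' Study configuration
#'
#' Bundles every knob of a full simulated study run. Defaults reproduce
#' the study conditions: 36 children and 22 adults playing a 30-game-clip
#' bank with the default group profiles.
#'
#' @param seed Root seed; every stage derives its own stream from it.
#' @param n_children,n_adults Cohort sizes.
#' @param bank_config A [bank_config()].
#' @param child_profile,adult_profile Group [observer_profile()]s.
#' @param jitter A [cohort_jitter()].
#' @param n_gaze_targets Number of analysed AOI targets.
#' @param min_glance,max_gap Glance-detection parameters (seconds).
#' @param include_gaze Simulate and analyse gaze traces.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(seed = 1L, n_children = 36L, n_adults = 22L,
                         bank_config = sagame::bank_config(),
                         child_profile = sagame::child_profile(),
                         adult_profile = sagame::adult_profile(),
                         jitter = cohort_jitter(),
                         n_gaze_targets = 10L,
                         min_glance = 0.1, max_gap = 0.075,
                         include_gaze = TRUE) {
  structure(list(seed = as.integer(seed), n_children = as.integer(n_children),
                 n_adults = as.integer(n_adults), bank_config = bank_config,
                 child_profile = child_profile, adult_profile = adult_profile,
                 jitter = jitter, n_gaze_targets = as.integer(n_gaze_targets),
                 min_glance = min_glance, max_gap = max_gap,
                 include_gaze = include_gaze),
            class = "study_config")
}

# Table-1-like: mean percentage correct by location kind x group x role
location_type_table <- function(cohort) {
  rows <- list()
  for (sess in cohort) {
    r <- sess$responses
    correct <- ifelse(r$target_present, r$selected, !r$selected)
    agg <- stats::aggregate(correct,
                            by = list(role = r$role, kind = r$kind),
                            FUN = mean)
    agg$participant_id <- sess$participant_id
    agg$group <- sess$profile$group
    rows[[length(rows) + 1L]] <- agg
  }
  all <- do.call(rbind, rows)
  out <- stats::aggregate(x ~ role + kind + group, data = all,
                          FUN = function(z) c(mean = mean(z), sd = stats::sd(z)))
  data.frame(role = out$role, kind = out$kind, group = out$group,
             pct_correct = 100 * out$x[, "mean"],
             sd = 100 * out$x[, "sd"])
}

# Table-2-like: group x phase means (sds) of rates, d', criteria, bias
phase_table <- function(sdt) {
  s <- sdt[sdt$window != "overall", ]
  vars <- c("hit_rate", "fa_rate", "d_prime", "lambda_obs", "lambda_opt",
            "bias")
  out <- stats::aggregate(s[, vars], by = list(group = s$group,
                                               window = s$window), mean)
  sds <- stats::aggregate(s[, vars], by = list(group = s$group,
                                               window = s$window), stats::sd)
  names(sds)[-(1:2)] <- paste0(vars, "_sd")
  m <- merge(out, sds, by = c("group", "window"))
  m$window <- factor(m$window, levels = c("start", "middle", "end"))
  m[order(m$group, m$window), ]
}

#' Run a full simulated study
#'
#' Generates the bank, simulates the cohort, scores the game, computes the
#' SDT and gaze summaries, and runs the study's inferential analyses:
#' group comparisons of overall accuracy and points (Welch), the
#' accuracy/response-time/d-prime/bias phase-by-group ANOVAs with linear
#' contrasts, gaze-parameter regressions on logit accuracy, the working
#' memory (PCU) regressions with the nested model comparison, and the
#' accuracy-points correlation.
#'
#' @param config A [study_config()].
#' @return A list of class `"study_report"` with elements `bank`, `tracks`,
#'   `sdt` (tidy per-participant per-window summaries), `points`,
#'   `pcu`, `gaze`, `tables` (table1/table2/table3-shaped data.frames),
#'   `inference`, and `provenance`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  bank <- generate_bank(config$bank_config, seed = seed)
  violations <- validate_bank(bank)
  if (length(violations))
    stop("stage bank: generated bank invalid: ", violations[1],
         call. = FALSE)
  tracks <- if (config$include_gaze)
    generate_aoi_tracks(bank, config$n_gaze_targets, seed = seed) else NULL
  cohort <- simulate_cohort(config$n_children, config$n_adults, bank,
                            seed = seed,
                            child_profile = config$child_profile,
                            adult_profile = config$adult_profile,
                            jitter = config$jitter, tracks = tracks)
  if (length(cohort) == 0L)
    stop("stage simulate: empty cohort", call. = FALSE)

  sdt <- summarize_cohort(cohort, bank)
  points <- data.frame(
    participant_id = vapply(cohort, `[[`, "", "participant_id"),
    group = vapply(cohort, function(s) s$profile$group, ""),
    final_points = vapply(cohort, function(s)
      score_session(s, bank)$board$final_points, numeric(1)))
  pcu <- data.frame(
    participant_id = points$participant_id, group = points$group,
    pcu = vapply(cohort, function(s)
      pcu_score(s$counting_span)$pcu, numeric(1)))

  gaze <- if (config$include_gaze)
    cohort_gaze_summary(cohort, tracks, min_glance = config$min_glance,
                        max_gap = config$max_gap) else NULL

  overall <- sdt[sdt$window == "overall", ]
  groups <- unique(overall$group)
  two_groups <- length(groups) == 2L

  inference <- list()
  if (two_groups) {
    acc_c <- overall$accuracy[overall$group == "child"]
    acc_a <- overall$accuracy[overall$group == "adult"]
    inference$accuracy_group <- welch_t(acc_a, acc_c)
    inference$points_group <- welch_t(
      points$final_points[points$group == "adult"],
      points$final_points[points$group == "child"])
    inference$pcu_group <- welch_t(pcu$pcu[pcu$group == "adult"],
                                   pcu$pcu[pcu$group == "child"])
  }
  inference$accuracy_points_r <- pearson_r(overall$accuracy,
                                           points$final_points)

  long <- sdt[sdt$window != "overall", ]
  mk_long <- function(var) data.frame(participant = long$participant_id,
                                      group = long$group, phase = long$window,
                                      value = long[[var]])
  if (two_groups && nrow(long)) {
    inference$accuracy_anova <- mixed_anova(mk_long("logit_accuracy"))
    inference$accuracy_trend <- linear_contrast(mk_long("accuracy"))
    inference$rt_anova <- mixed_anova(mk_long("mean_rt"))
    inference$rt_trend <- linear_contrast(mk_long("mean_rt"))
    inference$dprime_anova <- mixed_anova(mk_long("d_prime"))
    inference$bias_anova <- mixed_anova(mk_long("bias"))
  }

  acc_tbl <- overall[, c("participant_id", "logit_accuracy")]
  if (!is.null(gaze) && !is.null(gaze$summaries) &&
      nrow(gaze$summaries) >= 4L) {
    inference$gaze_regressions <- gaze_accuracy_regression(gaze$summaries,
                                                           acc_tbl)
  }
  wm <- merge(merge(acc_tbl, pcu, by = "participant_id"),
              overall[, c("participant_id", "group")], by = "participant_id")
  if (nrow(wm) > 3L) {
    m1 <- ols_regression(wm$logit_accuracy, data.frame(pcu = wm$pcu))
    inference$wm_model1 <- m1
    if (two_groups) {
      age <- as.integer(wm$group.x == "adult")
      m2 <- ols_regression(wm$logit_accuracy, data.frame(age_group = age))
      m12 <- ols_regression(wm$logit_accuracy,
                            data.frame(pcu = wm$pcu, age_group = age))
      inference$wm_model2 <- m2
      inference$wm_age_over_pcu <- nested_f(m1, m12)
      inference$wm_pcu_over_age <- nested_f(m2, m12)
    }
  }

  tables <- list(table1 = location_type_table(cohort),
                 table2 = phase_table(sdt),
                 table3 = if (!is.null(gaze) && !is.null(gaze$summaries)) {
                   g <- gaze$summaries
                   vars <- c("pct_targets_looked", "avg_glance_freq",
                             "avg_first_glance_latency", "avg_dwell_time")
                   means <- stats::aggregate(g[, vars],
                                             by = list(group = g$group), mean,
                                             na.rm = TRUE)
                   sds <- stats::aggregate(g[, vars],
                                           by = list(group = g$group),
                                           stats::sd, na.rm = TRUE)
                   names(sds)[-1] <- paste0(vars, "_sd")
                   merge(means, sds, by = "group")
                 } else NULL)

  structure(list(bank = bank, tracks = tracks, sdt = sdt, points = points,
                 pcu = pcu, gaze = gaze, tables = tables,
                 inference = inference,
                 provenance = list(seed = seed,
                                   n_children = config$n_children,
                                   n_adults = config$n_adults,
                                   package_version =
                                     as.character(utils::packageVersion("sagame")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d: %d children + %d adults\n",
              x$provenance$seed, x$provenance$n_children,
              x$provenance$n_adults))
  ov <- x$sdt[x$sdt$window == "overall", ]
  for (g in unique(ov$group))
    cat(sprintf("  %-6s accuracy %.1f%%, d' %.2f, bias %.2f\n", g,
                100 * mean(ov$accuracy[ov$group == g]),
                mean(ov$d_prime[ov$group == g]),
                mean(ov$bias[ov$group == g])))
  if (!is.null(x$inference$accuracy_group))
    cat(sprintf("  adults vs children accuracy: t(%.2f) = %.2f, p = %.3g, d = %.2f\n",
                x$inference$accuracy_group$df, x$inference$accuracy_group$t,
                x$inference$accuracy_group$p,
                x$inference$accuracy_group$cohen_d))
  cat(sprintf("  accuracy-points r = %.2f\n", x$inference$accuracy_points_r))
  invisible(x)
}

SESSIONS_SCHEMA_VERSION <- "1"

#' Serialize / restore a simulated cohort as delimited text
#'
#' Writes the response, response-time, counting-span (and, when present,
#' gaze sample and quality) tables as TSV files with a JSON sidecar
#' recording the schema version. `read_sessions` refuses files with a
#' different schema version.
#'
#' @param cohort An `"sa_cohort"`.
#' @param dir Output directory.
#' @return `write_sessions`: the directory, invisibly. `read_sessions`:
#'   a list of tables (`responses`, `clip_rt`, `counting_span`, `gaze`,
#'   `gaze_quality`) -- a tabular view sufficient for all downstream
#'   metrics.
#' @export
write_sessions <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  resp <- do.call(rbind, lapply(cohort, `[[`, "responses"))
  rt <- do.call(rbind, lapply(cohort, `[[`, "clip_rt"))
  span <- do.call(rbind, lapply(cohort, function(s) {
    tr <- s$counting_span$trials
    do.call(rbind, lapply(seq_along(tr), function(i) data.frame(
      participant_id = s$participant_id, trial = i,
      set_size = tr[[i]]$set_size, position = seq_len(tr[[i]]$set_size),
      true_tally = tr[[i]]$true_tallies,
      recalled_tally = tr[[i]]$recalled_tallies)))
  }))
  wr <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wr(resp, "responses.tsv"); wr(rt, "clip_rt.tsv"); wr(span, "counting_span.tsv")
  has_gaze <- !is.null(cohort[[1]]$gaze)
  if (has_gaze) {
    gz <- do.call(rbind, lapply(cohort, function(s)
      do.call(rbind, lapply(names(s$gaze), function(tid) {
        d <- s$gaze[[tid]]; d$target_id <- tid; d
      }))))
    wr(gz, "gaze.tsv")
    wr(do.call(rbind, lapply(cohort, `[[`, "gaze_quality")), "gaze_quality.tsv")
  }
  jsonlite::write_json(list(schema_version = SESSIONS_SCHEMA_VERSION,
                            n_sessions = length(cohort),
                            has_gaze = has_gaze),
                       file.path(dir, "sessions.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(dir) {
  side_path <- file.path(dir, "sessions.json")
  if (!file.exists(side_path))
    stop("not a sessions directory (sessions.json missing)", call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(as.character(side$schema_version), SESSIONS_SCHEMA_VERSION))
    stop("sessions schema version mismatch: file has ",
         side$schema_version %||% "<none>", ", expected ",
         SESSIONS_SCHEMA_VERSION, call. = FALSE)
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  out <- list(responses = rd("responses.tsv"), clip_rt = rd("clip_rt.tsv"),
              counting_span = rd("counting_span.tsv"))
  if (isTRUE(side$has_gaze)) {
    out$gaze <- rd("gaze.tsv")
    out$gaze_quality <- rd("gaze_quality.tsv")
  }
  out
}

#' Write a study report's tables and provenance to disk
#'
#' Emits the three report tables and the per-participant summary tables as
#' TSV, and the inferential results plus provenance as JSON.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wr(report$sdt, "sdt_summaries.tsv")
  wr(report$points, "points.tsv")
  wr(report$pcu, "pcu.tsv")
  if (!is.null(report$gaze) && !is.null(report$gaze$summaries))
    wr(report$gaze$summaries, "gaze_summaries.tsv")
  for (nm in names(report$tables))
    if (!is.null(report$tables[[nm]])) wr(report$tables[[nm]],
                                          paste0(nm, ".tsv"))
  flat <- lapply(report$inference, function(x) {
    if (inherits(x, "anova_result")) list(effects = x$effects,
                                          gg_epsilon = x$gg_epsilon)
    else if (inherits(x, "regression_result"))
      list(coefficients = x$coefficients, r_sq = x$r_sq,
           adj_r_sq = x$adj_r_sq, n = x$n)
    else if (is.list(x)) x[setdiff(names(x), c("L", "residuals", "y",
                                               "fitted"))]
    else x
  })
  jsonlite::write_json(list(schema_version = SESSIONS_SCHEMA_VERSION,
                            provenance = report$provenance,
                            inference = flat),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
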