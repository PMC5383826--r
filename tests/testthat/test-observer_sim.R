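# A larger bank gives ~10,000 locations for the rate-convergence checks.
big_bank <- generate_bank(bank_config(n_game = 300, n_practice = 0,
                                      n_overt = 330, n_covert = 120,
                                      n_empty = 340), seed = 77)

sim_rates <- function(profile, n_sessions = 13, bank = big_bank) {
  sel_t <- sel_n <- n_t <- n_n <- 0
  for (i in seq_len(n_sessions)) {
    ord <- randomize_order(bank, seed = i)
    sess <- simulate_responses(profile, bank, ord, seed = 1000 + i)
    r <- sess$responses
    sel_t <- sel_t + sum(r$selected & r$target_present)
    sel_n <- sel_n + sum(r$selected & !r$target_present)
    n_t <- n_t + sum(r$target_present)
    n_n <- n_n + sum(!r$target_present)
  }
  c(hit = sel_t / n_t, fa = sel_n / n_n, n = n_t + n_n)
}

test_that("a zero-sensitivity unbiased observer selects half of everything", {
  r <- sim_rates(flat_profile(0, 0))
  expect_gte(r[["n"]], 10000)
  expect_lt(abs(r[["hit"]] - 0.5), 0.02)
  expect_lt(abs(r[["fa"]] - 0.5), 0.02)
})

test_that("hit and false-alarm rates converge to the Gaussian tail probabilities", {
  # d' = 4, criterion 2: hit = Phi(2), fa = Phi(-2)
  r <- sim_rates(flat_profile(4, 2))
  expect_lt(abs(r[["hit"]] - stats::pnorm(2)), 0.01)
  expect_lt(abs(r[["fa"]] - stats::pnorm(-2)), 0.01)
})

test_that("sessions are deterministic for a fixed seed", {
  ord <- randomize_order(fixture_bank, seed = 4)
  s1 <- simulate_responses(adult_profile(), fixture_bank, ord, seed = 8)
  s2 <- simulate_responses(adult_profile(), fixture_bank, ord, seed = 8)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$clip_rt, s2$clip_rt)
  s3 <- simulate_responses(adult_profile(), fixture_bank, ord, seed = 9)
  expect_false(identical(s1$responses$selected, s3$responses$selected))
})

test_that("order/bank mismatch is rejected", {
  ord <- randomize_order(fixture_bank, seed = 4)
  expect_error(simulate_responses(adult_profile(), fixture_bank, ord[-5]),
               "order")
})

test_that("phase-wise parameters drive phase-wise behaviour", {
  prof <- observer_profile("adult", d_prime_by_phase = c(0.5, 1.5, 3),
                           criterion = 0.75)
  acc <- numeric(3)
  for (i in 1:40) {
    ord <- randomize_order(fixture_bank, seed = i)
    sess <- simulate_responses(prof, fixture_bank, ord, seed = i)
    s <- per_phase_summary(sess, fixture_bank)
    acc <- acc + s$accuracy[match(c("start", "middle", "end"), s$window)]
  }
  expect_true(all(diff(acc) > 0))
})

test_that("counting-span schedule, stop rule and determinism behave as specified", {
  tr <- simulate_counting_span(8, noise = 0, seed = 3)
  expect_length(tr$trials, 21)
  expect_false(tr$stopped_early)
  expect_equal(sum(vapply(tr$trials, `[[`, numeric(1), "set_size")), 105)
  expect_equal(vapply(tr$trials, `[[`, numeric(1), "set_size"),
               rep(2:8, each = 3))
  expect_true(all(vapply(tr$trials, function(x)
    all(x$true_tallies %in% 2:8), logical(1))))

  # capacity 0 with certain errors: stops after the first three trials
  tr0 <- simulate_counting_span(0, noise = 1, seed = 3)
  expect_length(tr0$trials, 3)
  expect_true(tr0$stopped_early)

  expect_identical(simulate_counting_span(4, seed = 11),
                   simulate_counting_span(4, seed = 11))
})

test_that("mean PCU is monotone in working-memory capacity", {
  mean_pcu <- function(cap) {
    mean(vapply(1:200, function(s)
      pcu_score(simulate_counting_span(cap, noise = 0.05, seed = s))$pcu,
      numeric(1)))
  }
  p2 <- mean_pcu(2); p4 <- mean_pcu(4); p8 <- mean_pcu(8)
  expect_lt(p2, p4)
  expect_lt(p4, p8)
})

test_that("gaze traces respect p_look and record the requested quality", {
  track <- make_track(appear = 1, end = 15)
  clip <- data.frame(clip_id = "g01", duration_s = 15, mask_time_s = 15)
  prof0 <- adult_profile(); prof0$p_look <- 0
  for (s in 1:20) {
    g <- simulate_gaze(prof0, clip, track, seed = s)
    expect_equal(nrow(detect_glances(g$samples, track)), 0)
  }
  g3 <- simulate_gaze(adult_profile(), clip, track, seed = 1,
                      calibration_error = 3)
  expect_equal(g3$quality$calibration_error, 3)
  expect_gte(g3$quality$effective_rate, 10)
  expect_lte(g3$quality$effective_rate, 30)
})

test_that("first-glance latency is recovered from generated gaze", {
  track <- make_track(appear = 1, end = 15)
  clip <- data.frame(clip_id = "g01", duration_s = 15, mask_time_s = 15)
  prof <- adult_profile()
  prof$p_look <- 1; prof$glance_latency_mean <- 2.0
  lat <- vapply(1:500, function(s) {
    g <- simulate_gaze(prof, clip, track, seed = s)
    gl <- detect_glances(g$samples, track)
    if (nrow(gl)) gl$onset[1] - track$appear_time else NA_real_
  }, numeric(1))
  expect_lt(mean(is.na(lat)), 0.02)
  expect_lt(abs(mean(lat, na.rm = TRUE) - 2.0), 0.15)
})

test_that("cohorts have the right size, derive independent seeds, and reproduce", {
  co <- simulate_cohort(3, 2, fixture_bank, seed = 6)
  expect_length(co, 5)
  expect_equal(vapply(co, function(s) s$profile$group, ""),
               c("child", "child", "child", "adult", "adult"))
  expect_length(simulate_cohort(0, 0, fixture_bank, seed = 6), 0)
  # distinct participants get distinct orders/responses
  expect_false(identical(co[[1]]$order, co[[2]]$order))

  co2 <- simulate_cohort(3, 2, fixture_bank, seed = 6)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_sessions(co, dir1); write_sessions(co2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
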