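counts_of <- function(h, m, fa, cr)
  structure(list(hits = h, misses = m, false_alarms = fa,
                 correct_rejections = cr, n_signal = h + m, n_noise = fa + cr),
            class = "confusion_counts")

test_that("confusion tallies match hand counts and collapse target kinds", {
  r <- data.frame(
    clip_id = "g01",
    target_present = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    selected = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  ct <- tally_counts(r, clips = "g01")
  expect_equal(ct$hits, 2); expect_equal(ct$misses, 1)
  expect_equal(ct$false_alarms, 1); expect_equal(ct$correct_rejections, 2)

  all45 <- data.frame(clip_id = "c",
                      target_present = rep(c(TRUE, FALSE), c(45, 34)),
                      selected = rep(c(TRUE, FALSE), c(45, 34)))
  ct2 <- tally_counts(all45, clips = "c")
  expect_equal(unlist(ct2[c("hits", "misses", "false_alarms",
                            "correct_rejections")]),
               c(hits = 45, misses = 0, false_alarms = 0,
                 correct_rejections = 34))
  all45$selected <- FALSE
  ct3 <- tally_counts(all45, clips = "c")
  expect_equal(c(ct3$hits, ct3$misses, ct3$false_alarms,
                 ct3$correct_rejections), c(0, 45, 0, 34))
  expect_error(tally_counts(all45, clips = "nope"), "empty")
})

test_that("log-linear correction adds 0.5/1 and keeps rates interior", {
  r <- loglinear_rates(counts_of(8, 2, 0, 34))
  expect_equal(r[["hit_rate"]], 8.5 / 11)
  expect_equal(r[["fa_rate"]], 0.5 / 35)
  r2 <- loglinear_rates(counts_of(45, 0, 34, 0))
  expect_equal(r2[["hit_rate"]], 45.5 / 46)
  expect_equal(r2[["fa_rate"]], 34.5 / 35)
  expect_true(all(r > 0 & r < 1) && all(r2 > 0 & r2 < 1))
  expect_error(loglinear_rates(counts_of(0, 0, 3, 4)), "signal")
})

test_that("d-prime matches the quantile oracle and is antisymmetric", {
  expect_equal(dprime(0.84, 0.16), 1.9889157664, tolerance = 1e-8)
  expect_equal(dprime(0.84, 0.16), qnorm_oracle(0.84) - qnorm_oracle(0.16),
               tolerance = 1e-8)
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.16, 0.84), -dprime(0.84, 0.16))
  # strictly increasing in hit rate, decreasing in fa rate
  h <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(dprime(h, 0.2)) > 0))
  expect_true(all(diff(dprime(0.8, h)) < 0))
  expect_error(dprime(1, 0.5), "log-linear")
})

test_that("observed criterion is the negated quantile of the false-alarm rate", {
  expect_equal(observed_criterion(0.5), 0)
  expect_equal(observed_criterion(0.16), 0.9944578832, tolerance = 1e-8)
  expect_equal(observed_criterion(0.84), -observed_criterion(0.16))
  # a liberal observer (FA 41%) sits at a small positive criterion,
  # matching the reported group means
  expect_lt(abs(observed_criterion(0.41) - 0.2275), 1e-3)
  expect_error(observed_criterion(0), "log-linear")
})

test_that("optimal criterion shifts liberal under high prevalence", {
  expect_equal(optimal_criterion(1.3, 0.5), 0.65)
  expect_equal(optimal_criterion(1.9889157664, 45 / 79), 0.8535258388,
               tolerance = 1e-8)
  expect_error(optimal_criterion(0, 0.5), "zero sensitivity")
  # continuity near s = 0.5
  expect_equal(optimal_criterion(1.5, 0.5 + 1e-9), optimal_criterion(1.5, 0.5),
               tolerance = 1e-6)
})

test_that("response bias is the criterion difference, as in the phase tables", {
  expect_equal(response_bias(1.2, 1.2), 0)
  expect_equal(response_bias(0.24, -0.20), 0.44)
  expect_lt(abs(response_bias(0.68, 0.64) - 0.04), 0.01)
})

test_that("accuracy and its logit follow the printed definitions", {
  expect_equal(accuracy(counts_of(45, 0, 0, 34)), 1)
  expect_equal(accuracy(counts_of(30, 15, 10, 24)), 54 / 79)
  expect_equal(logit_accuracy(0.5), 0)
  expect_equal(logit_accuracy(0.72), 0.9444616088, tolerance = 1e-8)
  expect_error(logit_accuracy(1), "log-linear")
})

test_that("PCU averages per-trial proportions over administered trials", {
  perfect <- make_transcript(list(
    list(true = c(2, 3), recalled = c(2, 3)),
    list(true = c(4, 5, 6), recalled = c(4, 5, 6))))
  expect_equal(pcu_score(perfect)$pcu, 1)
  wrong <- make_transcript(list(
    list(true = c(2, 3), recalled = c(3, 2))))
  expect_equal(pcu_score(wrong)$pcu, 0)
  mixed <- make_transcript(list(
    list(true = c(2, 3, 4), recalled = c(2, 3, 8)),   # 2/3
    list(true = c(5, 6), recalled = c(5, 2))))        # 1/2
  expect_equal(pcu_score(mixed)$pcu, 7 / 12)
  # positional scoring: right digits in the wrong slots earn nothing
  swapped <- make_transcript(list(list(true = c(2, 3), recalled = c(3, 2))))
  expect_equal(pcu_score(swapped)$pcu, 0)
  expect_error(pcu_score(make_transcript(list())), "empty")
})

test_that("per-phase windows partition the 79 game locations and carry the bias identity", {
  sess <- simulate_responses(adult_profile(), fixture_bank,
                             randomize_order(fixture_bank, seed = 2), seed = 2)
  s <- per_phase_summary(sess, fixture_bank)
  phases <- s[s$window != "overall", ]
  expect_equal(sum(phases$n_signal + phases$n_noise), 79)
  expect_equal(s$n_signal[s$window == "overall"], 45)
  expect_equal(s$bias, s$lambda_obs - s$lambda_opt)
  expect_true(all(s$hit_rate > 0 & s$hit_rate < 1))
})

test_that("summaries recover generative sensitivity and bias", {
  # moderate sensitivity: log-linear shrinkage is mild, so the mean
  # estimate should sit close to an exact binomial-expectation oracle
  dp <- 1.5; lam <- 0.75
  exp_z <- function(n, p) {
    k <- 0:n
    sum(stats::dbinom(k, n, p) * stats::qnorm((k + 0.5) / (n + 1)))
  }
  oracle_d <- exp_z(45, stats::pnorm(dp - lam)) - exp_z(34, stats::pnorm(-lam))
  est <- vapply(1:60, function(s) {
    sess <- simulate_responses(flat_profile(dp, lam), fixture_bank,
                               randomize_order(fixture_bank, seed = s),
                               seed = s)
    per_phase_summary(sess, fixture_bank)$d_prime[4]
  }, numeric(1))
  expect_lt(abs(mean(est) - oracle_d), 0.1)
  expect_lt(abs(mean(est) - dp), 0.15)

  # an observer holding the accuracy-optimal criterion shows ~zero bias
  lam_opt <- optimal_criterion(dp, 45 / 79)
  bias <- vapply(1:60, function(s) {
    sess <- simulate_responses(flat_profile(dp, lam_opt), fixture_bank,
                               randomize_order(fixture_bank, seed = s),
                               seed = s + 500)
    per_phase_summary(sess, fixture_bank)$bias[4]
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.15)
})
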