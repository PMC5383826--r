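test_that("Welch's t matches the Welch-Satterthwaite arithmetic", {
  r <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, -1.5491933385, tolerance = 1e-8)
  expect_equal(r$df, 2.9411764706, tolerance = 1e-8)
  # pooled-sd Cohen's d by hand: sd_p = sqrt((1 + 4) / 2)
  expect_equal(r$cohen_d, -2 / sqrt(2.5), tolerance = 1e-10)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # equal variances, equal n: df collapses to n1 + n2 - 2
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  expect_equal(welch_t(a, b)$df, 6, tolerance = 1e-9)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch's t is antisymmetric in its arguments", {
  set.seed(1)
  a <- rnorm(12); b <- rnorm(9, 1, 2)
  r1 <- welch_t(a, b); r2 <- welch_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$cohen_d, -r2$cohen_d)
})

make_rm_data <- function(n1, n2, seed = 1, phase_effect = c(0, 0, 0),
                         group_effect = 0, subj_sd = 1, noise_sd = 1) {
  withr::with_seed(seed, {
    n <- n1 + n2
    grp <- rep(c("g1", "g2"), c(n1, n2))
    subj <- rnorm(n, 0, subj_sd)
    do.call(rbind, lapply(1:3, function(j) data.frame(
      participant = sprintf("s%02d", 1:n), group = grp,
      phase = c("start", "middle", "end")[j],
      value = subj + phase_effect[j] + (grp == "g2") * group_effect +
        rnorm(n, 0, noise_sd))))
  })
}

test_that("mixed ANOVA reproduces the aov split-plot decomposition", {
  d <- make_rm_data(7, 5, seed = 42, phase_effect = c(0, 0.3, 0.8),
                    group_effect = 1)
  res <- mixed_anova(d)
  a <- summary(stats::aov(value ~ group * phase + Error(participant / phase),
                          data = d))
  between <- a[["Error: participant"]][[1]]
  within <- a[["Error: participant:phase"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  e <- res$effects
  expect_equal(e["group", "F"], between["group", "F value"], tolerance = 1e-10)
  expect_equal(e["group", "p"], between["group", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(e["phase", "F"], within["phase", "F value"], tolerance = 1e-10)
  expect_equal(e["phase:group", "F"], within["group:phase", "F value"],
               tolerance = 1e-10)
  expect_equal(e["phase", "df2"], 20)
  expect_equal(e["group", "df2"], 10)
  # partial eta^2 from the same SS
  expect_equal(e["group", "partial_eta_sq"],
               between["group", "Sum Sq"] /
                 (between["group", "Sum Sq"] + between["Residuals", "Sum Sq"]),
               tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon matches the multivariate reference", {
  d <- make_rm_data(7, 5, seed = 42, phase_effect = c(0, 0.3, 0.8),
                    group_effect = 1)
  res <- mixed_anova(d)
  wide <- stats::reshape(d, idvar = c("participant", "group"),
                         timevar = "phase", direction = "wide")
  mod <- stats::lm(cbind(value.start, value.middle, value.end) ~ group,
                   data = wide)
  idata <- data.frame(phase = factor(c("start", "middle", "end"),
                                     levels = c("start", "middle", "end")))
  s <- suppressWarnings(summary(car::Anova(mod, idata = idata,
                                           idesign = ~phase),
                                multivariate = FALSE))
  expect_equal(res$gg_epsilon, unname(s$pval.adjustments["phase", "GG eps"]),
               tolerance = 1e-10)
  expect_equal(res$effects["phase", "p_gg"],
               unname(s$pval.adjustments["phase", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("epsilon respects its analytic bounds and the sphericity-true case", {
  for (s in 1:15) {
    d <- make_rm_data(6, 6, seed = s, noise_sd = runif(1, 0.5, 2))
    eps <- mixed_anova(d)$gg_epsilon
    expect_gte(eps, 0.5)   # lower bound 1/(k-1) for k = 3
    expect_lte(eps, 1)
  }
  # compound symmetry: epsilon should hover near 1
  eps <- vapply(1:30, function(s)
    mixed_anova(make_rm_data(20, 20, seed = s, subj_sd = 1))$gg_epsilon,
    numeric(1))
  expect_gte(mean(eps), 0.9)
  expect_lte(mean(eps), 1)
})

test_that("identical phase means give zero phase F; constant data flags degenerate contrast", {
  d <- make_rm_data(5, 4, seed = 3)
  wide <- stats::xtabs(value ~ participant + phase, d)
  flat <- d
  flat$value <- ave(flat$value, flat$participant)  # same value in each phase
  res <- mixed_anova(flat)
  expect_equal(res$effects["phase", "F"], 0, tolerance = 1e-20)

  lc <- linear_contrast(flat)
  expect_true(lc$degenerate)
  expect_equal(lc$t, 0)

  ramp <- d
  ramp$value <- as.numeric(factor(ramp$phase,
                                  levels = c("start", "middle", "end"))) - 1
  lr <- linear_contrast(ramp)
  expect_equal(lr$mean_L, 2)
  expect_true(lr$degenerate)
})

test_that("the linear contrast estimates twice the per-phase slope", {
  mean_L <- mean(vapply(1:500, function(s) {
    d <- make_rm_data(10, 0, seed = s, phase_effect = c(0, 0.4, 0.8))
    linear_contrast(d)$mean_L
  }, numeric(1)))
  expect_lt(abs(mean_L - 0.8), 0.05)
})

test_that("OLS regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  r <- ols_regression(y, data.frame(x = x))
  # hand normal equations
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(r$coefficients$B, c(b0, b1), tolerance = 1e-10)
  expect_equal(r$adj_r_sq, 1 - (1 - r$r_sq) * 4 / 3, tolerance = 1e-12)

  exact <- suppressWarnings(ols_regression(2 * x + 1, data.frame(x = x)))
  expect_equal(exact$r_sq, 1)
  expect_equal(exact$adj_r_sq, 1)

  # residual orthogonality on standardized data
  set.seed(7)
  X <- scale(matrix(rnorm(200), 50, 4))
  yy <- rnorm(50)
  rr <- ols_regression(yy, as.data.frame(X))
  expect_lt(max(abs(crossprod(X, rr$residuals))), 1e-8)

  expect_error(ols_regression(yy, data.frame(a = X[, 1], b = X[, 1])),
               "rank")
  expect_error(ols_regression(1:3, data.frame(a = 1:3, b = 3:1)),
               "observations")
})

test_that("adjusted R-squared is centred at zero under the null", {
  adj <- vapply(1:100, function(s) withr::with_seed(s, {
    ols_regression(rnorm(1000), data.frame(x = rnorm(1000)))$adj_r_sq
  }), numeric(1))
  expect_lt(abs(mean(adj)), 0.02)
})

test_that("nested-model F agrees with the sequential anova table", {
  set.seed(9)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- 1 + 0.5 * x1 + 0.3 * x2 + rnorm(40)
  m1 <- ols_regression(y, data.frame(x1 = x1))
  m12 <- ols_regression(y, data.frame(x1 = x1, x2 = x2))
  cmp <- nested_f(m1, m12)
  ref <- stats::anova(stats::lm(y ~ x1), stats::lm(y ~ x1 + x2))
  expect_equal(cmp$F, ref$F[2], tolerance = 1e-10)
  expect_equal(cmp$p, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(cmp$df1, 1); expect_equal(cmp$df2, 37)
  expect_equal(cmp$delta_r_sq, m12$r_sq - m1$r_sq)

  self <- nested_f(m12, m12)
  expect_equal(self$F, 0); expect_equal(self$delta_r_sq, 0)
  m2 <- ols_regression(y, data.frame(x2 = x2))
  expect_error(nested_f(m12, m2), "nested")
  expect_error(nested_f(ols_regression(y + 1, data.frame(x1 = x1)), m12),
               "same response")
})

test_that("Pearson correlation hits the exact cases and flags zero variance", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_warning(r0 <- pearson_r(x, rep(2, 5)), "zero variance")
  expect_true(is.na(r0))
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("simulated default cohorts couple accuracy tightly to points", {
  bank <- fixture_bank
  co <- simulate_cohort(18, 12, bank, seed = 77)
  sdt <- summarize_cohort(co, bank)
  ov <- sdt[sdt$window == "overall", ]
  pts <- vapply(co, function(s) score_session(s, bank)$board$final_points,
                numeric(1))
  expect_gt(pearson_r(ov$accuracy, pts), 0.5)
})
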