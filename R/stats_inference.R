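# Inferential toolkit: Welch's t with Cohen's d, mixed two-way
# repeated-measures ANOVA with Greenhouse-Geisser correction and partial
# eta-squared, polynomial (linear) contrasts, OLS regression with adjusted
# R-squared, nested-model delta-R-squared F-tests, and Pearson correlation.

# order phase labels start/middle/end when present, else keep sorted order
canonical_phase <- function(phase) {
  if (is.factor(phase)) return(phase)
  lv <- c("start", "middle", "end")
  if (all(phase %in% lv)) factor(phase, levels = lv) else factor(phase)
}

#' Welch's unequal-variances t-test with Cohen's d
#'
#' Two-sided Welch t-test (delegating to [stats::t.test()]) plus a
#' standardized mean difference. By default Cohen's d uses the pooled
#' standard deviation; `pooled = FALSE` standardizes by the root mean of
#' the two variances instead.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param pooled Use the pooled-sd Cohen's d (default).
#' @return Object of class `"ttest_result"`: `t`, `df`
#'   (Welch-Satterthwaite, real), `p`, `cohen_d`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
welch_t <- function(a, b, pooled = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  sd_std <- if (pooled)
    sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  else sqrt((va + vb) / 2)
  d <- if (sd_std > 0) (mean(a) - mean(b)) / sd_std else NA_real_
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohen_d = d,
                 mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Welch's t(%.2f) = %.3f, p = %.4g, d = %.2f\n",
              x$df, x$t, x$p, x$cohen_d))
  invisible(x)
}

#' Mixed two-way repeated-measures ANOVA
#'
#' Split-plot ANOVA with one between-subjects factor (group) and one
#' within-subjects factor (phase), computed from the classical
#' sum-of-squares decomposition for designs balanced over the within
#' factor (unequal group sizes allowed; no missing cells). Reports F, df,
#' p and partial eta-squared per effect, plus the Greenhouse-Geisser
#' epsilon estimated from the eigenvalues of the double-centred pooled
#' within-group covariance of the repeated measures, and GG-corrected
#' degrees of freedom and p-values for the within-subject effects.
#'
#' @param data Data.frame with columns `participant`, `group`, `phase`,
#'   `value`; every participant must have exactly one value per phase.
#' @return Object of class `"anova_result"`: `effects` (data.frame with
#'   rows group, phase, phase:group), `gg_epsilon`, `n_subjects`,
#'   `n_phases`.
#' @export
mixed_anova <- function(data) {
  need <- c("participant", "group", "phase", "value")
  stopifnot(all(need %in% names(data)))
  if (any(is.na(data$value)))
    stop("missing cells are not supported (no imputation)", call. = FALSE)
  data$phase <- canonical_phase(data$phase)
  wide <- stats::xtabs(value ~ participant + phase, data)
  counts <- stats::xtabs(~ participant + phase, data)
  if (any(counts != 1L))
    stop("design must be balanced: one value per participant and phase",
         call. = FALSE)
  Y <- matrix(as.numeric(wide), nrow = nrow(wide),
              dimnames = dimnames(wide))
  pid <- rownames(Y)
  grp <- data$group[match(pid, data$participant)]
  k <- ncol(Y); N <- nrow(Y); G <- length(unique(grp))
  if (N < 2L || any(table(grp) < 2L))
    stop("need at least 2 participants per group", call. = FALSE)

  grand <- mean(Y)
  subj_mean <- rowMeans(Y)
  phase_mean <- colMeans(Y)
  group_mean <- tapply(subj_mean, grp, mean)
  n_g <- stats::setNames(as.numeric(table(grp)), names(table(grp)))

  ss_between <- k * sum((subj_mean - grand)^2)
  ss_group <- k * sum(n_g * (group_mean[names(n_g)] - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_phase <- N * sum((phase_mean - grand)^2)
  cell_mean <- apply(Y, 2, function(col) tapply(col, grp, mean))  # G x k
  inter_dev <- sweep(sweep(cell_mean, 1, group_mean[rownames(cell_mean)]),
                     2, phase_mean) + grand
  ss_inter <- sum(as.numeric(n_g[rownames(cell_mean)]) * inter_dev^2)
  ss_within <- sum((Y - subj_mean)^2)
  ss_err_within <- ss_within - ss_phase - ss_inter

  df_group <- G - 1; df_subj <- N - G
  df_phase <- k - 1; df_inter <- (G - 1) * (k - 1)
  df_err_w <- (N - G) * (k - 1)

  # GG epsilon from the double-centred pooled within-group covariance
  S <- Reduce(`+`, lapply(unique(grp), function(g) {
    Yg <- Y[grp == g, , drop = FALSE]
    (nrow(Yg) - 1) * stats::cov(Yg)
  })) / (N - G)
  C <- diag(k) - matrix(1 / k, k, k)
  lam <- eigen(C %*% S %*% C, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- if (sum(lam^2) > 0) sum(lam)^2 / ((k - 1) * sum(lam^2)) else 1
  eps <- min(max(eps, 1 / (k - 1)), 1)

  mkrow <- function(ss, df1, ss_err, df2, within) {
    ms <- ss / df1; mse <- ss_err / df2
    f <- if (mse > 0) ms / mse else ifelse(ss > 0, Inf, 0)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    p_gg <- if (within) stats::pf(f, eps * df1, eps * df2,
                                  lower.tail = FALSE) else NA_real_
    data.frame(F = f, df1 = df1, df2 = df2, p = p,
               df1_gg = if (within) eps * df1 else NA_real_,
               df2_gg = if (within) eps * df2 else NA_real_,
               p_gg = p_gg,
               partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
  }
  effects <- rbind(
    group = mkrow(ss_group, df_group, ss_subj, df_subj, FALSE),
    phase = mkrow(ss_phase, df_phase, ss_err_within, df_err_w, TRUE),
    `phase:group` = mkrow(ss_inter, df_inter, ss_err_within, df_err_w, TRUE)
  )
  effects$effect <- rownames(effects)
  structure(list(effects = effects, gg_epsilon = eps,
                 n_subjects = N, n_phases = k,
                 ss = c(group = ss_group, subj = ss_subj, phase = ss_phase,
                        inter = ss_inter, error_within = ss_err_within)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("%-12s F(%.2f, %.2f) = %.3f, p = %.4g, partial eta2 = %.3f\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i],
                e$partial_eta_sq[i]))
  }
  cat(sprintf("Greenhouse-Geisser epsilon = %.3f\n", x$gg_epsilon))
  invisible(x)
}

#' Linear polynomial contrast over three phases
#'
#' Scores each participant with `L = -x_start + x_end` (weights -1, 0, +1)
#' and tests the mean contrast against zero with a one-sample t-test.
#'
#' @param data Data.frame with `participant`, `phase`, `value` (three
#'   phases per participant).
#' @param weights Contrast weights, default `c(-1, 0, 1)`.
#' @return List: `L` (per-participant scores), `mean_L`, `t`, `df`, `p`,
#'   `degenerate` (TRUE when the contrast scores have zero variance).
#' @export
linear_contrast <- function(data, weights = c(-1, 0, 1)) {
  data$phase <- canonical_phase(data$phase)
  wide <- stats::xtabs(value ~ participant + phase, data)
  if (ncol(wide) != length(weights))
    stop("need one weight per phase", call. = FALSE)
  L <- as.numeric(as.matrix(wide) %*% weights)
  if (stats::sd(L) == 0) {
    return(list(L = L, mean_L = mean(L), t = if (mean(L) == 0) 0 else NA_real_,
                df = length(L) - 1, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(L, mu = 0)
  list(L = L, mean_L = mean(L), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}

#' Ordinary least-squares regression with adjusted R-squared
#'
#' Wraps [stats::lm()]; reports coefficients with standard errors, t and p,
#' plus R-squared and adjusted R-squared.
#'
#' @param y Response vector.
#' @param X Predictors: data.frame or matrix (an intercept is added).
#' @return Object of class `"regression_result"`: `coefficients`
#'   (data.frame term/B/se/t/p), `r_sq`, `adj_r_sq`, `n`, `n_predictors`,
#'   `residuals`, `y`.
#' @export
ols_regression <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L)
    stop("need more observations than predictors plus intercept",
         call. = FALSE)
  dat <- cbind(data.frame(.y = y), X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (fit$rank < p + 1L)
    stop("rank-deficient predictor matrix", call. = FALSE)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(
    coefficients = data.frame(term = rownames(co), B = co[, 1], se = co[, 2],
                              t = co[, 3], p = co[, 4], row.names = NULL),
    r_sq = sm$r.squared, adj_r_sq = sm$adj.r.squared,
    n = n, n_predictors = p,
    residuals = stats::residuals(fit), y = y, fitted = stats::fitted(fit)),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  print(x$coefficients, digits = 4)
  cat(sprintf("R2 = %.4f, adj. R2 = %.4f (n = %d, p = %d)\n",
              x$r_sq, x$adj_r_sq, x$n, x$n_predictors))
  invisible(x)
}

#' Nested-model F-test on the change in R-squared
#'
#' Compares two OLS fits of the same response, the reduced model's
#' predictors a subset of the full model's:
#' `F = (dR2 / dp) / ((1 - R2_full) / (n - p_full - 1))`.
#'
#' @param reduced,full `"regression_result"` objects on the same response.
#' @return Object of class `"model_comparison"`: `delta_r_sq`,
#'   `delta_adj_r_sq`, `F`, `df1`, `df2`, `p`.
#' @export
nested_f <- function(reduced, full) {
  if (full$n != reduced$n || !isTRUE(all.equal(reduced$y, full$y)))
    stop("models must be fit to the same response vector", call. = FALSE)
  red_terms <- setdiff(reduced$coefficients$term, "(Intercept)")
  full_terms <- setdiff(full$coefficients$term, "(Intercept)")
  if (!all(red_terms %in% full_terms))
    stop("models are not nested: reduced model has predictors absent from ",
         "the full model", call. = FALSE)
  df1 <- full$n_predictors - reduced$n_predictors
  df2 <- full$n - full$n_predictors - 1
  if (df1 == 0L) {
    return(structure(list(delta_r_sq = 0, delta_adj_r_sq = 0, F = 0,
                          df1 = 0, df2 = df2, p = 1),
                     class = "model_comparison"))
  }
  dr2 <- full$r_sq - reduced$r_sq
  f <- (dr2 / df1) / ((1 - full$r_sq) / df2)
  structure(list(delta_r_sq = dr2,
                 delta_adj_r_sq = full$adj_r_sq - reduced$adj_r_sq,
                 F = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE)),
            class = "model_comparison")
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return Sample correlation; `NA` with a warning when either input has
#'   zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need two equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
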