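# shared synthetic per-speaker table for regression tests
make_assoc_data <- function(n = 24, seed = 1, beta_cog = 0, sigma = 0.4) {
  set.seed(seed)
  d <- data.frame(
    speaker_id = sprintf("s%02d", 1:n),
    machiavellianism = round(rnorm(n, 25, 5)),
    psychopathy = round(rnorm(n, 17, 4)),
    cognitive_empathy = round(rnorm(n, 57, 8)),
    affective_empathy = round(rnorm(n, 37, 5)),
    age = round(rnorm(n, 21, 3)),
    sex = ifelse(runif(n) < 0.15, "male", "female"))
  d$ed <- 0.74 + beta_cog * as.numeric(scale(d$cognitive_empathy)) +
    rnorm(n, 0, sigma)
  d$delta_likeability <- rnorm(n, 1.3, 0.7)
  d$delta_hostility <- rnorm(n, 2.1, 1.4)
  d$delta_intelligence <- rnorm(n, 0.5, 0.9)
  d$neutral_likeability <- rnorm(n, 3.5, 0.6)
  d
}

test_that("fit_ols interpolates noiseless data exactly", {
  d <- data.frame(speaker_id = paste0("s", 1:10), x = 1:10)
  d$y <- 2 + 1 * d$x
  sp <- model_spec("y", predictors = "x", covariates = character(0))
  fit <- fit_ols(sp, d)
  # x is z-scored internally: beta on z-scale = sd(x); intercept = mean(y)
  expect_equal(fit$coefficients$beta, c(mean(d$y), sd(d$x)), tolerance = 1e-10)
  expect_equal(unname(fit$residuals), rep(0, 10), tolerance = 1e-10)
})

test_that("df structure matches the study design", {
  # 22 speakers, 4 indices + sex + age + intercept -> F(6, 15)
  d <- make_assoc_data(24)
  fit22 <- fit_ols(model_spec("ed"), d, exclude_ids = c("s01", "s02"))
  expect_identical(c(fit22$df1, fit22$df2), c(6L, 15L))
  expect_identical(fit22$n_used, 22L)
  # follow-up model on the full 24 -> F(6, 17)
  fit24 <- fit_ols(model_spec("delta_likeability"), d)
  expect_identical(c(fit24$df1, fit24$df2), c(6L, 17L))
})

test_that("fit_ols equals the normal-equations oracle and lm reference", {
  d <- make_assoc_data(30, seed = 8, beta_cog = -0.4)
  sp <- model_spec("ed")
  fit <- fit_ols(sp, d)
  # independent solve of (X'X) b = X'y on a manually built design
  Z <- scale(as.matrix(d[, c("machiavellianism", "psychopathy",
                             "affective_empathy", "cognitive_empathy")]))
  X <- cbind(1, Z[, c("machiavellianism", "psychopathy", "affective_empathy",
                      "cognitive_empathy")],
             sex = as.numeric(d$sex == "male"), age = d$age)
  b <- solve(t(X) %*% X, t(X) %*% d$ed)[, 1]
  ord <- c("(Intercept)", "machiavellianism", "psychopathy",
           "affective_empathy", "cognitive_empathy", "sex", "age")
  expect_equal(fit$coefficients$beta[match(ord, fit$coefficients$term)],
               unname(b[c(1, 2, 3, 4, 5, 6, 7)]), tolerance = 1e-9)
  # se / t / p / F against stats::lm on the same design
  dd <- data.frame(ed = d$ed, X[, -1])
  ref <- summary(lm(ed ~ ., data = dd))
  expect_equal(fit$coefficients$se, unname(ref$coefficients[, 2]), tolerance = 1e-9)
  expect_equal(fit$adj_r_squared, ref$adj.r.squared, tolerance = 1e-9)
  expect_equal(fit$f, unname(ref$fstatistic[1]), tolerance = 1e-9)
})

test_that("z-scored predictors make betas scale-invariant", {
  d <- make_assoc_data(24, seed = 5, beta_cog = -0.3)
  f1 <- fit_ols(model_spec("ed"), d)
  d2 <- d; d2$cognitive_empathy <- d2$cognitive_empathy * 10
  f2 <- fit_ols(model_spec("ed"), d2)
  i <- which(f1$coefficients$term == "cognitive_empathy")
  expect_equal(f1$coefficients$beta[i], f2$coefficients$beta[i], tolerance = 1e-10)
  expect_equal(f1$coefficients$t[i], f2$coefficients$t[i], tolerance = 1e-10)
})

test_that("fit_ols names rank-deficient terms", {
  d <- make_assoc_data(24)
  d$sex <- "female"
  expect_error(fit_ols(model_spec("ed"), d), "sex",
               class = "voicemod_rank_error")
})

test_that("influence diagnostics match rstudent/cooks and flag planted outliers", {
  d <- make_assoc_data(24, seed = 2, beta_cog = -0.3, sigma = 0.3)
  fit <- fit_ols(model_spec("ed"), d)
  rep <- influence_diagnostics(fit)
  X <- fit$X
  lmfit <- lm(fit$y ~ X - 1)
  expect_equal(rep$table$studentized, unname(rstudent(lmfit)), tolerance = 1e-9)
  expect_equal(rep$table$leverage, unname(hatvalues(lmfit)), tolerance = 1e-9)
  expect_equal(rep$table$cooks, unname(cooks.distance(lmfit)), tolerance = 1e-9)
  expect_equal(rep$table$p_bonferroni, pmin(1, rep$table$p * 24))

  # displace one response by +10 residual SDs -> that point has max |t| and is flagged
  d2 <- d
  d2$ed[7] <- d2$ed[7] + 10 * fit$sigma
  rep2 <- influence_diagnostics(fit_ols(model_spec("ed"), d2))
  expect_identical(which.max(abs(rep2$table$studentized)), 7L)
  expect_true("s07" %in% rep2$flagged_ids)

  # degenerate noiseless fit
  d3 <- d; d3$ed <- 1 + 0.5 * as.numeric(scale(d3$cognitive_empathy))
  expect_error(influence_diagnostics(fit_ols(model_spec("ed"), d3)),
               class = "voicemod_degenerate_error")
})

test_that("robust fit approaches OLS on clean data and equals it when weights are 1", {
  d <- make_assoc_data(200, seed = 4, beta_cog = -0.4, sigma = 0.3)
  sp <- model_spec("ed")
  ro <- fit_robust(sp, d)
  ols <- fit_ols(sp, d)
  expect_true(ro$converged)
  expect_lt(max(abs(ro$coefficients$beta - ols$coefficients$beta)), 0.05)
  # with huge tuning constant every weight is 1 -> exact OLS
  ro1 <- fit_robust(sp, d, c_tune = 1e6)
  expect_true(all(ro1$weights == 1))
  expect_equal(ro1$coefficients$beta, ols$coefficients$beta, tolerance = 1e-7)
  # Huber weight at residual 0 is 1 by the psi(0)/0 convention
  expect_identical(voicemod:::vm_huber_weight(0, 1.345), 1)
})

test_that("robust fit agrees with the MASS::rlm oracle", {
  skip_if_not_installed("MASS")
  d <- make_assoc_data(40, seed = 6, beta_cog = -0.4, sigma = 0.3)
  d$ed[c(3, 17)] <- d$ed[c(3, 17)] + c(4, -5)   # gross outliers
  sp <- model_spec("ed")
  ro <- fit_robust(sp, d)
  X <- ro$X
  ref <- MASS::rlm(X, ro$y, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 200, acc = 1e-10)
  expect_equal(unname(ro$coefficients$beta), unname(coef(ref)), tolerance = 1e-3)
})

test_that("robust beats OLS under contamination (planted-slope simulation)", {
  set.seed(99)
  wins <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    n <- 24
    x <- rnorm(n)
    y <- 1 * x + rnorm(n, 0, 0.5)
    y[sample(n, 2)] <- y[sample(n, 2)] + sample(c(-8, 8), 2, replace = TRUE)
    d <- data.frame(speaker_id = paste0("s", 1:n), x = x, y = y)
    sp <- model_spec("y", predictors = "x", covariates = character(0))
    bo <- fit_ols(sp, d)$coefficients$beta[2] / sd(x)
    br <- fit_robust(sp, d)$coefficients$beta[2] / sd(x)
    if (abs(br - 1) < abs(bo - 1)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("partial_correlation matches both independent oracles", {
  set.seed(10)
  for (r in 1:5) {
    n <- 30
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    Z <- cbind(a = rnorm(n), b = x + rnorm(n))
    pc <- partial_correlation(x, y, as.data.frame(Z))
    expect_equal(pc$r, oracle_partial_residuals(x, y, Z), tolerance = 1e-10)
    expect_equal(pc$r, oracle_partial_inverse(x, y, Z), tolerance = 1e-10)
    expect_identical(pc$df, n - 4L)
    # p-value from the stated t transform
    tt <- pc$r * sqrt(pc$df / (1 - pc$r^2))
    expect_equal(pc$p, 2 * pt(-abs(tt), pc$df))
  }
  # constant-only covariates reduce to plain Pearson
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  # y an exact linear function of covariates -> degenerate, reported 0
  z <- rnorm(20)
  expect_warning(pc0 <- partial_correlation(x, 2 * z + 1, data.frame(z = z)),
                 "degenerate")
  expect_identical(pc0$r, 0)
  expect_true(pc0$degenerate)
})

test_that("fdr_adjust implements BH step-up exactly", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(20)
  for (m in c(2, 3, 5, 8)) {
    p <- runif(m)
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    # monotone in raw p after sorting; capped at 1 (note: BH re-applied to
    # its own output is NOT the identity in general, so no idempotence test)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_error(fdr_adjust(numeric(0)), class = "voicemod_validation_error")
  expect_error(fdr_adjust(c(0.2, 1.3)), class = "voicemod_validation_error")
})

test_that("association suite runs the documented chain", {
  d <- make_assoc_data(24, seed = 12, beta_cog = -0.45, sigma = 0.4)
  perf <- d[, c("speaker_id", "ed", "delta_hostility", "delta_likeability",
                "delta_intelligence", "neutral_likeability")]
  prof <- d[, c("speaker_id", "machiavellianism", "psychopathy",
                "cognitive_empathy", "affective_empathy", "age", "sex")]
  rep <- run_association_suite(perf, prof)
  expect_s3_class(rep$ols_full, "vm_model_result")
  expect_identical(rep$robust$method, "robust_m")
  expect_identical(nrow(rep$partial_table), 12L)
  expect_equal(rep$partial_table$p_fdr, fdr_adjust(rep$partial_table$p))
  expect_identical(c(rep$likeability_model$df1, rep$likeability_model$df2),
                   c(6L, 17L))
  expect_false(is.null(rep$neutral_control))
  # no silent exclusion when the residual screen does not reject
  if (rep$diagnostics$resid_p >= 0.001) {
    expect_identical(rep$ols_primary$n_used, 24L)
    expect_length(rep$excluded_ids, 0)
  }
  # planted gross outliers: flagged and non-normal residuals; the exclusion
  # rule fires once the residual screen rejects at the configured level
  d2 <- d
  d2$ed[c(4, 9)] <- d2$ed[c(4, 9)] + c(6, -6)
  rep2 <- run_association_suite(d2[, names(perf)], prof, resid_alpha = 0.05)
  expect_true(rep2$diagnostics$resid_p < 0.05)
  expect_true(all(c("s04", "s09") %in% rep2$diagnostics$flagged_ids))
  expect_true(all(c("s04", "s09") %in% rep2$excluded_ids))
  expect_lt(rep2$ols_primary$n_used, 24L)
  expect_identical(rep2$ols_primary$n_used + length(rep2$excluded_ids), 24L)
  # at the default stricter threshold the same data are kept in full
  rep3 <- run_association_suite(d2[, names(perf)], prof)
  expect_identical(rep3$ols_primary$n_used, 24L)
  expect_length(rep3$excluded_ids, 0)
})
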