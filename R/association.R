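#' Model specification for performance-on-reactivity regressions
#'
#' @param outcome outcome column name (e.g. `"ed"`, `"delta_likeability"`).
#' @param predictors reactivity index columns; z-scored on the analysis
#'   sample before fitting.
#' @param covariates covariates of no interest entered raw; `sex` is coded
#'   female = 0, male = 1 (reference level female, matching a
#'   "Sex (male)" coefficient label).
#' @return An object of class `vm_model_spec`.
#' @export
model_spec <- function(outcome,
                       predictors = c("machiavellianism", "psychopathy",
                                      "affective_empathy", "cognitive_empathy"),
                       covariates = c("sex", "age")) {
  if (length(predictors) == 0) {
    vm_stop("predictors must be non-empty", class = "voicemod_validation_error")
  }
  terms <- c(predictors, covariates)
  if (anyDuplicated(terms)) {
    vm_stop("duplicate model terms: %s",
            paste(unique(terms[duplicated(terms)]), collapse = ", "),
            class = "voicemod_validation_error")
  }
  structure(list(outcome = outcome, predictors = predictors,
                 covariates = covariates), class = "vm_model_spec")
}

# Build y and design matrix (intercept first); predictors z-scored on the
# rows actually used. Sex recoded 0/1 if it arrives as a factor/character.
vm_design <- function(spec, data, exclude_ids = NULL) {
  stopifnot(inherits(spec, "vm_model_spec"))
  if (!is.null(exclude_ids)) data <- data[!data$speaker_id %in% exclude_ids, ]
  if ("sex" %in% names(data) && !is.numeric(data$sex)) {
    data$sex <- as.numeric(vm_normalize_label(data$sex, c("female", "male")) == "male")
  }
  y <- data[[spec$outcome]]
  Xp <- sapply(spec$predictors, function(v) as.numeric(scale(data[[v]])))
  Xc <- if (length(spec$covariates)) {
    sapply(spec$covariates, function(v) as.numeric(data[[v]]))
  } else NULL
  X <- cbind(`(Intercept)` = 1, Xp, Xc)
  colnames(X) <- c("(Intercept)", spec$predictors, spec$covariates)
  const <- apply(X[, -1, drop = FALSE], 2, function(col) stats::sd(col) == 0 || anyNA(col))
  if (any(const)) {
    vm_stop("rank-deficient design: term(s) %s constant or missing on the analysis sample",
            paste(colnames(X)[-1][const], collapse = ", "),
            class = "voicemod_rank_error")
  }
  if (qr(X)$rank < ncol(X)) {
    vm_stop("rank-deficient design (collinear terms)", class = "voicemod_rank_error")
  }
  list(y = y, X = X, ids = data$speaker_id, data = data)
}

#' Ordinary least squares fit with scaled predictors
#'
#' Multiple regression of a performance measure on z-scored reactivity
#' indices plus raw age/sex covariates, reporting per-term coefficient,
#' standard error, t and p, the adjusted R-squared, and the overall F test
#' with (k, n - k - 1) degrees of freedom.
#'
#' @param spec a [model_spec()].
#' @param data merged per-speaker table (performance + profiles).
#' @param exclude_ids speaker ids to drop before fitting; predictors are
#'   re-z-scored on the remaining sample.
#' @return A `vm_model_result` list: `coefficients` data.frame (term, beta,
#'   se, t, p), `adj_r_squared`, `f`, `df1`, `df2`, `n_used`,
#'   `excluded_ids`, `sigma`, `residuals`, `fitted`, `method = "ols"`.
#' @export
fit_ols <- function(spec, data, exclude_ids = NULL) {
  d <- vm_design(spec, data, exclude_ids)
  n <- length(d$y); p <- ncol(d$X)
  if (n <= p) {
    vm_stop("n_used (%d) must exceed number of terms (%d)", n, p,
            class = "voicemod_validation_error")
  }
  fit <- stats::lm.fit(d$X, d$y)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((d$y - mean(d$y))^2)
  df2 <- n - p
  sigma2 <- rss / df2
  XtXinv <- chol2inv(chol(crossprod(d$X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  beta <- fit$coefficients
  tval <- beta / se
  k <- p - 1
  fstat <- if (tss > 0) ((tss - rss) / k) / sigma2 else NA_real_
  structure(list(
    coefficients = data.frame(
      term = colnames(d$X), beta = unname(beta), se = unname(se),
      t = unname(tval), p = 2 * stats::pt(-abs(tval), df2),
      stringsAsFactors = FALSE),
    adj_r_squared = 1 - (rss / df2) / (tss / (n - 1)),
    r_squared = 1 - rss / tss,
    f = fstat, df1 = as.integer(k), df2 = as.integer(df2),
    f_p = if (is.na(fstat)) NA_real_ else stats::pf(fstat, k, df2, lower.tail = FALSE),
    n_used = as.integer(n), excluded_ids = exclude_ids %||% character(0),
    sigma = sqrt(sigma2), residuals = res, fitted = fit$fitted.values,
    ids = d$ids, X = d$X, y = d$y, spec = spec, method = "ols"),
    class = "vm_model_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vm_model_result <- function(x, ...) {
  cat(sprintf("%s regression of %s (n = %d%s)\n",
              toupper(x$method), x$spec$outcome, x$n_used,
              if (length(x$excluded_ids)) paste0(", excluded: ",
                paste(x$excluded_ids, collapse = ",")) else ""))
  print(transform(x$coefficients, beta = round(beta, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 2)), row.names = FALSE)
  if (x$method == "ols") {
    cat(sprintf("adj. R^2 = %.2f, F(%d,%d) = %.2f, p = %.3g\n",
                x$adj_r_squared, x$df1, x$df2, x$f, x$f_p))
  } else {
    cat(sprintf("robust R^2 = %.2f, residual scale (RSE) = %.2f, iterations = %d\n",
                x$r_squared, x$sigma, x$iterations))
  }
  invisible(x)
}

#' Influence diagnostics for an OLS fit
#'
#' Externally studentized residuals with two-sided outlier tests
#' (df = n - k - 2 for k slope terms), Bonferroni correction over the n
#' observations, leverage, Cook's distance, and a pluggable test of the
#' residual error distribution (default Shapiro-Wilk; the screen whose
#' failure licenses refitting without the flagged observations).
#'
#' @param fit a `vm_model_result` from [fit_ols()] on the full sample.
#' @param resid_test `"shapiro"` or `"none"`.
#' @return A `vm_influence_report` list: per-observation data.frame
#'   (`id`, `studentized`, `p`, `p_bonferroni`, `leverage`, `cooks`),
#'   `flagged_ids` (uncorrected p < .05), `resid_test`, `resid_stat`,
#'   `resid_p`.
#' @export
influence_diagnostics <- function(fit, resid_test = c("shapiro", "none")) {
  resid_test <- match.arg(resid_test)
  stopifnot(inherits(fit, "vm_model_result"), fit$method == "ols")
  n <- fit$n_used; p <- ncol(fit$X)
  if (n <= p + 1) {
    vm_stop("n = %d too small to studentize with %d terms", n, p,
            class = "voicemod_validation_error")
  }
  h <- rowSums((fit$X %*% chol2inv(chol(crossprod(fit$X)))) * fit$X)
  res <- fit$residuals
  s2 <- sum(res^2) / (n - p)
  if (s2 <= (1e-8 * (1 + stats::sd(fit$y)))^2) {
    vm_stop("zero residual variance: studentization undefined",
            class = "voicemod_degenerate_error")
  }
  # leave-one-out variance via the standard identity
  s2_i <- ((n - p) * s2 - res^2 / (1 - h)) / (n - p - 1)
  rstud <- res / sqrt(s2_i * (1 - h))
  p_unc <- 2 * stats::pt(-abs(rstud), df = n - p - 1)
  cooks <- (res^2 / (p * s2)) * h / (1 - h)^2
  tab <- data.frame(id = fit$ids, studentized = rstud, p = p_unc,
                    p_bonferroni = pmin(1, p_unc * n),
                    leverage = h, cooks = cooks, stringsAsFactors = FALSE)
  rt <- if (resid_test == "shapiro") stats::shapiro.test(res) else NULL
  structure(list(table = tab,
                 flagged_ids = tab$id[tab$p < 0.05],
                 resid_test = resid_test,
                 resid_stat = if (is.null(rt)) NA_real_ else unname(rt$statistic),
                 resid_p = if (is.null(rt)) NA_real_ else rt$p.value),
            class = "vm_influence_report")
}

# Huber psi weight: w(r) = min(1, c / |r|)
vm_huber_weight <- function(r, c) {
  w <- rep(1, length(r))
  big <- abs(r) > c
  w[big] <- c / abs(r[big])
  w
}

#' Robust regression via Huber M-estimation
#'
#' Iteratively reweighted least squares with the Huber weight function
#' (tuning constant `c` = 1.345, 95% Gaussian efficiency), residual scale
#' re-estimated each iteration as the median absolute deviation (MAD,
#' normal-consistent) of the residuals. Convergence when the maximum
#' absolute coefficient change falls below `tol` (default 1e-8), with at
#' most `max_iter` (200) iterations; non-convergence is flagged, not
#' fatal. Fitted on the full sample (no exclusions) by design.
#'
#' @inheritParams fit_ols
#' @param c_tune Huber tuning constant.
#' @param tol,max_iter IRLS convergence controls.
#' @return A `vm_model_result` with `method = "robust_m"`, Huber-corrected
#'   standard errors, a robust R-squared analogue (squared correlation of
#'   fitted and observed), the final residual scale in `sigma` (RSE), the
#'   final weights, `converged`, `iterations` and the coefficient-change
#'   `trace`.
#' @export
fit_robust <- function(spec, data, c_tune = 1.345, tol = 1e-8, max_iter = 200) {
  d <- vm_design(spec, data)
  n <- length(d$y); p <- ncol(d$X)
  if (n <= p) {
    vm_stop("n_used (%d) must exceed number of terms (%d)", n, p,
            class = "voicemod_validation_error")
  }
  beta <- stats::lm.fit(d$X, d$y)$coefficients
  trace <- numeric(0)
  converged <- FALSE
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    res <- d$y - d$X %*% beta
    s <- stats::mad(res, center = 0)
    if (s == 0) break  # exact fit
    w <- vm_huber_weight(res / s, c_tune)
    XtWX <- crossprod(d$X * w, d$X)
    beta_new <- solve(XtWX, crossprod(d$X * w, d$y))[, 1]
    delta <- max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && it == max_iter) {
    warning(sprintf("fit_robust: IRLS did not converge in %d iterations (last change %.3g)",
                    max_iter, utils::tail(trace, 1)))
  }
  res <- as.numeric(d$y - d$X %*% beta)
  s <- stats::mad(res, center = 0)
  # Huber (1981) asymptotic covariance, as used for M-estimator summaries:
  # s^2 * [sum psi^2 / (n-p)] / [mean psi']^2 * (X'X)^-1, with the usual
  # small-sample correction factor kappa.
  r_s <- res / s
  psi <- pmax(pmin(r_s, c_tune), -c_tune)
  dpsi <- as.numeric(abs(r_s) <= c_tune)
  mn <- mean(dpsi)
  kappa <- 1 + p / n * stats::var(dpsi) / mn^2
  s2_rob <- kappa^2 * s^2 * sum(psi^2) / (n - p) / mn^2
  XtXinv <- chol2inv(chol(crossprod(d$X)))
  se <- sqrt(diag(XtXinv) * s2_rob)
  tval <- beta / se
  fitted <- as.numeric(d$X %*% beta)
  structure(list(
    coefficients = data.frame(term = colnames(d$X), beta = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = 2 * stats::pt(-abs(tval), n - p),
                              stringsAsFactors = FALSE),
    r_squared = stats::cor(fitted, d$y)^2,
    adj_r_squared = NA_real_, f = NA_real_, df1 = as.integer(p - 1),
    df2 = as.integer(n - p),
    f_p = NA_real_, n_used = as.integer(n), excluded_ids = character(0),
    sigma = s, residuals = res, fitted = fitted, weights = w,
    converged = converged, iterations = it, trace = trace,
    ids = d$ids, X = d$X, y = d$y, spec = spec, method = "robust_m"),
    class = "vm_model_result")
}

#' Partial Pearson correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after OLS on the
#' covariates plus an intercept. The p-value comes from
#' t = r * sqrt((n - 2 - g) / (1 - r^2)) with g covariates, referred to a
#' t distribution with n - 2 - g degrees of freedom (two-sided).
#'
#' If either residual vector is degenerate (zero variance, e.g. `y` an
#' exact linear function of the covariates), the correlation is returned
#' as 0 with `degenerate = TRUE` and a warning rather than NaN.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of controlling variables
#'   (may be NULL/empty for a plain correlation).
#' @return List with `r`, `p`, `df`, `n`, `degenerate`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  Z <- if (is.null(covariates) || NCOL(covariates) == 0) {
    matrix(1, n, 1)
  } else {
    zm <- as.matrix(as.data.frame(covariates))
    if ("sex" %in% colnames(zm) && !is.numeric(covariates[["sex"]])) {
      zm[, "sex"] <- as.numeric(vm_normalize_label(covariates[["sex"]],
                                                   c("female", "male")) == "male")
    }
    storage.mode(zm) <- "double"
    cbind(1, zm)
  }
  g <- ncol(Z) - 1
  if (n <= g + 2) {
    vm_stop("n = %d too small for %d covariates", n, g,
            class = "voicemod_validation_error")
  }
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  # degenerate = numerically zero residual variance relative to the inputs
  if (stats::sd(rx) <= 1e-10 * max(1, stats::sd(x)) ||
      stats::sd(ry) <= 1e-10 * max(1, stats::sd(y))) {
    warning("degenerate residual variance; partial correlation reported as 0")
    return(list(r = 0, p = 1, df = n - 2 - g, n = n, degenerate = TRUE))
  }
  r <- vm_pearson(rx, ry, "residual")
  df <- n - 2 - g
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(t), df), df = df, n = n,
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: p_(i) * m / i, with monotonicity enforced
#' from the largest rank down and values capped at 1.
#'
#' @param p numeric vector of p-values in `[0,1]`.
#' @return Adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) vm_stop("empty p-value vector", class = "voicemod_validation_error")
  if (any(is.na(p) | p < 0 | p > 1)) {
    vm_stop("p-values must lie in [0,1]", class = "voicemod_validation_error")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Partial-correlation table of trait performance against reactivity
#'
#' 3 Delta-traits x 4 indices partial Pearson correlations controlling for
#' age and sex, with BH-FDR over the 12 cells (the correction family is
#' the full table by default).
#'
#' @param merged per-speaker table with delta columns, the four indices,
#'   `age` and `sex`.
#' @param outcomes,indices row/column variable names.
#' @return data.frame `outcome`, `index`, `r`, `p`, `p_fdr`.
#' @export
partial_correlation_table <- function(
    merged,
    outcomes = c("delta_hostility", "delta_intelligence", "delta_likeability"),
    indices = c("machiavellianism", "psychopathy", "cognitive_empathy",
                "affective_empathy")) {
  grid <- expand.grid(outcome = outcomes, index = indices,
                      stringsAsFactors = FALSE)
  covs <- merged[, c("age", "sex")]
  res <- mapply(function(o, i) {
    pc <- partial_correlation(merged[[o]], merged[[i]], covs)
    c(pc$r, pc$p)
  }, grid$outcome, grid$index)
  grid$r <- res[1, ]
  grid$p <- res[2, ]
  grid$p_fdr <- fdr_adjust(grid$p)
  grid
}

#' Run the full behavioral association analysis chain
#'
#' Executes, in order: (1) full-sample OLS of the modulation index (ED) on
#' the z-scored reactivity indices with age/sex covariates; (2) influence
#' diagnostics on that fit; (3) the exclusion rule - observations flagged
#' at uncorrected p < .05 are excluded and the OLS refit (predictors
#' re-scaled) only if the residual-distribution test rejects at
#' p < `resid_alpha` (default .001), otherwise the full-sample fit stands;
#' (4) Huber robust regression on the full sample; (5) the 12-cell
#' partial-correlation table with BH-FDR; (6) a follow-up OLS with
#' Delta-Likeability as outcome on the full sample; (7) the neutral-voice
#' likeability control partial correlation against Machiavellianism.
#'
#' @param performance per-speaker performance table from
#'   [compute_performance()] (needs `ed`, the three delta columns and,
#'   for step 7, `neutral_likeability`).
#' @param profiles per-speaker reactivity table from [score_profiles()].
#' @param resid_test residual-distribution screen, see
#'   [influence_diagnostics()].
#' @param resid_alpha threshold for the exclusion rule.
#' @return A `vm_association_report` list with elements `ols_full`,
#'   `diagnostics`, `excluded_ids`, `ols_primary` (refit or the full fit),
#'   `robust`, `partial_table`, `likeability_model`, `neutral_control`,
#'   and a text `log`.
#' @export
run_association_suite <- function(performance, profiles,
                                  resid_test = c("shapiro", "none"),
                                  resid_alpha = 0.001) {
  resid_test <- match.arg(resid_test)
  merged <- merge(performance, profiles, by = "speaker_id")
  if (nrow(merged) < nrow(performance)) {
    vm_stop("profiles missing for %d speaker(s)",
            nrow(performance) - nrow(merged), class = "voicemod_validation_error")
  }
  log <- character(0)
  spec_ed <- model_spec("ed")
  ols_full <- fit_ols(spec_ed, merged)
  diag <- influence_diagnostics(ols_full, resid_test = resid_test)
  log <- c(log, sprintf("full-sample OLS: n = %d, adjR2 = %.3f", ols_full$n_used,
                        ols_full$adj_r_squared),
           sprintf("influence: %d flagged at uncorrected p < .05 (%s)",
                   length(diag$flagged_ids),
                   paste(diag$flagged_ids, collapse = ", ")),
           sprintf("residual-distribution test (%s): p = %.4g",
                   resid_test, diag$resid_p))
  exclude <- character(0)
  if (resid_test != "none" && !is.na(diag$resid_p) &&
      diag$resid_p < resid_alpha && length(diag$flagged_ids) > 0) {
    exclude <- diag$flagged_ids
    log <- c(log, sprintf("exclusion rule triggered (p < %g): refitting without %s",
                          resid_alpha, paste(exclude, collapse = ", ")))
  } else {
    log <- c(log, "exclusion rule not triggered: primary OLS uses all observations")
  }
  ols_primary <- if (length(exclude)) fit_ols(spec_ed, merged, exclude_ids = exclude)
                 else ols_full
  robust <- fit_robust(spec_ed, merged)
  ptab <- partial_correlation_table(merged)
  lik <- fit_ols(model_spec("delta_likeability"), merged)
  neutral <- if ("neutral_likeability" %in% names(merged) &&
                 !anyNA(merged$neutral_likeability)) {
    partial_correlation(merged$neutral_likeability, merged$machiavellianism,
                        merged[, c("age", "sex")])
  } else NULL
  structure(list(ols_full = ols_full, diagnostics = diag,
                 excluded_ids = exclude, ols_primary = ols_primary,
                 robust = robust, partial_table = ptab,
                 likeability_model = lik, neutral_control = neutral,
                 n = nrow(merged), log = log),
            class = "vm_association_report")
}
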