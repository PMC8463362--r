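#' Apply the cohort exclusion filter
#'
#' Excludes, in order of precedence: (1) MCA occlusions beyond the proximal
#' M2 segment, (2) incomplete occlusions with residual blood flow, (3) CTA
#' slice thickness strictly greater than 3 mm. A record is tallied under
#' the first criterion it violates.
#'
#' @param records data.frame with columns `occlusion_site`, `residual_flow`
#'   and `slice_thickness_mm` (plus anything else, passed through).
#' @param allowed_sites occlusion-site labels considered measurable.
#' @param max_slice_mm slice-thickness cutoff (kept when `<=` this value).
#' @return list: `kept` (data.frame), `tally` (named integer vector
#'   `distal_occlusion`, `residual_flow`, `slice_thickness`).
#' @export
filter_cohort <- function(records,
                          allowed_sites = c("M1", "proximal_M2"),
                          max_slice_mm = 3) {
  need <- c("occlusion_site", "residual_flow", "slice_thickness_mm")
  for (f in need) {
    if (is.null(records[[f]])) {
      perv_error(sprintf("records lack required field '%s'", f),
                 "perv_schema_error")
    }
    bad <- which(is.na(records[[f]]))
    if (length(bad)) {
      id <- if (!is.null(records$id)) records$id[bad[1]] else bad[1]
      perv_error(sprintf("record %s has missing field '%s'", id, f),
                 "perv_schema_error")
    }
  }
  reason <- rep(NA_character_, nrow(records))
  reason[!(records$occlusion_site %in% allowed_sites)] <- "distal_occlusion"
  reason[is.na(reason) & records$residual_flow] <- "residual_flow"
  reason[is.na(reason) & records$slice_thickness_mm > max_slice_mm] <-
    "slice_thickness"
  tally <- c(distal_occlusion = sum(reason == "distal_occlusion", na.rm = TRUE),
             residual_flow = sum(reason == "residual_flow", na.rm = TRUE),
             slice_thickness = sum(reason == "slice_thickness", na.rm = TRUE))
  list(kept = records[is.na(reason), , drop = FALSE], tally = tally)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. Uses the exact permutation null (full enumeration of rank
#' assignments) when both groups have at most `exact_max` observations and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @param exact_max largest group size for which the exact null is used.
#' @return list: `U` (Mann-Whitney U of `group_a`), `p`, `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 8L) {
  if (!length(group_a) || !length(group_b)) {
    perv_error("both groups must be non-empty", "perv_stats_error")
  }
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && max(na, nb) <= exact_max) {
    # exact: U over all choose(n, na) assignments of the ranks to group a
    combos <- utils::combn(n, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    # tie-corrected variance of U and a 0.5 continuity correction
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    z <- max(abs(u_obs - mu) - 0.5, 0) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
    method <- "normal_approximation_tie_corrected"
  }
  list(U = u_obs, p = min(p, 1), method = method)
}

# design matrix from a covariate table (data.frame or matrix); intercept
# always included; errors on rank deficiency naming offending columns
build_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && !ncol(covariates))) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(covariates)
  x <- stats::model.matrix(~ ., data = df)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    perv_error(sprintf("rank-deficient design: collinear column(s) %s",
                       paste(bad, collapse = ", ")),
               "perv_stats_error")
  }
  x
}

#' Least-squares residuals of a response on covariates
#'
#' Ordinary least squares with an intercept always included; the residuals
#' are orthogonal to every design column.
#'
#' @param y numeric response.
#' @param covariates data.frame (or matrix) of predictors; factors are
#'   expanded via the usual treatment contrasts.
#' @return numeric vector of residuals.
#' @export
ols_residuals <- function(y, covariates) {
  x <- build_design(covariates, length(y))
  if (length(y) <= ncol(x)) {
    perv_error("need n > number of predictors + 1", "perv_stats_error")
  }
  as.numeric(qr.resid(qr(x), y))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value is from full
#' enumeration of rank permutations for `n <= 7` (no ties), otherwise the
#' t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list: `r`, `p`, `method`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) {
    perv_error("need equal-length vectors with n >= 3", "perv_stats_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    perv_error("undefined correlation: constant input", "perv_stats_error")
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 7 && !ties) {
    perms <- all_permutations(n)
    r_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_val <- mean(abs(r_all) >= abs(r) - 1e-12)
    method <- "exact_enumeration"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p_val <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t_approximation"
  }
  list(r = r, p = min(p_val, 1), method = method)
}

# all permutations of 1:n as an n! x n matrix (n <= 7 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Binary logistic regression with Wald tests and pseudo-R-squared
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence tolerance 1e-8). Reports per-coefficient Wald z tests and
#' both Nagelkerke and Cox-Snell pseudo-R-squared (Nagelkerke is the
#' headline value). Complete separation is detected and raised as an
#' explicit error rather than returned as a silently diverged fit.
#'
#' @param outcome binary vector (logical or 0/1).
#' @param covariates data.frame of predictors (include the exposure of
#'   interest as a column).
#' @return list: `coefficients` (data.frame with `term`, `estimate`, `se`,
#'   `z`, `p`), `r2_nagelkerke`, `r2_cox_snell`, `converged`, `n`.
#' @export
logistic_fit <- function(outcome, covariates) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) {
    perv_error("outcome must be binary (0/1 or logical)", "perv_stats_error")
  }
  if (length(unique(y)) < 2) {
    perv_error("both outcome classes must be present", "perv_stats_error")
  }
  x <- build_design(covariates, length(y))
  if (length(y) <= ncol(x)) {
    perv_error("need n > number of predictors", "perv_stats_error")
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  mu <- fit$fitted.values
  separated <- all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6)
  if (separated || (warned && max(abs(fit$coefficients)) > 50 && !fit$converged)) {
    perv_error("complete separation: the outcome is perfectly predicted",
               "perv_separation_error")
  }
  w <- mu * (1 - mu)
  xtwx <- crossprod(x * sqrt(w))
  se <- sqrt(diag(solve(xtwx)))
  est <- fit$coefficients
  z <- est / se
  n <- length(y)
  dev <- fit$deviance
  dev0 <- fit$null.deviance
  r2_cs <- 1 - exp((dev - dev0) / n)
  r2_max <- 1 - exp(-dev0 / n)
  list(coefficients = data.frame(
         term = colnames(x), estimate = unname(est), se = unname(se),
         z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
         stringsAsFactors = FALSE),
       r2_nagelkerke = r2_cs / r2_max,
       r2_cox_snell = r2_cs,
       converged = fit$converged, n = n)
}

#' Partial correlation
#'
#' Pearson correlation between the covariate-residualized `x` and `y`,
#' with the p-value from a t statistic on `n - k - 2` degrees of freedom
#' (`k` = number of covariate columns). With no covariates this is the
#' plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame of controls.
#' @return list: `r`, `p`, `df`, `covariates` (names).
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= k + 2) {
    perv_error("need n > number of covariates + 2", "perv_stats_error")
  }
  if (k > 0) {
    rx <- ols_residuals(x, covariates)
    ry <- ols_residuals(y, covariates)
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    perv_error("undefined correlation: constant input", "perv_stats_error")
  }
  # a residual that is zero to numerical precision means the covariates
  # explain that variable completely: the partial correlation is 0, not
  # a correlation of rounding noise
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    return(list(r = 0, p = 1, df = n - k - 2,
                covariates = colnames(as.data.frame(covariates))))
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = min(2 * stats::pt(-abs(tstat), df), 1), df = df,
       covariates = if (k > 0) colnames(as.data.frame(covariates)) else character(0))
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measures ICC from the two-way ANOVA mean
#' squares, with the 95% confidence interval by the F-based
#' Shrout-Fleiss/McGraw-Wong formula.
#'
#' @param ratings n x 2 numeric matrix or data.frame (subjects x raters),
#'   no missing cells, `n >= 5`.
#' @param alpha confidence level is `1 - alpha`.
#' @return list: `icc`, `ci_low`, `ci_high`, `model`
#'   (`"ICC(2,1) two-way random, absolute agreement, single measures"`),
#'   `ms` (the ANOVA mean squares).
#' @export
icc_two_way <- function(ratings, alpha = 0.05) {
  m <- as.matrix(ratings)
  if (ncol(m) != 2L) {
    perv_error("ratings must have exactly 2 rater columns", "perv_stats_error")
  }
  if (nrow(m) < 5L) {
    perv_error("need at least 5 subjects", "perv_stats_error")
  }
  if (any(!is.finite(m))) {
    perv_error("ratings must be complete (no missing cells)",
               "perv_stats_error")
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 1e-12 * max(1, mse)) {
    perv_error("degenerate data: no between-subject variance",
               "perv_stats_error")
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  model <- "ICC(2,1) two-way random, absolute agreement, single measures"
  if (mse < 1e-14 && msc < 1e-14) {
    return(list(icc = 1, ci_low = 1, ci_high = 1, model = model,
                ms = c(msr = msr, msc = msc, mse = mse)))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, model = model,
       ms = c(msr = msr, msc = msc, mse = mse))
}
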