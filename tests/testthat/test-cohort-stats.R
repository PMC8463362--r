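make_roster <- function(n = 10) {
  data.frame(id = sprintf("P%02d", 1:n),
             occlusion_site = rep("M1", n),
             residual_flow = rep(FALSE, n),
             slice_thickness_mm = rep(1.0, n),
             stringsAsFactors = FALSE)
}

test_that("cohort filter applies the three criteria in order", {
  roster <- make_roster(10)
  roster$occlusion_site[1] <- "distal_M2"
  roster$residual_flow[2] <- TRUE
  roster$slice_thickness_mm[3] <- 5
  out <- filter_cohort(roster)
  expect_equal(nrow(out$kept), 7)
  expect_equal(unname(out$tally), c(1L, 1L, 1L))

  # boundary: exactly 3 mm is kept (the rule is strictly "> 3 mm")
  roster2 <- make_roster(2)
  roster2$slice_thickness_mm <- c(3.0, 3.01)
  out2 <- filter_cohort(roster2)
  expect_equal(out2$kept$id, "P01")

  # precedence: first matching criterion wins the tally
  roster3 <- make_roster(1)
  roster3$occlusion_site <- "distal_M2"
  roster3$residual_flow <- TRUE
  expect_equal(unname(filter_cohort(roster3)$tally), c(1L, 0L, 0L))

  # missing field errors name the record
  roster4 <- make_roster(2)
  roster4$residual_flow[2] <- NA
  expect_error(filter_cohort(roster4), "P02", class = "perv_schema_error")
})

test_that("mann_whitney exact p matches enumeration oracles", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact_enumeration")

  # all no-tie group sizes up to 5, several random draws each, against the
  # independent DP rank-sum oracle
  set.seed(7)
  for (na in 2:5) for (nb in 2:5) {
    for (rep in 1:4) {
      x <- sample(seq_len(50), na + nb)
      a <- x[seq_len(na)]; b <- x[-seq_len(na)]
      expect_equal(mann_whitney(a, b)$p, oracle_mw_exact_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("na=%d nb=%d rep=%d", na, nb, rep))
    }
  }
})

test_that("mann_whitney handles ties and identical groups sensibly", {
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1.0)
  big <- mann_whitney(rnorm(40), rnorm(60))
  expect_equal(big$method, "normal_approximation_tie_corrected")
  expect_true(big$p >= 0 && big$p <= 1)
  expect_error(mann_whitney(numeric(0), 1:3), class = "perv_stats_error")
})

test_that("ols_residuals solves the normal equations and is orthogonal", {
  # 3-point fixture solved by hand: y = [1,2,4] on x = [0,1,2]
  r <- ols_residuals(c(1, 2, 4), data.frame(x = c(0, 1, 2)))
  expect_equal(r, c(1 / 6, -1 / 3, 1 / 6), tolerance = 1e-12)

  # perfect fit -> zero residuals
  x <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- 2 + 3 * x$a - 0.5 * x$b
  expect_lt(max(abs(ols_residuals(y, x))), 1e-10)

  # no covariates -> centering
  y2 <- rnorm(15)
  expect_equal(ols_residuals(y2, data.frame()[seq_along(y2), , drop = FALSE]),
               y2 - mean(y2), tolerance = 1e-12)

  # orthogonality to every design column, random designs
  set.seed(8)
  for (i in 1:20) {
    x <- data.frame(a = rnorm(30), b = rnorm(30), f = sample(c("u", "v"), 30,
                                                             replace = TRUE))
    y <- rnorm(30)
    r <- ols_residuals(y, x)
    mm <- model.matrix(~ ., x)
    expect_lt(max(abs(crossprod(mm, r))), 1e-8 * 30)
  }

  # collinear design errors and names the column
  xx <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_error(ols_residuals(rnorm(10), xx), "b", class = "perv_stats_error")
})

test_that("spearman_corr matches hand ranks and handles limits", {
  expect_equal(spearman_corr(1:8, (1:8)^3)$r, 1)
  expect_equal(spearman_corr(1:8, rev(1:8))$r, -1)
  s <- spearman_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(s$r, 0.6, tolerance = 1e-12)
  expect_equal(s$method, "exact_enumeration")
  # exact p agrees with scrambled-rank enumeration done by hand for n=4:
  # 8 of 24 permutations reach |r| >= 0.6
  expect_equal(s$p, 10 / 24, tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), class = "perv_stats_error")
})

test_that("logistic_fit recovers the 2x2 log odds ratio and pseudo-R2", {
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  x <- data.frame(g = c(rep(1, 15), rep(0, 15)))
  fit <- logistic_fit(y, x)
  slope <- fit$coefficients$estimate[fit$coefficients$term == "g"]
  expect_equal(slope, log(4), tolerance = 1e-6)
  expect_true(fit$r2_nagelkerke >= 0 && fit$r2_nagelkerke <= 1)
  expect_gt(fit$r2_nagelkerke, fit$r2_cox_snell)

  # zero-variance predictor -> rank-deficiency error
  expect_error(logistic_fit(y, data.frame(g = x$g, z = 1)),
               class = "perv_stats_error")

  # complete separation detected explicitly
  ys <- c(rep(0, 10), rep(1, 10))
  xs <- data.frame(v = c(rnorm(10, -5), rnorm(10, 5)))
  expect_error(logistic_fit(ys, xs), class = "perv_separation_error")
})

test_that("partial_corr matches the single-covariate closed form", {
  set.seed(9)
  for (i in 1:20) {
    n <- 40
    z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
    pc <- partial_corr(x, y, data.frame(z = z))
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(pc$r, closed, tolerance = 1e-10)
  }
  # no covariates -> plain Pearson
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(partial_corr(x, y)$r, cor(x, y), tolerance = 1e-12)
  # covariate fully explains y -> r = 0
  z <- rnorm(30); x2 <- rnorm(30)
  expect_lt(abs(partial_corr(x2, z, data.frame(z = z))$r), 1e-10)
})

test_that("icc_two_way matches the hand ANOVA oracle", {
  m6 <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  got <- icc_two_way(m6)
  expect_equal(got$icc, oracle_icc21(m6), tolerance = 1e-10)
  expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
  expect_match(got$model, "ICC\\(2,1\\)")

  set.seed(10)
  for (i in 1:10) {
    m <- matrix(rnorm(40, sd = 2), ncol = 2) + rnorm(20) %o% c(1, 1)
    expect_equal(icc_two_way(m)$icc, oracle_icc21(m), tolerance = 1e-10)
  }

  # perfect agreement
  r1 <- rnorm(10)
  expect_equal(icc_two_way(cbind(r1, r1))$icc, 1)
  # zero between-subject variance -> degenerate error
  expect_error(icc_two_way(cbind(rep(1, 6), rep(1, 6))),
               class = "perv_stats_error")
})

test_that("icc_two_way converges to the variance-ratio truth", {
  set.seed(77)
  n <- 500
  subj <- rnorm(n, sd = 2)          # sigma_s^2 = 4
  m <- cbind(subj + rnorm(n), subj + rnorm(n))  # sigma_e^2 = 1, true ICC 0.8
  expect_lt(abs(icc_two_way(m)$icc - 0.8), 0.02)
})
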