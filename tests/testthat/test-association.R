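test_that("OLS association matches the normal-equations oracle", {
  set.seed(1)
  n <- 200
  x <- rnorm(n)
  covs <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(NULL, paste0("c", 1:5)))
  y <- 0.4 * x + covs %*% runif(5, -1, 1) + rnorm(n)
  fit <- ols_assoc(y, x, covariates = covs)
  ## independent matrix-algebra oracle with classical SEs
  X <- cbind(1, x, covs)
  bh <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% bh
  df <- n - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(t(X) %*% X)))
  tv <- bh[2] / se[2]
  expect_equal(fit$beta, unname(bh[2]), tolerance = 1e-10)
  expect_equal(fit$se, unname(se[2]), tolerance = 1e-10)
  expect_equal(fit$t, unname(tv), tolerance = 1e-10)
  expect_equal(fit$p, unname(2 * pt(-abs(tv), df)), tolerance = 1e-12)
  expect_equal(fit$partial_eta_sq, unname(tv^2 / (tv^2 + df)),
               tolerance = 1e-12)

  ## exact fit and constructed orthogonality
  y2 <- 2 * (1:10)
  f2 <- ols_assoc(y2, 1:10)
  expect_equal(f2$beta, 2, tolerance = 1e-10)
  expect_lt(f2$p, 1e-12)
  x3 <- rep(c(-1, 1), 10)
  y3 <- rep(c(1, 1, -1, -1), 5)   # orthogonal to x3 by construction
  expect_equal(ols_assoc(y3, x3)$beta, 0, tolerance = 1e-10)
  ## standardized variables: beta equals Pearson r
  xs <- scale(rnorm(50))[, 1]; ys <- scale(rnorm(50))[, 1]
  expect_equal(ols_assoc(ys, xs)$beta, cor(xs, ys), tolerance = 1e-10)
  expect_error(ols_assoc(y, x, covariates = cbind(a = x, b = x)),
               "collinear")
})

test_that("interaction models report the product term", {
  set.seed(2)
  n <- 300
  g <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  y <- 0.2 * x + 0.6 * x * g + rnorm(n)
  fit <- ols_assoc(y, x, interaction_with = g)
  expect_match(fit$term, ":group")
  expect_equal(fit$beta, 0.6, tolerance = 0.2)
  expect_lt(fit$p, 1e-4)
})

test_that("partial eta squared follows t^2/(t^2+df)", {
  expect_equal(partial_eta_sq(0, 10), 0)
  expect_equal(partial_eta_sq(2, 100), 4 / 104, tolerance = 1e-12)
  expect_true(partial_eta_sq(5, 50) > partial_eta_sq(2, 50))
  expect_lt(abs(partial_eta_sq(1e8, 10) - 1), 1e-12)
  expect_error(partial_eta_sq(2, 0), "positive")
})

test_that("family random-intercept REML matches OLS for singletons and lme4 otherwise", {
  set.seed(3)
  y <- rnorm(60); x <- rnorm(60)
  f_lmm <- lmm_assoc(y, x, family_ids = seq_len(60))
  f_ols <- ols_assoc(y, x)
  expect_equal(f_lmm$beta, f_ols$beta, tolerance = 1e-6)
  expect_equal(f_lmm$se, f_ols$se, tolerance = 1e-6)
  expect_true(f_lmm$boundary)

  skip_if_not_installed("lme4")
  nf <- 150; fam <- rep(seq_len(nf), each = 2)
  u <- rnorm(nf)
  x2 <- rnorm(2 * nf)
  y2 <- 0.3 * x2 + u[fam] + rnorm(2 * nf)
  fit <- lmm_assoc(y2, x2, family_ids = fam)
  m <- lme4::lmer(y2 ~ x2 + (1 | fam), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$beta, unname(lme4::fixef(m)["x2"]), tolerance = 1e-5)
  expect_equal(fit$variance_ratio, vc$vcov[1] / vc$vcov[2],
               tolerance = 1e-3)
})

test_that("REML recovers a planted ICC of 0.5 and detects its absence", {
  iccs <- vapply(1:10, function(i) {
    set.seed(400 + i)
    nf <- 200; fam <- rep(seq_len(nf), each = 2)
    y <- rnorm(nf)[fam] + rnorm(2 * nf)
    lmm_assoc(y, rnorm(2 * nf), family_ids = fam)$icc
  }, numeric(1))
  expect_lt(abs(median(iccs) - 0.5), 0.15)

  ## five-member families make the variance ratio well determined, so a
  ## null family effect is estimated at (or near) the boundary
  null_theta <- vapply(1:10, function(i) {
    set.seed(500 + i)
    fam <- rep(1:60, each = 5)
    lmm_assoc(rnorm(300), rnorm(300), family_ids = fam)$variance_ratio
  }, numeric(1))
  expect_gte(sum(null_theta <= 0.05), 8)
})

test_that("the returned variance ratio is a local REML optimum", {
  set.seed(6)
  nf <- 80; fam <- rep(seq_len(nf), each = 3)
  y <- sqrt(0.6) * rnorm(nf)[fam] + rnorm(3 * nf)
  x <- rnorm(3 * nf)
  fit <- lmm_assoc(y, x, family_ids = fam)
  th <- fit$variance_ratio
  crit <- function(t) spicafuse:::reml_criterion(y, x, family_ids = fam,
                                                 theta = t)
  expect_lte(crit(th), crit(0) + 1e-6)
  expect_lte(crit(th), crit(10 * max(th, 0.01)) + 1e-6)
})

test_that("two-sample t-tests match the textbook pooled formula", {
  set.seed(7)
  a <- rnorm(20); b <- rnorm(25, 0.3)
  fit <- group_diff_ttest(c(a, b), rep(c("x", "y"), c(20, 25)))
  sp <- sqrt((19 * var(a) + 24 * var(b)) / 43)
  t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / 20 + 1 / 25))
  expect_equal(fit$t, t_ref, tolerance = 1e-12)
  expect_equal(fit$df, 43)

  same <- rep(c(1, 2, 3), 2)
  f0 <- group_diff_ttest(same, rep(c("a", "b"), each = 3))
  expect_equal(f0$t, 0)
  expect_equal(f0$p, 1)

  sep <- c(0, 0, 0, 1, 1, 1) + rnorm(6, 0, 1e-3)
  expect_lt(group_diff_ttest(sep, rep(c("a", "b"), each = 3))$p, 0.01)

  expect_warning(
    group_diff_ttest(c(1, 1, 1, 2.5), rep(c("a", "b"), each = 2)),
    "Welch")
})

test_that("multiple-testing adjustments follow Bonferroni and BH step-up", {
  bf <- adjust_pvalues(runif(111), "bonferroni", 0.05)
  expect_equal(bf$threshold, 0.05 / 111, tolerance = 1e-15)

  bh <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh_fdr", 0.05)
  expect_true(all(bh$reject))
  none <- adjust_pvalues(rep(1, 10), "bh_fdr")
  expect_false(any(none$reject))
  expect_false(any(adjust_pvalues(rep(1, 10), "bonferroni")$reject))
  expect_error(adjust_pvalues(numeric(0)), "empty")
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")

  ## BH rejections always contain the Bonferroni rejections
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(50)^2
    rb <- adjust_pvalues(p, "bonferroni")$reject
    rh <- adjust_pvalues(p, "bh_fdr")$reject
    expect_true(all(rh[rb]))
  }
})

test_that("the numbered model battery maps onto the right fits", {
  d <- make_linked_data(81, n = 150, grid = c(6, 6, 6), n_snps = 100,
                        k_s = 2, n_active = 10,
                        family_mode = "sibling-families")
  co <- d$cohort
  gmv <- d$sim$truth$A_g[, 1]; snp <- d$sim$truth$A_s[, 1]
  m1 <- fit_assoc_model(1, co, gmv = gmv, snp = snp)
  expect_equal(m1$model, 1)
  expect_lt(m1$p, 0.01)        # planted link
  m2 <- fit_assoc_model(2, co, gmv = gmv, outcome = co$digit_forward)
  expect_equal(m2$outcome, "behavior")
  m4 <- fit_assoc_model(4, co, snp = snp)
  expect_equal(m4$n, sum(co$group %in% c("ADHD", "control")))
  m5 <- fit_assoc_model(5, co, gmv = gmv, snp = snp)
  expect_true(!is.null(m5$variance_ratio))
  m7 <- fit_assoc_model(7, co, snp = snp)
  expect_equal(m7$predictor, "diagnosis")
  m8 <- fit_assoc_model(8, co, gmv = gmv, snp = snp)
  expect_match(m8$term, ":group")
  expect_error(fit_assoc_model(9, co), "unknown model")
})
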