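test_that("projection recovers loadings exactly in the identity cases", {
  set.seed(1)
  S <- matrix(rnorm(4 * 120), 4, 120)
  A0 <- matrix(rnorm(30 * 4), 30, 4)
  X <- A0 %*% S
  expect_equal(project_loadings(X, S, center = FALSE), A0,
               tolerance = 1e-10, ignore_attr = TRUE)

  ## self-projection of a fitted decomposition reproduces its loadings
  d <- make_linked_data(91, n = 100, grid = c(7, 7, 7), n_snps = 100,
                        k_s = 2, n_active = 10)
  fit <- fit_ica(d$sim$X_gmv, 3, seed = 2)
  expect_equal(project_loadings(d$sim$X_gmv, fit$S), fit$A,
               tolerance = 1e-8)

  ## pseudo-inverse oracle on arbitrary data
  X_new <- matrix(rnorm(25 * 120), 25, 120)
  A_hat <- project_loadings(X_new, S, center = FALSE)
  expect_equal(A_hat, X_new %*% t(S) %*% solve(S %*% t(S)),
               tolerance = 1e-10, ignore_attr = TRUE)
  ## least-squares optimality: any perturbation increases the residual
  resid0 <- norm(X_new - A_hat %*% S, "F")
  expect_lt(resid0, norm(X_new - (A_hat + 0.01) %*% S, "F"))

  ## feature-name alignment catches missing SNPs
  colnames(S) <- paste0("f", seq_len(120))
  Xn <- X_new[, 1:100]
  colnames(Xn) <- paste0("f", 1:100)
  expect_error(project_loadings(Xn, S), "missing")
})

test_that("identified pairs replicate in a linked cohort and not in a null one", {
  d <- make_linked_data(95, n = 120, grid = c(7, 7, 7), n_snps = 150,
                        k_s = 3, n_active = 12)
  fit <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 3, 3, n_runs = 2, seed = 4)
  hits_link <- 0L; hits_null <- 0L
  for (s in 1:6) {
    co2 <- generate_cohort(cohort_spec(n_subjects = 240,
                                       family_mode = "sibling-families",
                                       age_range = c(7, 17),
                                       seed = 600 + s))
    lk <- link_spec(cbind(1, 1), c(ADHD = 0.4, sibling = 0.4,
                                   control = 0.4))
    sim2 <- simulate_linked_data(co2, d$maps, d$weights, lk, seed = 600 + s)
    lk0 <- link_spec(cbind(1, 1), c(ADHD = 0, sibling = 0, control = 0))
    sim0 <- simulate_linked_data(co2, d$maps, d$weights, lk0,
                                 seed = 700 + s)
    mg <- which.max(abs(cor(t(fit$gmv$S), t(d$maps$maps))[, 1]))
    ms <- which.max(abs(cor(t(fit$snp$S), t(d$weights$weights))[, 1]))
    proj <- function(sim) list(
      g = project_loadings(sim$X_gmv, fit$gmv$S),
      s = project_loadings(scale(sim$X_snp), fit$snp$S))
    p2 <- proj(sim2); p0 <- proj(sim0)
    r2 <- replicate_pairs(p2$g, p2$s, co2, cbind(mg, ms))
    r0 <- replicate_pairs(p0$g, p0$s, co2, cbind(mg, ms))
    hits_link <- hits_link + as.integer(r2$replicated)
    hits_null <- hits_null + as.integer(r0$replicated)
  }
  expect_gte(hits_link, 4L)
  expect_lte(hits_null, 1L)
})

test_that("FDR over a single identified pair equals the raw p-value", {
  co <- generate_cohort(cohort_spec(n_subjects = 80,
                                    family_mode = "sibling-families",
                                    seed = 3))
  g <- rnorm(80); s <- 0.5 * g + rnorm(80, 0, 0.8)
  out <- replicate_pairs(cbind(g), cbind(s), co, cbind(1, 1))
  expect_equal(out$p_adjusted, out$p)
})

test_that("stratified associations respect strata structure", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, age_range = c(7, 17),
                                    seed = 5))
  set.seed(6)
  g <- rnorm(200); s <- 0.4 * g + rnorm(200, 0, 0.9)

  ## whole-sample stratum equals the unstratified model-1 fit
  whole <- stratified_assoc(g, s, co, strata = rep("all", 200))
  direct <- ols_assoc(g, s,
                      covariates = as.matrix(co[, paste0("anc", 1:5)]))
  expect_equal(whole$p, direct$p, tolerance = 1e-12)
  expect_equal(whole$beta, direct$beta, tolerance = 1e-12)

  ## identical strata give identical statistics
  half <- rep(c("a", "b"), each = 100)
  co2 <- co; co2[101:200, ] <- co[1:100, ]
  two <- stratified_assoc(c(g[1:100], g[1:100]), c(s[1:100], s[1:100]),
                          co2, strata = half)
  expect_equal(two$p[1], two$p[2], tolerance = 1e-10)

  ## default: five quantile age bins partitioning the sample
  bins <- stratified_assoc(g, s, co)
  expect_equal(nrow(bins), 5)
  expect_equal(sum(bins$n), 200)
  ## undersized strata are skipped with a warning
  expect_warning(
    small <- stratified_assoc(g, s, co,
                              strata = c(rep("tiny", 5), rep("rest", 195))),
    "skipping")
  expect_equal(nrow(small), 1)
})

test_that("univariate SNP scans find a planted causal SNP and control the null", {
  set.seed(7)
  n <- 500
  dos <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  colnames(dos) <- paste0("rs", 1:40)
  y <- 0.8 * scale(dos[, 17])[, 1] + rnorm(n, 0, 0.8)
  tab <- univariate_snp_assoc(y, dos)
  expect_equal(tab$snp_id[which.min(tab$p)], "rs17")
  expect_true(tab$significant[tab$snp_id == "rs17"])

  nulls <- vapply(1:10, function(s) {
    set.seed(800 + s)
    d0 <- matrix(rbinom(150 * 30, 2, 0.3), 150, 30)
    sum(univariate_snp_assoc(rnorm(150), d0)$significant)
  }, numeric(1))
  expect_gte(sum(nulls == 0), 9)

  ## monomorphic SNP skipped, table shrinks by one
  dos2 <- dos
  dos2[, 5] <- 1
  expect_warning(tab2 <- univariate_snp_assoc(y, dos2), "monomorphic")
  expect_equal(nrow(tab2), 39)
})
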