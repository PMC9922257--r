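test_that("decoupled unconstrained spICA equals per-modality Infomax exactly", {
  d <- make_linked_data(21, n = 120, grid = c(8, 8, 8), n_snps = 150,
                        k_s = 3, n_active = 10)
  Xg <- d$sim$X_gmv
  Xs <- scale(d$sim$X_snp)
  attributes(Xs)[c("scaled:center", "scaled:scale")] <- NULL
  joint <- fit_spica(Xg, Xs, k_g = 2, k_s = 3, hoyer_threshold = NULL,
                     couple_weight = 0, n_runs = 1, seed = 50,
                     standardize_snp = FALSE)
  ## run 1 of master seed 50 draws per-modality seeds 51 and 51 + 50021
  g <- fit_ica(Xg, 2, seed = 51)
  s <- fit_ica(Xs, 3, seed = 50 + 1 + 50021L)
  expect_identical(joint$gmv$unmixing, g$unmixing)
  expect_identical(joint$snp$unmixing, s$unmixing)
  expect_identical(joint$gmv$S, g$S)
  expect_identical(joint$snp$S, s$S)
})

test_that("coupling raises the best pair's loading correlation on linked data", {
  wins <- 0L
  for (seed in 301:303) {
    d <- make_linked_data(seed)
    on_ <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 3, 5, n_runs = 3,
                     seed = seed)
    off <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 3, 5, n_runs = 3,
                     seed = seed, couple_weight = 0)
    if (max(abs(on_$pair_table$r)) >= max(abs(off$pair_table$r)))
      wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("the coupling never pushes a pair beyond the correlation ceiling", {
  d <- make_linked_data(31, n = 150, grid = c(8, 8, 8), n_snps = 200,
                        k_s = 3, n_active = 15,
                        target_r = c(ADHD = 0.85, sibling = 0.85,
                                     control = 0.85))
  fit <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 3, 3, n_runs = 2, seed = 9,
                   r_ceiling = 0.8)
  expect_true(all(abs(fit$pair_table$r) <= 0.85))  # ceiling + small slack
})

test_that("the sparsity constraint keeps SNP components near the Hoyer target", {
  d <- make_linked_data(41)
  fit <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 3, 6, n_runs = 3, seed = 11,
                   hoyer_threshold = 0.4)
  hoyers <- apply(fit$snp$S, 1, hoyer_sparseness)
  expect_true(all(hoyers >= 0.35))
  off <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 3, 6, n_runs = 3, seed = 11,
                   hoyer_threshold = NULL)
  expect_gte(mean(hoyers), mean(apply(off$snp$S, 1, hoyer_sparseness)))
})

test_that("the pair table covers all component pairs with valid statistics", {
  d <- make_linked_data(51, n = 120, grid = c(8, 8, 8), n_snps = 150,
                        k_s = 4, n_active = 10)
  anc <- as.matrix(d$cohort[, paste0("anc", 1:5)])
  fit <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 2, 4, n_runs = 2, seed = 3,
                   covariates = anc)
  expect_equal(nrow(fit$pair_table), 8)
  expect_true(all(fit$pair_table$p >= 0 & fit$pair_table$p <= 1))
  expect_true(all(fit$pair_table$partial_eta_sq >= 0 &
                    fit$pair_table$partial_eta_sq <= 1))
  expect_equal(fit$pair_table$df, rep(120 - 7, 8))  # icpt + focal + 5 anc
})

test_that("order estimation selects a single candidate trivially and tracks noise", {
  set.seed(61)
  X <- matrix(rnorm(60 * 100), 60, 100)
  expect_equal(estimate_order(X, 5, n_runs = 2, seed = 1)$k, 5)
  expect_error(estimate_order(X, integer(0)), "empty")

  ## consistency trends down with k on pure noise
  Xn <- matrix(rnorm(120 * 500), 120, 500)
  oe <- estimate_order(Xn, c(2, 4, 6, 8, 10), n_runs = 3, seed = 2)
  expect_lt(cor(oe$consistency$k, oe$consistency$consistency,
                method = "spearman"), 0)
})

test_that("ICASSO prefers consistent runs and flags an outlier run", {
  set.seed(71)
  S <- matrix(0, 3, 400)
  for (i in 1:3) S[i, sample(400, 25)] <- rnorm(25, 0, 2)
  A <- matrix(rnorm(80 * 3), 80, 3)
  X <- A %*% S + matrix(rnorm(80 * 400, 0, 0.1), 80)
  good <- lapply(1:4, function(r) fit_ica(X, 3, seed = r))
  runs <- lapply(good, function(f) list(gmv = f))

  ## identical runs: any selection valid, quality near 1 within clusters
  same <- lapply(1:3, function(r) list(gmv = good[[1]]))
  sel_same <- icasso_select(same)
  expect_true(all(sel_same$quality$Iq > 0.5))

  ## replace one run's components with noise: outlier never representative
  bad <- good[[4]]
  bad$S <- matrix(rnorm(3 * 400), 3, 400)
  runs_out <- c(runs[1:3], list(list(gmv = bad)))
  sel <- icasso_select(runs_out)
  expect_true(sel$best_run != 4)

  ## two runs: selection equals the argmax of summed centrotype similarity
  two <- runs[1:2]
  sel2 <- icasso_select(two)
  expect_equal(sel2$best_run, which.max(sel2$similarity))
  expect_error(icasso_select(runs[1]), "at least 2")
})
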