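test_that("cohort generation hits exact group counts and is deterministic", {
  spec <- cohort_spec(n_subjects = 341,
                      group_proportions = c(ADHD = 167, sibling = 47,
                                            control = 127) / 341, seed = 1)
  co <- generate_cohort(spec)
  expect_equal(unname(table(co$group)[c("ADHD", "sibling", "control")]),
               c(167L, 47L, 127L), ignore_attr = TRUE)
  expect_identical(co, generate_cohort(spec))

  co2 <- generate_cohort(cohort_spec(n_subjects = 2,
                                     group_proportions = c(1, 0, 0),
                                     seed = 3))
  expect_true(all(co2$group == "ADHD"))

  expect_error(cohort_spec(group_proportions = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(cohort_spec(n_subjects = 1), ">= 2")
})

test_that("sibling families share covariates and respect size distribution", {
  spec <- cohort_spec(n_subjects = 300, family_mode = "sibling-families",
                      family_sizes = 3, family_size_probs = 1,
                      age_range = c(7, 17), seed = 5)
  co <- generate_cohort(spec)
  sizes <- table(co$family_id)
  expect_length(sizes, 100)
  expect_true(all(sizes == 3))
  for (col in c("site", "anc1", "anc3", "anc5")) {
    within_var <- tapply(co[[col]], co$family_id, function(v) diff(range(v)))
    expect_true(all(within_var == 0))
  }
  age_span <- tapply(co$age, co$family_id, function(v) diff(range(v)))
  expect_true(all(age_span <= 6 + 1e-9))
  expect_true(all(co$age >= 7 & co$age <= 17))
})

test_that("spatial maps are unit-norm, near-orthogonal, deterministic", {
  m <- generate_spatial_maps(c(20, 20, 20), k = 3, seed = 2)
  norms <- sqrt(rowSums(m$maps^2))
  expect_equal(norms, rep(1, 3), tolerance = 1e-12)
  cosines <- abs(tcrossprod(m$maps))[upper.tri(diag(3))]
  expect_true(all(cosines <= 0.3))
  expect_identical(m, generate_spatial_maps(c(20, 20, 20), k = 3, seed = 2))

  m1 <- generate_spatial_maps(c(10, 10, 10), k = 1, seed = 7)
  expect_equal(sum(m1$maps^2), 1, tolerance = 1e-12)
  expect_true(all(m1$maps >= 0))

  expect_error(generate_spatial_maps(c(10, 10, 10), k = 1,
                                     centers = rbind(c(30, 5, 5))),
               "outside")
})

test_that("sparse SNP weights have exact support, disjoint across components", {
  sw <- generate_sparse_snp_weights(1000, 10, n_active = 30,
                                    ld_block_size = 10, seed = 4)
  nz <- apply(sw$weights, 1, function(v) sum(v != 0))
  expect_true(all(nz == 30))
  hoyers <- apply(sw$weights, 1, hoyer_sparseness)
  expect_true(all(hoyers > 0.6))
  sets <- apply(sw$weights != 0, 1, which, simplify = FALSE)
  expect_equal(length(unique(unlist(sets))), 300)   # pairwise disjoint
  expect_equal(sort(unique(sw$blocks)), 1:100)

  one <- generate_sparse_snp_weights(50, 2, n_active = 1,
                                     ld_block_size = 5, seed = 4)
  expect_equal(apply(one$weights, 1, hoyer_sparseness), c(1, 1))

  expect_error(generate_sparse_snp_weights(100, 5, n_active = 30),
               "infeasible")
})

test_that("simulated dosages are valid and the planted link has target strength", {
  d <- make_linked_data(8, n = 300,
                        target_r = c(ADHD = 0.5, sibling = 0.5,
                                     control = 0.5))
  expect_true(all(d$sim$X_snp %in% 0:2))
  md <- colMeans(d$sim$X_snp)
  expect_true(all(md > 0 & md < 2))
  r <- cor(d$sim$truth$A_g[, 1], d$sim$truth$A_s[, 1])
  expect_gt(r, 0.35)   # Fisher-z band around 0.5 at n = 300
  expect_lt(r, 0.65)
  ## determinism
  d2 <- make_linked_data(8, n = 300,
                         target_r = c(ADHD = 0.5, sibling = 0.5,
                                      control = 0.5))
  expect_identical(d$sim, d2$sim)
})

test_that("a null link yields near-zero loading correlations across seeds", {
  hits <- vapply(1:10, function(s) {
    d <- make_linked_data(100 + s, n = 150, grid = c(6, 6, 6), n_snps = 100,
                          k_s = 2, n_active = 10,
                          target_r = c(ADHD = 0, sibling = 0, control = 0))
    abs(cor(d$sim$truth$A_g[, 1], d$sim$truth$A_s[, 1])) <= 2 / sqrt(150)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("noise-free voxel data equals baseline plus planted signal exactly", {
  d <- make_linked_data(9, n = 50, grid = c(8, 8, 8), n_snps = 100, k_s = 2,
                        n_active = 10, noise_sd = 0)
  planted <- matrix(d$sim$truth$baseline, 50, 512, byrow = TRUE) +
    d$sim$truth$A_g %*% d$sim$truth$gmv_maps
  expect_equal(unname(d$sim$X_gmv), planted, tolerance = 1e-12)
})

test_that("per-group loading correlations converge to their targets", {
  tr <- c(ADHD = 0.6, sibling = 0.7, control = 0.3)
  d <- make_linked_data(12, n = 3000, grid = c(5, 5, 5), n_snps = 60,
                        k_s = 2, n_active = 10, target_r = tr)
  for (g in names(tr)) {
    ix <- d$cohort$group == g
    expect_lt(abs(cor(d$sim$truth$A_g[ix, 1], d$sim$truth$A_s[ix, 1]) -
                    tr[g]), 0.05)
  }
})
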