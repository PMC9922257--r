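## Reduced-scale reference dataset shared by the stability tests.
ref_data <- local({
  d <- make_linked_data(31, target_r = c(ADHD = 0.6, sibling = 0.6,
                                         control = 0.6))
  d$ref <- fit_spica(d$sim$X_gmv, d$sim$X_snp, 3, 5, n_runs = 4, seed = 77)
  d
})

test_that("a strongly linked pair reproduces across stratified subsamples", {
  ss <- subsample_stability(ref_data$sim$X_gmv, ref_data$sim$X_snp,
                            ref_data$cohort$group, frac = 0.9, n_reps = 8,
                            reference = ref_data$ref, seed = 5, n_runs = 2)
  expect_equal(nrow(ss$pairs) * 0 + ss$n_reps, 8)
  expect_true(any(ss$pairs$fraction >= 0.75))
  expect_true(all(ss$pairs$fraction >= 0 & ss$pairs$fraction <= 1))
})

test_that("full-fraction subsampling refits match the reference components", {
  ss <- subsample_stability(ref_data$sim$X_gmv, ref_data$sim$X_snp,
                            ref_data$cohort$group, frac = 1, n_reps = 2,
                            reference = ref_data$ref, seed = 6, n_runs = 2)
  ## the near-noiseless GMV components re-lock almost exactly; SNP
  ## components carry intrinsic binomial dosage noise, so the bar is lower
  gmv_r <- unlist(lapply(ss$detail, `[[`, "match_r_gmv"))
  snp_r <- unlist(lapply(ss$detail, `[[`, "match_r_snp"))
  expect_true(all(gmv_r >= 0.95))
  expect_gte(median(snp_r), 0.8)
  expect_error(
    subsample_stability(ref_data$sim$X_gmv, ref_data$sim$X_snp,
                        ref_data$cohort$group, frac = 1e-4, n_reps = 1,
                        reference = ref_data$ref),
    "too small")
})

test_that("null data rarely reproduces a pair under subsampling", {
  d0 <- make_linked_data(32, target_r = c(ADHD = 0, sibling = 0,
                                          control = 0))
  ref0 <- fit_spica(d0$sim$X_gmv, d0$sim$X_snp, 3, 5, n_runs = 3, seed = 7)
  suppressWarnings(
    ss0 <- subsample_stability(d0$sim$X_gmv, d0$sim$X_snp, d0$cohort$group,
                               frac = 0.9, n_reps = 8, reference = ref0,
                               seed = 8, n_runs = 2))
  if (nrow(ss0$pairs) > 0) expect_true(all(ss0$pairs$fraction <= 0.25))
  else succeed("no pair identified on null data")
})

test_that("the forced identity permutation reproduces the observed pair table", {
  pn <- permutation_null(ref_data$sim$X_gmv, ref_data$sim$X_snp, n_perm = 1,
                         reference = ref_data$ref, seed = 9,
                         identity_first = TRUE)
  expect_equal(sort(pn$null_p), sort(ref_data$ref$pair_table$p),
               tolerance = 1e-12)
  expect_equal(max(pn$null_max_r), max(abs(ref_data$ref$pair_table$r)),
               tolerance = 1e-12)
})

test_that("permuting subjects breaks the planted link", {
  pn <- permutation_null(ref_data$sim$X_gmv, ref_data$sim$X_snp, n_perm = 6,
                         reference = ref_data$ref, seed = 10, n_runs = 2)
  expect_lte(pn$sig_fraction, 0.1)
  ## observed linked-pair |r| beats every one of the few null maxima
  expect_true(all(pn$pair_tails$tail_p <= 0.2))
  expect_equal(pn$n_perm, 6)
})

test_that("sweeps report matched components and respond to pruning strength", {
  sw <- robustness_sweep(ref_data$sim$X_gmv, ref_data$sim$X_snp,
                         ref_data$sim$snp_meta, axis = "pruning_r2",
                         values = c(0.2, 0.9), reference = ref_data$ref,
                         seed = 11, n_runs = 2)
  n_heavy <- unique(sw$n_snps[sw$value == 0.2])
  n_light <- unique(sw$n_snps[sw$value == 0.9])
  expect_lt(n_heavy, n_light)

  ## single-value sweep equals one direct refit on the same SNP set
  sw1 <- robustness_sweep(ref_data$sim$X_gmv, ref_data$sim$X_snp,
                          ref_data$sim$snp_meta, axis = "order",
                          values = 5, reference = ref_data$ref, seed = 12,
                          n_runs = 2)
  expect_equal(nrow(sw1), 5)          # one row per reference SNP component
  expect_true(all(sw1$k_s == 5))
  keep <- clump_snps(ref_data$sim$snp_meta, ref_data$sim$X_snp)
  direct <- fit_spica(
    ref_data$sim$X_gmv,
    ref_data$sim$X_snp[, match(keep, ref_data$sim$snp_meta$snp_id)],
    3, 5, n_runs = 2, seed = 12)
  mm <- spicafuse:::.greedy_match(
    ref_data$ref$snp$S[, keep, drop = FALSE], direct$snp$S)
  expect_equal(sort(sw1$match_r), sort(mm$r), tolerance = 1e-8)

  ## infeasible order is skipped with a warning
  expect_warning(
    sw_bad <- robustness_sweep(ref_data$sim$X_gmv, ref_data$sim$X_snp,
                               ref_data$sim$snp_meta, axis = "order",
                               values = 1000, reference = ref_data$ref,
                               seed = 13, n_runs = 2),
    "exceeds")
  expect_null(sw_bad)
})

test_that("identical subject permutations in both blocks leave associations unchanged", {
  A_g <- ref_data$ref$gmv$A
  A_s <- ref_data$ref$snp$A
  perm <- sample(nrow(A_g))
  t1 <- pair_assoc_table(A_g, A_s)
  t2 <- pair_assoc_table(A_g[perm, ], A_s[perm, ])
  expect_equal(t1$r, t2$r, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})
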