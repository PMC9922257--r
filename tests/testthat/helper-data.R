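## Shared fixture builders: all data is generated in code at test time.

## A compact linked two-modality dataset that the decomposition recovers
## reliably: 200 subjects, 12^3 grid, 400 SNPs in 10-SNP LD blocks,
## 5 SNP components, one planted GMV1-SNP1 link.
make_linked_data <- function(seed, n = 200, grid = c(12, 12, 12), k_g = 3,
                             n_snps = 400, k_s = 5, n_active = 20,
                             target_r = c(ADHD = 0.6, sibling = 0.7,
                                          control = 0.3),
                             age_range = c(18, 63),
                             family_mode = "unrelated", age_slope = 0,
                             ...) {
  co <- generate_cohort(cohort_spec(n_subjects = n, age_range = age_range,
                                    family_mode = family_mode, seed = seed))
  maps <- generate_spatial_maps(grid, k = k_g, seed = seed)
  sw <- generate_sparse_snp_weights(n_snps, k_s, n_active, 10, seed = seed)
  lk <- link_spec(cbind(1, 1), target_r, age_slope = age_slope)
  sim <- simulate_linked_data(co, maps, sw, lk, seed = seed, ...)
  list(cohort = co, maps = maps, weights = sw, link = lk, sim = sim)
}

## Greedy best |r| of each row of truth against fitted components.
best_match <- function(S_fit, S_true) apply(abs(cor(t(S_true), t(S_fit))), 1,
                                            max)

## Brute-force reference for p-value-informed clumping, written
## independently of clump_snps(): sort by (p, chrom, pos, id), walk the
## list, drop anything correlated at >= r2_max with an earlier survivor on
## the same chromosome.
clump_bruteforce <- function(meta, dos, p_max, r2_max) {
  keep <- meta$gwas_p < p_max
  ord <- order(meta$gwas_p, meta$chrom, meta$pos, meta$snp_id)
  ord <- ord[keep[ord]]
  surv <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (s in surv) {
      if (meta$chrom[s] == meta$chrom[i] &&
          isTRUE(cor(dos[, s], dos[, i])^2 >= r2_max)) { ok <- FALSE; break }
    }
    if (ok) surv <- c(surv, i)
  }
  meta$snp_id[surv]
}

## Random SNP panel with LD blocks for clumping tests.
random_snp_panel <- function(seed, n = 60, p = 50, block = 10) {
  set.seed(seed)
  blocks <- ceiling(seq_len(p) / block)
  root <- matrix(rnorm(n * max(blocks)), n)
  dos <- sapply(seq_len(p), function(j) {
    mix <- runif(1, 0, 1)
    v <- sqrt(mix) * root[, blocks[j]] + sqrt(1 - mix) * rnorm(n)
    as.numeric(cut(v, c(-Inf, -0.5, 0.8, Inf))) - 1
  })
  meta <- data.frame(snp_id = sprintf("s%03d", seq_len(p)),
                     chrom = 1L + (blocks - 1L) %% 3L,
                     pos = sample(seq_len(10 * p), p),
                     gwas_p = 10^-runif(p, 0, 6))
  list(meta = meta, dos = dos)
}
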