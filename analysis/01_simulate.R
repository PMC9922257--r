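#!/usr/bin/env Rscript
## Step 1 — simulate the paired cohorts.
##
## Discovery: 341 unrelated adults (167 ADHD / 47 unaffected siblings /
## 127 controls, ages 18-63) with a 20^3 voxel grid (3 planted gray-matter
## networks) and 800 SNPs in 10-SNP LD blocks (10 sparse genomic
## components). One GMV-SNP loading link is planted, stronger in siblings
## (r = 0.7) and cases (0.6) than controls (0.3).
## Replication: 461 adolescents (ages 7-17) in sibling families, same
## latent components, weaker link modulated by age.
##
## Writes: results/sim/ (matrices, cohort tables, SNP metadata, truth).

suppressPackageStartupMessages(library(spicafuse))
seed <- 20260927L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

co <- generate_cohort(cohort_spec(n_subjects = 341, seed = seed))
maps <- generate_spatial_maps(c(20, 20, 20), k = 3, seed = seed)
sw <- generate_sparse_snp_weights(800, 10, n_active = 30,
                                  ld_block_size = 10, seed = seed)
lk <- link_spec(cbind(1, 1), c(ADHD = 0.6, sibling = 0.7, control = 0.3))
sim <- simulate_linked_data(co, maps, sw, lk, seed = seed)

co2 <- generate_cohort(cohort_spec(
  n_subjects = 461,
  group_proportions = c(ADHD = 188, sibling = 129, control = 144) / 461,
  family_mode = "sibling-families", age_range = c(7, 17), seed = seed + 1L))
lk2 <- link_spec(cbind(1, 1), c(ADHD = 0.45, sibling = 0.55,
                                control = 0.25), age_slope = 0.1)
sim2 <- simulate_linked_data(co2, maps, sw, lk2, seed = seed + 1L)

write_matrix_tsv(sim$X_gmv, file.path(out, "adult_gmv.tsv"))
write_matrix_tsv(sim$X_snp, file.path(out, "adult_snp.tsv"))
write.table(co, file.path(out, "adult_cohort.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_matrix_tsv(sim2$X_gmv, file.path(out, "adolescent_gmv.tsv"))
write_matrix_tsv(sim2$X_snp, file.path(out, "adolescent_snp.tsv"))
write.table(co2, file.path(out, "adolescent_cohort.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$snp_meta, file.path(out, "snp_meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_matrix_tsv(maps$maps, file.path(out, "prior_maps.tsv"))
write_matrix_tsv(sim$truth$A_g, file.path(out, "truth_gmv_loadings.tsv"))
write_matrix_tsv(sim$truth$A_s, file.path(out, "truth_snp_loadings.tsv"))
write_matrix_tsv(sw$weights, file.path(out, "truth_snp_weights.tsv"))
jsonlite::write_json(list(seed = seed), file.path(out, "seed.json"),
                     auto_unbox = TRUE)

cat(sprintf(
  "simulated %d adults (planted within-sample link r = %.3f) and %d adolescents\n",
  nrow(co), cor(sim$truth$A_g[, 1], sim$truth$A_s[, 1]), nrow(co2)))
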