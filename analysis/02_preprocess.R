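#!/usr/bin/env Rscript
## Step 2 — data preparation for both modalities of the adult sample.
##
## Voxels are masked at mean GMV > 0.2, subjects at r > 0.8 with the mean
## map, age/sex/site are residualized voxel-wise, the data are
## reconstructed onto the three prior networks, and the SNP panel is
## preselected at GWAS p < 1e-3 with light p-value-informed clumping
## (r^2 < 0.9).
##
## Reads results/sim/; writes results/preprocessed/.

suppressPackageStartupMessages(library(spicafuse))
sim_dir <- "results/sim"
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

inp <- read_inputs(file.path(sim_dir, "adult_gmv.tsv"),
                   file.path(sim_dir, "adult_snp.tsv"),
                   file.path(sim_dir, "adult_cohort.tsv"),
                   file.path(sim_dir, "snp_meta.tsv"))
priors <- read_matrix_tsv(file.path(sim_dir, "prior_maps.tsv"))

mask <- mask_voxels(colMeans(inp$X_gmv), 0.2)
X <- inp$X_gmv[, mask]
qc <- qc_subjects(X, 0.8)
X <- X[qc$keep, ]
cohort <- inp$cohort[qc$keep, ]
X <- residualize(X, cbind(age = cohort$age, sex = cohort$sex,
                          site = cohort$site))
roi <- reconstruct_roi(X, priors[, mask])

surv <- clump_snps(inp$snp_meta, inp$X_snp[qc$keep, ],
                   p_max = 1e-3, r2_max = 0.9)
Xs <- inp$X_snp[qc$keep, match(surv, inp$snp_meta$snp_id)]

write_matrix_tsv(roi$X_roi, file.path(out, "gmv_prepared.tsv"))
write_matrix_tsv(Xs, file.path(out, "snp_prepared.tsv"))
write.table(cohort, file.path(out, "cohort.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(voxel = seq_along(mask), in_mask = mask),
            file.path(out, "voxel_mask.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(snp_id = surv), file.path(out, "snp_survivors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "mask kept %d/%d voxels; QC kept %d/%d subjects; clumping kept %d/%d SNPs\n",
  sum(mask), length(mask), sum(qc$keep), length(qc$keep),
  length(surv), nrow(inp$snp_meta)))
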