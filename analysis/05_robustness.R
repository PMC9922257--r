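#!/usr/bin/env Rscript
## Step 5 — stability of the identified pair.
##
## (i) 20 stratified 90% subsamples (per diagnostic group) refit and
## matched to the reference; (ii) a 40-permutation cross-modality null
## (subjects permuted independently in each block) scored by the
## percentage-of-significant-pairs rule and the conventional max-|r|
## tail; (iii) sweeps over the SNP order and the preselection/pruning
## thresholds. Run counts are reduced from the full 100/1000 design to
## keep the driver interactive; the statistics are the same.
##
## Reads results/preprocessed/ and results/fit/; writes results/stability/.

suppressPackageStartupMessages(library(spicafuse))
out <- "results/stability"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- jsonlite::read_json("results/sim/seed.json")$seed

X <- read_matrix_tsv("results/preprocessed/gmv_prepared.tsv")
Xs <- read_matrix_tsv("results/preprocessed/snp_prepared.tsv")
cohort <- read.table("results/preprocessed/cohort.tsv", header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
snp_meta <- read.table("results/sim/snp_meta.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
Xs_all <- read_matrix_tsv("results/sim/adult_snp.tsv")[cohort$subject_id, ]
pt <- read.table("results/fit/pair_table.tsv", header = TRUE, sep = "\t")
anc <- as.matrix(cohort[, paste0("anc", 1:5)])

## refit the reference (cheap and keeps this step self-contained)
fit <- fit_spica(X, Xs, k_g = 3, k_s = max(pt$snp_ic), n_runs = 10,
                 seed = seed, covariates = anc)

ss <- subsample_stability(X, Xs, cohort$group, frac = 0.9, n_reps = 20,
                          reference = fit, seed = seed, n_runs = 3)
write.table(ss$pairs, file.path(out, "subsample_reproduction.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("subsample reproduction fractions:\n"); print(ss$pairs)

pn <- permutation_null(X, Xs, n_perm = 40, reference = fit,
                       seed = seed + 10000L, n_runs = 2)
cat(sprintf("permutation pooled significant-fraction = %.3f\n", pn$sig_fraction))
if (!is.null(pn$pair_tails)) print(pn$pair_tails)
write.table(data.frame(sig_fraction = pn$sig_fraction, n_perm = pn$n_perm),
            file.path(out, "permutation_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(pn$pair_tails))
  write.table(pn$pair_tails, file.path(out, "permutation_tails.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

for (ax in c("order", "preselection_p", "pruning_r2")) {
  vals <- switch(ax, order = c(5, 10, 15, 20),
                 preselection_p = c(1e-4, 1e-3, 1e-2),
                 pruning_r2 = c(0.2, 0.9))
  sw <- robustness_sweep(X, Xs_all, snp_meta, axis = ax, values = vals,
                         reference = fit, seed = seed, n_runs = 2)
  write.table(sw, file.path(out, paste0("sweep_", ax, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  agg <- aggregate(match_r ~ value, sw, max)
  cat(sprintf("sweep %s: best reference-component match per setting\n", ax))
  print(agg)
}
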