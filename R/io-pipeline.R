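## Formats, configuration and orchestration: TSV/NIfTI/JSON readers and
## writers, subject alignment, and the end-to-end pipeline driver
## (preprocess -> fit -> associations -> robustness -> replication).

#' Write / read a numeric matrix as TSV
#'
#' Values are written at 10 significant digits with row identifiers in the
#' first column, so a write/read round trip is bit-stable for data produced
#' at that precision.
#'
#' @param X Numeric matrix with rownames (subject IDs).
#' @param path Output file.
#' @export
write_matrix_tsv <- function(X, path) {
  df <- data.frame(id = rownames(X) %||% seq_len(nrow(X)),
                   signif(as.data.frame(X), 10), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv`: the matrix with the `id` column as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a component map vector as a NIfTI volume
#'
#' Un-masks a per-voxel vector back into its 3-D grid (zeros outside the
#' mask) and writes a float32 NIfTI file.
#'
#' @param values Per-voxel values (length = sum(mask) or prod(grid_dims)).
#' @param grid_dims Integer 3-vector.
#' @param path Output `.nii`/`.nii.gz` file.
#' @param mask Optional logical vector over the full grid.
#' @export
write_nifti_map <- function(values, grid_dims, path, mask = NULL) {
  full <- numeric(prod(grid_dims))
  if (is.null(mask)) full[] <- values else full[mask] <- values
  RNifti::writeNifti(array(full, dim = grid_dims), path, datatype = "float")
  invisible(path)
}

#' @rdname write_nifti_map
#' @return `read_nifti_map`: numeric array read from the volume.
#' @export
read_nifti_map <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Pipeline configuration with study-default settings
#'
#' All defaults equal the published analysis settings: voxel-mask threshold
#' 0.2, subject-QC correlation 0.8, SNP preselection p 1e-3 with clumping
#' r-squared 0.9, three GMV components, SNP order estimated by consistency
#' ("auto"), Hoyer threshold 0.4, 10 ICASSO runs, 90% stratified subsamples
#' (100 reps) and 1000 permutations.
#'
#' @param ... Overrides of any default element.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(mask_threshold = 0.2, qc_r_min = 0.8, clump_p_max = 1e-3,
              clump_r2_max = 0.9, k_g = 3, k_s = "auto",
              k_s_candidates = seq(5, 60, by = 5), hoyer_threshold = 0.4,
              n_runs = 10, couple_weight = 0.005, r_ceiling = 0.8,
              subsample_frac = 0.9, subsample_reps = 100, n_perm = 1000,
              alpha = 0.05, seed = 1, out_dir = NULL,
              run_robustness = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$mask_threshold >= 0, cfg$qc_r_min >= -1,
            cfg$clump_p_max > 0, cfg$clump_p_max <= 1,
            cfg$clump_r2_max > 0, cfg$clump_r2_max <= 1,
            cfg$hoyer_threshold >= 0, cfg$hoyer_threshold <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read and align the pipeline inputs
#'
#' Reads the GMV matrix, dosage matrix and cohort table (TSV) and aligns
#' all three to the sorted intersection of their subject IDs; dropped
#' counts are reported. Duplicate IDs or an empty intersection are errors.
#'
#' @param gmv_path,snp_path,cohort_path TSV file paths (matrices with an
#'   `id` first column; cohort with a `subject_id` column).
#' @param snp_meta_path Optional SNP metadata TSV.
#' @return List with aligned `X_gmv`, `X_snp`, `cohort`, optional
#'   `snp_meta`, and `dropped` counts per input.
#' @export
read_inputs <- function(gmv_path, snp_path, cohort_path,
                        snp_meta_path = NULL) {
  X_gmv <- read_matrix_tsv(gmv_path)
  X_snp <- read_matrix_tsv(snp_path)
  cohort <- read.table(cohort_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  ids <- list(gmv = rownames(X_gmv), snp = rownames(X_snp),
              cohort = cohort$subject_id)
  for (nm in names(ids)) {
    dup <- ids[[nm]][duplicated(ids[[nm]])]
    if (length(dup)) stopf("duplicate subject ID in %s input: %s", nm,
                           dup[1])
  }
  common <- sort(Reduce(intersect, ids))
  if (length(common) == 0) stopf("no subject ID shared by all inputs")
  dropped <- vapply(ids, function(v) length(v) - length(common), integer(1))
  if (any(dropped > 0))
    message(sprintf("aligned n = %d; dropped per input: %s", length(common),
                    paste(names(dropped), dropped, sep = "=",
                          collapse = ", ")))
  out <- list(X_gmv = X_gmv[common, , drop = FALSE],
              X_snp = X_snp[common, , drop = FALSE],
              cohort = cohort[match(common, cohort$subject_id), ],
              dropped = dropped)
  if (!is.null(snp_meta_path))
    out$snp_meta <- read.table(snp_meta_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  out
}

#' Run the full discovery pipeline
#'
#' Preprocesses both modalities (voxel masking, subject QC, voxel-wise
#' age/sex/site residualization, optional ROI reconstruction; SNP
#' preselection and clumping), fits the sparse parallel ICA, computes the
#' pair-association table with ancestry covariates, the per-component
#' case-control contrasts (two-sample t-test for GMV, model 4 for SNP), and
#' optionally the robustness battery. Deterministic given
#' (`config`, inputs): rerunning reproduces every number.
#'
#' @param inputs List with `X_gmv`, `X_snp`, `cohort`, optionally
#'   `snp_meta` and `priors` (k x voxels prior maps).
#' @param config A [pipeline_config()].
#' @return A result bundle (list) with elements `preprocess`, `data` (the
#'   prepared matrices), `fusion`, `pair_table`, `group_diffs`, optionally
#'   `stability`/`permutation`, and `settings`; written as TSV/JSON under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- inputs$cohort
  X <- inputs$X_gmv

  ## --- GMV side ---
  mask <- mask_voxels(colMeans(X), config$mask_threshold)
  X <- X[, mask, drop = FALSE]
  qc <- qc_subjects(X, config$qc_r_min)
  keep <- qc$keep
  X <- X[keep, , drop = FALSE]
  cohort <- cohort[keep, , drop = FALSE]
  Xs_all <- inputs$X_snp[keep, , drop = FALSE]
  covs <- cbind(age = cohort$age, sex = cohort$sex, site = cohort$site)
  X <- residualize(X, covs)
  roi <- NULL
  if (!is.null(inputs$priors)) {
    roi <- reconstruct_roi(X, inputs$priors[, mask, drop = FALSE])
    X <- roi$X_roi
  }

  ## --- SNP side ---
  if (!is.null(inputs$snp_meta)) {
    surv <- clump_snps(inputs$snp_meta, Xs_all,
                       p_max = config$clump_p_max,
                       r2_max = config$clump_r2_max)
    Xs <- Xs_all[, match(surv, inputs$snp_meta$snp_id), drop = FALSE]
  } else {
    surv <- colnames(Xs_all)
    Xs <- Xs_all
  }

  ## --- order and fit ---
  k_s <- config$k_s
  order_est <- NULL
  if (identical(k_s, "auto")) {
    cand <- config$k_s_candidates
    cand <- cand[cand <= min(dim(Xs)) - 1]
    order_est <- estimate_order(Xs, cand, n_runs = 3, seed = config$seed)
    k_s <- order_est$k
  }
  anc <- as.matrix(cohort[, paste0("anc", 1:5)])
  fusion <- fit_spica(X, Xs, k_g = config$k_g, k_s = k_s,
                      hoyer_threshold = config$hoyer_threshold,
                      couple_weight = config$couple_weight,
                      r_ceiling = config$r_ceiling,
                      n_runs = config$n_runs, seed = config$seed,
                      covariates = anc)

  ## --- group contrasts ---
  cc <- cohort$group %in% c("ADHD", "control")
  gmv_diff <- do.call(rbind, lapply(seq_len(config$k_g), function(i)
    cbind(component = paste0("gmv_ic", i),
          group_diff_ttest(fusion$gmv$A[cc, i], cohort$group[cc]))))
  snp_diff <- do.call(rbind, lapply(seq_len(k_s), function(j)
    cbind(component = paste0("snp_ic", j),
          fit_assoc_model(4, cohort, snp = fusion$snp$A[, j]))))

  bundle <- list(
    preprocess = list(n_voxels = sum(mask), n_subjects = nrow(X),
                      qc_dropped = sum(!keep), snp_survivors = surv,
                      mask = mask),
    data = list(X_gmv = X, X_snp = Xs),
    order = order_est, fusion = fusion, pair_table = fusion$pair_table,
    group_diffs = list(gmv = gmv_diff, snp = snp_diff),
    cohort = cohort, settings = unclass(config))

  if (isTRUE(config$run_robustness)) {
    bundle$stability <- subsample_stability(
      X, Xs, cohort$group, frac = config$subsample_frac,
      n_reps = config$subsample_reps, reference = fusion,
      seed = config$seed, alpha = config$alpha)
    bundle$permutation <- permutation_null(
      X, Xs, n_perm = config$n_perm, reference = fusion,
      alpha = config$alpha, seed = config$seed)
  }

  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(bundle$pair_table, file.path(out_dir, "pair_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(bundle$fusion$gmv$A, file.path(out_dir,
                                                  "gmv_loadings.tsv"))
  write_matrix_tsv(bundle$fusion$snp$A, file.path(out_dir,
                                                  "snp_loadings.tsv"))
  write_matrix_tsv(bundle$fusion$snp$S, file.path(out_dir,
                                                  "snp_components.tsv"))
  jsonlite::write_json(
    list(settings = bundle$settings,
         n_voxels = bundle$preprocess$n_voxels,
         n_subjects = bundle$preprocess$n_subjects,
         runs = bundle$fusion$runs),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
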