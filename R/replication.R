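## Replication in an independent cohort: project fixed components into new
## data to obtain loadings, test identified pairs with family-aware models,
## run age-stratified analyses, and per-SNP univariate association.

#' Project new data onto fixed components
#'
#' Least-squares loadings for fixed components S:
#' \eqn{A = X_c S^T (S S^T)^{-1}}, with each subject's feature mean removed
#' first (the same centering the decomposition itself uses). Projecting the
#' discovery data onto its own full-rank components
#' recovers the discovery loadings. When both `S` and `X_new` carry feature
#' names, columns are aligned by name and any component feature missing
#' from the new data is an error.
#'
#' @param X_new Subjects x features matrix.
#' @param S k x features component matrix.
#' @param center Remove each subject's feature mean first (default TRUE).
#' @return Subjects x k loading matrix.
#' @export
project_loadings <- function(X_new, S, center = TRUE) {
  S <- as.matrix(S)
  if (!is.null(colnames(S)) && !is.null(colnames(X_new))) {
    missing <- setdiff(colnames(S), colnames(X_new))
    if (length(missing))
      stopf("features missing from the new data: %s%s",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) sprintf(" (+%d more)",
                                             length(missing) - 5) else "")
    X_new <- X_new[, colnames(S), drop = FALSE]
  } else if (ncol(X_new) != ncol(S)) {
    stopf("feature mismatch: %d columns vs %d component features",
          ncol(X_new), ncol(S))
  }
  Xc <- if (center) X_new - rowMeans(X_new) else X_new
  G <- tcrossprod(S)
  if (rcond(G) < 1e-12) stopf("components are not full rank")
  A <- t(solve(G, S %*% t(Xc)))
  rownames(A) <- rownames(X_new)
  A
}

#' Test identified pairs in a replication cohort
#'
#' For each identified (GMV, SNP) component pair, fits the family
#' random-intercept model GMV loading ~ SNP loading + five ancestry
#' components + medication (model 5) on the projected loadings, and applies
#' Benjamini-Hochberg FDR across the identified pairs only.
#'
#' @param proj_gmv,proj_snp Projected loading matrices (subjects x k).
#' @param cohort Replication cohort data.frame (needs `family_id`,
#'   `medication`, `anc1`..`anc5`).
#' @param pairs Two-column matrix of identified (gmv_ic, snp_ic) indices.
#' @param alpha FDR level.
#' @return data.frame: one row per pair with r, beta, t, df, p,
#'   `p_adjusted`, partial eta squared, `replicated` flag.
#' @export
replicate_pairs <- function(proj_gmv, proj_snp, cohort, pairs,
                            alpha = 0.05) {
  need <- c("family_id", "medication", paste0("anc", 1:5))
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort lacks columns: %s",
                          paste(miss, collapse = ", "))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  anc <- as.matrix(cohort[, paste0("anc", 1:5)])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs[i, 1]; s <- pairs[i, 2]
    fit <- lmm_assoc(proj_gmv[, g], proj_snp[, s],
                     covariates = cbind(anc, medication = cohort$medication),
                     family_ids = cohort$family_id,
                     outcome = paste0("gmv_ic", g),
                     predictor = paste0("snp_ic", s), model_tag = 5)
    cbind(gmv_ic = g, snp_ic = s, r = cor(proj_gmv[, g], proj_snp[, s]),
          fit[, c("beta", "se", "t", "df", "p", "partial_eta_sq", "n")])
  })
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p, "bh_fdr", alpha)
  out$p_adjusted <- adj$adjusted
  out$replicated <- adj$reject
  out
}

#' Age-stratified (or subgroup) loading associations
#'
#' Splits the cohort into strata (quantile-based age bins by default, five
#' bins) and tests the GMV-SNP loading association within each: ancestry
#' covariates always, a family random intercept when the stratum contains
#' multi-member families. Strata smaller than `min_n` are skipped with a
#' warning.
#'
#' @param gmv,snp Loading vectors aligned with `cohort`.
#' @param cohort Cohort data.frame.
#' @param strata Optional factor of stratum labels; default cuts `age` into
#'   `n_bins` quantile bins.
#' @param n_bins Number of age bins when `strata` is NULL.
#' @param min_n Minimum stratum size.
#' @return data.frame: stratum, n, r, beta, t, df, p, partial_eta_sq.
#' @export
stratified_assoc <- function(gmv, snp, cohort, strata = NULL, n_bins = 5,
                             min_n = 10) {
  if (is.null(strata)) {
    qs <- quantile(cohort$age, probs = seq(0, 1, length.out = n_bins + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    strata <- cut(cohort$age, breaks = unique(qs), include.lowest = TRUE)
  }
  strata <- factor(strata)
  anc <- as.matrix(cohort[, paste0("anc", 1:5)])
  rows <- list()
  for (lv in levels(strata)) {
    ix <- which(strata == lv)
    if (length(ix) < min_n) {
      warnf("skipping stratum %s: n = %d < %d", lv, length(ix), min_n)
      next
    }
    has_fam <- anyDuplicated(cohort$family_id[ix]) > 0
    fit <- if (has_fam)
      lmm_assoc(gmv[ix], snp[ix], covariates = anc[ix, , drop = FALSE],
                family_ids = cohort$family_id[ix])
    else
      ols_assoc(gmv[ix], snp[ix], covariates = anc[ix, , drop = FALSE])
    rows[[lv]] <- data.frame(
      stratum = lv, n = length(ix), mean_age = mean(cohort$age[ix]),
      r = cor(gmv[ix], snp[ix]), beta = fit$beta, t = fit$t, df = fit$df,
      p = fit$p, partial_eta_sq = fit$partial_eta_sq,
      family_model = has_fam, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate per-SNP association with a GMV component loading
#'
#' Regresses the GMV loading on each SNP's dosage plus ancestry covariates,
#' applies Benjamini-Hochberg FDR across SNPs, and returns a
#' Manhattan-ready table. Monomorphic SNPs are skipped with a warning.
#'
#' @param gmv_loading Loading vector of one GMV component.
#' @param dosages Subjects x SNPs dosage matrix.
#' @param covariates Covariate matrix (e.g. five ancestry components).
#' @param snp_meta Optional data.frame with `snp_id`, `chrom`, `pos`
#'   aligned with the dosage columns.
#' @param alpha FDR level.
#' @return data.frame: snp_id, chrom, pos, beta, t, p, `p_adjusted`,
#'   `neg_log10_p`, `significant`.
#' @export
univariate_snp_assoc <- function(gmv_loading, dosages, covariates = NULL,
                                 snp_meta = NULL, alpha = 0.05) {
  p_snps <- ncol(dosages)
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      snp_id = colnames(dosages) %||% paste0("snp", seq_len(p_snps)),
      chrom = NA_integer_, pos = seq_len(p_snps))
  }
  mono <- apply(dosages, 2, function(d) var(d) == 0)
  if (any(mono)) warnf("skipping %d monomorphic SNP(s)", sum(mono))
  keep <- which(!mono)
  rows <- lapply(keep, function(j) {
    fit <- ols_assoc(gmv_loading, dosages[, j], covariates = covariates,
                     predictor = snp_meta$snp_id[j])
    data.frame(snp_id = snp_meta$snp_id[j], chrom = snp_meta$chrom[j],
               pos = snp_meta$pos[j], beta = fit$beta, t = fit$t,
               p = fit$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p, "bh_fdr", alpha)
  out$p_adjusted <- adj$adjusted
  out$neg_log10_p <- -log10(out$p)
  out$significant <- adj$reject
  rownames(out) <- NULL
  out
}
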