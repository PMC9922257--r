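## Data preparation for both modalities: gray-matter voxel masking, subject
## quality control, voxel-wise covariate residualization, ROI reconstruction
## from prior spatial maps, and p-value-informed LD clumping of SNPs.

#' Gray-matter voxel mask from the mean map
#'
#' Keeps voxels whose across-subject mean gray matter volume strictly
#' exceeds `threshold` (default 0.2).
#'
#' @param mean_map Numeric vector of per-voxel means.
#' @param threshold Strict lower cutoff.
#' @return Logical mask of the same length.
#' @export
mask_voxels <- function(mean_map, threshold = 0.2) {
  if (!all(is.finite(mean_map))) stopf("mean map must be finite")
  mask <- mean_map > threshold
  if (!any(mask)) stopf("mask is empty: no voxel exceeds %g", threshold)
  mask
}

#' Subject quality control by correlation with the mean map
#'
#' Computes the Pearson correlation of every subject's voxel vector with the
#' across-subject mean map (computed once, on all input subjects) and
#' retains subjects with r strictly above `r_min` (default 0.8).
#' Zero-variance subject vectors are excluded with a warning.
#'
#' @param X Subjects x voxels matrix.
#' @param r_min Strict correlation cutoff.
#' @return List with `keep` (logical), `r` (per-subject correlation).
#' @export
qc_subjects <- function(X, r_min = 0.8) {
  assert_matrix(X)
  if (nrow(X) < 2) stopf("need at least 2 subjects")
  mean_map <- colMeans(X)
  sds <- apply(X, 1, sd)
  r <- rep(NA_real_, nrow(X))
  ok <- sds > 0 & sd(mean_map) > 0
  if (any(!ok)) warnf("excluding %d zero-variance subject vector(s)",
                      sum(!ok))
  r[ok] <- as.vector(cor(t(X[ok, , drop = FALSE]), mean_map))
  list(keep = !is.na(r) & r > r_min, r = r)
}

#' Voxel-wise covariate residualization
#'
#' Replaces every column of `X` by its ordinary least-squares residual
#' against an intercept plus the covariate columns (age, sex, site dummies,
#' ...). With no covariates this is column mean-centering.
#'
#' @param X Subjects x features matrix.
#' @param covariates Optional matrix/data.frame of covariate columns.
#' @return Residual matrix, same shape as `X`, orthogonal to every
#'   covariate column and to the intercept.
#' @export
residualize <- function(X, covariates = NULL) {
  assert_matrix(X)
  n <- nrow(X)
  D <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    D <- cbind(D, covariates)
  }
  qd <- .check_full_rank(D)
  X - qr.fitted(qd, X)
}

#' Reconstruct data restricted to prior regions of interest
#'
#' Projects every subject's voxel vector onto the row space of the prior
#' spatial maps: with priors S (k x voxels), the prior loadings are
#' \eqn{A = X S^T (S S^T)^{-1}} and the reconstruction is \eqn{A S}, so
#' only variation expressible by the priors survives.
#'
#' @param X Subjects x voxels matrix.
#' @param priors k x voxels prior maps (same voxel indexing as `X`).
#' @return List with `X_roi` (reconstructed matrix) and `A_prior`
#'   (subjects x k prior loadings).
#' @export
reconstruct_roi <- function(X, priors) {
  assert_matrix(X)
  priors <- as.matrix(priors)
  if (ncol(priors) != ncol(X))
    stopf("priors have %d voxels, data has %d", ncol(priors), ncol(X))
  G <- tcrossprod(priors)
  if (rcond(G) < 1e-12) stopf("degenerate priors: S %%*%% t(S) is singular")
  A <- t(solve(G, priors %*% t(X)))
  list(X_roi = A %*% priors, A_prior = A)
}

#' P-value-informed LD clumping
#'
#' Discards SNPs with GWAS p >= `p_max`, then greedily: take the
#' smallest-p remaining SNP as an index SNP and remove every other
#' remaining SNP on the same chromosome with squared dosage correlation
#' >= `r2_max` against it. Survivors are the index SNPs. Ties on p are
#' broken by (chromosome, position, ID) so the result does not depend on
#' input order; cross-chromosome r-squared is treated as 0.
#'
#' @param snp_meta data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `gwas_p`.
#' @param dosages Subjects x SNPs matrix aligned with `snp_meta` rows
#'   (used to compute r-squared).
#' @param p_max Preselection p-value cutoff (default 1e-3).
#' @param r2_max Clumping r-squared cutoff (default 0.9).
#' @return Character vector of surviving SNP IDs (index SNPs), ordered by
#'   ascending p.
#' @export
clump_snps <- function(snp_meta, dosages, p_max = 1e-3, r2_max = 0.9) {
  stopifnot(all(c("snp_id", "chrom", "pos", "gwas_p") %in% names(snp_meta)))
  if (any(snp_meta$gwas_p < 0 | snp_meta$gwas_p > 1))
    stopf("GWAS p-values must lie in [0, 1]")
  if (anyDuplicated(snp_meta$snp_id)) stopf("duplicate SNP IDs")
  if (ncol(dosages) != nrow(snp_meta))
    stopf("dosage columns do not match snp_meta rows")
  pass <- which(snp_meta$gwas_p < p_max)
  if (length(pass) == 0) return(character(0))
  ord <- pass[order(snp_meta$gwas_p[pass], snp_meta$chrom[pass],
                    snp_meta$pos[pass], snp_meta$snp_id[pass])]
  alive <- rep(TRUE, length(ord))
  survivors <- integer(0)
  for (a in seq_along(ord)) {
    if (!alive[a]) next
    idx <- ord[a]
    survivors <- c(survivors, idx)
    alive[a] <- FALSE
    rest <- which(alive)
    if (length(rest) == 0) break
    same_chr <- rest[snp_meta$chrom[ord[rest]] == snp_meta$chrom[idx]]
    if (length(same_chr)) {
      r2 <- as.vector(cor(dosages[, idx],
                          dosages[, ord[same_chr], drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      alive[same_chr[r2 >= r2_max]] <- FALSE
    }
  }
  snp_meta$snp_id[survivors]
}
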