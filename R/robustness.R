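## Stability machinery for identified GMV-SNP pairs: stratified subsampling,
## cross-modality permutation null, and hyperparameter sweeps with greedy
## component matching against a reference fit.

## Pairs of the reference fit significant at its own Bonferroni threshold.
.identified_pairs <- function(reference, alpha = 0.05) {
  pt <- reference$pair_table
  thr <- alpha / nrow(pt)
  pt[pt$p < thr, c("gmv_ic", "snp_ic", "r", "p"), drop = FALSE]
}

## Refit with the reference's settings (overridable), returning a fusion.
.refit_like <- function(reference, Xg, Xs, seed, ...) {
  s <- reference$settings
  over <- list(...)
  args <- list(Xg = Xg, Xs = Xs, k_g = s$k_g, k_s = s$k_s,
               hoyer_threshold = s$hoyer_threshold,
               couple_weight = s$couple_weight, r_ceiling = s$r_ceiling,
               sparsity_step = s$sparsity_step, n_runs = s$n_runs,
               seed = seed, standardize_snp = s$standardize_snp,
               lr = s$lr, max_iter = s$max_iter, tol = s$tol)
  args[names(over)] <- over
  do.call(fit_spica, args)
}

#' Subsampling stability of identified GMV-SNP pairs
#'
#' Repeatedly draws a stratified subsample (fraction `frac` of each
#' diagnostic group, without replacement), refits the sparse parallel ICA,
#' matches every reference component to the refit by maximum |r| of feature
#' weights, and declares an identified pair reproduced when the matched
#' loading pair is associated at the full-sample Bonferroni threshold with
#' the same sign as in the reference.
#'
#' @param Xg,Xs Full data matrices used for the reference fit.
#' @param groups Diagnostic group per subject (stratification variable).
#' @param frac Subsample fraction per group.
#' @param n_reps Number of subsamples.
#' @param reference A fitted `spica_fusion` on the full data.
#' @param seed Integer seed; rep i uses `seed + i`.
#' @param alpha Significance level defining both the identified pairs and
#'   the reproduction threshold (Bonferroni over the pair table).
#' @param ... Overrides passed to the refit (e.g. `n_runs = 3`).
#' @return List with `pairs` (per identified pair: reproduction count and
#'   fraction), `n_reps`, and per-rep detail.
#' @export
subsample_stability <- function(Xg, Xs, groups, frac = 0.9, n_reps = 100,
                                reference, seed = 1, alpha = 0.05, ...) {
  gs <- split(seq_along(groups), groups)
  if (any(floor(lengths(gs) * frac) < 1))
    stopf("a group is too small for frac = %g", frac)
  idp <- .identified_pairs(reference, alpha)
  if (nrow(idp) == 0) warnf("reference has no significant pairs")
  thr <- alpha / nrow(reference$pair_table)
  hits <- matrix(FALSE, n_reps, nrow(idp))
  detail <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    take <- sort(unlist(with_seed(seed + rep_i, lapply(gs, function(ix)
      sample(ix, floor(length(ix) * frac))))))
    fit <- .refit_like(reference, Xg[take, , drop = FALSE],
                       Xs[take, , drop = FALSE], seed = seed + rep_i, ...)
    mg <- .greedy_match(reference$gmv$S, fit$gmv$S)
    ms <- .greedy_match(reference$snp$S, fit$snp$S)
    if (nrow(idp)) for (pi in seq_len(nrow(idp))) {
      gi <- idp$gmv_ic[pi]; si <- idp$snp_ic[pi]
      g2 <- mg$map[match(gi, mg$from)]; s2 <- ms$map[match(si, ms$from)]
      if (is.na(g2) || is.na(s2)) next
      a <- fit$gmv$A[, g2] * mg$sign[match(gi, mg$from)]
      b <- fit$snp$A[, s2] * ms$sign[match(si, ms$from)]
      ar <- ols_assoc(a, b)
      hits[rep_i, pi] <- ar$p < thr && sign(ar$beta) == sign(idp$r[pi])
    }
    detail[[rep_i]] <- list(match_r_gmv = mg$r, match_r_snp = ms$r)
  }
  pairs <- cbind(idp[, c("gmv_ic", "snp_ic")],
                 reproduced = colSums(hits),
                 fraction = colSums(hits) / n_reps)
  list(pairs = pairs, n_reps = n_reps, frac = frac, detail = detail)
}

#' Cross-modality permutation null for loading associations
#'
#' Permutes the subject order independently in the two modalities (breaking
#' any true cross-modal link), refits, and pools all pairwise loading
#' associations into a null. Two summaries are returned: `sig_fraction`, the
#' fraction of null pairs significant under Bonferroni at
#' `alpha / (n_perm * k_g * k_s)`, and the conventional max-statistic tail
#' (per identified pair, the fraction of permutations whose maximum |r|
#' exceeds the observed |r|).
#'
#' @param Xg,Xs Data matrices.
#' @param n_perm Number of permutations.
#' @param reference Fitted `spica_fusion` providing settings and the
#'   observed pair table.
#' @param alpha Level for the Bonferroni rule.
#' @param seed Integer seed; permutation i uses `seed + i`.
#' @param identity_first If TRUE, permutation 1 is the identity in both
#'   modalities (sanity path).
#' @param ... Overrides passed to the refit.
#' @return List with `sig_fraction`, `pair_tails` (per identified pair),
#'   `null_max_r`, `null_p` (all null p-values), `n_perm`.
#' @export
permutation_null <- function(Xg, Xs, n_perm = 1000, reference, alpha = 0.05,
                             seed = 1, identity_first = FALSE, ...) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  n <- nrow(Xg)
  null_p <- numeric(0)
  null_max_r <- numeric(n_perm)
  done <- 0L
  for (i in seq_len(n_perm)) {
    ident <- identity_first && i == 1
    perm <- if (ident) list(g = seq_len(n), s = seq_len(n))
      else with_seed(seed + i, list(g = sample(n), s = sample(n)))
    ## the identity permutation refits with the reference seed so its pair
    ## table reproduces the observed one exactly
    fit <- tryCatch(
      .refit_like(reference, Xg[perm$g, , drop = FALSE],
                  Xs[perm$s, , drop = FALSE],
                  seed = if (ident) reference$settings$seed else seed + i,
                  ...),
      error = function(e) { warnf("permutation %d failed: %s", i,
                                  conditionMessage(e)); NULL })
    if (is.null(fit)) { null_max_r[i] <- NA; next }
    done <- done + 1L
    null_p <- c(null_p, fit$pair_table$p)
    null_max_r[i] <- max(abs(fit$pair_table$r))
  }
  thr <- alpha / (done * nrow(reference$pair_table))
  idp <- .identified_pairs(reference, alpha)
  tails <- if (nrow(idp)) data.frame(
    idp[, c("gmv_ic", "snp_ic")],
    observed_r = idp$r,
    tail_p = vapply(abs(idp$r), function(r0)
      mean(null_max_r >= r0, na.rm = TRUE), numeric(1)))
  else NULL
  list(sig_fraction = mean(null_p < thr), pair_tails = tails,
       null_max_r = null_max_r, null_p = null_p, n_perm = done,
       bonferroni_threshold = thr)
}

#' Hyperparameter sweep with component matching
#'
#' Refits the decomposition across a sweep of the SNP order
#' (`axis = "order"`), the GWAS preselection p cutoff
#' (`"preselection_p"`), or the clumping r-squared cutoff
#' (`"pruning_r2"`), and reports how well each reference SNP component is
#' recovered (best-match |r| of feature weights) together with the matched
#' pair's loading correlation. Feature-axis sweeps reselect the SNP set
#' from the full dosage matrix via [clump_snps()].
#'
#' @param Xg GMV matrix (fixed across the sweep).
#' @param dosages Full subjects x SNPs dosage matrix (before preselection).
#' @param snp_meta SNP metadata (`snp_id`, `chrom`, `pos`, `gwas_p`).
#' @param axis One of `"order"`, `"preselection_p"`, `"pruning_r2"`.
#' @param values Sweep values.
#' @param reference Fitted `spica_fusion` (its SNP feature set must be a
#'   named subset of `snp_meta$snp_id` for feature-axis sweeps).
#' @param seed Integer seed.
#' @param p_max,r2_max Baseline preselection settings used for the axes not
#'   being swept.
#' @param ... Overrides passed to the refit.
#' @return data.frame: one row per (value, reference SNP component) with
#'   `n_snps`, `k_s`, `match_r`, `pair_loading_r`; infeasible settings are
#'   skipped with a warning.
#' @export
robustness_sweep <- function(Xg, dosages, snp_meta,
                             axis = c("order", "preselection_p",
                                      "pruning_r2"),
                             values, reference, seed = 1,
                             p_max = 1e-3, r2_max = 0.9, ...) {
  axis <- match.arg(axis)
  out <- list()
  for (v in values) {
    if (axis == "order") {
      keep <- clump_snps(snp_meta, dosages, p_max = p_max, r2_max = r2_max)
      k_s <- v
    } else if (axis == "preselection_p") {
      keep <- clump_snps(snp_meta, dosages, p_max = v, r2_max = r2_max)
      k_s <- reference$settings$k_s
    } else {
      keep <- clump_snps(snp_meta, dosages, p_max = p_max, r2_max = v)
      k_s <- reference$settings$k_s
    }
    cols <- match(keep, snp_meta$snp_id)
    Xs <- dosages[, cols, drop = FALSE]
    if (k_s > min(dim(Xs)) - 1) {
      warnf("skipping %s = %s: k_s = %d exceeds data rank", axis,
            format(v), k_s)
      next
    }
    fit <- .refit_like(reference, Xg, Xs, seed = seed, k_s = k_s, ...)
    ## match reference SNP components to the refit on shared SNPs
    Sref <- reference$snp$S
    if (is.null(colnames(Sref)))
      colnames(Sref) <- snp_meta$snp_id[seq_len(ncol(Sref))]
    Sfit <- fit$snp$S
    colnames(Sfit) <- keep
    common <- intersect(colnames(Sref), colnames(Sfit))
    if (length(common) < 3) {
      warnf("skipping %s = %s: fewer than 3 shared SNPs with the reference",
            axis, format(v))
      next
    }
    mm <- .greedy_match(Sref[, common, drop = FALSE],
                        Sfit[, common, drop = FALSE])
    for (ci in seq_along(mm$from)) {
      ref_ic <- mm$from[ci]; fit_ic <- mm$map[ci]
      best_pair <- which.max(abs(cor(fit$gmv$A, fit$snp$A[, fit_ic])))
      out[[length(out) + 1]] <- data.frame(
        axis = axis, value = v, n_snps = length(keep), k_s = k_s,
        ref_snp_ic = ref_ic, match_r = mm$r[ci],
        pair_loading_r = cor(fit$gmv$A[, best_pair],
                             fit$snp$A[, fit_ic]))
    }
  }
  do.call(rbind, out)
}
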