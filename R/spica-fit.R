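## Joint two-modality sparse parallel ICA: alternating Infomax updates with a
## cross-modal loading-correlation coupling step and a Hoyer sparsity step on
## the genomic components, repeated over several runs with ICASSO selection.

## Per-modality optimizer state; .ica_step performs exactly one Infomax
## iteration (with divergence restarts) so that a decoupled joint fit follows
## the same trajectory as fit_ica() on the same seed.
.ica_state_init <- function(k, seed, lr, max_iter, tol, anneal,
                            on_fail = "error") {
  st <- list(k = k, seed = seed, lr0 = lr, rate = lr, max_iter = max_iter,
             tol = tol, anneal = anneal, attempt = 0L, it = 0L,
             prev_g = NULL, delta = Inf, done = FALSE, on_fail = on_fail,
             failed = FALSE)
  st$W <- with_seed(seed, matrix(rnorm(k * k), k, k) / sqrt(k) + diag(k))
  st
}

.ica_step <- function(st, Z) {
  if (st$done || st$it >= st$max_iter) return(st)
  st$it <- st$it + 1L
  ks <- .kurt_signs(st$W %*% Z)
  g <- .infomax_grad(st$W, Z, ks)
  Wn <- st$W + st$rate * g
  if (!all(is.finite(g)) || !all(is.finite(Wn))) {
    st$attempt <- st$attempt + 1L
    if (st$attempt > 3L) {
      if (identical(st$on_fail, "error"))
        stopf("Infomax diverged after 4 attempts with halved learning rates")
      ## joint-engine policy: restart once more at a tiny rate and carry
      ## on; the run is flagged non-converged rather than aborted
      st$failed <- TRUE
      st$attempt <- 0L
      st$lr0 <- st$lr0 / 8
    }
    st$W <- with_seed(st$seed + 101L * st$attempt + 7L * st$failed,
                      matrix(rnorm(st$k^2), st$k, st$k) / sqrt(st$k) +
                        diag(st$k))
    st$rate <- st$lr0 / 2^st$attempt
    st$prev_g <- NULL
    st$it <- 0L
    st$delta <- Inf
    return(st)
  }
  if (!is.null(st$prev_g) && sum(g * st$prev_g) < 0)
    st$rate <- st$rate * st$anneal
  st$W <- Wn
  st$prev_g <- g
  st$delta <- st$rate * sqrt(sum(g^2))
  if (st$delta < st$tol) st$done <- TRUE
  st
}

## Symmetric (least-change) orthogonalization W <- (W W^T)^{-1/2} W.
.sym_orth <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values)) return(W)  # leave degenerate W
  (e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*%
     t(e$vectors)) %*% W
}

## Gradient ascent on smoothed Hoyer sparseness of w %*% Z along w, with
## step halving on failure and growth when stuck; stops at `threshold`.
.hoyer_ascend <- function(w, Z, threshold, step0 = 0.02, iters = 300) {
  step <- step0; best_h <- -Inf; best_w <- w; stuck <- 0L; steps <- 0L
  p <- ncol(Z)
  repeat {
    S_i <- as.vector(w %*% Z)
    if (!all(is.finite(S_i)) || all(S_i == 0)) break
    h <- hoyer_sparseness(S_i)
    if (h > best_h + 1e-6) { best_h <- h; best_w <- w; stuck <- 0L } else
      stuck <- stuck + 1L
    if (best_h >= threshold || steps >= iters || stuck > 50) break
    gv <- as.vector(Z %*% hoyer_smooth_grad(S_i)) / p
    gn <- sqrt(sum(gv^2))
    if (!is.finite(gn) || gn == 0) break
    w2 <- w + step * sqrt(sum(w^2)) * gv / gn
    if (hoyer_sparseness(as.vector(w2 %*% Z)) >= h) {
      w <- w2
    } else {
      step <- max(step / 2, 0.005)
    }
    steps <- steps + 1L
  }
  list(w = best_w, h = best_h, steps = steps)
}

## Single spICA run on pre-whitened data. Coupling acts on the mixing matrix
## M = W^{-1} in the reduced space (loadings are A = dewhiten %*% M), taking a
## relative-size gradient-ascent step on the squared correlation of the
## currently best-matched loading pair. Sparsity acts on rows of W for SNP
## components whose Hoyer sparseness falls below the threshold; each
## component carries a multiplicative step weight initialized at 1.
.spica_run <- function(wh_g, wh_s, seed_g, seed_s, hoyer_threshold,
                       couple_weight, r_ceiling, sparsity_step,
                       lr, max_iter, tol, anneal) {
  k_g <- wh_g$k; k_s <- wh_s$k
  st_g <- .ica_state_init(k_g, seed_g, lr, max_iter, tol, anneal,
                          on_fail = "freeze")
  st_s <- .ica_state_init(k_s, seed_s, lr, max_iter, tol, anneal,
                          on_fail = "freeze")
  couple <- couple_weight > 0
  sparse <- !is.null(hoyer_threshold) && hoyer_threshold > 0
  lam <- couple_weight
  mus <- rep(1, k_s)                    # per-component sparsity weights
  prev_r <- 0
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    st_g <- .ica_step(st_g, wh_g$Z)
    st_s <- .ica_step(st_s, wh_s$Z)
    quiet <- st_g$done && st_s$done

    if (couple && rcond(st_g$W) > 1e-6 && rcond(st_s$W) > 1e-6) {
      M_g <- solve(st_g$W); M_s <- solve(st_s$W)
      A_g <- wh_g$dewhiten %*% M_g
      A_s <- wh_s$dewhiten %*% M_s
      R <- cor(A_g, A_s)
      ij <- arrayInd(which.max(abs(R)), dim(R))
      i <- ij[1]; j <- ij[2]
      rbest <- R[i, j]
      if (abs(rbest) >= r_ceiling) {
        lam <- max(lam * 0.5, 1e-5)
      } else {
        if (abs(rbest) < abs(prev_r)) lam <- min(lam * 1.1, 0.05)
        gg <- .corsq_grad(A_g[, i], A_s[, j])$grad
        gs <- .corsq_grad(A_s[, j], A_g[, i])$grad
        dg <- crossprod(wh_g$dewhiten, gg)   # chain rule: A[,i] = Dw M[,i]
        ds <- crossprod(wh_s$dewhiten, gs)
        ng <- sqrt(sum(dg^2)); ns <- sqrt(sum(ds^2))
        if (is.finite(ng) && is.finite(ns) && ng > 0 && ns > 0) {
          M_g[, i] <- M_g[, i] + lam * sqrt(sum(M_g[, i]^2)) * dg / ng
          M_s[, j] <- M_s[, j] + lam * sqrt(sum(M_s[, j]^2)) * ds / ns
          ## revert an update that degrades invertibility or explodes
          W_g2 <- if (rcond(M_g) > 1e-6) solve(M_g) else NULL
          W_s2 <- if (rcond(M_s) > 1e-6) solve(M_s) else NULL
          if (!is.null(W_g2) && !is.null(W_s2) &&
              max(abs(W_g2)) < 1e3 && max(abs(W_s2)) < 1e3) {
            st_g$W <- W_g2; st_s$W <- W_s2
            st_g$done <- FALSE; st_s$done <- FALSE
            quiet <- FALSE
          } else {
            lam <- max(lam * 0.5, 1e-5)
          }
        }
      }
      prev_r <- rbest
    }

    if (sparse) {
      S <- st_s$W %*% wh_s$Z
      W_try <- st_s$W
      touched <- FALSE
      for (i in seq_len(k_s)) {
        if (!all(is.finite(S[i, ]))) next
        h <- hoyer_sparseness(S[i, ])
        if (h < hoyer_threshold) {
          mus[i] <- min(mus[i] * 1.1, 5)
          gv <- as.vector(wh_s$Z %*% hoyer_smooth_grad(S[i, ])) / ncol(wh_s$Z)
          ngv <- sqrt(sum(gv^2))
          if (is.finite(ngv) && ngv > 0) {
            W_try[i, ] <- W_try[i, ] +
              mus[i] * sparsity_step * sqrt(sum(W_try[i, ]^2)) * gv / ngv
            touched <- TRUE
          }
        } else {
          mus[i] <- max(mus[i] * 0.9, 0.05)
        }
      }
      if (touched) {
        if (all(is.finite(W_try)) && rcond(W_try) > 1e-6 &&
            max(abs(W_try)) < 1e3) {
          st_s$W <- W_try
          st_s$done <- FALSE
          quiet <- FALSE
        } else {
          mus <- pmax(mus * 0.5, 0.05)   # back off: step hurt invertibility
        }
      }
    }

    ## the coupling and sparsity forces can drive two unmixing rows onto
    ## the same source; in whitened space the true unmixing is orthogonal,
    ## so re-orthogonalize symmetrically whenever rows start to collapse
    if ((couple || sparse) && iter %% 10 == 0) {
      st_g$W <- .sym_orth(st_g$W)
      st_s$W <- .sym_orth(st_s$W)
    }

    if (quiet) break
  }

  ## terminal polish: pure Hoyer ascent on components still below the
  ## threshold (no opposing Infomax force here). If the ascent stalls in a
  ## local optimum well under the threshold, seeded random restarts in the
  ## whitened space look for a sparser direction; a replacement is only
  ## accepted if it beats the current sparseness, keeps the unmixing
  ## matrix well-conditioned, and does not duplicate another component.
  polish <- 0L
  if (sparse) {
    for (i in seq_len(k_s)) {
      h0 <- hoyer_sparseness(as.vector(st_s$W[i, ] %*% wh_s$Z))
      if (h0 >= hoyer_threshold) next
      cands <- list(.hoyer_ascend(st_s$W[i, ], wh_s$Z, hoyer_threshold))
      polish <- polish + cands[[1]]$steps
      if (cands[[1]]$h < hoyer_threshold) {
        for (t in 1:8) {
          w0 <- with_seed(seed_s + 1000L * i + t, rnorm(k_s))
          cands[[t + 1]] <- .hoyer_ascend(w0, wh_s$Z, hoyer_threshold,
                                          step0 = 0.05, iters = 500)
        }
      }
      ## adopt the sparsest candidate that improves on the current row and
      ## does not duplicate another component; the loadings are computed
      ## by least squares on S afterwards, so distinct rows are all that
      ## is required
      S_cur <- st_s$W %*% wh_s$Z
      for (ci in order(vapply(cands, `[[`, 0, "h"), decreasing = TRUE)) {
        if (cands[[ci]]$h <= h0) break
        S_new <- as.vector(cands[[ci]]$w %*% wh_s$Z)
        dup <- if (k_s > 1)
          max(abs(cor(S_new, t(S_cur[-i, , drop = FALSE])))) else 0
        if (dup < 0.85) {
          st_s$W[i, ] <- cands[[ci]]$w *
            sqrt(sum(st_s$W[i, ]^2)) / sqrt(sum(cands[[ci]]$w^2))
          break
        }
      }
    }
  }

  list(W_g = st_g$W, W_s = st_s$W,
       log = list(iterations = iter,
                  converged = st_g$done && st_s$done &&
                    !st_g$failed && !st_s$failed,
                  diverged = st_g$failed || st_s$failed,
                  delta_g = st_g$delta, delta_s = st_s$delta,
                  lambda_final = lam, sparsity_weights = mus,
                  polish_steps = polish))
}

#' Sparse parallel ICA of paired GMV and SNP data
#'
#' Decomposes two subject-aligned blocks \eqn{X_g = A_g S_g} and
#' \eqn{X_s = A_s S_s} jointly: per-modality Infomax ICA, an adaptive
#' gradient step enhancing the squared correlation of the currently
#' best-correlated loading-column pair (capped at `r_ceiling`), and a
#' smoothed-Hoyer gradient step pushing each SNP component whose Hoyer
#' sparseness is below `hoyer_threshold` toward it. No sparsity constraint is
#' placed on the GMV components. Several runs from different initializations
#' are clustered with [icasso_select()] and the most representative run is
#' returned with its pairwise loading-association table.
#'
#' @param Xg,Xs Subjects x voxels and subjects x SNPs matrices with aligned
#'   rows.
#' @param k_g,k_s Component numbers per modality (see [estimate_order()]).
#' @param hoyer_threshold Target Hoyer sparseness for SNP components
#'   (default 0.4); `NULL` disables the constraint.
#' @param couple_weight Initial relative step size of the coupling update;
#'   0 disables coupling, making the fit two independent (sparse) ICAs.
#' @param r_ceiling Loading-correlation cap beyond which coupling backs off.
#' @param sparsity_step Base relative step size of the sparsity update; each
#'   component's multiplicative weight starts at 1 and adapts (x1.1 while
#'   under the threshold, x0.9 above).
#' @param n_runs Number of ICASSO runs; run r uses seed `seed + r`.
#' @param seed Master seed.
#' @param covariates Optional numeric matrix (e.g. genomic ancestry
#'   components) used as covariates in the pair-association model; with
#'   `NULL` the table reports plain correlation tests.
#' @param standardize_snp Z-score the SNP columns before decomposition
#'   (default TRUE): dosage variance is allele-frequency dependent
#'   (2f(1-f)), and without standardization the principal subspace reflects
#'   frequency rather than latent structure.
#' @param lr,max_iter,tol,anneal Infomax optimizer controls, as in
#'   [fit_ica()].
#' @return A `spica_fusion` object: `gmv`, `snp` (fitted
#'   `spica_components`), `pair_table` (one row per GMV-SNP component pair:
#'   r, t, df, p, partial eta squared), `icasso` diagnostics, `runs` logs and
#'   `settings`.
#' @export
fit_spica <- function(Xg, Xs, k_g = 3, k_s, hoyer_threshold = 0.4,
                      couple_weight = 0.005, r_ceiling = 0.8,
                      sparsity_step = 0.05, n_runs = 10, seed = 1,
                      covariates = NULL, standardize_snp = TRUE,
                      lr = 0.2, max_iter = 1000, tol = 1e-6, anneal = 0.9) {
  assert_matrix(Xg); assert_matrix(Xs)
  if (nrow(Xg) != nrow(Xs))
    stopf("Xg and Xs must have the same subjects (rows): %d vs %d",
          nrow(Xg), nrow(Xs))
  if (standardize_snp) {
    cn <- colnames(Xs)
    Xs <- scale_cols(Xs)
    colnames(Xs) <- cn
  }
  wh_g <- whiten(Xg, k_g)
  wh_s <- whiten(Xs, k_s)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fit <- .spica_run(wh_g, wh_s,
                      seed_g = seed + r, seed_s = seed + r + 50021L,
                      hoyer_threshold = hoyer_threshold,
                      couple_weight = couple_weight, r_ceiling = r_ceiling,
                      sparsity_step = sparsity_step, lr = lr,
                      max_iter = max_iter, tol = tol, anneal = anneal)
    runs[[r]] <- list(
      gmv = .make_component_model(Xg, wh_g, fit$W_g, "gmv", fit$log),
      snp = .make_component_model(Xs, wh_s, fit$W_s, "snp", fit$log),
      log = fit$log)
  }
  sel <- if (n_runs >= 2) icasso_select(runs) else
    list(best_run = 1L, quality = NULL)
  best <- runs[[sel$best_run]]
  pair_table <- pair_assoc_table(best$gmv$A, best$snp$A,
                                 covariates = covariates)
  structure(list(
    gmv = best$gmv, snp = best$snp, pair_table = pair_table,
    icasso = sel, runs = lapply(runs, `[[`, "log"),
    settings = list(k_g = k_g, k_s = k_s, hoyer_threshold = hoyer_threshold,
                    couple_weight = couple_weight, r_ceiling = r_ceiling,
                    sparsity_step = sparsity_step, n_runs = n_runs,
                    seed = seed, standardize_snp = standardize_snp,
                    lr = lr, max_iter = max_iter, tol = tol)),
    class = "spica_fusion")
}

#' Pairwise loading-association table
#'
#' For every (GMV component, SNP component) pair, regresses the GMV loading
#' on the SNP loading plus optional covariates and reports the Pearson
#' correlation of the two loadings, the focal t statistic, its p-value and
#' partial eta squared.
#'
#' @param Ag,As Loading matrices (subjects x k).
#' @param covariates Optional covariate matrix (e.g. ancestry components).
#' @return A data.frame with `k_g * k_s` rows.
#' @export
pair_assoc_table <- function(Ag, As, covariates = NULL) {
  out <- vector("list", ncol(Ag) * ncol(As))
  idx <- 0L
  for (i in seq_len(ncol(Ag))) for (j in seq_len(ncol(As))) {
    fit <- ols_assoc(Ag[, i], As[, j], covariates = covariates,
                     outcome = paste0("gmv_ic", i),
                     predictor = paste0("snp_ic", j))
    idx <- idx + 1L
    out[[idx]] <- data.frame(
      gmv_ic = i, snp_ic = j, r = cor(Ag[, i], As[, j]),
      beta = fit$beta, t = fit$t, df = fit$df, p = fit$p,
      partial_eta_sq = fit$partial_eta_sq, n = fit$n)
  }
  do.call(rbind, out)
}

#' Estimate the ICA order (component number) by run-to-run consistency
#'
#' For each candidate k the decomposition is repeated `n_runs` times, each
#' run on a fresh random `subsample_frac` subject subsample and from a
#' fresh seed; components are greedily matched across every run pair by
#' maximum absolute correlation of their feature weights. Consistency(k)
#' is the mean over run pairs of the weakest matched |r| (the least
#' reproducible component governs): on fixed data even spurious components
#' re-lock onto stable noise directions, so subject resampling is what
#' makes over-specified orders visible. The largest candidate whose
#' consistency exceeds `floor` is selected; if none qualifies, the argmax.
#' The mean matched |r| is reported alongside.
#'
#' @param X Subjects x features matrix.
#' @param k_candidates Integer vector of candidate orders.
#' @param n_runs Runs per candidate.
#' @param seed Master seed.
#' @param floor Consistency floor for the largest-k rule.
#' @param subsample_frac Fraction of subjects drawn (without replacement)
#'   per run.
#' @param ... Passed to [fit_ica()].
#' @return List with `k` (selected order) and `consistency` (data.frame
#'   with per-candidate min- and mean-match consistency).
#' @export
estimate_order <- function(X, k_candidates, n_runs = 5, seed = 1,
                           floor = 0.8, subsample_frac = 0.9, ...) {
  if (length(k_candidates) == 0) stopf("empty candidate set")
  n <- nrow(X)
  n_sub <- max(2L, floor(subsample_frac * n))
  rk <- min(n_sub, ncol(X)) - 1L
  stats <- vapply(k_candidates, function(k) {
    if (k > rk) return(c(NA_real_, NA_real_))
    fits <- lapply(seq_len(n_runs), function(r) {
      idx <- with_seed(seed + 31L * k + r, sample(n, n_sub))
      fit_ica(X[idx, , drop = FALSE], k, seed = seed + 997L * k + r, ...)
    })
    pairs <- utils::combn(n_runs, 2)
    mm <- apply(pairs, 2, function(pr) {
      m <- .greedy_match(fits[[pr[1]]]$S, fits[[pr[2]]]$S)$r
      c(min(m), mean(m))
    })
    rowMeans(mm)
  }, numeric(2))
  tab <- data.frame(k = k_candidates, consistency = stats[1, ],
                    mean_match = stats[2, ])
  ok <- which(!is.na(stats[1, ]) & stats[1, ] > floor)
  k_sel <- if (length(ok)) max(k_candidates[ok]) else
    k_candidates[which.max(stats[1, ])]
  list(k = k_sel, consistency = tab)
}

## Greedy one-to-one matching of rows of S1 to rows of S2 by max |cor|.
## Returns matched |r| values and the index mapping (and signs).
.greedy_match <- function(S1, S2) {
  R <- abs(cor(t(S1), t(S2)))
  sgn <- sign(cor(t(S1), t(S2)))
  k1 <- nrow(S1); k2 <- nrow(S2)
  m <- min(k1, k2)
  map <- integer(k1); rs <- numeric(k1); sg <- numeric(k1)
  avail1 <- rep(TRUE, k1); avail2 <- rep(TRUE, k2)
  for (step in seq_len(m)) {
    Rm <- R
    Rm[!avail1, ] <- -Inf; Rm[, !avail2] <- -Inf
    ij <- arrayInd(which.max(Rm), dim(Rm))
    map[ij[1]] <- ij[2]; rs[ij[1]] <- R[ij[1], ij[2]]
    sg[ij[1]] <- sgn[ij[1], ij[2]]
    avail1[ij[1]] <- FALSE; avail2[ij[2]] <- FALSE
  }
  keep <- map > 0
  list(map = map[keep], r = rs[keep], sign = sg[keep],
       from = which(keep))
}

#' ICASSO-style representative-run selection
#'
#' Pools the components of all runs per modality, clusters them by
#' agglomerative (average-linkage) clustering on dissimilarity 1 - |r|, and
#' scores each cluster's compactness as Iq = mean within-cluster |r| - mean
#' between-cluster |r|. The representative run maximizes the summed
#' similarity of its components to their clusters' centrotypes (the member
#' with the largest within-cluster similarity sum), totalled over both
#' modalities.
#'
#' @param runs List of runs, each a list with `gmv` and `snp`
#'   `spica_components` (a list with a single modality entry also works).
#' @return List with `best_run` (index), `quality` (per-cluster Iq by
#'   modality), and `similarity` (per-run score).
#' @export
icasso_select <- function(runs) {
  if (length(runs) < 2) stopf("icasso_select needs at least 2 runs")
  modalities <- intersect(c("gmv", "snp"), names(runs[[1]]))
  score <- numeric(length(runs))
  quality <- list()
  for (mod in modalities) {
    Ss <- lapply(runs, function(r) r[[mod]]$S)
    k <- nrow(Ss[[1]])
    pool <- do.call(rbind, Ss)
    run_of <- rep(seq_along(runs), each = k)
    R <- abs(cor(t(pool)))
    cl <- tryCatch(
      cutree(hclust(as.dist(1 - R), method = "average"), k = k),
      error = function(e) NULL)
    if (is.null(cl) || length(unique(cl)) < k) {
      ## degenerate clustering: greedy fallback seeded by run 1's components
      cl <- .greedy_cluster(R, k, run_of)
    }
    iq <- vapply(seq_len(k), function(cc) {
      inside <- cl == cc
      win <- R[inside, inside, drop = FALSE]
      wmean <- if (sum(inside) > 1)
        mean(win[upper.tri(win)]) else 1
      bmean <- mean(R[inside, !inside, drop = FALSE])
      wmean - bmean
    }, numeric(1))
    quality[[mod]] <- data.frame(modality = mod, cluster = seq_len(k),
                                 size = as.vector(table(factor(cl, seq_len(k)))),
                                 Iq = iq)
    cent <- vapply(seq_len(k), function(cc) {
      members <- which(cl == cc)
      members[which.max(rowSums(R[members, cl == cc, drop = FALSE]))]
    }, integer(1))
    for (ri in seq_along(runs)) {
      rows <- which(run_of == ri)
      score[ri] <- score[ri] + sum(R[cbind(rows, cent[cl[rows]])])
    }
  }
  list(best_run = which.max(score), quality = do.call(rbind, quality),
       similarity = score)
}

## Fallback clustering when hclust yields fewer than k usable clusters:
## components of run 1 seed the clusters; every other component joins its
## best-matching seed.
.greedy_cluster <- function(R, k, run_of) {
  seeds <- which(run_of == 1)
  cl <- integer(nrow(R))
  cl[seeds] <- seq_len(k)
  others <- which(run_of != 1)
  cl[others] <- apply(R[others, seeds, drop = FALSE], 1, which.max)
  cl
}

#' Z-score components and extract top contributing features
#'
#' Each component row is normalized to zero mean and unit standard deviation
#' across features, its sign flipped so that the maximum-|z| feature is
#' positive, and the features exceeding `z_threshold` in absolute value are
#' reported (the conventional |z| > 2.5 for voxels and |z| > 2 for SNPs).
#'
#' @param model A `spica_components` object or a components matrix
#'   (k x features).
#' @param z_threshold Absolute z cutoff.
#' @return List with `z` (k x features z-scored, sign-aligned), `top` (list
#'   of feature index vectors), and `flipped` (logical per component).
#' @export
component_top_features <- function(model, z_threshold) {
  S <- if (inherits(model, "spica_components")) model$S else as.matrix(model)
  sds <- apply(S, 1, sd)
  if (any(sds == 0)) stopf("constant component has no z-scores")
  Z <- (S - rowMeans(S)) / sds
  flipped <- logical(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    jmax <- which.max(abs(Z[i, ]))
    if (Z[i, jmax] < 0) { Z[i, ] <- -Z[i, ]; flipped[i] <- TRUE }
  }
  top <- lapply(seq_len(nrow(Z)), function(i) which(abs(Z[i, ]) > z_threshold))
  list(z = Z, top = top, flipped = flipped)
}
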