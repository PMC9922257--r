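## Association-model battery: OLS with covariates, family random-intercept
## mixed models (profiled REML), two-sample t-tests, partial eta squared,
## Bonferroni / Benjamini-Hochberg adjustment, and the numbered model
## formulas used throughout the discovery and replication analyses.

#' Partial eta squared from a single-df t statistic
#'
#' \eqn{\eta_p^2 = t^2 / (t^2 + df)}.
#'
#' @param t t statistic.
#' @param df Residual degrees of freedom (> 0).
#' @return Effect size in \[0, 1\].
#' @export
partial_eta_sq <- function(t, df) {
  if (any(df <= 0)) stopf("df must be positive")
  t^2 / (t^2 + df)
}

.design_matrix <- function(n, x, covariates, interaction_with = NULL) {
  X <- cbind(`(Intercept)` = rep(1, n), focal = x)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  if (!is.null(interaction_with)) {
    X <- cbind(X, group = interaction_with,
               `focal:group` = x * interaction_with)
  }
  X
}

.check_full_rank <- function(X) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  qd
}

#' Ordinary least-squares association test
#'
#' Regresses `y` on `x` plus covariates (intercept always included) and
#' reports the focal coefficient; with `interaction_with` a binary grouping,
#' the main effect of the group and the `x:group` interaction are added and
#' the interaction becomes the focal (reported) term.
#'
#' @param y Outcome vector.
#' @param x Focal predictor.
#' @param covariates Optional matrix/data.frame of additional columns.
#' @param interaction_with Optional binary (0/1) grouping vector.
#' @param outcome,predictor,model_tag Labels carried into the result.
#' @return A one-row data.frame: beta, se, t, df, p, partial_eta_sq, n.
#' @export
ols_assoc <- function(y, x, covariates = NULL, interaction_with = NULL,
                      outcome = "y", predictor = "x", model_tag = NA) {
  n <- length(y)
  X <- .design_matrix(n, x, covariates, interaction_with)
  if (nrow(X) != n) stopf("design rows do not match length(y)")
  qd <- .check_full_rank(X)
  beta <- qr.coef(qd, y)
  res <- y - X %*% beta
  df <- n - ncol(X)
  if (df <= 0) stopf("no residual degrees of freedom")
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qd))
  se <- sqrt(sigma2 * diag(XtXinv))
  focal <- if (is.null(interaction_with)) "focal" else "focal:group"
  fi <- match(focal, colnames(X))
  tval <- beta[fi] / se[fi]
  data.frame(outcome = outcome, predictor = predictor,
             term = if (focal == "focal") predictor else
               paste0(predictor, ":group"),
             beta = unname(beta[fi]), se = unname(se[fi]), t = unname(tval),
             df = df, p = 2 * pt(-abs(tval), df),
             partial_eta_sq = unname(partial_eta_sq(tval, df)),
             model = model_tag, n = n, stringsAsFactors = FALSE)
}

## Half-decorrelating transform for one family-block: subtract
## (1 - 1/sqrt(1 + n_f * theta)) times the family mean from each member.
.family_whiten <- function(v, fam, theta, sizes) {
  shrink <- 1 - 1 / sqrt(1 + as.numeric(sizes) * theta)   # per family
  fm <- as.numeric(tapply(v, fam, mean)[names(sizes)])
  v - (shrink * fm)[match(as.character(fam), names(sizes))]
}

#' Family random-intercept association test (profiled REML)
#'
#' Fits \eqn{y = X\beta + u_{family} + \epsilon} with a single random
#' intercept per family, maximizing the restricted likelihood over the
#' variance ratio \eqn{\theta = \sigma^2_u / \sigma^2_e} by 1-D optimization
#' (the block structure makes the generalized least squares exact and cheap).
#' Reports a Wald test on the focal fixed effect with residual degrees of
#' freedom \eqn{n - p}. With all-singleton families, or when the variance
#' ratio estimate hits 0, the fit reduces to OLS (the boundary case is
#' flagged, not an error).
#'
#' @inheritParams ols_assoc
#' @param family_ids Family identifier per subject (>= 2 distinct families).
#' @return One-row data.frame as [ols_assoc()], plus `variance_ratio`,
#'   `icc` (\eqn{\theta/(1+\theta)}), and `boundary` flag.
#' @export
lmm_assoc <- function(y, x, covariates = NULL, family_ids,
                      outcome = "y", predictor = "x", model_tag = NA) {
  n <- length(y)
  fam <- factor(family_ids)
  if (nlevels(fam) < 2) stopf("need at least 2 families")
  X <- .design_matrix(n, x, covariates)
  .check_full_rank(X)
  p <- ncol(X)
  sizes <- table(fam)
  fam_chr <- as.character(fam)

  reml_fit <- function(theta) {
    ys <- .family_whiten(y, fam, theta, sizes)
    Xs <- apply(X, 2, .family_whiten, fam = fam, theta = theta,
                sizes = sizes)
    qd <- qr(Xs)
    beta <- qr.coef(qd, ys)
    r <- ys - Xs %*% beta
    rss <- sum(r^2)
    list(qd = qd, beta = beta, rss = rss,
         crit = (n - p) * log(rss) + sum(sizes * 0) +
           sum(log(1 + as.numeric(sizes) * theta)) +
           2 * sum(log(abs(diag(qr.R(qd))))))
  }

  if (all(sizes == 1)) {
    theta_hat <- 0
  } else {
    obj <- function(lt) reml_fit(exp(lt))$crit
    opt <- optimize(obj, interval = c(log(1e-8), log(1e4)))
    theta_hat <- exp(opt$minimum)
    if (reml_fit(0)$crit <= opt$objective) theta_hat <- 0
  }
  boundary <- theta_hat < 1e-6
  if (boundary) theta_hat <- 0
  fit <- reml_fit(theta_hat)
  df <- n - p
  sigma2 <- fit$rss / df
  XtXinv <- chol2inv(qr.R(fit$qd))
  se <- sqrt(sigma2 * diag(XtXinv))
  fi <- match("focal", colnames(X))
  tval <- fit$beta[fi] / se[fi]
  data.frame(outcome = outcome, predictor = predictor, term = predictor,
             beta = unname(fit$beta[fi]), se = unname(se[fi]),
             t = unname(tval), df = df, p = 2 * pt(-abs(tval), df),
             partial_eta_sq = unname(partial_eta_sq(tval, df)),
             model = model_tag, n = n,
             variance_ratio = theta_hat, icc = theta_hat / (1 + theta_hat),
             boundary = boundary, stringsAsFactors = FALSE)
}

## Restricted-likelihood criterion at a given variance ratio, exposed for
## local-optimum checks (smaller is better; -2 log REML up to a constant).
reml_criterion <- function(y, x, covariates = NULL, family_ids, theta) {
  n <- length(y)
  fam <- factor(family_ids)
  X <- .design_matrix(n, x, covariates)
  sizes <- table(fam)
  ys <- .family_whiten(y, fam, theta, sizes)
  Xs <- apply(X, 2, .family_whiten, fam = fam, theta = theta, sizes = sizes)
  qd <- qr(Xs)
  r <- ys - Xs %*% qr.coef(qd, ys)
  (n - ncol(X)) * log(sum(r^2)) +
    sum(log(1 + as.numeric(sizes) * theta)) +
    2 * sum(log(abs(diag(qr.R(qd)))))
}

#' Two-sample t-test on a component loading between two groups
#'
#' Classical pooled-variance two-sample t-test by default; Welch on request
#' or as an automatic fallback when a group has zero variance with n = 2.
#'
#' @param values Numeric vector.
#' @param groups Two-level factor/vector aligned with `values`.
#' @param var_equal Pooled variance (default) or Welch.
#' @return One-row data.frame: mean difference, t, df, p, n per group.
#' @export
group_diff_ttest <- function(values, groups, var_equal = TRUE) {
  g <- factor(groups)
  if (nlevels(g) != 2) stopf("exactly two group labels required")
  split_v <- split(values, g)
  ns <- lengths(split_v)
  if (any(ns < 2)) stopf("both groups need n >= 2")
  if (var_equal && any(vapply(split_v, var, 0) == 0 & ns == 2)) {
    warnf("zero-variance group with n = 2; falling back to Welch")
    var_equal <- FALSE
  }
  ht <- stats::t.test(split_v[[1]], split_v[[2]], var.equal = var_equal)
  data.frame(group1 = levels(g)[1], group2 = levels(g)[2],
             mean_diff = unname(diff(rev(ht$estimate))),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, n1 = ns[[1]], n2 = ns[[2]],
             pooled = var_equal, stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (reject iff p < alpha/m, threshold reported) or
#' Benjamini-Hochberg step-up FDR (adjusted p-values reported).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @param alpha Family-wise / FDR level.
#' @return List with `method`, `alpha`, `m`, `threshold` (Bonferroni only),
#'   `adjusted` (BH only), and logical `reject`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0) stopf("empty p-value list")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (method == "bonferroni") {
    thr <- alpha / m
    list(method = method, alpha = alpha, m = m, threshold = thr,
         reject = p < thr)
  } else {
    adj <- p.adjust(p, method = "BH")
    list(method = method, alpha = alpha, m = m, adjusted = adj,
         reject = adj <= alpha)
  }
}

#' Fit one of the numbered association models
#'
#' Maps the study's model numbers onto concrete fits over a cohort table:
#' \describe{
#'   \item{1}{GMV loading ~ SNP loading + 5 ancestry components (OLS).}
#'   \item{2}{behavioral outcome ~ age + sex + GMV loading (OLS).}
#'   \item{3}{behavioral outcome ~ age + sex + SNP loading + ancestry (OLS).}
#'   \item{4}{SNP loading ~ diagnosis (ADHD vs control) + ancestry (OLS).}
#'   \item{5}{GMV ~ SNP + ancestry + medication, family random intercept.}
#'   \item{6}{GMV ~ diagnosis + medication, family random intercept.}
#'   \item{7}{SNP ~ diagnosis + ancestry, family random intercept.}
#'   \item{8}{GMV ~ SNP + ancestry + family label + family label x SNP
#'     (OLS); the interaction is the reported term.}
#' }
#' Models 4, 6 and 7 drop unaffected siblings (cases vs. controls only).
#'
#' @param model Integer 1-8.
#' @param cohort Cohort data.frame with columns `group`
#'   (ADHD/sibling/control), `age`, `sex`, `anc1`..`anc5`, and for mixed
#'   models `family_id` and `medication`; model 8 additionally needs
#'   `family_label` (0/1).
#' @param gmv,snp Loading vectors aligned with the cohort rows.
#' @param outcome Behavioral outcome vector (models 2-3).
#' @return One-row association data.frame (see [ols_assoc()]).
#' @export
fit_assoc_model <- function(model, cohort, gmv = NULL, snp = NULL,
                            outcome = NULL) {
  anc <- as.matrix(cohort[, paste0("anc", 1:5)])
  keep_cc <- cohort$group %in% c("ADHD", "control")
  diag01 <- as.numeric(cohort$group == "ADHD")
  switch(as.character(model),
    "1" = ols_assoc(gmv, snp, covariates = anc, outcome = "gmv_loading",
                    predictor = "snp_loading", model_tag = 1),
    "2" = ols_assoc(outcome, gmv,
                    covariates = cbind(age = cohort$age, sex = cohort$sex),
                    outcome = "behavior", predictor = "gmv_loading",
                    model_tag = 2),
    "3" = ols_assoc(outcome, snp,
                    covariates = cbind(age = cohort$age, sex = cohort$sex,
                                       anc),
                    outcome = "behavior", predictor = "snp_loading",
                    model_tag = 3),
    "4" = ols_assoc(snp[keep_cc], diag01[keep_cc],
                    covariates = anc[keep_cc, , drop = FALSE],
                    outcome = "snp_loading", predictor = "diagnosis",
                    model_tag = 4),
    "5" = lmm_assoc(gmv, snp,
                    covariates = cbind(anc, medication = cohort$medication),
                    family_ids = cohort$family_id, outcome = "gmv_loading",
                    predictor = "snp_loading", model_tag = 5),
    "6" = lmm_assoc(gmv[keep_cc], diag01[keep_cc],
                    covariates = cbind(medication = cohort$medication)[keep_cc, ,
                                                                       drop = FALSE],
                    family_ids = cohort$family_id[keep_cc],
                    outcome = "gmv_loading", predictor = "diagnosis",
                    model_tag = 6),
    "7" = lmm_assoc(snp[keep_cc], diag01[keep_cc],
                    covariates = anc[keep_cc, , drop = FALSE],
                    family_ids = cohort$family_id[keep_cc],
                    outcome = "snp_loading", predictor = "diagnosis",
                    model_tag = 7),
    "8" = ols_assoc(gmv, snp, covariates = anc,
                    interaction_with = cohort$family_label,
                    outcome = "gmv_loading", predictor = "snp_loading",
                    model_tag = 8),
    stopf("unknown model number: %s", model))
}
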