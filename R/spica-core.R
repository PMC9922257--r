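## spICA engine: PCA whitening, extended Infomax ICA, cross-modal loading
## coupling, Hoyer sparsity constraint, multi-run stability selection.

#' Hoyer sparseness of a vector
#'
#' Scale-invariant sparsity measure based on the L1/L2 norm ratio:
#' \eqn{(\sqrt{n} - \|v\|_1/\|v\|_2) / (\sqrt{n} - 1)}. Equals 0 for a
#' constant vector and 1 for a one-hot vector.
#'
#' @param v Numeric vector, length >= 2, not all zero.
#' @return A value in \[0, 1\].
#' @examples
#' hoyer_sparseness(c(1, 0, 0, 0)) # 1
#' hoyer_sparseness(c(1, 1, 1, 1)) # 0
#' @export
hoyer_sparseness <- function(v) {
  if (!is.numeric(v) || length(v) < 2) stopf("'v' must be numeric, length >= 2")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) stopf("Hoyer sparseness undefined for the zero vector")
  n <- length(v)
  (sqrt(n) - sum(abs(v)) / l2) / (sqrt(n) - 1)
}

## Smoothed Hoyer (|x| ~ sqrt(x^2 + eps)) and its gradient; used by the
## sparsity-ascent step where a differentiable surrogate is needed.
hoyer_smooth <- function(v, eps = 1e-8) {
  n <- length(v)
  l1 <- sum(sqrt(v^2 + eps))
  l2 <- sqrt(sum(v^2))
  (sqrt(n) - l1 / l2) / (sqrt(n) - 1)
}

hoyer_smooth_grad <- function(v, eps = 1e-8) {
  n <- length(v)
  sv <- sqrt(v^2 + eps)
  l1 <- sum(sv)
  l2 <- sqrt(sum(v^2))
  ## d/dv [ -(l1/l2) / (sqrt(n)-1) ]
  -(v / sv / l2 - l1 * v / l2^3) / (sqrt(n) - 1)
}

#' PCA whitening of a subjects x features matrix
#'
#' Removes each subject's mean over features (the channel mean, in ICA
#' terms) and projects onto the top-k principal subspace of the subject
#' dimension, returning reduced data whose rows have exactly identity
#' second-moment matrix over features, plus the record needed to
#' back-project components into feature space.
#'
#' @param X Numeric matrix, subjects x features.
#' @param k Number of retained components; must not exceed the rank of the
#'   centered matrix.
#' @return A list with `Z` (k x features, whitened), `dewhiten`
#'   (subjects x k), `subject_means`, singular values `d`, and
#'   `retained_variance` (fraction of total variance kept).
#' @export
whiten <- function(X, k) {
  assert_matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p)) stopf("k = %d exceeds min(dim) = %d", k, min(n, p))
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc, nu = k, nv = k)
  if (sv$d[k] < max(sv$d) * 1e-12)
    stopf("k = %d exceeds the numerical rank of the centered data", k)
  d <- sv$d[seq_len(k)]
  Z <- sqrt(p) * t(sv$v)                  # k x p, tcrossprod(Z)/p = I
  dewhiten <- sv$u %*% diag(d / sqrt(p), k, k)  # X_c ~ dewhiten %*% Z
  list(Z = Z, dewhiten = dewhiten, subject_means = mu, d = sv$d,
       retained_variance = sum(d^2) / sum(sv$d^2), k = k)
}

## Kurtosis-sign diagonal for extended Infomax: +1 super-Gaussian source
## (logistic score), -1 sub-Gaussian.
.kurt_signs <- function(U) {
  m2 <- rowMeans(U^2)
  m4 <- rowMeans(U^4)
  sign(m4 / m2^2 - 3 + 1e-12)
}

## One natural-gradient extended-Infomax update. Returns the increment dW.
.infomax_grad <- function(W, Z, ksign) {
  U <- W %*% Z
  p <- ncol(Z)
  k <- nrow(W)
  bracket <- diag(k) - (ksign * tanh(U)) %*% t(U) / p - U %*% t(U) / p
  bracket %*% W
}

## Core single-modality Infomax loop over whitened data Z (k x p), driven by
## the same .ica_step() the joint spICA loop uses, so a decoupled joint fit
## follows this trajectory exactly.
.infomax_run <- function(Z, seed, lr, max_iter, tol, anneal = 0.9) {
  st <- .ica_state_init(nrow(Z), seed, lr, max_iter, tol, anneal)
  while (!st$done && st$it < st$max_iter) st <- .ica_step(st, Z)
  list(W = st$W, iterations = st$it, delta = st$delta,
       converged = st$done, learning_rate = st$rate)
}

## Assemble a ComponentModel from a whitening record and an unmixing matrix:
## unit-variance component rows in feature space, least-squares loadings.
.make_component_model <- function(X, wh, W, modality, log = NULL) {
  S <- W %*% wh$Z                              # k x features
  sds <- apply(S, 1, sd)
  if (any(sds == 0)) stopf("degenerate (constant) component encountered")
  S <- S / sds
  Xc <- X - wh$subject_means
  A <- t(solve(tcrossprod(S), S %*% t(Xc)))    # X_c ~ A %*% S
  colnames(S) <- colnames(X)
  rownames(A) <- rownames(X)
  structure(list(A = A, S = S, modality = modality,
                 whitening = wh[c("subject_means", "dewhiten",
                                  "retained_variance", "k")],
                 unmixing = W, convergence = log),
            class = "spica_components")
}

#' Infomax ICA decomposition of one modality
#'
#' Reduces `X` to `k` principal dimensions, runs natural-gradient extended
#' Infomax (kurtosis-adaptive nonlinearity, so both super- and sub-Gaussian
#' sources separate), and returns unit-variance feature-space components with
#' their least-squares subject loadings.
#'
#' @param X Subjects x features matrix.
#' @param k Number of components.
#' @param seed Integer seed controlling the (single) random initialization.
#' @param lr Initial learning rate; halved and restarted (up to 3 times) on
#'   divergence, annealed by `anneal` when successive updates oppose.
#' @param max_iter,tol Stopping rule on the unmixing-update Frobenius norm.
#' @param anneal Multiplicative learning-rate decay applied on oscillation.
#' @return A `spica_components` object: loadings `A` (subjects x k),
#'   components `S` (k x features), whitening record and convergence log.
#' @export
fit_ica <- function(X, k, seed = 1, lr = 0.2, max_iter = 1000, tol = 1e-6,
                    anneal = 0.9) {
  wh <- whiten(X, k)
  run <- .infomax_run(wh$Z, seed = seed, lr = lr, max_iter = max_iter,
                      tol = tol, anneal = anneal)
  .make_component_model(X, wh, run$W, modality = "generic",
                        log = run[c("iterations", "delta", "converged",
                                    "learning_rate")])
}

## Gradient of r^2 = cor(a, b)^2 with respect to a (b held fixed).
.corsq_grad <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  sa <- sqrt(sum(ac^2)); sb <- sqrt(sum(bc^2))
  r <- sum(ac * bc) / (sa * sb)
  list(r = r, grad = 2 * r * (bc / (sa * sb) - r * ac / sa^2))
}
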