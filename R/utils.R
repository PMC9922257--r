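#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd rnorm runif rbinom pt p.adjust lm coef var
#'   quantile hclust cutree as.dist qlogis plogis pnorm optimize setNames
#'   complete.cases
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Local RNG scope: run `expr` under `seed` without disturbing the caller's
## RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Column-standardize keeping matrix shape; constant columns become 0.
scale_cols <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, s, "/")
}

assert_matrix <- function(X, name = deparse(substitute(X))) {
  if (!is.matrix(X) || !is.numeric(X))
    stopf("'%s' must be a numeric matrix", name)
  if (anyNA(X)) stopf("'%s' contains missing values", name)
  invisible(X)
}
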