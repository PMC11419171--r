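#' @importFrom stats dist cutree hclust kmeans glm glm.fit binomial pnorm
#'   pchisq rbinom rnorm runif sd var cor complete.cases coef quantile
#'   setNames prcomp qbinom
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_cfg(field, "must be numeric and non-missing")
  lo <- if (allow_zero) 0 else .Machine$double.eps
  if (any(x < lo) || any(x > 1)) stop_cfg(field, "must lie in [0, 1]")
  invisible(x)
}

check_maf <- function(x, field = "maf") {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0) || any(x > 0.5))
    stop_cfg(field, "must lie in (0, 0.5]")
  invisible(x)
}

#' Run an expression under a fixed RNG seed
#'
#' Thin wrapper around [withr::with_seed()] so every stochastic operation in
#' the package is reproducible without disturbing the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Manhattan distance matrix between rows of (possibly binary) matrices.
# For a single matrix returns the full symmetric n x n matrix.
manhattan_matrix <- function(X, Y = NULL) {
  if (is.null(Y)) return(as.matrix(dist(X, method = "manhattan")))
  # cross-distance; exact for binary 0/1, general fallback otherwise
  if (all(X %in% c(0, 1)) && all(Y %in% c(0, 1))) {
    X %*% t(1 - Y) + (1 - X) %*% t(Y)
  } else {
    t(apply(X, 1, function(r) colSums(abs(t(Y) - r))))
  }
}
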