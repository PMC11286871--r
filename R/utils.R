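#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' functions never perturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stage-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1000L
}

stopifnot_scalar <- function(x, name, finite = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

#' Fisher r-to-z transform
#'
#' `atanh(r)`, the variance-stabilizing transform used for both FC and MPC
#' edges. Values with |r| >= 1 are clipped to 1 - 1e-7 with a warning so
#' that degenerate (identical-profile) correlations stay finite.
#'
#' @param r correlations.
#' @param clip clipping bound applied to |r| before transforming.
#' @return z scores, same shape as `r`.
#' @export
#' @examples
#' fisher_z(0.5)          # atanh(0.5)
#' tanh(fisher_z(0.3))    # round-trips
fisher_z <- function(r, clip = 1 - 1e-7) {
  if (any(!is.finite(r))) stop("non-finite correlation passed to fisher_z", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12)) stop("|r| > 1 is not a correlation", call. = FALSE)
  if (any(abs(r) >= 1 - 1e-12)) {
    warning("correlations with |r| ~ 1 clipped before Fisher transform")
  }
  atanh(pmin(pmax(r, -clip), clip))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]) plus the
#' significance mask at `alpha`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (adjusted p-values) and `mask` (logical, q < alpha).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, mask = !is.na(q) & q < alpha)
}

## rank-based Spearman rho of y columns against x, with t-approximation p.
## x: length-m vector; Y: m x k matrix. Returns list(rho, p).
spearman_cols <- function(x, Y) {
  Y <- as.matrix(Y)
  rx <- rank(x)
  rY <- apply(Y, 2L, rank)
  rho <- suppressWarnings(stats::cor(rx, rY))
  rho <- as.numeric(rho)
  m <- length(x)
  tstat <- rho * sqrt((m - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(abs(tstat), df = m - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  list(rho = rho, p = p)
}

## symmetry check helper
check_symmetric <- function(m, tol = 1e-10, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be square", name), call. = FALSE)
  }
  d <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(d) && d > tol) {
    stop(sprintf("`%s` is not symmetric (max |m - t(m)| = %.3g)", name, d), call. = FALSE)
  }
  invisible(TRUE)
}
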