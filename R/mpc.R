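#' Cortex-average depth profile (the MPC controller)
#'
#' Depth-wise mean myelin-proxy profile across included parcels of one
#' session; used as the control variable when building microstructural
#' profile covariance so that inter-regional similarity is not driven by
#' the shared mean intensity across intracortical surfaces.
#'
#' @param profiles parcels x depths matrix.
#' @param include logical mask of included parcels (default all).
#' @return numeric depth profile of length `ncol(profiles)`.
#' @export
cohort_controller <- function(profiles, include = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(include)) include <- rep(TRUE, nrow(profiles))
  if (sum(include) < 2L) stop("need at least 2 included parcels", call. = FALSE)
  colMeans(profiles[include, , drop = FALSE])
}

#' Microstructural profile covariance for one session
#'
#' Edge (i, j) is the partial Pearson correlation between the depth
#' profiles of parcels i and j, controlling for the cortex-average profile,
#' Fisher r-to-z transformed (default). Parcels whose profile is constant,
#' or collinear with the controller (zero residual variance), are excluded
#' and their rows/columns returned as NA.
#'
#' @param profiles parcels x depths matrix for one session.
#' @param controller depth profile used as the control variable; defaults
#'   to [cohort_controller()] of `profiles`.
#' @param transform `"fisher_z"` (default) or `"raw_r"`.
#' @param clip clipping bound on |partial r| before the Fisher transform.
#' @return object of class `parcel_matrix`: list with `values` (P x P,
#'   symmetric, zero diagonal), `excluded` (logical), `kind = "mpc"`,
#'   `transform`.
#' @export
build_mpc <- function(profiles, controller = NULL,
                      transform = c("fisher_z", "raw_r"), clip = 1 - 1e-7) {
  transform <- match.arg(transform)
  profiles <- as.matrix(profiles)
  P <- nrow(profiles); D <- ncol(profiles)
  if (D < 3L) stop("need at least 3 depths to build MPC", call. = FALSE)
  excluded <- apply(profiles, 1L, function(x) stats::var(x) < 1e-14)
  if (is.null(controller)) controller <- cohort_controller(profiles, !excluded)
  if (length(controller) != D) stop("controller length must equal depth count", call. = FALSE)

  if (stats::var(controller) < 1e-14) {
    warning("constant controller: falling back to plain correlation")
    resid <- sweep(profiles, 1L, rowMeans(profiles))
  } else {
    ## residualize each profile on [1, controller]
    X <- cbind(1, controller)
    qrX <- qr(X)
    resid <- t(profiles) - X %*% qr.coef(qrX, t(profiles))
    resid <- t(resid)
  }
  rv <- apply(resid, 1L, function(x) sum(x^2))
  excluded <- excluded | rv < 1e-12 * D
  vals <- matrix(NA_real_, P, P, dimnames = list(rownames(profiles), rownames(profiles)))
  inc <- which(!excluded)
  if (length(inc) >= 2L) {
    r <- suppressWarnings(stats::cor(t(resid[inc, , drop = FALSE])))
    if (transform == "fisher_z") {
      r <- atanh(pmin(pmax(r, -clip), clip))
    }
    diag(r) <- 0
    vals[inc, inc] <- r
  }
  structure(list(values = vals, excluded = excluded, kind = "mpc",
                 transform = transform),
            class = "parcel_matrix")
}

#' @export
print.parcel_matrix <- function(x, ...) {
  cat(sprintf("<parcel_matrix> kind=%s transform=%s  %d parcels (%d excluded)\n",
              x$kind, x$transform, nrow(x$values), sum(x$excluded)))
  invisible(x)
}
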