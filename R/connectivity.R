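#' Regress mean framewise displacement out of edge values
#'
#' Each edge (column) is residualized on the per-session mean framewise
#' displacement with a simple linear regression, removing residual motion
#' effects from Fisher-z connectivity. If `mean_fd` has (near) zero
#' variance the input is passed through with a warning.
#'
#' @param edges sessions x edges matrix of z-scores.
#' @param mean_fd per-session mean framewise displacement (mm).
#' @return residualized matrix, same shape; residuals have zero sample
#'   correlation with `mean_fd`.
#' @export
regress_fd <- function(edges, mean_fd) {
  edges <- as.matrix(edges)
  if (nrow(edges) != length(mean_fd)) stop("`mean_fd` must match rows of `edges`", call. = FALSE)
  if (nrow(edges) < 3L) stop("need at least 3 sessions", call. = FALSE)
  if (any(!is.finite(mean_fd)) || any(mean_fd < 0)) {
    stop("mean framewise displacement must be finite and nonnegative", call. = FALSE)
  }
  if (stats::var(mean_fd) < 1e-14) {
    warning("mean_fd has no variance: edges passed through unchanged")
    return(edges)
  }
  X <- cbind(1, mean_fd)
  edges - X %*% qr.coef(qr(X), edges)
}

#' Exclude low-signal regions
#'
#' A region is excluded when its standardized signal summary falls below
#' `threshold` for at least one participant; the resulting mask is applied
#' consistently to every connectivity matrix downstream.
#'
#' @param region_stats participants x regions matrix of standardized signal
#'   summaries (z-scores).
#' @param threshold exclusion cut (default 1.96); the rule is strictly
#'   `< threshold`.
#' @return logical vector, TRUE = excluded.
#' @export
exclude_low_snr <- function(region_stats, threshold = 1.96) {
  region_stats <- as.matrix(region_stats)
  if (any(!is.finite(region_stats))) stop("non-finite region summary", call. = FALSE)
  apply(region_stats, 2L, function(z) any(z < threshold))
}

#' Seed-based connectivity of a region of interest
#'
#' Per-target connectivity of an ROI: the mean over seed parcels of the
#' edge to each target parcel. Targets inside the ROI, and excluded
#' parcels, are returned as NA.
#'
#' @param mat P x P symmetric edge matrix (or a `parcel_matrix`).
#' @param roi integer indices (or logical mask) of seed parcels.
#' @param excluded optional logical exclusion mask.
#' @return numeric vector of length P.
#' @export
seed_fc <- function(mat, roi, excluded = NULL) {
  m <- extract_values(mat, excluded)
  excluded <- attr(m, "excluded")
  roi <- normalize_roi(roi, nrow(m))
  roi <- roi[!excluded[roi]]
  if (length(roi) == 0L) stop("ROI is entirely excluded", call. = FALSE)
  v <- colMeans(m[roi, , drop = FALSE])
  v[roi] <- NA_real_
  v[excluded] <- NA_real_
  v
}

#' Weighted degree centrality of a region of interest
#'
#' Global connectivity of the ROI: the sum over all included non-ROI
#' target parcels of the ROI-mean edge value, i.e.
#' `sum(seed_fc(mat, roi), na.rm = TRUE)`.
#'
#' @inheritParams seed_fc
#' @return scalar z-sum.
#' @export
degree_centrality <- function(mat, roi, excluded = NULL) {
  sum(seed_fc(mat, roi, excluded), na.rm = TRUE)
}

## accept either a plain matrix or a parcel_matrix
extract_values <- function(mat, excluded = NULL) {
  if (inherits(mat, "parcel_matrix")) {
    if (is.null(excluded)) excluded <- mat$excluded
    mat <- mat$values
  }
  mat <- as.matrix(mat)
  check_symmetric(mat, tol = 1e-8)
  if (is.null(excluded)) excluded <- rep(FALSE, nrow(mat))
  attr(mat, "excluded") <- excluded
  mat
}

normalize_roi <- function(roi, P) {
  if (is.logical(roi)) roi <- which(roi)
  roi <- as.integer(roi)
  if (length(roi) == 0L || any(roi < 1L | roi > P)) stop("invalid ROI", call. = FALSE)
  unique(roi)
}

#' Build a Fisher-z FC matrix from raw correlations
#'
#' Convenience constructor: clips, Fisher-transforms, zeroes the diagonal
#' and attaches an exclusion mask.
#'
#' @param r P x P correlation (or z) matrix.
#' @param excluded logical exclusion mask.
#' @param already_z set TRUE if `r` is already Fisher-transformed.
#' @return a `parcel_matrix` of kind `"fc"`.
#' @export
as_fc_matrix <- function(r, excluded = NULL, already_z = FALSE) {
  r <- as.matrix(r)
  check_symmetric(r, tol = 1e-8)
  if (is.null(excluded)) excluded <- rep(FALSE, nrow(r))
  z <- if (already_z) r else suppressWarnings(fisher_z(r))
  diag(z) <- 0
  z[excluded, ] <- NA_real_
  z[, excluded] <- NA_real_
  structure(list(values = z, excluded = excluded, kind = "fc",
                 transform = "fisher_z"),
            class = "parcel_matrix")
}
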