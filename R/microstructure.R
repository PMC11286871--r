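#' Equivolumetric depth coordinate
#'
#' Position of an intracortical surface so that a fraction `alpha` of the
#' cortical volume lies between the inner (white) boundary and the surface,
#' assuming surface area interpolates linearly with the normalized distance
#' rho between the boundaries. Unlike equidistant sampling this compensates
#' for cortical folding: surfaces crowd toward the boundary with the larger
#' area.
#'
#' The closed form solves A_in*rho + (A_out - A_in)*rho^2/2 =
#' alpha * (A_in + A_out)/2:
#' rho = (-A_in + sqrt(alpha*A_out^2 + (1-alpha)*A_in^2)) / (A_out - A_in),
#' with the limit rho = alpha when the areas are equal.
#'
#' @param a_in inner (white) boundary surface area, > 0.
#' @param a_out outer (pial) boundary surface area, > 0.
#' @param alpha volume fraction(s) in `[0, 1]`, measured from the inner
#'   boundary.
#' @return rho in `[0, 1]`: normalized distance from the inner boundary.
#' @export
#' @examples
#' equivolumetric_rho(1, 1, 0.5)   # 0.5: equal areas reduce to equidistant
#' equivolumetric_rho(1, 4, 0.25)  # ~0.393: surfaces crowd toward the pial side
equivolumetric_rho <- function(a_in, a_out, alpha) {
  stopifnot_scalar(a_in, "a_in"); stopifnot_scalar(a_out, "a_out")
  if (a_in <= 0 || a_out <= 0) stop("surface areas must be positive", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(a_out - a_in) < 1e-12 * max(a_in, a_out)) {
    return(alpha)
  }
  (-a_in + sqrt(alpha * a_out^2 + (1 - alpha) * a_in^2)) / (a_out - a_in)
}

#' Construct the equivolumetric depth grid with outer-surface exclusion
#'
#' Builds `n_surfaces` equivolumetric surfaces at interior volume fractions
#' i/(n_surfaces + 1) and removes the two pial-most to avoid partial-volume
#' contamination, leaving (by default) the 10 analysis depths. Retained
#' depths are returned pial-to-white, the storage orientation used
#' throughout the package.
#'
#' @param a_in,a_out boundary surface areas (see [equivolumetric_rho()]).
#' @param n_surfaces number of constructed surfaces (default 12).
#' @param n_exclude number of pial-most surfaces removed (default 2).
#' @return list with `rho` (all surfaces, white-to-pial construction order),
#'   `alpha` (volume fractions), `retained` (logical mask), and
#'   `depth_rho` / `depth_alpha`: the retained grid ordered pial-to-white.
#' @export
build_depth_grid <- function(a_in, a_out, n_surfaces = 12L, n_exclude = 2L) {
  if (n_surfaces < 4L) stop("need at least 4 surfaces", call. = FALSE)
  alpha <- seq_len(n_surfaces) / (n_surfaces + 1)
  rho <- vapply(alpha, function(a) equivolumetric_rho(a_in, a_out, a), numeric(1))
  retained <- rep(TRUE, n_surfaces)
  ## pial-most surfaces are the largest volume fractions
  retained[order(alpha, decreasing = TRUE)[seq_len(n_exclude)]] <- FALSE
  keep <- which(retained)
  ord <- order(alpha[keep], decreasing = TRUE)  # pial -> white
  list(rho = rho, alpha = alpha, retained = retained,
       depth_rho = rho[keep][ord], depth_alpha = alpha[keep][ord])
}

#' CSF partial-volume correction of depth profiles
#'
#' Per parcel, a linear model MT ~ b0 + b1*CSF is fitted and the corrected
#' values are the residuals plus the group-averaged (across sessions) MT
#' at that (parcel, depth). With the default `method = "pooled"` one model
#' per parcel is fitted to all sessions' depth points jointly: a shared
#' intercept and CSF slope remove the depth-wise contamination while
#' session-level mean differences - the longitudinal signal - are
#' preserved in the residuals. `method = "per_session"` refits the model
#' within each (session, parcel) profile; note that this constrains every
#' corrected profile's depth mean to the group profile's mean (per-profile
#' residuals sum to zero), which removes all intra-individual change from
#' depth-averaged summaries - appropriate only for strictly
#' cross-sectional profile analyses. Parcels (or profiles) whose CSF
#' fraction is constant carry no partial-volume information and pass
#' through unchanged.
#'
#' @param mt sessions x parcels x depths array of myelin-proxy intensities.
#' @param csf array of CSF fractions in `[0, 1]`, same shape as `mt`.
#' @param group_mean optional parcels x depths matrix used as the restored
#'   group profile; defaults to the mean of `mt` over sessions. Supplying
#'   the same matrix across runs makes the correction reproducible across
#'   sub-samples.
#' @param tol minimum CSF variance for a fit to be attempted.
#' @param method `"pooled"` (one fit per parcel across sessions, default)
#'   or `"per_session"` (one fit per profile).
#' @return array shaped like `mt`, with attribute `"uncorrected"` counting
#'   parcels/profiles skipped by the zero-variance guard.
#' @export
csf_correct <- function(mt, csf, group_mean = NULL, tol = 1e-12,
                        method = c("pooled", "per_session")) {
  method <- match.arg(method)
  if (!is.array(mt) || length(dim(mt)) != 3L) stop("`mt` must be a 3-d array", call. = FALSE)
  if (!identical(dim(mt), dim(csf))) stop("`mt` and `csf` shapes differ", call. = FALSE)
  if (dim(mt)[3] < 3L) stop("need at least 3 depths", call. = FALSE)
  if (any(csf < -1e-9 | csf > 1 + 1e-9)) {
    warning("CSF values outside [0, 1]; proceeding (correction is scale-invariant)")
  }
  ns <- dim(mt)[1]; np <- dim(mt)[2]; nd <- dim(mt)[3]
  if (is.null(group_mean)) {
    group_mean <- apply(mt, c(2, 3), mean)
  }
  if (!identical(dim(group_mean), c(np, nd))) {
    stop("`group_mean` must be parcels x depths", call. = FALSE)
  }
  out <- mt
  skipped <- 0L
  if (method == "pooled") {
    for (p in seq_len(np)) {
      y <- as.numeric(mt[, p, ])
      x <- as.numeric(csf[, p, ])
      if (stats::var(x) <= tol) { skipped <- skipped + 1L; next }
      fit <- stats::lm.fit(cbind(1, x), y)
      out[, p, ] <- matrix(fit$residuals, ns, nd) +
        matrix(group_mean[p, ], ns, nd, byrow = TRUE)
    }
  } else {
    for (s in seq_len(ns)) {
      for (p in seq_len(np)) {
        y <- mt[s, p, ]
        x <- csf[s, p, ]
        if (stats::var(x) <= tol) { skipped <- skipped + 1L; next }
        fit <- stats::lm.fit(cbind(1, x), y)
        out[s, p, ] <- fit$residuals + group_mean[p, ]
      }
    }
  }
  attr(out, "uncorrected") <- skipped
  out
}

#' Aggregate vertex-level depth profiles into parcels
#'
#' Unweighted mean of vertex values within each parcel, per depth.
#'
#' @param vertex_values vertices x depths matrix.
#' @param parcel_map integer/character parcel label per vertex.
#' @param parcels optional vector fixing the output parcel order; parcels
#'   with no vertices are returned as all-NA rows with a warning.
#' @return parcels x depths matrix with parcel labels as rownames.
#' @export
parcel_aggregate <- function(vertex_values, parcel_map, parcels = NULL) {
  vertex_values <- as.matrix(vertex_values)
  if (nrow(vertex_values) != length(parcel_map)) {
    stop("one parcel label required per vertex", call. = FALSE)
  }
  if (anyNA(parcel_map)) stop("every vertex must be mapped to a parcel", call. = FALSE)
  if (is.null(parcels)) parcels <- sort(unique(parcel_map))
  out <- matrix(NA_real_, length(parcels), ncol(vertex_values),
                dimnames = list(as.character(parcels), colnames(vertex_values)))
  for (i in seq_along(parcels)) {
    idx <- which(parcel_map == parcels[i])
    if (length(idx) == 0L) next
    out[i, ] <- colMeans(vertex_values[idx, , drop = FALSE])
  }
  empty <- rowSums(!is.na(out)) == 0L
  if (any(empty)) {
    warning(sprintf("%d parcel(s) without vertices returned as missing: %s",
                    sum(empty), paste(rownames(out)[empty], collapse = ", ")))
  }
  out
}
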