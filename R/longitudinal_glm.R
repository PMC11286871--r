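#' Intra-individual change map
#'
#' Last-minus-first session difference per subject and parcel. Subjects
#' with fewer than two sessions are dropped (with a message). The returned
#' subject table carries the covariates needed downstream: imaging
#' inter-session interval (delta_age), mean age across the used sessions,
#' sex and site.
#'
#' @param values sessions x parcels matrix, rows aligned with `cohort`.
#' @param cohort data frame with columns `subject_id`, `session_id`, `age`,
#'   and optionally `sex`, `site`.
#' @return object of class `change_map`: list with `delta` (subjects x
#'   parcels), `subjects` (data frame), `winsor_bounds` (NULL until
#'   [winsorize()]), `interval_adjusted` flag.
#' @export
compute_delta <- function(values, cohort) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(cohort)) stop("`values` rows must align with `cohort` rows", call. = FALSE)
  subj <- unique(cohort$subject_id)
  keep <- vapply(subj, function(s) sum(cohort$subject_id == s) >= 2L, logical(1))
  if (any(!keep)) {
    message(sprintf("dropping %d subject(s) with a single session", sum(!keep)))
  }
  subj <- subj[keep]
  delta <- matrix(NA_real_, length(subj), ncol(values),
                  dimnames = list(as.character(subj), colnames(values)))
  tab <- data.frame(subject_id = subj, age_first = NA_real_, age_last = NA_real_,
                    delta_age = NA_real_, mean_age = NA_real_,
                    sex = NA, site = NA, stringsAsFactors = FALSE)
  for (i in seq_along(subj)) {
    rows <- which(cohort$subject_id == subj[i])
    rows <- rows[order(cohort$session_id[rows])]
    first <- rows[1L]; last <- rows[length(rows)]
    delta[i, ] <- values[last, ] - values[first, ]
    tab$age_first[i] <- cohort$age[first]
    tab$age_last[i] <- cohort$age[last]
    tab$delta_age[i] <- cohort$age[last] - cohort$age[first]
    tab$mean_age[i] <- (cohort$age[first] + cohort$age[last]) / 2
    if (!is.null(cohort$sex)) tab$sex[i] <- cohort$sex[first]
    if (!is.null(cohort$site)) tab$site[i] <- cohort$site[first]
  }
  structure(list(delta = delta, subjects = tab, winsor_bounds = NULL,
                 interval_adjusted = FALSE),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf("<change_map> %d subjects x %d parcels%s%s\n",
              nrow(x$delta), ncol(x$delta),
              if (!is.null(x$winsor_bounds)) ", winsorized" else "",
              if (isTRUE(x$interval_adjusted)) ", interval-adjusted" else ""))
  invisible(x)
}

#' Winsorize a change map
#'
#' Per parcel, values are clipped to mean +/- k * SD, with moments computed
#' before clipping. Zero-variance parcels pass through.
#'
#' @param delta a `change_map` or subjects x parcels matrix.
#' @param k SD multiple (default 3).
#' @return same type as input; a `change_map` gains `winsor_bounds`.
#' @export
winsorize <- function(delta, k = 3) {
  is_cm <- inherits(delta, "change_map")
  m <- if (is_cm) delta$delta else as.matrix(delta)
  if (nrow(m) < 3L) stop("need at least 3 subjects to winsorize", call. = FALSE)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  lo <- mu - k * sdv
  hi <- mu + k * sdv
  out <- m
  for (j in seq_len(ncol(m))) {
    if (!is.finite(sdv[j]) || sdv[j] < 1e-14) next
    out[, j] <- pmin(pmax(m[, j], lo[j]), hi[j])
  }
  if (!is_cm) return(out)
  delta$delta <- out
  delta$winsor_bounds <- cbind(low = lo, high = hi)
  delta
}

#' Adjust change scores for inter-session interval
#'
#' Residualizes each column of the change matrix on the per-subject age
#' interval (delta age), removing the effect of variable time between
#' sessions. Behavioral and imaging visits have distinct intervals; pass
#' the appropriate `delta_age` for each data type.
#'
#' @param delta a `change_map`, matrix, or vector of change scores.
#' @param delta_age per-subject interval in years (> 0).
#' @return same type as input, interval-adjusted (residuals of the
#'   regression on delta age, i.e. centered).
#' @export
adjust_interval <- function(delta, delta_age) {
  vec <- is.null(dim(delta)) && !inherits(delta, "change_map")
  is_cm <- inherits(delta, "change_map")
  m <- if (is_cm) delta$delta else as.matrix(delta)
  if (length(delta_age) != nrow(m)) stop("`delta_age` must match subjects", call. = FALSE)
  if (any(delta_age <= 0)) stop("intervals must be positive", call. = FALSE)
  if (stats::var(delta_age) < 1e-14) {
    warning("constant interval: change scores only centered")
    out <- sweep(m, 2L, colMeans(m))
  } else {
    X <- cbind(1, delta_age)
    out <- m - X %*% qr.coef(qr(X), m)
  }
  if (vec) return(drop(out))
  if (!is_cm) return(out)
  delta$delta <- out
  delta$interval_adjusted <- TRUE
  delta
}

## Design matrix for the per-parcel change GLM:
## [1, delta_res, mean_res, mean_age, sex(0/1), site dummies]
glm_design <- function(delta_res, mean_res, subjects) {
  n <- length(delta_res)
  sex01 <- as.numeric(subjects$sex == 2)
  site <- factor(subjects$site)
  X <- cbind(intercept = 1, delta_res = delta_res, mean_res = mean_res,
             mean_age = subjects$mean_age, sex = sex01)
  if (nlevels(site) > 1L) {
    S <- stats::model.matrix(~ site)[, -1L, drop = FALSE]
    colnames(S) <- paste0("site", levels(site)[-1L])
    X <- cbind(X, S)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient GLM design (collinear covariates)", call. = FALSE)
  }
  if (n <= ncol(X)) stop("more design columns than subjects", call. = FALSE)
  X
}

#' Per-parcel change GLM
#'
#' Fits, for every parcel, the ordinary least squares model
#' `delta ~ 1 + delta_res + mean_res + mean_age + sex + site`
#' and returns the coefficient, t statistic and parametric p-value for the
#' change-in-resilience (`delta_res`) term, plus the standardized
#' coefficient obtained by z-scoring the response and `delta_res` before
#' refitting. With 3 sites the design has 7 columns, so df = n - 7
#' (n = 141 gives t with 134 df).
#'
#' @param delta a `change_map` or subjects x parcels matrix (interval
#'   adjustment and winsorization are the caller's responsibility; see
#'   [winsorize()], [adjust_interval()]).
#' @param delta_res per-subject change in resilient functioning.
#' @param mean_res per-subject mean resilient functioning.
#' @param subjects data frame with `mean_age`, `sex` (1/2), `site`.
#' @return object of class `parcel_glm`: data frame `table` (parcel, beta,
#'   beta_std, t, p_param), plus `df`, `design` and residual info.
#' @export
fit_parcel_glm <- function(delta, delta_res, mean_res, subjects) {
  m <- if (inherits(delta, "change_map")) delta$delta else as.matrix(delta)
  X <- glm_design(delta_res, mean_res, subjects)
  n <- nrow(X); p <- ncol(X); df <- n - p
  qrX <- qr(X)
  coefs <- qr.coef(qrX, m)
  resid <- m - X %*% coefs
  rss <- colSums(resid^2)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(rss / df * XtXinv[2, 2])
  beta <- coefs[2, ]
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  ## standardized coefficient: z-score response and delta_res, refit
  Xs <- X
  Xs[, 2] <- as.numeric(scale(X[, 2]))
  ms <- scale(m)
  ms[, attr(ms, "scaled:scale") < 1e-14] <- 0
  coefs_s <- qr.coef(qr(Xs), ms)
  beta_std <- coefs_s[2, ]
  tab <- data.frame(parcel = colnames(m) %||% as.character(seq_len(ncol(m))),
                    beta = beta, beta_std = beta_std, t = tval, p_param = pval,
                    row.names = NULL)
  structure(list(table = tab, df = df, n = n, design = X), class = "parcel_glm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.parcel_glm <- function(x, ...) {
  cat(sprintf("<parcel_glm> %d parcels, df = %d\n", nrow(x$table), x$df))
  cat(sprintf("  |t| range: %.2f .. %.2f\n", min(abs(x$table$t)), max(abs(x$table$t))))
  invisible(x)
}

#' Permutation inference for the change GLM
#'
#' Permutes the (delta_res, mean_res) pair jointly across subjects while
#' holding the remaining covariates fixed, refits the GLM, and returns a
#' two-sided permutation p-value per parcel:
#' p = (1 + #\{|t_perm| >= |t_obs|\}) / (n_perm + 1).
#'
#' Implementation uses Frisch-Waugh residualization on the fixed
#' covariates, so each permutation costs two small regressions rather than
#' a full refit; the resulting t statistics are identical to the full
#' model's.
#'
#' @inheritParams fit_parcel_glm
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `p_perm` (per parcel), `t_obs`, `n_perm`.
#' @export
permute_glm <- function(delta, delta_res, mean_res, subjects,
                        n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop("use at least 100 permutations", call. = FALSE)
  m <- if (inherits(delta, "change_map")) delta$delta else as.matrix(delta)
  X <- glm_design(delta_res, mean_res, subjects)
  n <- nrow(X); p_full <- ncol(X); df <- n - p_full
  C <- X[, -c(2L, 3L), drop = FALSE]           # fixed covariates incl. intercept
  qrC <- qr(C)
  Yr <- m - C %*% qr.coef(qrC, m)              # residualized responses (fixed)
  Z0 <- cbind(delta_res, mean_res)
  tstat_fw <- function(Z) {
    Zr <- Z - C %*% qr.coef(qrC, Z)
    A <- crossprod(Zr)                          # 2 x 2
    Ai <- solve(A)
    B <- crossprod(Zr, Yr)                      # 2 x P
    bh <- Ai %*% B
    rss <- colSums(Yr^2) - colSums(B * bh)
    se <- sqrt(pmax(rss, 0) / df * Ai[1, 1])
    unname(bh[1, ] / pmax(se, 1e-300))
  }
  t_obs <- tstat_fw(Z0)
  count <- numeric(ncol(m))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      t_b <- tstat_fw(Z0[idx, , drop = FALSE])
      count <- count + (abs(t_b) >= abs(t_obs))
    }
  })
  list(p_perm = (1 + count) / (n_perm + 1), t_obs = t_obs, n_perm = n_perm)
}

#' Depth-resolved change GLM within an ROI
#'
#' Refits the per-parcel change GLM at each cortical depth separately
#' (rather than on the depth-averaged profile), restricted to an ROI -
#' typically the significant parcels of the depth-averaged analysis. The
#' same preprocessing (winsorization, interval adjustment) is applied per
#' depth.
#'
#' @param mt_depth sessions x parcels x depths array.
#' @param cohort session-level cohort table (see [compute_delta()]).
#' @param roi parcel indices defining the ROI.
#' @param delta_res,mean_res per-subject scores, aligned with the subjects
#'   that [compute_delta()] retains.
#' @param winsor_k winsorization SD multiple (default 3).
#' @param adjust logical: interval-adjust the per-depth deltas.
#' @return matrix of t statistics, ROI parcels x depths.
#' @export
depthwise_glm <- function(mt_depth, cohort, roi, delta_res, mean_res,
                          winsor_k = 3, adjust = TRUE) {
  roi <- normalize_roi(roi, dim(mt_depth)[2])
  nd <- dim(mt_depth)[3]
  out <- matrix(NA_real_, length(roi), nd,
                dimnames = list(paste0("parcel", roi), paste0("depth", seq_len(nd))))
  for (d in seq_len(nd)) {
    cm <- compute_delta(mt_depth[, , d][, roi, drop = FALSE], cohort)
    cm <- winsorize(cm, winsor_k)
    if (adjust) cm <- adjust_interval(cm, cm$subjects$delta_age)
    fit <- fit_parcel_glm(cm, delta_res, mean_res, cm$subjects)
    out[, d] <- fit$table$t
  }
  out
}

#' Stratify a parcel map by atlas labels
#'
#' Summarizes a per-parcel statistic within categories of an atlas
#' (cortical types, functional networks). For a significance mask, also
#' reports each category's share of significant parcels. Unlabeled parcels
#' fall into an "unknown" category with a warning.
#'
#' @param values per-parcel statistic (e.g. unthresholded t map).
#' @param labels per-parcel category labels.
#' @param mask optional logical significance mask.
#' @return data frame with per-category n, mean, sd, median and (if `mask`
#'   given) `n_sig` and `share_sig` (percent of significant parcels in the
#'   category; shares sum to 100).
#' @export
stratify_map <- function(values, labels, mask = NULL) {
  if (length(values) != length(labels)) stop("one label per parcel required", call. = FALSE)
  labels <- as.character(labels)
  if (anyNA(labels)) {
    warning("unlabeled parcels assigned to category 'unknown'")
    labels[is.na(labels)] <- "unknown"
  }
  cats <- sort(unique(labels))
  out <- data.frame(category = cats,
                    n = as.integer(table(factor(labels, cats))),
                    mean = tapply(values, factor(labels, cats), mean),
                    sd = tapply(values, factor(labels, cats), stats::sd),
                    median = tapply(values, factor(labels, cats), stats::median),
                    row.names = NULL)
  if (!is.null(mask)) {
    nsig <- tapply(mask, factor(labels, cats), sum)
    out$n_sig <- as.integer(nsig)
    tot <- sum(mask)
    out$share_sig <- if (tot > 0) 100 * out$n_sig / tot else 0
  }
  out
}
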