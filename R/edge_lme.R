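## Edge-wise random-intercept mixed models.
##
## Model per edge:  y = X beta + b_subject + e,  b ~ N(0, sb^2), e ~ N(0, se^2).
## All edges share the design X = [1, age, sex, site dummies] and the subject
## grouping, so the REML problem is profiled to a single variance ratio
## theta = sb^2 / se^2 per edge and solved on a shared theta grid with all
## edges vectorized. The data are rotated subject-block-wise into "between"
## rows (subject means, scaled) and "within" rows (Helmert contrasts); in
## that basis the covariance is diagonal with weights 1/(1 + theta * n_i)
## for a between row of a subject with n_i sessions and 1 for within rows.

## Rotate rows subject-wise; returns rotated X, Y and the d value per row
## (d = n_i for between rows, 0 for within rows) plus the subject of origin.
rotate_by_subject <- function(X, Y, subject) {
  subject <- as.character(subject)
  subj <- unique(subject)
  n <- nrow(X)
  Xr <- matrix(0, n, ncol(X), dimnames = list(NULL, colnames(X)))
  Yr <- matrix(0, n, ncol(Y))
  dval <- numeric(n)
  sub_of <- character(n)
  row <- 0L
  for (s in subj) {
    idx <- which(subject == s)
    ni <- length(idx)
    ## between (mean) row
    row <- row + 1L
    Xr[row, ] <- colSums(X[idx, , drop = FALSE]) / sqrt(ni)
    Yr[row, ] <- colSums(Y[idx, , drop = FALSE]) / sqrt(ni)
    dval[row] <- ni
    sub_of[row] <- s
    ## within rows: Helmert contrasts
    if (ni > 1L) {
      for (k in 2:ni) {
        row <- row + 1L
        w <- c(rep(1, k - 1L), -(k - 1L), rep(0, ni - k)) / sqrt(k * (k - 1L))
        Xr[row, ] <- crossprod(w, X[idx, , drop = FALSE])
        Yr[row, ] <- crossprod(w, Y[idx, , drop = FALSE])
        dval[row] <- 0
        sub_of[row] <- s
      }
    }
  }
  list(X = Xr, Y = Yr, d = dval, subject = sub_of)
}

## Sufficient statistics per subject and stratum (d value), enabling both
## full-sample fits and fast per-group refits under permutation.
lme_suffstats <- function(X, Y, subject) {
  rot <- rotate_by_subject(X, Y, subject)
  p <- ncol(X); E <- ncol(Y)
  subj <- unique(as.character(subject))
  q <- length(subj)
  dvals <- sort(unique(rot$d))          # 0 = within, then session counts
  per <- lapply(dvals, function(dv) {
    A <- matrix(0, q, p * p); B <- matrix(0, q, p * E)
    cc <- matrix(0, q, E); nr <- integer(q)
    for (i in seq_len(q)) {
      rows <- which(rot$subject == subj[i] & rot$d == dv)
      if (length(rows) == 0L) next
      Xs <- rot$X[rows, , drop = FALSE]; Ys <- rot$Y[rows, , drop = FALSE]
      A[i, ] <- as.numeric(crossprod(Xs))
      B[i, ] <- as.numeric(crossprod(Xs, Ys))
      cc[i, ] <- colSums(Ys^2)
      nr[i] <- length(rows)
    }
    list(A = A, B = B, c = cc, nrow = nr)
  })
  names(per) <- as.character(dvals)
  list(per = per, dvals = dvals, subjects = subj, p = p, E = E)
}

## Aggregate per-subject stats over a subject subset.
aggregate_stats <- function(ss, which_subj = NULL) {
  sel <- if (is.null(which_subj)) rep(TRUE, length(ss$subjects))
         else ss$subjects %in% which_subj
  w <- as.numeric(sel)
  lapply(ss$per, function(st) {
    list(A = matrix(crossprod(w, st$A), ss$p, ss$p),
         B = matrix(crossprod(w, st$B), ss$p, ss$E),
         c = as.numeric(crossprod(w, st$c)),
         nrow = sum(st$nrow[sel]))
  })
}

## Profiled REML criterion over a shared theta grid, vectorized over edges.
## agg: aggregated stats (one entry per d value); returns the grid index of
## the per-edge minimum plus criterion pieces for optional refinement.
reml_grid <- function(agg, dvals, p, theta_grid, keep = NULL, track_beta = FALSE) {
  n <- sum(vapply(agg, function(a) a$nrow, numeric(1)))
  E <- length(agg[[1]]$c)
  if (is.null(keep)) keep <- seq_len(p)
  best_crit <- rep(Inf, E); best_idx <- rep(NA_integer_, E)
  crits <- matrix(NA_real_, length(theta_grid), E)
  best_beta <- if (track_beta) matrix(NA_real_, length(keep), E) else NULL
  for (g in seq_along(theta_grid)) {
    th <- theta_grid[g]
    fit <- gls_at_theta(agg, dvals, th, keep)
    if (is.null(fit)) next
    crit <- (n - length(keep)) * log(pmax(fit$rss, 1e-300)) + fit$logpen + fit$logdet
    crits[g, ] <- crit
    upd <- crit < best_crit
    best_crit[upd] <- crit[upd]
    best_idx[upd] <- g
    if (track_beta && any(upd)) best_beta[, upd] <- fit$beta[, upd, drop = FALSE]
  }
  list(idx = best_idx, crits = crits, n = n, beta = best_beta, keep = keep)
}

## Weighted GLS solve at one theta for all edges; keep = retained columns.
gls_at_theta <- function(agg, dvals, th, keep) {
  p0 <- nrow(agg[[1]]$A)
  XWX <- matrix(0, p0, p0); XWY <- NULL; yy <- 0; logpen <- 0
  for (k in seq_along(dvals)) {
    dv <- dvals[k]; a <- agg[[k]]
    w <- 1 / (1 + th * dv)
    XWX <- XWX + w * a$A
    XWY <- if (is.null(XWY)) w * a$B else XWY + w * a$B
    yy <- yy + w * a$c
    if (dv > 0) logpen <- logpen + a$nrow * log(1 + th * dv)
  }
  XWX <- XWX[keep, keep, drop = FALSE]
  XWY <- XWY[keep, , drop = FALSE]
  ch <- tryCatch(chol(XWX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), XWY))
  rss <- yy - colSums(XWY * beta)
  list(beta = beta, rss = pmax(rss, 0), logdet = 2 * sum(log(diag(ch))),
       logpen = logpen, chol = ch)
}

## Columns estimable within a subject subset: drop dummies with no
## variation (rank check on X'X at theta = 0).
estimable_columns <- function(agg, dvals, p) {
  XtX <- Reduce(`+`, lapply(agg, function(a) a$A))
  qrx <- qr(XtX)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  keep
}

#' Edge-wise linear mixed-effects age model
#'
#' Fits, to every included edge of a session-wise stack of symmetric
#' parcel matrices, the random-intercept model
#' `edge ~ 1 + age + sex + site + (1 | subject)`.
#' The default engine is a vectorized REML solver that profiles the
#' subject-intercept variance ratio on a log-spaced grid (with local
#' quadratic refinement), exact for this model class and orders of
#' magnitude faster than per-edge generic fits; `engine = "lmer"` fits
#' each edge with \pkg{lme4} instead (identical up to optimizer
#' tolerance; used as a cross-check).
#'
#' @param matrices list of P x P symmetric matrices (or `parcel_matrix`
#'   objects), one per session, aligned with `cohort` rows.
#' @param cohort session-level data frame: `subject_id`, `age`, `sex`
#'   (1/2), `site`.
#' @param engine `"grid"` (default) or `"lmer"`.
#' @param theta_grid variance-ratio grid for the fast engine.
#' @param refine logical: quadratically refine theta per edge.
#' @return object of class `edge_lme`: per-edge coefficient table,
#'   `baseline14` and `change` P x P matrices (see
#'   [predict_baseline14()]; change = age coefficient), variance
#'   components, and bookkeeping (`edges`, `excluded`, `df`).
#' @export
fit_edge_lme <- function(matrices, cohort,
                         engine = c("grid", "lmer"),
                         theta_grid = exp(seq(log(1e-4), log(1e4), length.out = 49)),
                         refine = TRUE) {
  engine <- match.arg(engine)
  es <- edge_stack(matrices)
  Y <- es$Y
  ## random intercept identifiable only with repeated measures
  ns <- table(cohort$subject_id)
  if (all(ns < 2L)) {
    stop("all subjects have a single session: random intercept unidentifiable; use OLS instead",
         call. = FALSE)
  }
  if (mean(ns >= 2L) < 0.5) {
    warning("fewer than half the subjects have repeated sessions")
  }
  X <- lme_design(cohort)
  p <- ncol(X)

  if (engine == "lmer") {
    fit <- fit_edge_lmer(Y, X, cohort)
  } else {
    ss <- lme_suffstats(X, Y, cohort$subject_id)
    agg <- aggregate_stats(ss)
    gr <- reml_grid(agg, ss$dvals, p, theta_grid)
    theta <- theta_grid[gr$idx]
    boundary <- gr$idx %in% c(1L, length(theta_grid))
    if (refine) {
      lg <- log(theta_grid)
      for (e in seq_len(ncol(Y))) {
        k <- gr$idx[e]
        if (is.na(k) || k <= 1L || k >= length(theta_grid)) next
        ys <- gr$crits[(k - 1):(k + 1), e]
        xs <- lg[(k - 1):(k + 1)]
        den <- (xs[2] - xs[1]) * (ys[2] - ys[3]) - (xs[2] - xs[3]) * (ys[2] - ys[1])
        if (abs(den) < 1e-12) next
        num <- (xs[2] - xs[1])^2 * (ys[2] - ys[3]) - (xs[2] - xs[3])^2 * (ys[2] - ys[1])
        theta[e] <- exp(xs[2] - 0.5 * num / den)
      }
    }
    fit <- finalize_edges(agg, ss$dvals, theta, p, gr$n)
    fit$boundary <- boundary
  }
  rownames(fit$beta) <- colnames(X)
  rownames(fit$se) <- colnames(X)

  P <- es$P
  base <- coef_to_matrix(edge_baseline14(fit$beta, colnames(X)), es, P)
  change <- coef_to_matrix(fit$beta["age", ], es, P)
  structure(list(beta = fit$beta, se = fit$se, sigma_e = sqrt(fit$sigma_e2),
                 sigma_b = sqrt(fit$sigma_b2), theta = fit$theta,
                 boundary = fit$boundary %||% rep(FALSE, ncol(Y)),
                 baseline14 = base, change = change,
                 edges = es$edges, excluded = es$excluded,
                 design_cols = colnames(X), n = nrow(Y), engine = engine),
            class = "edge_lme")
}

## per-edge final estimates at the chosen theta
finalize_edges <- function(agg, dvals, theta, p, n) {
  E <- length(theta)
  beta <- matrix(NA_real_, p, E)
  se <- matrix(NA_real_, p, E)
  s2 <- numeric(E)
  groups <- split(seq_len(E), factor(signif(theta, 10)))
  for (g in groups) {
    th <- theta[g[1]]
    f <- gls_at_theta(agg, dvals, th, seq_len(p))
    if (is.null(f)) next
    beta[, g] <- f$beta[, g, drop = FALSE]
    sig2 <- f$rss[g] / (n - p)
    s2[g] <- sig2
    Vi <- chol2inv(f$chol)
    se[, g] <- sqrt(outer(diag(Vi), sig2))
  }
  list(beta = beta, se = se, sigma_e2 = s2, sigma_b2 = theta * s2, theta = theta)
}

lme_design <- function(cohort) {
  sex01 <- as.numeric(cohort$sex == 2)
  site <- factor(cohort$site)
  X <- cbind(intercept = 1, age = cohort$age, sex = sex01)
  if (nlevels(site) > 1L) {
    S <- stats::model.matrix(~ site)[, -1L, drop = FALSE]
    colnames(S) <- paste0("site", levels(site)[-1L])
    X <- cbind(X, S)
  }
  rownames(X) <- NULL
  X
}

## stack edge values: upper triangle over parcels included in every session
edge_stack <- function(matrices) {
  first <- extract_values(matrices[[1]])
  P <- nrow(first)
  excluded <- rep(FALSE, P)
  vals <- lapply(matrices, function(m) {
    mm <- extract_values(m)
    excluded <<- excluded | attr(mm, "excluded") | apply(mm, 1L, function(r) all(!is.finite(r) | is.na(r)))
    mm
  })
  inc <- which(!excluded)
  ut <- which(upper.tri(first), arr.ind = TRUE)
  ut <- ut[ut[, 1] %in% inc & ut[, 2] %in% inc, , drop = FALSE]
  Y <- t(vapply(vals, function(m) m[ut], numeric(nrow(ut))))
  if (any(!is.finite(Y))) stop("non-finite edge values among included parcels", call. = FALSE)
  list(Y = Y, edges = ut, P = P, excluded = excluded)
}

coef_to_matrix <- function(v, es, P) {
  out <- matrix(NA_real_, P, P)
  out[es$edges] <- v
  out[es$edges[, c(2, 1), drop = FALSE]] <- v
  diag(out) <- 0
  diag(out)[es$excluded] <- NA_real_
  out
}

## demographically marginalized baseline at age 14: intercept + 14*b_age +
## b_sex/2 + mean over site dummies (1/n_sites each).
edge_baseline14 <- function(beta, cols, age = 14) {
  b <- beta
  rownames(b) <- cols
  out <- b["intercept", ] + age * b["age", ] + 0.5 * b["sex", ]
  site_rows <- grep("^site", cols, value = TRUE)
  if (length(site_rows)) {
    n_sites <- length(site_rows) + 1L
    out <- out + colSums(b[site_rows, , drop = FALSE]) / n_sites
  }
  out
}

#' Predicted baseline connectivity at age 14
#'
#' Evaluates the fitted edge model at age 14 with demographic covariates
#' marginalized: sex at 1/2 (balanced 0/1 coding) and each site indicator
#' at 1/number-of-sites, i.e. the model prediction for a demographically
#' balanced 14-year-old. Returned by [fit_edge_lme()] as `baseline14`;
#' exposed separately for custom ages.
#'
#' @param fit an `edge_lme` object.
#' @param age baseline age (default 14).
#' @return P x P symmetric matrix.
#' @export
predict_baseline14 <- function(fit, age = 14) {
  stopifnot(inherits(fit, "edge_lme"))
  v <- edge_baseline14(fit$beta, fit$design_cols, age)
  es <- list(edges = fit$edges, excluded = fit$excluded)
  coef_to_matrix(v, es, nrow(fit$baseline14))
}

#' @export
print.edge_lme <- function(x, ...) {
  cat(sprintf("<edge_lme> %d edges over %d parcels (%d excluded), n = %d sessions, engine = %s\n",
              ncol(x$beta), nrow(x$baseline14), sum(x$excluded), x$n, x$engine))
  invisible(x)
}

## reference engine: per-edge lme4 fit (slow; used for validation)
fit_edge_lmer <- function(Y, X, cohort) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("engine 'lmer' requires the lme4 package", call. = FALSE)
  }
  E <- ncol(Y); p <- ncol(X)
  beta <- matrix(NA_real_, p, E); se <- matrix(NA_real_, p, E)
  s2e <- numeric(E); s2b <- numeric(E); conv <- logical(E)
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$subject <- factor(cohort$subject_id)
  rhs <- paste(c(setdiff(colnames(df), "subject"), "(1 | subject)"), collapse = " + ")
  for (e in seq_len(E)) {
    df$y <- Y[, e]
    m <- tryCatch(
      lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(err) NULL)
    if (is.null(m)) { conv[e] <- FALSE; next }
    conv[e] <- TRUE
    beta[, e] <- lme4::fixef(m)
    se[, e] <- sqrt(diag(as.matrix(stats::vcov(m))))
    vc <- as.data.frame(lme4::VarCorr(m))
    s2b[e] <- vc$vcov[vc$grp == "subject"]
    s2e[e] <- vc$vcov[vc$grp == "Residual"]
  }
  rownames(beta) <- colnames(X)
  list(beta = beta, se = se, sigma_e2 = s2e, sigma_b2 = s2b,
       theta = s2b / pmax(s2e, 1e-300), boundary = !conv)
}
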