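#' Fit the single-factor distress model
#'
#' Maximum-likelihood single-factor analysis of the questionnaire items
#' (no rotation, which is undefined for one factor). Loadings are oriented
#' so that the majority of symptom items load positively; reverse-keyed
#' well-being/self-esteem items are then expected to load negatively.
#' Missing item handling: sessions missing more than `max_missing` of
#' items are dropped, remaining gaps are mean-imputed.
#'
#' @param items sessions x items matrix or data frame.
#' @param symptom_items indices (or names) of items keyed in the symptom
#'   direction; default: all items.
#' @param max_missing maximum tolerated per-session missing-item fraction
#'   (default 0.2).
#' @return object of class `distress_model`: `loadings` (per item, on the
#'   standardized scale), `center`/`scale` (per-item standardization),
#'   `fit_stat` (chi-square statistic, df, p), `n_fit`.
#' @export
fit_distress_factor <- function(items, symptom_items = NULL, max_missing = 0.2) {
  items <- as.matrix(items)
  if (ncol(items) < 3L) stop("need at least 3 items for a factor model", call. = FALSE)
  if (is.null(colnames(items))) colnames(items) <- paste0("item", seq_len(ncol(items)))
  miss_frac <- rowMeans(is.na(items))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    message(sprintf("dropping %d session(s) with > %.0f%% missing items",
                    sum(drop), 100 * max_missing))
    items <- items[!drop, , drop = FALSE]
  }
  for (j in seq_len(ncol(items))) {
    nas <- is.na(items[, j])
    if (any(nas)) items[nas, j] <- mean(items[, j], na.rm = TRUE)
  }
  const <- apply(items, 2L, stats::sd) < 1e-12
  if (any(const)) {
    stop(sprintf("constant item(s): %s", paste(colnames(items)[const], collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(items) < 10L * ncol(items)) {
    warning("fewer than 10 sessions per item; loadings may be unstable")
  }
  R <- stats::cor(items)
  if (rcond(R) < 1e-12) stop("singular item covariance: factorization failed", call. = FALSE)
  fa <- tryCatch(
    stats::factanal(covmat = R, factors = 1L, n.obs = nrow(items), rotation = "none"),
    error = function(e) stop("factorization failed: ", conditionMessage(e), call. = FALSE))
  lam <- as.numeric(fa$loadings)
  names(lam) <- colnames(items)
  if (is.null(symptom_items)) symptom_items <- seq_len(ncol(items))
  if (is.character(symptom_items)) symptom_items <- match(symptom_items, colnames(items))
  if (stats::median(sign(lam[symptom_items])) < 0) lam <- -lam
  structure(list(loadings = lam,
                 center = colMeans(items),
                 scale = apply(items, 2L, stats::sd),
                 fit_stat = list(chisq = unname(fa$STATISTIC),
                                 df = unname(fa$dof), p = unname(fa$PVAL)),
                 n_fit = nrow(items)),
            class = "distress_model")
}

#' @export
print.distress_model <- function(x, ...) {
  cat(sprintf("<distress_model> %d items, fitted on %d sessions\n",
              length(x$loadings), x$n_fit))
  if (!is.null(x$fit_stat$chisq)) {
    cat(sprintf("  chi-square(%d) = %.2f, p = %.3g\n",
                x$fit_stat$df, x$fit_stat$chisq, x$fit_stat$p))
  }
  invisible(x)
}

#' Score sessions on the distress factor
#'
#' The distress score is the loading-weighted sum of item scores,
#' score_t = sum_j lambda_j * y_jt. By default items are standardized
#' with the centering/scaling stored in the model (the scale the loadings
#' were estimated on); set `standardize = FALSE` to weight raw item
#' values.
#'
#' @param items sessions x items matrix; columns must match the model.
#' @param model a `distress_model`.
#' @param standardize standardize items with the model's center/scale.
#' @return numeric per-session distress score.
#' @export
score_distress <- function(items, model, standardize = TRUE) {
  items <- as.matrix(items)
  if (is.null(colnames(items))) colnames(items) <- paste0("item", seq_len(ncol(items)))
  unknown <- setdiff(colnames(items), names(model$loadings))
  if (length(unknown)) {
    stop(sprintf("unknown item column(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  items <- items[, names(model$loadings), drop = FALSE]
  for (j in seq_len(ncol(items))) {
    nas <- is.na(items[, j])
    if (any(nas)) items[nas, j] <- model$center[j]
  }
  if (standardize) {
    items <- sweep(sweep(items, 2L, model$center), 2L, pmax(model$scale, 1e-12), `/`)
  }
  drop(items %*% model$loadings)
}

#' Default random-forest hyperparameter grid
#'
#' Number of trees in \{50, ..., 300\} and maximum depth 5 to 15.
#' @return data frame with columns `num_trees`, `max_depth`.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = seq(50L, 300L, by = 50L), max_depth = 5:15)
}

#' Predict distress from adversity with nested cross-validation
#'
#' Random-forest regression of the distress score on adversity features
#' with leakage-guarded nested cross-validation: the outer loop leaves all
#' sessions of one subject out; the inner loop is 5-fold grouped by
#' subject on the remaining data; features are standardized inside each
#' training fold only; hyperparameters are chosen by minimal inner mean
#' absolute error; out-of-fold predictions are returned for every session.
#'
#' @param adversity sessions x features matrix.
#' @param distress per-session distress score.
#' @param cohort session-level data frame with `subject_id`.
#' @param grid hyperparameter grid (see [default_rf_grid()]); a reduced
#'   grid speeds exploratory runs.
#' @param seed RNG seed (forests are seeded per outer fold).
#' @param inner_folds inner fold count (default 5).
#' @param num_threads threads passed to \pkg{ranger} (default 1 for
#'   reproducibility).
#' @return object of class `distress_prediction`: `predicted`
#'   (per-session out-of-fold), `report` (r2, mae, r_true_pred,
#'   chosen hyperparameters per outer fold), `fold_audit` (data frame
#'   proving no subject is split across train/test).
#' @export
predict_distress_nested_cv <- function(adversity, distress, cohort,
                                       grid = default_rf_grid(), seed = 1L,
                                       inner_folds = 5L, num_threads = 1L) {
  adversity <- as.matrix(adversity)
  if (any(!is.finite(adversity))) stop("non-finite adversity feature", call. = FALSE)
  if (nrow(adversity) != length(distress) || nrow(adversity) != nrow(cohort)) {
    stop("adversity, distress and cohort must align by session", call. = FALSE)
  }
  if (nrow(grid) < 1L) stop("empty hyperparameter grid", call. = FALSE)
  subj <- unique(as.character(cohort$subject_id))
  if (length(subj) < 10L) stop("need at least 10 subjects", call. = FALSE)
  if (length(subj) <= inner_folds) stop("fewer subjects than inner folds", call. = FALSE)
  if (is.null(colnames(adversity))) colnames(adversity) <- paste0("x", seq_len(ncol(adversity)))

  predicted <- rep(NA_real_, length(distress))
  chosen <- vector("list", length(subj))
  audit <- data.frame(subject = subj, n_test = NA_integer_, leaked = NA)

  rf_fit_predict <- function(xtr, ytr, xte, num_trees, max_depth, fold_seed) {
    mu <- colMeans(xtr); sdv <- pmax(apply(xtr, 2L, stats::sd), 1e-12)
    ztr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, `/`)
    zte <- sweep(sweep(xte, 2L, mu), 2L, sdv, `/`)
    ## mtry = all features, the scikit-learn regression-forest default
    fit <- ranger::ranger(x = ztr, y = ytr, num.trees = num_trees,
                          max.depth = max_depth, mtry = ncol(ztr),
                          seed = fold_seed,
                          num.threads = num_threads, verbose = FALSE)
    stats::predict(fit, data = as.data.frame(zte))$predictions
  }

  with_seed(seed, {
    for (k in seq_along(subj)) {
      test <- which(cohort$subject_id == subj[k])
      train <- setdiff(seq_along(distress), test)
      tr_subj <- as.character(cohort$subject_id[train])
      fold_of <- make_grouped_folds(tr_subj, inner_folds)
      ## inner grid search by MAE (skipped for a single candidate)
      mae <- numeric(nrow(grid))
      if (nrow(grid) > 1L) for (g in seq_len(nrow(grid))) {
        err <- 0; cnt <- 0
        for (f in seq_len(inner_folds)) {
          va <- train[fold_of == f]
          tr <- train[fold_of != f]
          pr <- rf_fit_predict(adversity[tr, , drop = FALSE], distress[tr],
                               adversity[va, , drop = FALSE],
                               grid$num_trees[g], grid$max_depth[g],
                               fold_seed = child_seed(seed, k * 131L + g * 7L + f))
          err <- err + sum(abs(pr - distress[va])); cnt <- cnt + length(va)
        }
        mae[g] <- err / cnt
      }
      best <- which.min(mae)
      chosen[[k]] <- data.frame(subject = subj[k],
                                num_trees = grid$num_trees[best],
                                max_depth = grid$max_depth[best],
                                inner_mae = mae[best])
      predicted[test] <- rf_fit_predict(adversity[train, , drop = FALSE],
                                        distress[train],
                                        adversity[test, , drop = FALSE],
                                        grid$num_trees[best], grid$max_depth[best],
                                        fold_seed = child_seed(seed, k))
      audit$n_test[k] <- length(test)
      audit$leaked[k] <- any(cohort$subject_id[train] == subj[k])
    }
  })

  ss_res <- sum((distress - predicted)^2)
  ss_tot <- sum((distress - mean(distress))^2)
  report <- list(r2 = 1 - ss_res / ss_tot,
                 mae = mean(abs(distress - predicted)),
                 r_true_pred = stats::cor(distress, predicted),
                 chosen_hyperparams = do.call(rbind, chosen))
  structure(list(predicted = predicted, report = report, fold_audit = audit),
            class = "distress_prediction")
}

#' @export
print.distress_prediction <- function(x, ...) {
  cat(sprintf("<distress_prediction> out-of-fold R2 = %.3f, MAE = %.3f, r(true, pred) = %.3f\n",
              x$report$r2, x$report$mae, x$report$r_true_pred))
  invisible(x)
}

## balanced grouped k-fold assignment: all sessions of a subject share a fold
make_grouped_folds <- function(subject, k) {
  subj <- unique(subject)
  fold_of_subj <- rep_len(seq_len(k), length(subj))[sample.int(length(subj))]
  fold_of_subj[match(subject, subj)]
}

#' Resilient psychosocial functioning scores
#'
#' Res_PSF = predicted - observed distress, so lower-than-expected
#' distress (resilient adaptation) is positive. Per subject, the change
#' score is last minus first session and the mean score the average of
#' first and last; both are NA (flagged, not an error) for subjects with
#' a single scored session.
#'
#' @param observed per-session observed distress.
#' @param predicted per-session model-predicted distress.
#' @param cohort session-level data frame with `subject_id`, `session_id`.
#' @return object of class `resilience_scores`: `sessions` data frame
#'   (subject_id, session_id, observed, predicted, res_psf) and
#'   `subjects` data frame (subject_id, delta_res, mean_res, n_sessions).
#' @export
compute_res_psf <- function(observed, predicted, cohort) {
  if (length(observed) != length(predicted) || length(observed) != nrow(cohort)) {
    stop("session keys must align", call. = FALSE)
  }
  res <- predicted - observed
  sessions <- data.frame(subject_id = cohort$subject_id,
                         session_id = cohort$session_id,
                         observed = observed, predicted = predicted,
                         res_psf = res, row.names = NULL)
  subj <- unique(cohort$subject_id)
  tab <- data.frame(subject_id = subj, delta_res = NA_real_,
                    mean_res = NA_real_, n_sessions = NA_integer_)
  for (i in seq_along(subj)) {
    rows <- which(cohort$subject_id == subj[i])
    rows <- rows[order(cohort$session_id[rows])]
    tab$n_sessions[i] <- length(rows)
    if (length(rows) >= 2L) {
      first <- res[rows[1L]]; last <- res[rows[length(rows)]]
      tab$delta_res[i] <- last - first
      tab$mean_res[i] <- (first + last) / 2
    }
  }
  structure(list(sessions = sessions, subjects = tab), class = "resilience_scores")
}

#' @export
print.resilience_scores <- function(x, ...) {
  cat(sprintf("<resilience_scores> %d sessions, %d subjects (%d with change scores)\n",
              nrow(x$sessions), nrow(x$subjects), sum(!is.na(x$subjects$delta_res))))
  invisible(x)
}
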