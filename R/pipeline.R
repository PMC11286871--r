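#' Pipeline run configuration
#'
#' Settings for [run_pipeline()]: output directory, master seed (every
#' stochastic stage derives its own child seed from it), simulation size,
#' permutation count, FDR level, stage toggles, and analysis knobs.
#'
#' @param out output directory.
#' @param seed master RNG seed.
#' @param n_subjects simulated subjects (ignored when `bundle_dir` given).
#' @param bundle_dir optional existing bundle directory to analyse
#'   instead of simulating.
#' @param generator overrides passed to [cohort_config()].
#' @param rf_grid random-forest hyperparameter grid.
#' @param n_perm permutations for GLM and group-comparison inference.
#' @param alpha FDR level.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "score", "mpc", "glm", "fc", "mi", "axis", "compare")`.
#' @param atlas_labels optional per-parcel labels for stratification.
#' @return config list of class `run_config`.
#' @export
run_config <- function(out = "adolmat_run", seed = 1L, n_subjects = 50L,
                       bundle_dir = NULL, generator = list(),
                       rf_grid = default_rf_grid(), n_perm = 1000L,
                       alpha = 0.05,
                       stages = c("simulate", "score", "mpc", "glm", "fc",
                                  "mi", "axis", "compare"),
                       atlas_labels = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(out = out, seed = as.integer(seed), n_subjects = n_subjects,
                 bundle_dir = bundle_dir, generator = generator,
                 rf_grid = rf_grid, n_perm = as.integer(n_perm), alpha = alpha,
                 stages = stages, atlas_labels = atlas_labels),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in analysis order - simulate (or load), resilience
#' scoring, CSF-corrected profiles + MPC, per-parcel change GLM with
#' permutation/FDR, seed-FC analysis, maturational indices for MPC and
#' FC, diffusion-map age axis, and the group comparison of maturational
#' indices - writing TSV outputs and a provenance manifest under
#' `config$out`. Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!"simulate" %in% config$stages && is.null(config$bundle_dir)) {
    stop("no bundle: enable 'simulate' or set bundle_dir", call. = FALSE)
  }
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  res <- list()
  manifest <- list(seed = config$seed, alpha = config$alpha,
                   n_perm = config$n_perm, stages = stages)

  ## ---- data -----------------------------------------------------------
  if ("simulate" %in% stages) {
    gen <- do.call(cohort_config, config$generator)
    bundle <- simulate_cohort(config$n_subjects, gen, seed = child_seed(config$seed, 1L))
    write_bundle(bundle, file.path(out, "bundle"))
  } else {
    if (is.null(config$bundle_dir)) stop("no bundle: enable 'simulate' or set bundle_dir", call. = FALSE)
    bundle <- read_bundle(config$bundle_dir)
  }
  res$bundle <- bundle
  cohort <- bundle$cohort
  manifest$n_sessions <- nrow(cohort)
  manifest$n_parcels <- dim(bundle$mt_depth)[2]

  ## ---- resilience scoring ----------------------------------------------
  if ("score" %in% stages) {
    message("stage score: latent distress factor + nested-CV prediction")
    nw <- if (!is.null(bundle$config$n_wellbeing_items)) bundle$config$n_wellbeing_items else 0L
    J <- ncol(bundle$items)
    symptom <- if (nw > 0) seq_len(J - nw) else seq_len(J)
    model <- fit_distress_factor(bundle$items, symptom_items = symptom)
    observed <- score_distress(bundle$items, model)
    pred <- predict_distress_nested_cv(bundle$adversity, observed, cohort,
                                       grid = config$rf_grid,
                                       seed = child_seed(config$seed, 2L))
    scores <- compute_res_psf(observed, pred$predicted, cohort)
    res$scores <- scores; res$prediction <- pred; res$distress_model <- model
    write_tsv(scores$sessions, file.path(out, "res_psf.tsv"))
    write_tsv(scores$subjects, file.path(out, "res_psf_subject.tsv"))
    jsonlite::write_json(pred$report[c("r2", "mae", "r_true_pred")],
                         file.path(out, "prediction_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## ---- profiles and MPC --------------------------------------------------
  if ("mpc" %in% stages) {
    message("stage mpc: CSF correction + profile covariance")
    mt_c <- csf_correct(bundle$mt_depth, bundle$csf_depth)
    res$mt_corrected <- mt_c
    res$mpc <- lapply(seq_len(nrow(cohort)), function(s) build_mpc(mt_c[s, , ]))
  }

  ## ---- per-parcel change GLM ----------------------------------------------
  if ("glm" %in% stages && !is.null(res$scores)) {
    message("stage glm: intra-individual change model")
    mt_parcel <- apply(if (!is.null(res$mt_corrected)) res$mt_corrected else bundle$mt_depth,
                       c(1, 2), mean)
    cm <- compute_delta(mt_parcel, cohort)
    cm <- winsorize(cm, 3)
    cm <- adjust_interval(cm, cm$subjects$delta_age)
    subj_tab <- res$scores$subjects
    keep <- match(cm$subjects$subject_id, subj_tab$subject_id)
    dres <- subj_tab$delta_res[keep]
    mres <- subj_tab$mean_res[keep]
    beh_cm <- compute_delta(matrix(0, nrow(cohort), 1),
                            transform_cohort_beh(cohort))
    dres_adj <- adjust_interval(dres, beh_cm$subjects$delta_age)
    glm_fit <- fit_parcel_glm(cm, dres_adj, mres, cm$subjects)
    perm <- permute_glm(cm, dres_adj, mres, cm$subjects,
                        n_perm = config$n_perm, seed = child_seed(config$seed, 3L))
    fdr <- bh_fdr(perm$p_perm, config$alpha)
    tab <- glm_fit$table
    tab$p_perm <- perm$p_perm; tab$q <- fdr$q; tab$sig <- fdr$mask
    res$glm <- list(fit = glm_fit, table = tab, change = cm,
                    delta_res = dres_adj, mean_res = mres)
    write_tsv(tab, file.path(out, "glm_result.tsv"))
    if (!is.null(config$atlas_labels)) {
      strat <- stratify_map(tab$t, config$atlas_labels, tab$sig)
      write_tsv(strat, file.path(out, "stratification.tsv"))
      res$stratification <- strat
    }
  }

  ## ---- functional connectivity ops ---------------------------------------
  if ("fc" %in% stages) {
    message("stage fc: motion regression, exclusions, seed analysis")
    excl <- exclude_low_snr(bundle$region_snr)
    P <- dim(bundle$mt_depth)[2]
    ut <- which(upper.tri(matrix(0, P, P)))
    edges <- t(vapply(bundle$fc, function(m) m[ut], numeric(length(ut))))
    edges_r <- regress_fd(edges, cohort$mean_fd)
    fc_clean <- lapply(seq_len(nrow(cohort)), function(s) {
      m <- matrix(0, P, P); m[ut] <- edges_r[s, ]; m <- m + t(m)
      as_fc_matrix(m, excluded = excl, already_z = TRUE)
    })
    res$fc_clean <- fc_clean; res$fc_excluded <- excl
    if (!is.null(res$glm)) {
      roi <- which(res$glm$table$sig)
      if (length(roi) == 0L) roi <- bundle$truth$seed_parcels %||% seq_len(min(3L, P))
      roi <- roi[!excl[roi]]
      if (length(roi)) {
        seed_maps <- t(vapply(fc_clean, function(m) seed_fc(m, roi), numeric(P)))
        cm_fc <- compute_delta(seed_maps, cohort)
        ok <- colSums(is.na(cm_fc$delta)) == 0
        cm_fc$delta <- cm_fc$delta[, ok, drop = FALSE]
        cm_fc <- winsorize(cm_fc, 3)
        cm_fc <- adjust_interval(cm_fc, cm_fc$subjects$delta_age)
        fit_fc <- fit_parcel_glm(cm_fc, res$glm$delta_res, res$glm$mean_res, cm_fc$subjects)
        perm_fc <- permute_glm(cm_fc, res$glm$delta_res, res$glm$mean_res, cm_fc$subjects,
                               n_perm = config$n_perm, seed = child_seed(config$seed, 4L))
        fdr_fc <- bh_fdr(perm_fc$p_perm, config$alpha)
        tab_fc <- fit_fc$table
        tab_fc$p_perm <- perm_fc$p_perm; tab_fc$q <- fdr_fc$q; tab_fc$sig <- fdr_fc$mask
        res$seed_fc_glm <- tab_fc
        write_tsv(tab_fc, file.path(out, "seed_fc_glm.tsv"))
        dc <- vapply(fc_clean, function(m) degree_centrality(m, roi), numeric(1))
        write_tsv(data.frame(key = session_key(cohort), degree_centrality = dc),
                  file.path(out, "degree_centrality.tsv"))
      }
    }
  }

  ## ---- maturational indices ------------------------------------------------
  if ("mi" %in% stages && !is.null(res$mpc)) {
    message("stage mi: edge-wise mixed models + maturational index")
    fit_mpc <- fit_edge_lme(res$mpc, cohort)
    res$lme_mpc <- fit_mpc
    res$mi_mpc <- maturational_index(fit_mpc$baseline14, fit_mpc$change,
                                     alpha = config$alpha)
    write_tsv(res$mi_mpc$table, file.path(out, "mi_mpc.tsv"))
    if (!is.null(res$fc_clean)) {
      fit_fc <- fit_edge_lme(res$fc_clean, cohort)
      res$lme_fc <- fit_fc
      res$mi_fc <- maturational_index(fit_fc$baseline14, fit_fc$change,
                                      alpha = config$alpha)
      write_tsv(res$mi_fc$table, file.path(out, "mi_fc.tsv"))
      overlap <- crossmodal_overlap(res$mi_mpc, res$mi_fc)
      res$overlap <- overlap
      write_tsv(overlap, file.path(out, "mi_overlap.tsv"))
    }
  }

  ## ---- diffusion-map axis of age effects -----------------------------------
  if ("axis" %in% stages && !is.null(res$lme_mpc)) {
    message("stage axis: diffusion-map embedding of age-effect t-values")
    fit <- res$lme_mpc
    tmat <- coef_to_matrix(fit$beta["age", ] / fit$se["age", ],
                           list(edges = fit$edges, excluded = fit$excluded),
                           nrow(fit$baseline14))
    tmat[!is.finite(tmat)] <- 0
    ax <- embed_age_axis(tmat)
    res$axis <- ax
    write_tsv(data.frame(node = seq_len(nrow(ax$loadings)),
                         loading = ax$loadings[, 1]),
              file.path(out, "axis.tsv"))
  }

  ## ---- group comparison -----------------------------------------------------
  if ("compare" %in% stages && !is.null(res$mpc) && !is.null(res$scores)) {
    message("stage compare: +delta vs -delta maturational indices")
    subj_tab <- res$scores$subjects
    grp <- split_groups(stats::setNames(subj_tab$delta_res, subj_tab$subject_id))
    keep_subj <- names(grp)[!is.na(grp)]
    sel <- cohort$subject_id %in% keep_subj
    cmp <- compare_mi_groups(res$mpc[sel], cohort[sel, ], droplevels(grp[!is.na(grp)]),
                             n_perm = config$n_perm,
                             seed = child_seed(config$seed, 5L),
                             alpha = config$alpha)
    res$compare <- cmp
    write_tsv(cmp$table, file.path(out, "mi_group_compare.tsv"))
  }

  manifest$outputs <- list.files(out, recursive = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

## behavioral visit ages replace imaging ages for the behavioral interval
transform_cohort_beh <- function(cohort) {
  ch <- cohort
  if (!is.null(cohort$age_beh)) ch$age <- cohort$age_beh
  ch
}
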