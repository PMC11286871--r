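#' Default synthetic-cohort configuration
#'
#' Generator settings mirroring the study design the analysis assumes:
#' an accelerated longitudinal cohort sampled in five age strata
#' (14-15 / 16-17 / 18-19 / 20-21 / 22-25, equal weights, balanced sex,
#' three sites), two sessions per subject about 1.26 +/- 0.33 years
#' apart, one-latent-factor questionnaire items, adversity features
#' explaining ~21% of distress variance with an independent resilience
#' residual, depth-resolved myelin-proxy arrays with a
#' posterior-to-anterior age-slope gradient peaking at mid depth, and
#' block-structured functional connectivity. Planted effects (coupling
#' of change in the resilience residual with myelin change in
#' `n_planted` parcels at standardized strength `gamma`; a seed-FC
#' effect; low-signal regions) provide ground truth for recovery tests.
#'
#' `gamma` and `seed_gamma` are target standardized couplings
#' (correlations); the raw generative slopes are derived from the noise
#' settings (see [planted_coupling_theory()]).
#'
#' @param ... overrides of the defaults.
#' @return named list of generator settings.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_parcels = 40L, n_depths = 10L, n_items = 20L, n_adversity = 8L,
    third_session_prob = 0,
    age_strata = list(c(14, 15), c(16, 17), c(18, 19), c(20, 21), c(22, 25)),
    interval_mean = 1.26, interval_sd = 0.33, interval_range = c(0.5, 2.5),
    beh_jitter_sd = 0.08,
    site_probs = c(0.4, 0.35, 0.25),
    fd_meanlog = log(0.12), fd_sdlog = 0.35,
    ## behavioral model: Var(distress latent) = 1, split 0.21 / 0.79
    adversity_r2 = 0.21, adversity_subject_cor = 0.7,
    resilience_var = 0.79, resilience_autocor = 0.5,
    n_wellbeing_items = 2L, item_missing_rate = 0,
    ## myelin proxy
    area_ratio = 1.5, mt_base = 0.9, mt_depth_gain = 0.3,
    mt_parcel_sd = 0.05, beta_age_min = 0.003, beta_age_max = 0.010,
    beta_age_bump_sd = 0.2, subject_intercept_sd = 0.05, mt_noise_sd = 0.02,
    n_planted = 10L, gamma = 0.36,
    ## CSF fraction profile
    csf_pial = 0.35, csf_steepness = 10, csf_mid = 0.75, csf_session_sd = 0.1,
    ## functional connectivity
    fc_blocks = 4L, fc_within = 0.35, fc_between = 0.05,
    fc_noise_sd = 0.08, fc_subject_sd = 0.05,
    seed_parcels = NULL, seed_gamma = 0.36,
    n_low_snr = 3L, snr_mean = 3, snr_sd = 0.25, snr_low_value = 1.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

#' Theoretical planted standardized coupling
#'
#' Closed-form correlation between the change in the resilience residual
#' and parcel-mean myelin change in planted parcels, from the generative
#' variance bookkeeping: the raw slope is
#' g = gamma/sqrt(1-gamma^2) * sd(delta noise)/sd(delta r), with
#' Var(delta noise) = 2 sigma_mt^2 / D (parcel mean over D depths, two
#' sessions) and Var(delta r) = 2 (1 - rho_r) Var(r).
#'
#' @param config a [cohort_config()] list.
#' @return list with `slope` (raw generative slope) and `cor` (implied
#'   correlation, equal to `config$gamma` by construction).
#' @export
planted_coupling_theory <- function(config) {
  v_dr <- 2 * (1 - config$resilience_autocor) * config$resilience_var
  v_dn <- 2 * config$mt_noise_sd^2 / config$n_depths
  g <- config$gamma
  slope <- if (g == 0) 0 else g / sqrt(1 - g^2) * sqrt(v_dn / v_dr)
  list(slope = slope, cor = slope * sqrt(v_dr) / sqrt(slope^2 * v_dr + v_dn))
}

seed_fc_slope <- function(config) {
  v_dr <- 2 * (1 - config$resilience_autocor) * config$resilience_var
  v_dn <- 2 * config$fc_noise_sd^2
  g <- config$seed_gamma
  if (g == 0) 0 else g / sqrt(1 - g^2) * sqrt(v_dn / v_dr)
}

#' Simulate a longitudinal cohort with planted ground truth
#'
#' Generates a full synthetic bundle: cohort table, questionnaire items,
#' adversity features, depth-resolved myelin-proxy array, CSF fraction
#' profiles, per-session FC matrices, per-region signal summaries, and a
#' ground-truth record for parameter-recovery tests. Identical
#' (config, seed) pairs reproduce the bundle bit for bit.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param config generator settings, see [cohort_config()].
#' @param seed integer RNG seed.
#' @return object of class `synthetic_bundle` with elements `cohort`,
#'   `items`, `adversity`, `mt_depth` (sessions x parcels x depths),
#'   `csf_depth`, `fc` (list of matrices), `region_snr`, `truth`,
#'   `depth_alpha`, `config`.
#' @export
simulate_cohort <- function(n_subjects, config = cohort_config(), seed = 1L) {
  if (n_subjects < 4L) stop("need at least 4 subjects", call. = FALSE)
  P <- as.integer(config$n_parcels); D <- as.integer(config$n_depths)
  J <- as.integer(config$n_items); K <- as.integer(config$n_adversity)
  if (any(c(P, D, J, K) <= 0L)) stop("configuration error: nonpositive dimension", call. = FALSE)
  if (config$gamma < 0 || config$gamma >= 1 || config$seed_gamma < 0 || config$seed_gamma >= 1) {
    stop("configuration error: standardized couplings must lie in [0, 1)", call. = FALSE)
  }

  with_seed(seed, {
    ## ---- cohort design -------------------------------------------------
    strat <- rep_len(seq_along(config$age_strata), n_subjects)
    strat <- strat[sample.int(n_subjects)]
    age1 <- vapply(strat, function(s) stats::runif(1, config$age_strata[[s]][1],
                                                   config$age_strata[[s]][2]), numeric(1))
    interval <- truncnorm(n_subjects, config$interval_mean, config$interval_sd,
                          config$interval_range[1], config$interval_range[2])
    age1 <- pmin(age1, 26 - interval)
    third <- stats::runif(n_subjects) < config$third_session_prob
    sex <- rep_len(c(1L, 2L), n_subjects)[sample.int(n_subjects)]
    site <- sample(1:3, n_subjects, replace = TRUE, prob = config$site_probs)

    rows <- list()
    for (i in seq_len(n_subjects)) {
      ages <- if (third[i]) c(age1[i], age1[i] + interval[i] / 2, age1[i] + interval[i])
              else c(age1[i], age1[i] + interval[i])
      for (t in seq_along(ages)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%03d", i), session_id = t, age = ages[t],
          sex = sex[i], site = site[i], stringsAsFactors = FALSE)
      }
    }
    cohort <- do.call(rbind, rows)
    n_sess <- nrow(cohort)
    cohort$age_beh <- cohort$age + stats::rnorm(n_sess, 0, config$beh_jitter_sd)
    cohort$mean_fd <- stats::rlnorm(n_sess, config$fd_meanlog, config$fd_sdlog)
    subj_of <- match(cohort$subject_id, unique(cohort$subject_id))

    ## ---- adversity and the resilience residual -------------------------
    ## adversity instruments are ordinal severity bands 0..3 (questionnaire
    ## sums binned), from a subject-correlated latent normal; a few
    ## instruments dominate the normative distress response
    rho_x <- config$adversity_subject_cor
    u <- matrix(stats::rnorm(n_subjects * K), n_subjects, K)
    latent <- rho_x * u[subj_of, ] +
      sqrt(1 - rho_x^2) * matrix(stats::rnorm(n_sess * K), n_sess, K)
    band_q <- stats::qnorm(c(0.5, 0.75, 0.9))
    adversity <- matrix(0L, n_sess, K)
    for (k in seq_len(K)) {
      adversity[, k] <- findInterval(latent[, k], band_q)
    }
    colnames(adversity) <- paste0("adv", seq_len(K))
    ## population moments of the band distribution (probs .5/.25/.15/.1)
    bp <- c(0.5, 0.25, 0.15, 0.1)
    b_mu <- sum((0:3) * bp); b_sd <- sqrt(sum((0:3)^2 * bp) - b_mu^2)
    adv_std <- (adversity - b_mu) / b_sd
    w_raw <- exp(-0.55 * (seq_len(K) - 1))
    w <- w_raw * sqrt(config$adversity_r2 / sum(w_raw^2))

    v_r <- config$resilience_var; rho_r <- config$resilience_autocor
    s_i <- stats::rnorm(n_subjects)
    r <- sqrt(rho_r * v_r) * s_i[subj_of] + sqrt((1 - rho_r) * v_r) * stats::rnorm(n_sess)

    sys <- drop(adv_std %*% w)
    distress_latent <- sys - r

    ## ---- items: one-factor structure -----------------------------------
    lam <- seq(0.45, 0.85, length.out = J)
    nw <- min(config$n_wellbeing_items, J - 1L)
    if (nw > 0) lam[seq(J - nw + 1L, J)] <- -lam[seq(J - nw + 1L, J)]
    items <- outer(distress_latent, lam) +
      matrix(stats::rnorm(n_sess * J), n_sess, J) %*% diag(sqrt(1 - lam^2))
    colnames(items) <- paste0("item", seq_len(J))
    if (config$item_missing_rate > 0) {
      items[matrix(stats::runif(n_sess * J) < config$item_missing_rate, n_sess, J)] <- NA
    }

    ## ---- myelin-proxy depth profiles ------------------------------------
    grid <- build_depth_grid(1, config$area_ratio, n_surfaces = D + 2L)
    alpha_d <- grid$depth_alpha                    # pial -> white, volume fraction from white
    mu <- outer(stats::rnorm(P, 0, config$mt_parcel_sd),
                rep(1, D)) + config$mt_base +
      config$mt_depth_gain * matrix((1 - alpha_d), P, D, byrow = TRUE)
    bump <- exp(-((alpha_d - 0.5)^2) / (2 * config$beta_age_bump_sd^2))
    grad <- config$beta_age_min +
      (config$beta_age_max - config$beta_age_min) * (seq_len(P) - 1) / (P - 1)
    beta_age <- outer(grad, bump)                  # P x D

    planted <- sort(sample.int(P, min(config$n_planted, P)))
    slope <- planted_coupling_theory(config)$slope
    subj_int <- stats::rnorm(n_subjects, 0, config$subject_intercept_sd)
    first_row <- match(unique(cohort$subject_id), cohort$subject_id)
    r_first <- r[first_row][subj_of]
    dr_sess <- r - r_first                         # 0 at first session

    mt <- array(0, dim = c(n_sess, P, D))
    for (s in seq_len(n_sess)) {
      mt[s, , ] <- mu + beta_age * cohort$age[s] + subj_int[subj_of[s]] +
        matrix(stats::rnorm(P * D, 0, config$mt_noise_sd), P, D)
      if (slope != 0 && dr_sess[s] != 0) {
        mt[s, planted, ] <- mt[s, planted, ] + slope * dr_sess[s]
      }
    }
    if (any(!is.finite(mt))) stop("configuration error: values outside numeric range", call. = FALSE)

    ## ---- CSF fraction: logistic ramp, ~0 at white, max at pial ----------
    ## alpha is the volume fraction measured from the white boundary, so
    ## alpha itself indexes closeness to the pial surface
    pialness <- alpha_d
    csf_base <- config$csf_pial /
      (1 + exp(-config$csf_steepness * (pialness - config$csf_mid)))
    csf <- array(0, dim = c(n_sess, P, D))
    sess_scale <- exp(stats::rnorm(n_sess, 0, config$csf_session_sd))
    for (s in seq_len(n_sess)) {
      csf[s, , ] <- matrix(pmin(csf_base * sess_scale[s], 1), P, D, byrow = TRUE)
    }

    ## ---- functional connectivity ----------------------------------------
    block <- sort(rep_len(seq_len(config$fc_blocks), P))
    Z0 <- matrix(config$fc_between, P, P)
    for (b in seq_len(config$fc_blocks)) {
      idx <- which(block == b)
      Z0[idx, idx] <- config$fc_within
    }
    seed_parcels <- config$seed_parcels %||% planted[seq_len(min(3L, length(planted)))]
    fseed <- seed_fc_slope(config)
    subj_fc <- lapply(seq_len(n_subjects), function(i) sym_noise(P, config$fc_subject_sd))
    fc <- vector("list", n_sess)
    for (s in seq_len(n_sess)) {
      M <- Z0 + subj_fc[[subj_of[s]]] + sym_noise(P, config$fc_noise_sd)
      if (fseed != 0 && dr_sess[s] != 0) {
        tgt <- setdiff(seq_len(P), seed_parcels)
        M[seed_parcels, tgt] <- M[seed_parcels, tgt] + fseed * dr_sess[s]
        M[tgt, seed_parcels] <- t(M[seed_parcels, tgt, drop = FALSE])
      }
      diag(M) <- 0
      fc[[s]] <- M
    }

    ## ---- per-region signal summaries (low-SNR plants) --------------------
    region_snr <- matrix(stats::rnorm(n_subjects * P, config$snr_mean, config$snr_sd),
                         n_subjects, P)
    region_snr[region_snr < 2] <- 2 + abs(region_snr[region_snr < 2] - 2)
    low_regions <- integer(0)
    if (config$n_low_snr > 0) {
      low_regions <- sort(sample(setdiff(seq_len(P), seed_parcels), config$n_low_snr))
      for (reg in low_regions) {
        region_snr[sample.int(n_subjects, 1L), reg] <- config$snr_low_value
      }
    }

    truth <- list(item_loadings = lam, adversity_weights = w,
                  adversity_composite = sys,
                  resilience_signal = r, planted_parcels = planted,
                  gamma = config$gamma, coupling_slope = slope,
                  age_slopes = beta_age, mu = mu,
                  seed_parcels = seed_parcels, seed_fc_effect = fseed,
                  low_snr_regions = low_regions, rng_seed = as.integer(seed))

    structure(list(cohort = cohort, items = items, adversity = adversity,
                   mt_depth = mt, csf_depth = csf, fc = fc,
                   region_snr = region_snr, truth = truth,
                   depth_alpha = alpha_d, config = config),
              class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d sessions / %d subjects, %d parcels x %d depths, %d items, %d adversity features\n",
              nrow(x$cohort), length(unique(x$cohort$subject_id)),
              dim(x$mt_depth)[2], dim(x$mt_depth)[3],
              ncol(x$items), ncol(x$adversity)))
  cat(sprintf("  planted: %d coupled parcels (gamma = %.2f), seed ROI of %d, %d low-SNR regions\n",
              length(x$truth$planted_parcels), x$truth$gamma,
              length(x$truth$seed_parcels), length(x$truth$low_snr_regions)))
  invisible(x)
}

truncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

sym_noise <- function(P, sd) {
  m <- matrix(0, P, P)
  m[upper.tri(m)] <- stats::rnorm(P * (P - 1) / 2, 0, sd)
  m + t(m)
}

#' Simulate per-session matrices with planted maturational structure
#'
#' Builds session matrices M(age) = M0 + (age * c) * B + noise where the
#' change pattern B couples each node's edges to its baseline pattern
#' with per-node strength kappa: B_ij = ((kappa_i + kappa_j)/2) *
#' (M0_ij - rowmean). M0 is a symmetric circulant matrix (constant row
#' means by construction), so a node whose neighbors have homogeneous
#' kappa has an exactly monotone baseline-change relation: kappa > 0
#' yields conservative (MI = +1 in the noiseless limit), kappa < 0
#' disruptive (MI = -1), kappa = 0 a null node.
#'
#' @param kappa per-node coupling strengths in `[-2, 2]`.
#' @param ages per-session ages (>= 2 distinct values).
#' @param seed RNG seed.
#' @param noise_sd per-session edge noise SD (default 0.02).
#' @param subject optional per-session subject ids; adds a shared
#'   symmetric subject matrix with SD `subject_sd`.
#' @param subject_sd subject-level edge SD (default 0.02 when `subject`
#'   given).
#' @param base,amp circulant base level and harmonic amplitudes of M0.
#' @param change_scale per-year scaling of B (default 0.02).
#' @return list of symmetric zero-diagonal matrices with attribute
#'   `"truth"` (kappa, M0, B).
#' @export
simulate_mpc_series <- function(kappa, ages, seed = 1L, noise_sd = 0.02,
                                subject = NULL, subject_sd = 0.02,
                                base = 0.3, amp = c(0.15, 0.08),
                                change_scale = 0.02) {
  P <- length(kappa)
  if (P < 10L) stop("need at least 10 nodes", call. = FALSE)
  if (length(unique(ages)) < 2L) stop("ages must span at least 2 distinct values", call. = FALSE)
  if (any(abs(kappa) > 2)) stop("configuration error: |kappa| too large", call. = FALSE)

  idx <- outer(seq_len(P), seq_len(P), `-`)
  M0 <- matrix(base, P, P)
  for (h in seq_along(amp)) M0 <- M0 + amp[h] * cos(2 * pi * h * idx / P)
  ## deterministic symmetric texture breaks the circulant's exact ties so
  ## ranks are unique and the noiseless kappa = +/-1 cases are exact
  u <- seq(-1, 1, length.out = P)
  M0 <- M0 + 0.05 * outer(u, u)
  diag(M0) <- 0
  m <- mean(M0[upper.tri(M0)])      # near-constant row means by construction
  K <- outer(kappa, kappa, `+`) / 2
  B <- change_scale * K * (M0 - m)
  diag(B) <- 0
  if (max(abs(M0 + max(ages) * B)) > 6) {
    stop("configuration error: |kappa| too large to keep edge values bounded", call. = FALSE)
  }
  with_seed(seed, {
    subj_mats <- NULL
    if (!is.null(subject)) {
      us <- unique(subject)
      subj_mats <- lapply(us, function(s) sym_noise(P, subject_sd))
      names(subj_mats) <- as.character(us)
    }
    out <- lapply(seq_along(ages), function(s) {
      M <- M0 + ages[s] * B
      if (!is.null(subj_mats)) M <- M + subj_mats[[as.character(subject[s])]]
      if (noise_sd > 0) M <- M + sym_noise(P, noise_sd)
      diag(M) <- 0
      M
    })
    attr(out, "truth") <- list(kappa = kappa, M0 = M0, B = B)
    out
  })
}
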