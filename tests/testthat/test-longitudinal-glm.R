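test_that("change maps are last-minus-first with single-session subjects dropped", {
  coh <- data.frame(subject_id = c("a", "a", "b", "b", "b", "c"),
                    session_id = c(1, 2, 1, 2, 3, 1),
                    age = c(15, 16, 20, 21, 22.5, 18),
                    sex = c(1, 1, 2, 2, 2, 1), site = c(1, 1, 2, 2, 2, 3))
  v <- matrix(c(3, 5, 1, 4, 9, 2), ncol = 1)
  expect_message(cm <- compute_delta(v, coh), "single session")
  expect_equal(unname(cm$delta[, 1]), c(2, 8))      # b: session 3 minus session 1
  expect_equal(cm$subjects$delta_age, c(1, 2.5))
  expect_equal(cm$subjects$mean_age, c(15.5, 21.25))
})

test_that("winsorization clips at pre-clip mean +/- k SD and is idempotent", {
  set.seed(31)
  x <- matrix(rnorm(200), 100, 2)
  x[1, 1] <- 50
  w <- winsorize(x, 3)
  bound <- mean(x[, 1]) + 3 * sd(x[, 1])
  expect_equal(w[1, 1], bound)
  expect_equal(w[-1, ], x[-1, ])                     # in-range values untouched
  ## every value lies within the pre-clip bounds
  mu <- colMeans(x); sdv <- apply(x, 2, sd)
  expect_true(all(t(w) >= mu - 3 * sdv - 1e-12 & t(w) <= mu + 3 * sdv + 1e-12))
  ## untouched data are a fixed point
  y <- matrix(rnorm(60, 0, 0.1), 30, 2)
  expect_equal(winsorize(y, 3), y, tolerance = 1e-12)
  ## zero-variance column passes through
  z <- cbind(rep(1, 10), rnorm(10))
  expect_equal(winsorize(z, 3)[, 1], z[, 1])
})

test_that("interval adjustment equals brute-force OLS on delta age", {
  set.seed(32)
  da <- runif(40, 0.8, 2)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  Y[, 1] <- 1.7 * da                                  # exactly proportional
  got <- adjust_interval(Y, da)
  expect_lt(max(abs(got[, 1])), 1e-10)
  expect_lt(max(abs(got - residualize_bruteforce(Y, da))), 1e-10)
  ## constant interval: centering only
  expect_warning(g2 <- adjust_interval(Y, rep(1.3, 40)), "constant")
  expect_equal(g2, sweep(Y, 2, colMeans(Y)), tolerance = 1e-12)
  expect_error(adjust_interval(Y, rep(-1, 40)), "positive")
})

test_that("parcel GLM matches brute-force normal equations and lm()", {
  set.seed(33)
  n <- 141
  subjects <- data.frame(mean_age = runif(n, 15, 25),
                         sex = sample(1:2, n, TRUE), site = sample(1:3, n, TRUE))
  dr <- rnorm(n); mr <- rnorm(n)
  Y <- matrix(rnorm(n * 3), n, 3)
  fit <- fit_parcel_glm(Y, dr, mr, subjects)
  expect_equal(fit$df, 134L)                          # 7 design columns at 3 sites
  for (j in 1:3) {
    lmfit <- lm(Y[, j] ~ dr + mr + subjects$mean_age + factor(subjects$sex) +
                  factor(subjects$site))
    expect_equal(fit$table$beta[j], unname(coef(lmfit)["dr"]), tolerance = 1e-8)
    expect_equal(fit$table$t[j], unname(summary(lmfit)$coefficients["dr", "t value"]),
                 tolerance = 1e-8)
  }
  ## noiseless planted effect: exact coefficient, huge t
  Y2 <- cbind(2 * dr)
  fit2 <- fit_parcel_glm(Y2, dr, mr, subjects)
  expect_equal(fit2$table$beta[1], 2, tolerance = 1e-8)
  expect_gt(abs(fit2$table$t[1]), 1e6)
  ## standardized coefficient equals the correlation-scale effect
  Y3 <- cbind(0.5 * scale(dr)[, 1] + sqrt(1 - 0.25) * rnorm(n))
  fit3 <- fit_parcel_glm(Y3, dr, mr, subjects)
  expect_lt(abs(fit3$table$beta_std[1] - 0.5), 0.15)
  expect_error(fit_parcel_glm(Y, dr, dr, subjects), "rank")
})

test_that("null t statistics follow the t(134) reference distribution", {
  set.seed(34)
  n <- 141
  subjects <- data.frame(mean_age = runif(n, 15, 25),
                         sex = sample(1:2, n, TRUE), site = sample(1:3, n, TRUE))
  tstats <- replicate(500, {
    fit_parcel_glm(matrix(rnorm(n), n, 1), rnorm(n), rnorm(n), subjects)$table$t
  })
  ks <- suppressWarnings(ks.test(tstats, pt, df = 134))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p-values match a brute-force refit loop and keep pairs intact", {
  set.seed(35)
  n <- 24
  subjects <- data.frame(mean_age = runif(n, 15, 25),
                         sex = sample(1:2, n, TRUE), site = sample(1:3, n, TRUE))
  dr <- rnorm(n); mr <- 0.5 * dr + rnorm(n)
  Y <- matrix(rnorm(n * 2), n, 2)
  B <- 199
  got <- permute_glm(Y, dr, mr, subjects, n_perm = B, seed = 77)
  ## brute force: same permutation stream, full lm refits with the
  ## (delta_res, mean_res) rows shuffled jointly
  count <- numeric(2)
  adolmat:::with_seed(77, {
    for (b in seq_len(B)) {
      idx <- sample.int(n)
      for (j in 1:2) {
        lmfit <- lm(Y[, j] ~ dr[idx] + mr[idx] + subjects$mean_age +
                      factor(subjects$sex) + factor(subjects$site))
        tb <- summary(lmfit)$coefficients[2, "t value"]
        count[j] <- count[j] + (abs(tb) >= abs(got$t_obs[j]))
      }
    }
  })
  expect_equal(got$p_perm, (1 + count) / (B + 1), tolerance = 1e-12)

  ## a planted strong effect sits at the permutation floor
  Y2 <- cbind(dr + 0.01 * rnorm(n))
  g2 <- permute_glm(Y2, dr, mr, subjects, n_perm = 499, seed = 1)
  expect_equal(g2$p_perm[1], 1 / 500)
  expect_error(permute_glm(Y, dr, mr, subjects, n_perm = 10), "100")
})

test_that("BH step-up matches the hand-applied rule", {
  got <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(got$mask))                           # all pass the step-up
  expect_equal(got$q, c(0.04, 0.04, 0.04, 0.04))
  expect_false(any(bh_fdr(rep(1, 5))$mask))
  expect_true(bh_fdr(0.04)$mask)                       # m = 1 reduces to raw p
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("depth-resolved GLM localizes planted depth-specific coupling", {
  set.seed(36)
  n_sub <- 60; P <- 6; D <- 10
  coh <- toy_cohort(n_sub, seed = 36)
  dr <- rnorm(n_sub)
  mt <- array(rnorm(nrow(coh) * P * D, 1, 0.05), c(nrow(coh), P, D))
  last <- seq(2, nrow(coh), by = 2)
  ## mid-depth-only effect in parcels 1:2; depth-uniform effect in parcel 3
  for (i in seq_len(n_sub)) {
    mt[last[i], 1:2, 5] <- mt[last[i], 1:2, 5] + 0.3 * dr[i]
    mt[last[i], 3, ] <- mt[last[i], 3, ] + 0.2 * dr[i]
  }
  dr_sub <- dr; mr_sub <- rnorm(n_sub)
  tt <- depthwise_glm(mt, coh, roi = 1:3, dr_sub, mr_sub)
  expect_equal(dim(tt), c(3L, 10L))
  expect_equal(unname(which.max(colMeans(tt[1:2, ]))), 5L)
  ## uniform effect: per-depth t spread is modest relative to its mean
  expect_lt(diff(range(tt[3, ])), max(abs(tt[3, ])))
  ## null parcels elsewhere: small t throughout
  mt0 <- array(rnorm(nrow(coh) * P * D, 1, 0.05), c(nrow(coh), P, D))
  tt0 <- depthwise_glm(mt0, coh, roi = 4:6, dr_sub, mr_sub)
  expect_false(any(bh_fdr(2 * pt(abs(tt0), df = n_sub - 7, lower.tail = FALSE))$mask))
})

test_that("atlas stratification partitions parcels and shares sum to 100", {
  vals <- c(1, 1, 3, 3)
  lab <- c("A", "A", "B", "B")
  got <- stratify_map(vals, lab)
  expect_equal(got$mean, c(1, 3), ignore_attr = TRUE)
  mask <- c(TRUE, TRUE, TRUE, FALSE)
  got2 <- stratify_map(vals, lab, mask)
  expect_equal(got2$share_sig, c(200 / 3, 100 / 3), tolerance = 1e-12)
  expect_equal(sum(got2$share_sig), 100)
  expect_warning(g3 <- stratify_map(vals, c("A", NA, "B", "B"), mask), "unknown")
  expect_equal(sum(g3$share_sig), 100)
})
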