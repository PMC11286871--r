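test_that("identical (config, seed) reproduce the bundle bit for bit", {
  b1 <- simulate_cohort(12, seed = 7)
  b2 <- simulate_cohort(12, seed = 7)
  expect_identical(b1$cohort, b2$cohort)
  expect_identical(b1$items, b2$items)
  expect_identical(b1$mt_depth, b2$mt_depth)
  expect_identical(b1$fc, b2$fc)
  b3 <- simulate_cohort(12, seed = 8)
  expect_false(identical(b1$mt_depth, b3$mt_depth))
})

test_that("cohort tables respect the design invariants", {
  b <- simulate_cohort(60, seed = 70)
  co <- b$cohort
  expect_true(all(co$age >= 14 & co$age <= 26))
  expect_true(all(co$mean_fd >= 0))
  expect_true(all(co$sex %in% 1:2) && all(co$site %in% 1:3))
  for (s in split(co, co$subject_id)) {
    expect_gte(nrow(s), 2L)
    expect_true(all(diff(s$age[order(s$session_id)]) > 0))
  }
  ## inter-scan interval within the configured truncation range
  iv <- tapply(co$age, co$subject_id, function(a) diff(range(a)))
  expect_true(all(iv >= 0.5 & iv <= 2.5))
  ## roughly balanced sex
  expect_lt(abs(mean(co$sex == 1) - 0.5), 0.1)
  ## CSF profile in [0, 1], nondecreasing toward the pial-most depth
  expect_true(all(b$csf_depth >= 0 & b$csf_depth <= 1))
  prof <- b$csf_depth[1, 1, ]              # stored pial -> white
  expect_true(all(diff(prof) <= 1e-12))
  ## FC matrices symmetric, zero diagonal
  expect_lt(max(abs(b$fc[[1]] - t(b$fc[[1]]))), 1e-12)
  expect_true(all(diag(b$fc[[1]]) == 0))
  expect_error(simulate_cohort(2), "4 subjects")
  expect_error(simulate_cohort(10, cohort_config(n_parcels = 0)), "configuration")
})

test_that("items carry the configured one-factor structure", {
  b <- simulate_cohort(400, seed = 71)
  lam <- b$truth$item_loadings
  ## empirical item correlations track lambda_j * lambda_k
  R <- cor(b$items)
  pred <- outer(lam, lam); diag(pred) <- 1
  expect_lt(max(abs(R - pred)), 0.12)
})

test_that("zero planted coupling yields no delta-r / delta-MT correlation", {
  b <- simulate_cohort(250, cohort_config(gamma = 0), seed = 72)
  mtp <- apply(b$mt_depth, c(1, 2), mean)
  cm <- compute_delta(mtp, b$cohort)
  sub_first <- match(unique(b$cohort$subject_id), b$cohort$subject_id)
  sub_last <- sub_first + 1
  dr <- b$truth$resilience_signal[sub_last] - b$truth$resilience_signal[sub_first]
  rho <- cor(dr, rowMeans(cm$delta[, b$truth$planted_parcels]))
  expect_lt(abs(rho), 0.1)
})

test_that("planted coupling matches the closed-form variance bookkeeping", {
  cfg <- cohort_config(gamma = 0.4)
  theory <- planted_coupling_theory(cfg)
  ## oracle: recompute the implied correlation from raw generative variances
  v_dr <- 2 * (1 - cfg$resilience_autocor) * cfg$resilience_var
  v_dn <- 2 * cfg$mt_noise_sd^2 / cfg$n_depths
  expect_equal(theory$cor,
               theory$slope * sqrt(v_dr) / sqrt(theory$slope^2 * v_dr + v_dn),
               tolerance = 1e-12)
  expect_equal(theory$cor, 0.4, tolerance = 1e-12)

  b <- simulate_cohort(250, cfg, seed = 73)
  mtp <- apply(b$mt_depth, c(1, 2), mean)
  cm <- compute_delta(mtp, b$cohort)
  cm <- adjust_interval(cm, cm$subjects$delta_age)
  sub_first <- match(unique(b$cohort$subject_id), b$cohort$subject_id)
  dr <- b$truth$resilience_signal[sub_first + 1] - b$truth$resilience_signal[sub_first]
  emp <- mean(sapply(b$truth$planted_parcels, function(p) cor(dr, cm$delta[, p])))
  expect_lt(abs(emp - theory$cor), 0.1)
})

test_that("planted matrix series produce exact MI at kappa = +/-1 without noise", {
  coh <- toy_cohort(20, seed = 74)
  for (k1 in c(1, -1)) {
    kappa <- rep(0, 12); kappa[1] <- k1
    mats <- simulate_mpc_series(kappa, coh$age, seed = 75, noise_sd = 0,
                                subject_sd = 0)
    fit <- fit_edge_lme(mats, coh)
    mi <- maturational_index(fit$baseline14, fit$change)
    expect_equal(mi$table$rho[1], k1)
  }
  expect_error(simulate_mpc_series(rep(5, 12), coh$age), "kappa")
  expect_error(simulate_mpc_series(rep(0.5, 5), coh$age), "10 nodes")
  expect_error(simulate_mpc_series(rep(0.5, 12), rep(15, 4)), "distinct")
})

test_that("bundle round-trips through the plain-text directory format", {
  b <- simulate_cohort(6, cohort_config(n_parcels = 8), seed = 76)
  dir <- file.path(tempdir(), "bundle_rt")
  write_bundle(b, dir)
  rb <- read_bundle(dir)
  expect_equal(rb$cohort$age, b$cohort$age, tolerance = 1e-9)
  expect_equal(rb$mt_depth, b$mt_depth, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(rb$fc[[3]]), b$fc[[3]], tolerance = 1e-9)
  expect_equal(rb$manifest$truth$planted_parcels, b$truth$planted_parcels)
  val <- validate_tables(dir)
  expect_length(val$errors, 0)
  unlink(dir, recursive = TRUE)
})

test_that("table validation flags duplicate keys, asymmetry and odd ages", {
  b <- simulate_cohort(6, cohort_config(n_parcels = 6), seed = 77)
  dir <- file.path(tempdir(), "bundle_bad")
  write_bundle(b, dir)
  ## duplicate key
  co <- read.table(file.path(dir, "cohort.tsv"), sep = "\t", header = TRUE)
  co2 <- rbind(co, co[1, ])
  write.table(co2, file.path(dir, "cohort.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ## flip one FC cell
  f <- list.files(file.path(dir, "fc"), full.names = TRUE)[1]
  m <- as.matrix(read.table(f, sep = "\t", header = TRUE, check.names = FALSE)[, -1])
  m[1, 2] <- m[1, 2] + 1
  df <- data.frame(parcel = paste0("p", 1:6), m)
  colnames(df) <- c("parcel", paste0("p", 1:6))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  val <- validate_tables(dir)
  expect_true(any(grepl("duplicate", val$errors)))
  expect_true(any(grepl("asymmetric.*\\((1, 2|2, 1)\\)", val$errors)))
  ## age out of range is a warning, not an error
  co2$age[1] <- 27
  co2 <- co2[!duplicated(paste(co2$subject_id, co2$session_id)), ]
  write.table(co2, file.path(dir, "cohort.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  val2 <- validate_tables(dir)
  expect_true(any(grepl("ages", val2$warnings)))
  unlink(dir, recursive = TRUE)
})
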