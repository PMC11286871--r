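test_that("maturational index is exactly +/-1 for (anti)proportional change", {
  set.seed(51)
  base <- random_sym(15)
  mi_pos <- maturational_index(base, 2 * base + 1)
  expect_true(all(mi_pos$table$rho == 1))
  expect_true(all(mi_pos$table$class == "conservative"))
  mi_neg <- maturational_index(base, -base)
  expect_true(all(mi_neg$table$rho == -1))
  expect_true(all(mi_neg$table$class == "disruptive"))
  expect_equal(mi_pos$table$m, rep(14L, 15))
})

test_that("maturational index is invariant under strictly monotone transforms", {
  set.seed(52)
  base <- random_sym(12)
  chg <- random_sym(12)
  r0 <- maturational_index(base, chg)$table$rho
  maps <- list(function(x) exp(x), function(x) x^3 + 2 * x, function(x) atan(x) * 5)
  for (f in maps) {
    expect_equal(maturational_index(f(base), chg)$table$rho, r0, tolerance = 1e-12)
    expect_equal(maturational_index(base, f(chg))$table$rho, r0, tolerance = 1e-12)
  }
})

test_that("null maturational index has Spearman sampling SD ~ 1/sqrt(P-2)", {
  set.seed(53)
  P <- 41
  rhos <- unlist(lapply(1:50, function(i) {
    maturational_index(random_sym(P), random_sym(P))$table$rho
  }))
  expect_lt(abs(mean(rhos)), 0.02)
  expect_lt(abs(sd(rhos) - 1 / sqrt(P - 2)) / (1 / sqrt(P - 2)), 0.07)
})

test_that("undefined nodes are flagged, not classified", {
  base <- random_sym(12, seed = 54)
  chg <- random_sym(12, seed = 55)
  base[3, ] <- 1; base[, 3] <- 1           # constant row -> undefined
  mi <- maturational_index(base, chg)
  expect_equal(mi$table$class[3], "undefined")
  expect_true(is.na(mi$table$rho[3]))
})

test_that("cross-modal overlap categories partition the parcels", {
  mk <- function(classes) {
    structure(list(table = data.frame(node = seq_along(classes),
                                      rho = 0.5, p = 0.01, q = 0.01,
                                      m = 20L, class = classes),
                   alpha = 0.05),
              class = "maturational_index")
  }
  a <- mk(c("conservative", "conservative", "disruptive", "ns", "undefined"))
  b <- mk(c("conservative", "disruptive", "conservative", "conservative", "ns"))
  got <- crossmodal_overlap(a, b)
  expect_equal(got$category, c("+/+", "+/-", "-/+", "ns", "undefined"))
  expect_equal(nrow(got), 5L)
})

test_that("group split is sign-based, zeros excluded, sizes add up", {
  dr <- c(a = 3, b = -1, c = 0, d = 0.2, e = -5)
  expect_message(g <- suppressWarnings(split_groups(dr)), "zero")
  expect_equal(as.character(g[c("a", "d")]), c("+delta", "+delta"))
  expect_equal(as.character(g[c("b", "e")]), c("-delta", "-delta"))
  expect_true(is.na(g["c"]))
  expect_equal(sum(table(g)), length(dr) - 1L)
  expect_warning(split_groups(c(1, -1, 2)), "fewer than 10")
})

test_that("planted conservative/disruptive nodes are classified correctly", {
  n_sub <- 100; P <- 40
  coh <- toy_cohort(n_sub, seed = 56)
  kappa <- rep(0, P)
  kappa[1:12] <- 0.9; kappa[13:24] <- -0.9
  mats <- simulate_mpc_series(kappa, coh$age, seed = 57,
                              subject = coh$subject_id)
  fit <- fit_edge_lme(mats, coh)
  mi <- maturational_index(fit$baseline14, fit$change)
  cls <- mi$table$class
  acc <- mean(c(cls[1:12] == "conservative", cls[13:24] == "disruptive"))
  expect_gte(acc, 0.9)
})

test_that("group MI comparison reports Fisher-scale z and Cohen's q consistently", {
  n_sub <- 36; P <- 12
  coh <- toy_cohort(n_sub, seed = 58)
  mats <- simulate_mpc_series(rep(0.6, P), coh$age, seed = 59,
                              subject = coh$subject_id)
  grp <- factor(rep(c("+delta", "-delta"), length.out = n_sub),
                levels = c("+delta", "-delta"))
  names(grp) <- unique(coh$subject_id)
  cmp <- compare_mi_groups(mats, coh, grp, n_perm = 99, seed = 3)
  tab <- cmp$table
  ## Cohen's q is the Fisher-z difference of the group MIs
  expect_equal(tab$cohens_q, atanh(tab$rho_a) - atanh(tab$rho_b), tolerance = 1e-12)
  ## z uses the Fieller SE 1.06/sqrt(m - 3) on the Fisher scale
  se <- sqrt(1.06^2 / (cmp$mi_a$table$m - 3) + 1.06^2 / (cmp$mi_b$table$m - 3))
  expect_equal(tab$z, tab$cohens_q / se, tolerance = 1e-12)
  expect_true(all(tab$p_perm >= 1 / 100 & tab$p_perm <= 1))
  ## equal-MI case: rho_a == rho_b implies z = 0 and q = 0
  i <- which.min(abs(tab$rho_a - tab$rho_b))
  expect_equal(sign(tab$z[i]), sign(tab$cohens_q[i]))
})
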