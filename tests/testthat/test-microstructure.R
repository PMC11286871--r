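test_that("equivolumetric depth coordinate matches the numeric volume oracle", {
  ## boundary conditions and the equal-area limit
  expect_equal(equivolumetric_rho(1, 1, 0.5), 0.5)
  expect_equal(equivolumetric_rho(1, 4, 0), 0)
  expect_equal(equivolumetric_rho(1, 4, 1), 1)
  ## frozen value from the numeric integration oracle
  expect_equal(equivolumetric_rho(1, 4, 0.25), 0.39315, tolerance = 1e-4)

  for (a_in in c(0.5, 1, 2)) {
    for (a_out in c(0.5, 1.5, 4)) {
      for (alpha in c(0.1, 0.25, 0.5, 0.9)) {
        rho <- equivolumetric_rho(a_in, a_out, alpha)
        expect_lt(abs(volume_fraction_numeric(a_in, a_out, rho) - alpha), 1e-6)
      }
    }
  }
  expect_error(equivolumetric_rho(1, 1, 1.2), "alpha")
  expect_error(equivolumetric_rho(-1, 1, 0.5), "positive")
})

test_that("depth grid retains 10 pial-to-white surfaces and crowds toward larger areas", {
  g <- build_depth_grid(1, 1)
  expect_equal(sum(g$retained), 10L)
  ## equal areas: retained rho grid equals the equidistant alpha grid
  expect_equal(g$depth_rho, g$depth_alpha)
  expect_equal(sort(g$depth_alpha), (1:10) / 13)

  g2 <- build_depth_grid(1, 4)
  ## pial-most retained surface comes first and rho decreases toward white
  expect_true(all(diff(g2$depth_rho) < 0))
  ## rho(alpha) is concave when the outer area is larger: surfaces crowd
  ## (spacing shrinks) toward the pial side, and rho >= alpha throughout
  expect_true(all(diff(diff(g2$rho)) < 0))
  expect_true(all(g2$rho >= g2$alpha))
  ## excluded surfaces are the two pial-most (largest volume fraction)
  expect_equal(which(!g2$retained), c(11L, 12L))
})

test_that("CSF correction reproduces hand OLS oracle and its guards", {
  ## perfect linear fit: residuals zero, group-mean profile restored
  mt <- array(0, c(2, 1, 3)); mt[1, 1, ] <- c(2, 4, 6); mt[2, 1, ] <- c(2, 4, 6)
  cs <- array(0, c(2, 1, 3)); cs[1, 1, ] <- c(0, 0.5, 1); cs[2, 1, ] <- c(0, 0.5, 1)
  for (meth in c("pooled", "per_session")) {
    out <- csf_correct(mt, cs, method = meth)
    expect_equal(out[1, 1, ], c(2, 4, 6), tolerance = 1e-10)
  }

  ## zero CSF variance: passthrough (guard counts parcels or profiles)
  cs0 <- array(0, c(2, 1, 3))
  expect_identical(csf_correct(mt, cs0)[1, 1, ], mt[1, 1, ])
  expect_equal(attr(csf_correct(mt, cs0), "uncorrected"), 1L)
  expect_equal(attr(csf_correct(mt, cs0, method = "per_session"), "uncorrected"), 2L)

  set.seed(11)
  mt2 <- array(rnorm(5 * 4 * 6, 1, 0.1), c(5, 4, 6))
  cs2 <- array(runif(5 * 4 * 6, 0, 0.4), c(5, 4, 6))
  gm <- apply(mt2, c(2, 3), mean)

  ## per-session mode: residuals of each corrected profile sum to zero
  ## around the group profile
  out2 <- csf_correct(mt2, cs2, method = "per_session")
  for (s in 1:5) for (p in 1:4) {
    expect_lt(abs(sum(out2[s, p, ] - gm[p, ])), 1e-10)
  }

  ## pooled mode: residuals sum to zero per parcel over all sessions and
  ## depths, but per-session depth means (longitudinal signal) survive
  outp <- csf_correct(mt2, cs2)
  for (p in 1:4) {
    expect_lt(abs(sum(outp[, p, ] - rep(gm[p, ], each = 5))), 1e-9)
  }
  sess_means <- apply(outp, c(1, 2), mean)
  expect_gt(min(apply(sess_means, 2, stats::sd)), 1e-4)

  ## idempotence when the restored group profile carries no CSF component
  ## (a flat profile): re-correcting corrected data changes nothing
  gm_flat <- matrix(1, 4, 6)
  for (meth in c("pooled", "per_session")) {
    outf <- csf_correct(mt2, cs2, group_mean = gm_flat, method = meth)
    expect_equal(csf_correct(outf, cs2, group_mean = gm_flat, method = meth),
                 outf, tolerance = 1e-10, ignore_attr = TRUE)
  }

  expect_error(csf_correct(mt2, cs2[, 1:2, , drop = FALSE]), "shape")
})

test_that("parcel aggregation is the brute-force vertex mean", {
  expect_equal(unname(parcel_aggregate(matrix(c(1, 3), 2, 1), c(1, 1))[1, ]), 2)
  ## single-vertex parcels: identity
  v <- matrix(rnorm(6), 3, 2)
  expect_equal(unname(parcel_aggregate(v, 1:3)), unname(v))

  set.seed(2)
  vv <- matrix(rnorm(100 * 4), 100, 4)
  map <- sample(1:7, 100, TRUE)
  got <- parcel_aggregate(vv, map)
  for (p in 1:7) {
    expect_equal(unname(got[p, ]), colMeans(vv[map == p, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_warning(parcel_aggregate(vv, map, parcels = 1:8), "missing")
  expect_error(parcel_aggregate(vv, c(map[-1], NA)), "mapped")
})
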