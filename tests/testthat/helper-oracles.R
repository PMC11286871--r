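## Independent brute-force oracles used across tests.

## numeric volume-fraction oracle: cumulative cortical volume between the
## inner boundary and normalized depth rho, under linear area interpolation,
## by trapezoidal integration on a fine grid
volume_fraction_numeric <- function(a_in, a_out, rho, n_grid = 20001L) {
  t_all <- seq(0, 1, length.out = n_grid)
  area <- a_in + t_all * (a_out - a_in)
  total <- sum((area[-1] + area[-n_grid]) / 2) * (1 / (n_grid - 1))
  t_sub <- seq(0, rho, length.out = n_grid)
  area_s <- a_in + t_sub * (a_out - a_in)
  part <- sum((area_s[-1] + area_s[-n_grid]) / 2) * (rho / (n_grid - 1))
  part / total
}

## brute-force MPC: regress the controller out of each profile with lm(),
## correlate residuals
mpc_bruteforce <- function(profiles, controller) {
  P <- nrow(profiles)
  resid <- t(apply(profiles, 1L, function(y) stats::resid(stats::lm(y ~ controller))))
  r <- stats::cor(t(resid))
  diag(r) <- 0
  r
}

## per-column OLS residuals via lm()
residualize_bruteforce <- function(Y, x) {
  apply(as.matrix(Y), 2L, function(y) stats::resid(stats::lm(y ~ x)))
}

## two-session toy cohort with subject-constant sex/site
toy_cohort <- function(n_sub, seed = 1, interval = NULL, base_age = NULL) {
  withr_seed <- function(s, e) adolmat:::with_seed(s, e)
  withr_seed(seed, {
    iv <- if (is.null(interval)) runif(n_sub, 0.8, 1.8) else rep_len(interval, n_sub)
    a1 <- if (is.null(base_age)) runif(n_sub, 14, 24) else rep_len(base_age, n_sub)
    data.frame(subject_id = rep(sprintf("S%03d", seq_len(n_sub)), each = 2),
               session_id = rep(1:2, n_sub),
               age = rep(a1, each = 2) + rep(c(0, 1), n_sub) * rep(iv, each = 2),
               sex = rep(sample(1:2, n_sub, TRUE), each = 2),
               site = rep(sample(1:3, n_sub, TRUE), each = 2),
               mean_fd = abs(rnorm(2 * n_sub, 0.12, 0.03)))
  })
}

## dense spectral oracle for the diffusion axis: rebuild the operator from
## scratch and take the leading nontrivial eigenvector of the
## (nonsymmetric) Markov matrix directly
embed_oracle <- function(age_t, pct = 90, alpha = 0.5) {
  M <- age_t; diag(M) <- NA
  thr <- apply(M, 1, quantile, probs = pct / 100, na.rm = TRUE)
  S <- M; S[M < thr] <- 0; S[is.na(S)] <- 0
  S <- pmax(S, t(S))
  A <- 1 - acos(pmin(pmax(cor(t(S)), -1), 1)) / pi
  diag(A) <- 1
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  Pm <- W / rowSums(W)
  eg <- eigen(Pm)
  Re(eg$vectors[, 2])
}

## symmetric random parcel matrix
random_sym <- function(P, sd = 1, seed = NULL) {
  gen <- function() {
    m <- matrix(0, P, P)
    m[upper.tri(m)] <- rnorm(P * (P - 1) / 2, 0, sd)
    m <- m + t(m)
    diag(m) <- 0
    m
  }
  if (is.null(seed)) gen() else adolmat:::with_seed(seed, gen())
}
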