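#' Maturational index
#'
#' Per node, the signed Spearman correlation between the node's predicted
#' baseline (age-14) edge pattern and its edge-wise rate of change (the
#' age coefficient), over all included edges to other nodes. A positive
#' correlation ("conservative") means edges that were strong at baseline
#' strengthen further; a negative one ("disruptive") means baseline-strong
#' edges weaken or baseline-weak edges integrate. Nodes are classified at
#' FDR-corrected p < `alpha`.
#'
#' @param baseline P x P baseline matrix (e.g. `fit$baseline14`).
#' @param change P x P change matrix (e.g. `fit$change`).
#' @param alpha FDR level for classification (default 0.05).
#' @param min_edges minimum included edges per node (default 10).
#' @return object of class `maturational_index`: data frame `table` with
#'   node, rho, p, q, m (edge count) and class in
#'   `{"conservative", "disruptive", "ns", "undefined"}`.
#' @export
maturational_index <- function(baseline, change, alpha = 0.05, min_edges = 10L) {
  baseline <- as.matrix(baseline); change <- as.matrix(change)
  if (!identical(dim(baseline), dim(change))) stop("shape mismatch", call. = FALSE)
  P <- nrow(baseline)
  rho <- rep(NA_real_, P); p <- rep(NA_real_, P); m <- integer(P)
  for (i in seq_len(P)) {
    x <- baseline[i, -i]; y <- change[i, -i]
    ok <- is.finite(x) & is.finite(y)
    m[i] <- sum(ok)
    if (m[i] < min_edges) next
    if (stats::var(x[ok]) < 1e-14 || stats::var(y[ok]) < 1e-14) next  # undefined
    sp <- spearman_cols(x[ok], matrix(y[ok], ncol = 1))
    rho[i] <- sp$rho; p[i] <- sp$p
  }
  q <- rep(NA_real_, P)
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok], alpha)$q
  cls <- ifelse(is.na(rho), "undefined",
         ifelse(q < alpha & rho > 0, "conservative",
         ifelse(q < alpha & rho < 0, "disruptive", "ns")))
  structure(list(table = data.frame(node = seq_len(P), rho = rho, p = p, q = q,
                                    m = m, class = cls, row.names = NULL),
                 alpha = alpha),
            class = "maturational_index")
}

#' @export
print.maturational_index <- function(x, ...) {
  tt <- table(factor(x$table$class,
                     c("conservative", "disruptive", "ns", "undefined")))
  cat(sprintf("<maturational_index> %d nodes: %d conservative, %d disruptive, %d ns, %d undefined (q < %.2f)\n",
              nrow(x$table), tt[1], tt[2], tt[3], tt[4], x$alpha))
  invisible(x)
}

#' Cross-modal overlap of maturational indices
#'
#' Joins per-node classifications from two modalities (typically
#' microstructural profile covariance and functional connectivity) into
#' categories: both conservative ("+/+"), both disruptive ("-/-"),
#' decoupled ("+/-" or "-/+"), "ns" if either is non-significant,
#' "undefined" if either is undefined.
#'
#' @param mi_a,mi_b `maturational_index` objects on the same parcel space.
#' @return data frame with node, class_a, class_b, category.
#' @export
crossmodal_overlap <- function(mi_a, mi_b) {
  a <- mi_a$table; b <- mi_b$table
  if (nrow(a) != nrow(b)) stop("parcel spaces differ", call. = FALSE)
  cat_of <- function(ca, cb) {
    if (ca == "undefined" || cb == "undefined") return("undefined")
    if (ca == "ns" || cb == "ns") return("ns")
    if (ca == "conservative" && cb == "conservative") return("+/+")
    if (ca == "disruptive" && cb == "disruptive") return("-/-")
    if (ca == "conservative") return("+/-")
    "-/+"
  }
  data.frame(node = a$node, class_a = a$class, class_b = b$class,
             category = mapply(cat_of, a$class, b$class, USE.NAMES = FALSE),
             row.names = NULL)
}

#' Split subjects by the sign of their resilience change
#'
#' Labels subjects "+delta" when resilient functioning increased between
#' sessions and "-delta" when it decreased; exact zeros are excluded.
#'
#' @param delta_res per-subject change in resilient functioning (named or
#'   aligned with subjects).
#' @return factor with levels `c("+delta", "-delta")`; NA for zeros.
#' @export
split_groups <- function(delta_res) {
  if (any(delta_res == 0, na.rm = TRUE)) {
    message(sprintf("excluding %d subject(s) with exactly zero change",
                    sum(delta_res == 0, na.rm = TRUE)))
  }
  g <- ifelse(delta_res > 0, "+delta", ifelse(delta_res < 0, "-delta", NA))
  g <- factor(g, levels = c("+delta", "-delta"))
  names(g) <- names(delta_res)
  sizes <- table(g)
  if (any(sizes < 10L)) warning("a group has fewer than 10 subjects; low power")
  g
}

#' Group comparison of maturational indices
#'
#' Computes the maturational index separately in two groups (each via the
#' full edge-LME pipeline), tests per-node differences with a z-test on
#' Fisher-transformed Spearman correlations using the Fieller-corrected
#' standard error 1.06/sqrt(m - 3), reports Cohen's q =
#' atanh(rho_a) - atanh(rho_b), and validates against a
#' demography-stratified permutation (group labels shuffled within
#' sex x age-tertile strata, group sizes preserved, the entire
#' LME-to-MI chain recomputed per permutation). A node is significant
#' only if both the FDR-corrected z-test and the permutation agree
#' (p < `alpha` each).
#'
#' @param matrices list of P x P matrices per session.
#' @param cohort session-level cohort table (`subject_id`, `age`, `sex`,
#'   `site`).
#' @param group per-subject factor with two levels (first level = "a",
#'   e.g. the +delta group), named by subject id or aligned with
#'   `unique(cohort$subject_id)`.
#' @param n_perm permutations (default 1000; the headline analysis used
#'   10000).
#' @param seed RNG seed.
#' @param alpha significance level.
#' @param theta_grid passed to the fast LME engine.
#' @return object of class `mi_group_comparison`: data frame `table`
#'   (node, rho_a, rho_b, z, cohens_q, p_fdr, p_perm, sig,
#'   shift_category), plus the per-group `maturational_index` objects.
#' @export
compare_mi_groups <- function(matrices, cohort, group, n_perm = 1000L,
                              seed = 1L, alpha = 0.05,
                              theta_grid = exp(seq(log(1e-4), log(1e4), length.out = 25))) {
  subj <- unique(as.character(cohort$subject_id))
  group <- resolve_group(group, subj)
  es <- edge_stack(matrices)
  X <- lme_design(cohort)
  ss <- lme_suffstats(X, es$Y, cohort$subject_id)
  P <- es$P

  edge_beta_of <- function(members, grid) {
    agg <- aggregate_stats(ss, members)
    keep <- estimable_columns(agg, ss$dvals, ss$p)
    gr <- reml_grid(agg, ss$dvals, ss$p, grid, keep, track_beta = TRUE)
    beta <- matrix(0, ss$p, ss$E)        # dropped (inestimable) dummies marginalize at 0
    beta[keep, ] <- gr$beta
    rownames(beta) <- colnames(X)
    beta
  }
  mi_of <- function(members) {
    beta <- edge_beta_of(members, theta_grid)
    maturational_index(coef_to_matrix(edge_baseline14(beta, colnames(X)), es, P),
                       coef_to_matrix(beta["age", ], es, P))
  }
  ## permutation fast path: per-node Spearman rho straight from edge vectors
  node_edges <- lapply(seq_len(P), function(i)
    which(es$edges[, 1] == i | es$edges[, 2] == i))
  perm_grid <- theta_grid[seq(1, length(theta_grid), by = 2)]
  rho_of <- function(members) {
    beta <- edge_beta_of(members, perm_grid)
    b14 <- edge_baseline14(beta, colnames(X))
    chg <- beta["age", ]
    vapply(node_edges, function(ix) {
      if (length(ix) < 10L) return(NA_real_)
      suppressWarnings(stats::cor(rank(b14[ix]), rank(chg[ix])))
    }, numeric(1))
  }

  subj_a <- subj[group == levels(group)[1]]
  subj_b <- subj[group == levels(group)[2]]
  mi_a <- mi_of(subj_a)
  mi_b <- mi_of(subj_b)

  ra <- mi_a$table$rho; rb <- mi_b$table$rho
  ma <- mi_a$table$m; mb <- mi_b$table$m
  fz <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  dq <- fz(ra) - fz(rb)
  se <- sqrt(1.06^2 / pmax(ma - 3, 1) + 1.06^2 / pmax(mb - 3, 1))
  z <- dq / se
  p_z <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  okn <- !is.na(p_z)
  p_fdr <- rep(NA_real_, P)
  p_fdr[okn] <- bh_fdr(p_z[okn], alpha)$q

  ## stratified permutation: shuffle group labels within sex x age-tertile
  strata <- permutation_strata(cohort, subj)
  count <- numeric(P)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      gperm <- permute_within_strata(group, strata)
      dq_b <- fz(rho_of(subj[gperm == levels(group)[1]])) -
              fz(rho_of(subj[gperm == levels(group)[2]]))
      count <- count + (!is.na(dq_b) & !is.na(dq) & abs(dq_b) >= abs(dq))
    }
  })
  p_perm <- (1 + count) / (n_perm + 1)
  sig <- okn & p_fdr < alpha & p_perm < alpha

  shift <- rep(NA_character_, P)
  ca <- mi_a$table$class; cb <- mi_b$table$class
  for (i in which(sig)) {
    shift[i] <-
      if (ca[i] == "conservative" && cb[i] == "conservative" && abs(ra[i]) < abs(rb[i])) "less conservative"
      else if (ca[i] == "disruptive" && cb[i] == "disruptive" && ra[i] < rb[i]) "more disruptive"
      else if (ca[i] == "disruptive" && cb[i] == "ns") "tipping point"
      else "other"
  }
  structure(list(table = data.frame(node = seq_len(P), rho_a = ra, rho_b = rb,
                                    z = z, cohens_q = dq, p_fdr = p_fdr,
                                    p_perm = p_perm, sig = sig,
                                    shift_category = shift, row.names = NULL),
                 mi_a = mi_a, mi_b = mi_b, n_perm = n_perm, alpha = alpha,
                 groups = levels(group)),
            class = "mi_group_comparison")
}

#' @export
print.mi_group_comparison <- function(x, ...) {
  cat(sprintf("<mi_group_comparison> %s vs %s: %d/%d nodes significant (z-FDR & permutation, alpha = %.2f)\n",
              x$groups[1], x$groups[2], sum(x$table$sig, na.rm = TRUE),
              nrow(x$table), x$alpha))
  invisible(x)
}

## rho-only maturational index (no inference), used inside permutations
mi_rho_only <- function(baseline, change, min_edges = 10L) {
  P <- nrow(baseline)
  rho <- rep(NA_real_, P)
  for (i in seq_len(P)) {
    x <- baseline[i, -i]; y <- change[i, -i]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_edges) next
    rho[i] <- suppressWarnings(stats::cor(rank(x[ok]), rank(y[ok])))
  }
  rho
}

resolve_group <- function(group, subj) {
  if (!is.null(names(group))) group <- group[subj]
  if (length(group) != length(subj)) {
    stop("`group` must have one label per subject", call. = FALSE)
  }
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L || anyNA(group)) {
    stop("`group` must be a complete two-level factor over subjects", call. = FALSE)
  }
  group
}

## sex x age-tertile strata at each subject's first session; singleton
## strata merged with the nearest age stratum within sex
permutation_strata <- function(cohort, subj) {
  first <- cohort[!duplicated(cohort$subject_id), ]
  first <- first[match(subj, first$subject_id), ]
  br <- stats::quantile(first$age, c(0, 1/3, 2/3, 1))
  br <- unique(br)
  tert <- cut(first$age, br, include.lowest = TRUE, labels = FALSE)
  strata <- interaction(first$sex, tert, drop = TRUE)
  tab <- table(strata)
  if (any(tab < 2L)) {
    message("merging singleton permutation strata with nearest age stratum")
    lv <- names(tab)[tab < 2L]
    for (l in lv) {
      idx <- which(strata == l)
      sx <- first$sex[idx][1]
      cand <- which(first$sex == sx & strata != l)
      if (length(cand)) {
        near <- cand[which.min(abs(first$age[cand] - first$age[idx][1]))]
        strata[idx] <- strata[near]
      }
    }
    strata <- droplevels(strata)
  }
  strata
}

permute_within_strata <- function(group, strata) {
  out <- group
  for (s in levels(strata)) {
    idx <- which(strata == s)
    out[idx] <- group[idx][sample.int(length(idx))]
  }
  out
}
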