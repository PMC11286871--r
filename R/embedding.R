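#' Diffusion-map axis of synchronized age effects
#'
#' Given a symmetric matrix of edge-wise age-effect t-values, keeps per
#' row only values above the row's `threshold_pct` percentile (the rest
#' set to 0; the sparsified matrix is re-symmetrized by the elementwise
#' maximum), builds a normalized-angle affinity between row profiles, and
#' applies diffusion-map embedding (anisotropic diffusion parameter
#' `alpha_diff = 0.5`, diffusion time 0). Nodes with similar loadings on
#' the first nontrivial component share a pattern of age effects; apices
#' of the axis change most differently.
#'
#' The component sign is fixed so the loading correlates positively with
#' the input row sums (first element positive as the tie-break), making
#' runs comparable.
#'
#' @param age_t P x P symmetric matrix (e.g. t-values of the age effect).
#' @param threshold_pct row-wise sparsity percentile in (0, 100),
#'   default 90.
#' @param alpha_diff anisotropic diffusion parameter (default 0.5).
#' @param n_components number of components to return (default 5).
#' @return object of class `axis_result`: `loadings` (P x n_components),
#'   `lambdas` (eigenvalue spectrum), `affinity`.
#' @export
embed_age_axis <- function(age_t, threshold_pct = 90, alpha_diff = 0.5,
                           n_components = 5L) {
  age_t <- as.matrix(age_t)
  check_symmetric(age_t, tol = 1e-8)
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    stop("`threshold_pct` must lie in (0, 100)", call. = FALSE)
  }
  P <- nrow(age_t)
  M <- age_t
  diag(M) <- NA
  ## row-wise sparsification: keep each node's top (100 - pct)% of edges
  thr <- apply(M, 1L, stats::quantile, probs = threshold_pct / 100, na.rm = TRUE)
  S <- M
  S[M < thr] <- 0
  S[is.na(S)] <- 0
  S <- pmax(S, t(S))  # re-symmetrize by max

  ## normalized-angle affinity between sparsified row profiles
  cs <- suppressWarnings(stats::cor(t(S)))
  if (any(!is.finite(cs))) {
    stop("degenerate (constant) rows: no informative affinity", call. = FALSE)
  }
  A <- 1 - acos(pmin(pmax(cs, -1), 1)) / pi
  diag(A) <- 1

  ## connectivity check on the affinity support
  comp <- graph_components(A > 1e-12)
  if (max(comp) > 1L) {
    stop(sprintf("affinity graph is disconnected (%d components)", max(comp)), call. = FALSE)
  }

  ## anisotropic normalization then symmetric diffusion operator
  d <- rowSums(A)
  W <- A / outer(d^alpha_diff, d^alpha_diff)
  dw <- rowSums(W)
  Ssym <- W / outer(sqrt(dw), sqrt(dw))
  eg <- eigen((Ssym + t(Ssym)) / 2, symmetric = TRUE)
  lam <- eg$values
  psi <- eg$vectors / sqrt(dw)          # right eigenvectors of the Markov operator
  if (lam[2] >= 1 - 1e-10 || abs(lam[1] - lam[2]) < 1e-10 ||
      abs(lam[2] - lam[3]) < 1e-10) {
    stop("degenerate spectrum: no informative axis", call. = FALSE)
  }
  k <- min(n_components, P - 1L)
  idx <- 2:(k + 1L)
  scale_f <- lam[idx] / (1 - lam[idx])  # diffusion time 0 convention
  load <- sweep(psi[, idx, drop = FALSE], 2L, scale_f, `*`)
  ## deterministic sign: align first component with input row sums
  ref <- rowSums(age_t)
  for (j in seq_len(ncol(load))) {
    s <- sum(load[, j] * ref)
    if (abs(s) < 1e-12) s <- load[1, j]
    if (s < 0) load[, j] <- -load[, j]
  }
  structure(list(loadings = load, lambdas = lam, affinity = A,
                 threshold_pct = threshold_pct),
            class = "axis_result")
}

#' @export
print.axis_result <- function(x, ...) {
  cat(sprintf("<axis_result> %d nodes, %d components; lambda_1 = %.3f\n",
              nrow(x$loadings), ncol(x$loadings), x$lambdas[2]))
  invisible(x)
}

#' Align embedding axes to a reference by orthogonal Procrustes
#'
#' Embeddings have arbitrary sign (and rotation for multiple components);
#' comparing loading distributions across groups requires a common frame.
#' Finds the orthogonal transform R minimizing ||X R - ref||_F.
#'
#' @param loadings P x k matrix to align.
#' @param reference P x k reference matrix.
#' @return aligned P x k matrix with attribute `"rotation"`.
#' @export
align_axes <- function(loadings, reference) {
  loadings <- as.matrix(loadings); reference <- as.matrix(reference)
  if (!identical(dim(loadings), dim(reference))) stop("shape mismatch", call. = FALSE)
  sv <- svd(crossprod(loadings, reference))
  R <- sv$u %*% t(sv$v)
  out <- loadings %*% R
  attr(out, "rotation") <- R
  out
}

## connected components of an undirected adjacency (logical matrix)
graph_components <- function(adj) {
  P <- nrow(adj)
  comp <- integer(P)
  cur <- 0L
  for (s in seq_len(P)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
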