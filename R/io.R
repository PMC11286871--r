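## Plain-text bundle I/O: TSV tables, per-session matrix TSVs and a JSON
## manifest recording shapes, labels, depth fractions, seed and config.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  df <- data.frame(parcel = rownames(m) %||% paste0("p", seq_len(nrow(m))), m,
                   check.names = FALSE)
  colnames(df) <- c("parcel", colnames(m) %||% paste0("c", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

session_key <- function(cohort) {
  sprintf("%s_s%d", cohort$subject_id, cohort$session_id)
}

#' Write a synthetic bundle to a plain-text directory
#'
#' Layout: `cohort.tsv`, `items.tsv`, `adversity.tsv`, `region_snr.tsv`,
#' per-session matrices under `mt_depth/`, `csf_depth/` and `fc/`, and a
#' `manifest.json` recording shapes, parcel labels, depth fractions, the
#' RNG seed and the generator config.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("mt_depth", "csf_depth", "fc")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  keys <- session_key(bundle$cohort)
  write_tsv(bundle$cohort, file.path(dir, "cohort.tsv"))
  write_tsv(data.frame(key = keys, bundle$items, check.names = FALSE),
            file.path(dir, "items.tsv"))
  write_tsv(data.frame(key = keys, bundle$adversity, check.names = FALSE),
            file.path(dir, "adversity.tsv"))
  write_tsv(data.frame(subject_id = unique(bundle$cohort$subject_id),
                       bundle$region_snr, check.names = FALSE),
            file.path(dir, "region_snr.tsv"))
  P <- dim(bundle$mt_depth)[2]
  plabs <- paste0("p", seq_len(P))
  dlabs <- paste0("d", seq_len(dim(bundle$mt_depth)[3]))
  for (s in seq_along(keys)) {
    mt <- bundle$mt_depth[s, , ]; rownames(mt) <- plabs; colnames(mt) <- dlabs
    write_matrix_tsv(mt, file.path(dir, "mt_depth", paste0(keys[s], ".tsv")))
    cs <- bundle$csf_depth[s, , ]; rownames(cs) <- plabs; colnames(cs) <- dlabs
    write_matrix_tsv(cs, file.path(dir, "csf_depth", paste0(keys[s], ".tsv")))
    f <- bundle$fc[[s]]; rownames(f) <- colnames(f) <- plabs
    write_matrix_tsv(f, file.path(dir, "fc", paste0(keys[s], ".tsv")))
  }
  manifest <- list(
    n_sessions = nrow(bundle$cohort), n_parcels = P,
    n_depths = dim(bundle$mt_depth)[3],
    parcel_labels = plabs, depth_alpha = bundle$depth_alpha,
    depth_orientation = "pial_to_white",
    session_keys = keys, seed = bundle$truth$rng_seed,
    config = bundle$config[!vapply(bundle$config, is.list, logical(1))],
    truth = bundle$truth[c("planted_parcels", "seed_parcels",
                           "low_snr_regions", "gamma")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return list mirroring the `synthetic_bundle` layout (without the full
#'   ground-truth record: only the planted indices in the manifest).
#' @export
read_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cohort <- read_tsv(file.path(dir, "cohort.tsv"))
  keys <- man$session_keys
  items <- as.matrix(read_tsv(file.path(dir, "items.tsv"))[, -1, drop = FALSE])
  adversity <- as.matrix(read_tsv(file.path(dir, "adversity.tsv"))[, -1, drop = FALSE])
  snr <- as.matrix(read_tsv(file.path(dir, "region_snr.tsv"))[, -1, drop = FALSE])
  P <- man$n_parcels; D <- man$n_depths; S <- man$n_sessions
  mt <- array(NA_real_, c(S, P, D)); csf <- array(NA_real_, c(S, P, D))
  fc <- vector("list", S)
  for (s in seq_len(S)) {
    mt[s, , ] <- read_matrix_tsv(file.path(dir, "mt_depth", paste0(keys[s], ".tsv")))
    csf[s, , ] <- read_matrix_tsv(file.path(dir, "csf_depth", paste0(keys[s], ".tsv")))
    fc[[s]] <- read_matrix_tsv(file.path(dir, "fc", paste0(keys[s], ".tsv")))
  }
  list(cohort = cohort, items = items, adversity = adversity,
       mt_depth = mt, csf_depth = csf, fc = fc, region_snr = snr,
       depth_alpha = man$depth_alpha, manifest = man)
}

#' Validate bundle tables
#'
#' Schema and range checks: unique (subject, session) keys (fatal if
#' duplicated), sex in \{1, 2\} and site in \{1, 2, 3\} (fatal), ages in
#' [14, 26] (warning only), nonnegative mean framewise displacement,
#' matrix symmetry (fatal, naming the worst cell).
#'
#' @param dir bundle directory.
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_tables <- function(dir) {
  errors <- character(0); warns <- character(0)
  cohort <- read_tsv(file.path(dir, "cohort.tsv"))
  key <- paste(cohort$subject_id, cohort$session_id)
  if (anyDuplicated(key)) {
    errors <- c(errors, sprintf("duplicate (subject, session) key: %s",
                                key[duplicated(key)][1]))
  }
  if (!all(cohort$sex %in% c(1, 2))) errors <- c(errors, "sex outside {1, 2}")
  if (!all(cohort$site %in% c(1, 2, 3))) errors <- c(errors, "site outside {1, 2, 3}")
  if (any(cohort$age < 14 | cohort$age > 26)) {
    warns <- c(warns, "ages outside [14, 26]")
  }
  if (!is.null(cohort$mean_fd) && any(cohort$mean_fd < 0)) {
    errors <- c(errors, "negative mean_fd")
  }
  fc_dir <- file.path(dir, "fc")
  if (dir.exists(fc_dir)) {
    for (f in list.files(fc_dir, full.names = TRUE)) {
      m <- read_matrix_tsv(f)
      dlt <- abs(m - t(m))
      if (max(dlt, na.rm = TRUE) > 1e-8) {
        ij <- which(dlt == max(dlt, na.rm = TRUE), arr.ind = TRUE)[1, ]
        errors <- c(errors, sprintf("asymmetric matrix %s at cell (%d, %d)",
                                    basename(f), ij[1], ij[2]))
      }
    }
  }
  list(errors = errors, warnings = warns)
}
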