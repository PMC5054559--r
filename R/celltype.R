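#' Select cell-type discriminating CpGs from a reference
#'
#' For each cell type, picks the `n_per_type` CpGs with the largest absolute
#' difference between that type's mean beta and the mean of the remaining
#' types, then deduplicates across types (deterministic order: by cell type,
#' then by decreasing difference).
#'
#' @param reference Reference profile matrix, cell types x CpGs (beta scale),
#'   with row and column names.
#' @param n_per_type Number of discriminating CpGs kept per cell type.
#' @return Character vector of CpG ids.
#' @export
select_discriminating_cpgs <- function(reference, n_per_type = 50) {
  reference <- as_reference_matrix(reference)
  K <- nrow(reference)
  if (K < 2) abort("need at least 2 cell types")
  if (n_per_type > ncol(reference)) abort("n_per_type exceeds available CpGs")
  picks <- character(0)
  any_signal <- FALSE
  for (t in seq_len(K)) {
    d <- abs(reference[t, ] - colMeans(reference[-t, , drop = FALSE]))
    if (max(d) > 0) any_signal <- TRUE
    ord <- order(-d, seq_along(d))
    picks <- c(picks, colnames(reference)[ord[seq_len(n_per_type)]])
  }
  if (!any_signal) abort("cell-type profiles are identical; no discriminating CpGs")
  unique(picks)
}

#' Estimate cell-type proportions by constrained least squares
#'
#' Houseman-style reference-based deconvolution: for each sample, solves
#' \deqn{\min_\pi \| W^\top \pi - y \|^2 \quad \text{s.t. } \pi \ge 0,\;
#' \sum_k \pi_k \le 1,} where `y` holds the sample's beta values on the
#' reference CpGs and `W` the reference profiles. The inequality form follows
#' the original constrained-projection formulation; `1 - sum(pi)` is the
#' unexplained fraction. Solved exactly by non-negative least squares, with
#' the sum constraint activated (as a heavily weighted equality) only when the
#' unconstrained NNLS solution exceeds the simplex.
#'
#' @param bm Beta matrix, samples x CpGs; must contain the reference CpGs
#'   (restricted automatically). Missing values on reference CpGs are dropped
#'   per sample.
#' @param reference Reference profile matrix, cell types x CpGs.
#' @param cpg_ids CpGs used for the fit; default: the discriminating subset
#'   from [select_discriminating_cpgs()].
#' @param n_per_type Passed to [select_discriminating_cpgs()] when `cpg_ids`
#'   is `NULL`.
#' @return A tibble: `sample_id`, one proportion column per cell type, and
#'   `residual` (root residual sum of squares).
#' @export
estimate_cell_proportions <- function(bm, reference, cpg_ids = NULL,
                                      n_per_type = 50) {
  validate_beta_matrix(bm)
  reference <- as_reference_matrix(reference)
  if (nrow(reference) < 2) abort("need at least 2 cell types")
  if (is.null(cpg_ids)) {
    cpg_ids <- select_discriminating_cpgs(reference,
                                          min(n_per_type, ncol(reference)))
  }
  cpg_ids <- intersect(cpg_ids, colnames(bm))
  if (length(cpg_ids) < nrow(reference)) {
    abort("fewer usable reference CpGs than cell types")
  }
  W <- reference[, cpg_ids, drop = FALSE]
  A <- t(W)                       # CpGs x cell types
  K <- nrow(reference)
  out <- matrix(NA_real_, nrow(bm), K,
                dimnames = list(rownames(bm), rownames(reference)))
  resid <- numeric(nrow(bm))
  for (i in seq_len(nrow(bm))) {
    y <- bm[i, cpg_ids]
    keep <- !is.na(y)
    if (sum(keep) < K) abort(paste0("too few non-missing reference CpGs for sample ",
                                    rownames(bm)[i]))
    Ai <- A[keep, , drop = FALSE]
    yi <- y[keep]
    pi_hat <- pracma::lsqnonneg(Ai, yi)$x
    if (sum(pi_hat) > 1 + 1e-8) {
      big <- 1e6
      pi_hat <- pracma::lsqnonneg(rbind(Ai, rep(big, K)), c(yi, big))$x
      if (sum(pi_hat) > 1) pi_hat <- pi_hat / sum(pi_hat)
    }
    out[i, ] <- pi_hat
    resid[i] <- sqrt(sum((drop(Ai %*% pi_hat) - yi)^2))
  }
  res <- as_tibble(out)
  res <- tibble(sample_id = rownames(bm), res, residual = resid)
  res
}

as_reference_matrix <- function(reference) {
  m <- as.matrix(reference)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("reference profiles need cell-type rownames and CpG colnames")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate cell-type labels")
  v <- m[!is.na(m)]
  if (min(v) < 0 || max(v) > 1) abort("reference beta values must lie in [0,1]")
  m
}

#' Read / write reference cell-type profiles
#'
#' Tab-delimited, rows = cell types (first column `cell_type`), columns =
#' CpG ids.
#'
#' @param path File path.
#' @return For the reader, a cell types x CpGs matrix.
#' @export
read_reference_profiles <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_reference_matrix(m)
}

#' @rdname read_reference_profiles
#' @param reference Cell types x CpGs matrix.
#' @export
write_reference_profiles <- function(reference, path) {
  df <- data.frame(cell_type = rownames(reference), reference,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write estimated cell proportions
#' @param proportions Tibble from [estimate_cell_proportions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_proportions <- function(proportions, path) {
  utils::write.table(as.data.frame(proportions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
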