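default_ewas_covariates <- c("sex", "maternal_smoking", "maternal_age",
                             "design_flag", "caesarean")

#' Epigenome-wide association scan of methylation on gestational age
#'
#' Runs one MM-type robust linear regression per CpG with the probe's beta
#' values as outcome and gestational age (GA, days) as the exposure, adjusted
#' for phenotype covariates and, when supplied, estimated cell-type
#' proportions. Reported per probe: the GA coefficient (beta units per day),
#' its robust standard error, the raw two-sided p-value, the
#' Bonferroni-adjusted p-value and the Benjamini-Hochberg q-value (both over
#' the number of probes actually tested), and a convergence flag.
#'
#' Samples with missing GA or covariates are dropped (a message reports the
#' count). Probes with missing beta values are median-imputed; probes constant
#' across the usable samples are skipped with undefined results. One
#' cell-proportion column is dropped from the design to avoid the sum-to-one
#' collinearity with the intercept.
#'
#' @param bm Beta matrix, samples x CpGs.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param proportions Optional tibble from [estimate_cell_proportions()]
#'   (`sample_id` plus one column per cell type; a `residual` column is
#'   ignored). `NULL` fits the unadjusted-for-composition model.
#' @param ga_column `"ga_ultrasound"` or `"ga_lmp"`.
#' @param covariates Character vector of sample-sheet columns entered as
#'   adjustment covariates.
#' @param alpha Family-wise level recorded alongside the results.
#' @param control [mm_control()] settings of the per-probe robust fits.
#' @return A tibble of class `ewas_results`: `cpg_id`, `estimate`,
#'   `std_error`, `p_raw`, `p_bonferroni`, `q_fdr`, `converged`, with
#'   attributes `n_used`, `n_dropped`, `n_tested` and `alpha`.
#' @export
run_ewas <- function(bm, sheet, proportions = NULL,
                     ga_column = c("ga_ultrasound", "ga_lmp"),
                     covariates = default_ewas_covariates,
                     alpha = 0.05, control = mm_control()) {
  ga_column <- match.arg(ga_column)
  validate_beta_matrix(bm)
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(rownames(bm), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) abort("sample sheet does not cover all beta-matrix samples")

  design <- cbind(`(Intercept)` = 1, ga = sheet[[ga_column]])
  colnames(design)[2] <- ga_column
  for (cv in covariates) {
    if (!cv %in% names(sheet)) abort(paste0("covariate not in sample sheet: ", cv))
    design <- cbind(design, sheet[[cv]])
    colnames(design)[ncol(design)] <- cv
  }
  if (!is.null(proportions)) {
    pm <- as.data.frame(proportions)
    rownames(pm) <- pm$sample_id
    pm <- pm[rownames(bm), setdiff(names(pm), c("sample_id", "residual")), drop = FALSE]
    if (anyNA(pm)) abort("proportions do not cover all beta-matrix samples")
    # drop one cell type: the proportions sum to (at most) one
    pm <- pm[, -ncol(pm), drop = FALSE]
    design <- cbind(design, as.matrix(pm))
  }

  usable <- stats::complete.cases(design)
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(sprintf("run_ewas: dropping %d sample(s) with missing GA or covariates", n_dropped))
  }
  X <- design[usable, , drop = FALSE]
  if (nrow(X) < ncol(X) + 5) {
    abort(sprintf("too few usable samples (%d) for %d regressors", nrow(X), ncol(X)))
  }
  Y <- bm[usable, , drop = FALSE]
  if (anyNA(Y)) Y <- median_impute(Y)

  prep <- mm_prepare(X, control)
  m <- ncol(Y)
  estimate <- std_error <- p_raw <- rep(NA_real_, m)
  converged <- rep(NA, m)
  for (j in seq_len(m)) {
    yj <- Y[, j]
    if (sd(yj) == 0) next  # constant probe: skipped, undefined p-value
    fit <- mm_fit_prepared(yj, prep, control)
    estimate[j] <- fit$coefficients[[ga_column]]
    std_error[j] <- fit$std_error[[ga_column]]
    p_raw[j] <- fit$p_value[[ga_column]]
    converged[j] <- fit$converged
  }

  res <- tibble(
    cpg_id = colnames(Y),
    estimate = estimate,
    std_error = std_error,
    p_raw = p_raw,
    p_bonferroni = adjust_pvalues(p_raw, "bonferroni"),
    q_fdr = adjust_pvalues(p_raw, "BH"),
    converged = converged
  )
  structure(res,
            class = c("ewas_results", class(res)),
            n_used = nrow(X), n_dropped = n_dropped,
            n_tested = sum(!is.na(p_raw)), alpha = alpha,
            ga_column = ga_column)
}

#' Multiple-testing adjustment of p-values
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up q-values with
#' enforced monotonicity. Undefined (`NA`) entries are excluded from the test
#' count `m` and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param method `"bonferroni"` or `"BH"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = method)
  out
}

#' Select significant CpGs from EWAS results
#'
#' @param res An `ewas_results` tibble.
#' @param criterion Adjusted column to threshold: `"p_bonferroni"` or
#'   `"q_fdr"`.
#' @param alpha Significance level (adjusted value strictly below `alpha`).
#' @return A tibble `cpg_id`, `estimate`, `direction`
#'   (`"increased"`/`"decreased"` methylation with GA), sorted by adjusted
#'   value.
#' @export
select_significant <- function(res, criterion = c("p_bonferroni", "q_fdr"),
                               alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (!criterion %in% names(res)) abort(paste0("column not present: ", criterion))
  hit <- !is.na(res[[criterion]]) & res[[criterion]] < alpha
  out <- res[hit, c("cpg_id", "estimate", criterion)]
  out$direction <- ifelse(out$estimate > 0, "increased", "decreased")
  out[order(out[[criterion]], out$cpg_id), ]
}

#' Write EWAS results to a tab-delimited file
#' @param res An `ewas_results` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ewas_results <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Volcano plot of EWAS results
#'
#' @param object An `ewas_results` tibble.
#' @param alpha Family-wise level drawn as the Bonferroni threshold line.
#' @param ... Unused.
#' @return A ggplot object: per-day effect estimate against -log10 raw
#'   p-value, Bonferroni-significant probes highlighted.
#' @export
autoplot.ewas_results <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(object, !is.na(.data$p_raw))
  df$significant <- !is.na(df$p_bonferroni) & df$p_bonferroni < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(pmax(.data$p_raw, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "GA effect (beta units / day)",
                  y = expression(-log[10](p)),
                  colour = "Bonferroni hit") +
    ggplot2::theme_minimal()
}
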