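#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation proportions with
#' samples as rows and CpG probes as columns; `NA` entries mark missing
#' measurements. All non-missing values must lie in `[0, 1]` and both id sets
#' must be unique.
#'
#' @param bm Numeric matrix, samples x CpGs, with `rownames` = sample ids and
#'   `colnames` = CpG ids.
#' @return `bm`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(bm) {
  if (!is.matrix(bm) || !is.numeric(bm)) {
    abort("beta matrix must be a numeric matrix (samples x CpGs)")
  }
  if (is.null(rownames(bm)) || is.null(colnames(bm))) {
    abort("beta matrix must carry sample ids (rownames) and CpG ids (colnames)")
  }
  if (anyDuplicated(rownames(bm))) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(rownames(bm)[duplicated(rownames(bm))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(bm))) {
    abort(paste0("duplicate CpG ids: ",
                 paste(unique(colnames(bm)[duplicated(colnames(bm))]), collapse = ", ")))
  }
  v <- bm[!is.na(bm)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    abort("value out of [0,1] in beta matrix")
  }
  invisible(bm)
}

#' Read a beta-value matrix from a delimited file
#'
#' The on-disk convention of 450K-style exports is CpGs as rows and samples as
#' columns; the in-memory canonical form is always samples x CpGs. The
#' `orientation` flag declares how the file is laid out. Missing values are the
#' literal `NA` (empty fields are also accepted).
#'
#' @param path Path to a tab-delimited table with one header row of ids and one
#'   leading id column.
#' @param orientation `"cpgs_as_rows"` (default, the on-disk convention) or
#'   `"samples_as_rows"`.
#' @return A validated numeric matrix, samples x CpGs.
#' @export
read_beta_matrix <- function(path, orientation = c("cpgs_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      na.strings = c("NA", ""), stringsAsFactors = FALSE),
    error = function(e) abort(paste0("failed to parse ", path, ": ", conditionMessage(e)))
  )
  if (ncol(df) < 2) abort(paste0("malformed file ", path, ": need an id column plus data columns"))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    abort(paste0("malformed file ", path, ": non-numeric data in column '",
                 names(df)[-1][bad], "'"))
  }
  rownames(m) <- ids
  if (orientation == "cpgs_as_rows") m <- t(m)
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix to a delimited file
#'
#' @param bm Beta matrix, samples x CpGs.
#' @param path Output path (tab-delimited).
#' @param orientation File layout; see [read_beta_matrix()].
#' @param digits Decimal digits kept on disk (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path,
                              orientation = c("cpgs_as_rows", "samples_as_rows"),
                              digits = 6) {
  orientation <- match.arg(orientation)
  validate_beta_matrix(bm)
  out <- if (orientation == "cpgs_as_rows") t(bm) else bm
  df <- data.frame(id = rownames(out), round(out, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (orientation == "cpgs_as_rows") "cpg_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ss_required_cols <- c("sample_id", "ga_ultrasound", "ga_lmp", "sex",
                      "maternal_smoking", "maternal_age", "caesarean",
                      "design_flag", "batch")

#' Validate a sample sheet
#'
#' @param sheet Data frame of per-sample phenotypes. Required columns:
#'   `sample_id`, `ga_ultrasound` and `ga_lmp` (days, `NA` allowed), binary
#'   `sex`, `maternal_smoking`, `caesarean`, `design_flag`, numeric
#'   `maternal_age` (years) and a `batch` label.
#' @param ga_range Plausible range (days) for non-missing gestational ages.
#' @return The sheet as a tibble, invisibly.
#' @export
validate_sample_sheet <- function(sheet, ga_range = c(150, 320)) {
  miss <- setdiff(ss_required_cols, names(sheet))
  if (length(miss)) abort(paste0("sample sheet missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample_id in sample sheet")
  for (col in c("ga_ultrasound", "ga_lmp")) {
    v <- sheet[[col]]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < ga_range[1] || max(v) > ga_range[2])) {
      abort(paste0(col, " outside plausible range [", ga_range[1], ", ", ga_range[2], "] days"))
    }
  }
  for (col in c("sex", "maternal_smoking", "caesarean", "design_flag")) {
    v <- sheet[[col]]
    if (!all(is.na(v) | v %in% c(0, 1))) abort(paste0(col, " must be binary (0/1)"))
  }
  invisible(as_tibble(sheet))
}

#' Read a sample sheet
#'
#' @inheritParams validate_sample_sheet
#' @param path Tab-delimited file with the columns listed in
#'   [validate_sample_sheet()].
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path, ga_range = c(150, 320)) {
  df <- utils::read.delim(path, sep = "\t", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$batch <- as.character(df$batch)
  validate_sample_sheet(df, ga_range)
  as_tibble(df)
}

#' Write a sample sheet
#' @param sheet Sample-sheet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CpG annotation table
#'
#' Columns: `cpg_id`, `chromosome` (1-22, X, Y; 1-based coordinates),
#' `position`, `genes` (semicolon-separated symbols, possibly empty) and
#' `is_control` (0/1).
#'
#' @param path Tab-delimited annotation file.
#' @return A tibble, one row per probe.
#' @export
read_cpg_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", na.strings = c("NA"),
                          stringsAsFactors = FALSE,
                          colClasses = c(genes = "character"))
  validate_cpg_annotation(df)
}

#' Validate a CpG annotation table
#' @param ann Data frame with the columns of [read_cpg_annotation()].
#' @return The annotation as a tibble.
#' @export
validate_cpg_annotation <- function(ann) {
  miss <- setdiff(c("cpg_id", "chromosome", "position", "genes", "is_control"), names(ann))
  if (length(miss)) abort(paste0("annotation missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(ann$cpg_id)) abort("duplicate cpg_id in annotation")
  if (any(ann$position < 1, na.rm = TRUE)) abort("annotation positions must be >= 1")
  ann$genes[is.na(ann$genes)] <- ""
  as_tibble(ann)
}

#' Drop sex-chromosome and control probes
#'
#' Restricts a beta matrix to autosomal, non-control probes, preserving probe
#' order. Probes on the X and Y chromosomes are removed because their
#' methylation tracks child sex rather than gestational age.
#'
#' @param bm Beta matrix, samples x CpGs.
#' @param ann CpG annotation covering every probe in `bm`.
#' @return The filtered beta matrix.
#' @export
filter_probes <- function(bm, ann) {
  validate_beta_matrix(bm)
  missing_ids <- setdiff(colnames(bm), ann$cpg_id)
  if (length(missing_ids)) {
    abort(paste0("probes missing from annotation: ",
                 paste(head(missing_ids, 10), collapse = ", "),
                 if (length(missing_ids) > 10) sprintf(" (and %d more)", length(missing_ids) - 10) else ""))
  }
  ann <- ann[match(colnames(bm), ann$cpg_id), ]
  keep <- !(ann$chromosome %in% c("X", "Y")) & ann$is_control == 0
  bm[, keep, drop = FALSE]
}

#' Median imputation of missing beta values
#'
#' Replaces each missing entry by the median of the non-missing values of its
#' CpG across samples (per-probe imputation; even-count medians average the
#' middle two values). Penalized-regression training cannot handle missing
#' values, so run this before [train_clock()].
#'
#' @param bm Beta matrix, samples x CpGs.
#' @return The imputed beta matrix.
#' @export
median_impute <- function(bm) {
  validate_beta_matrix(bm)
  nmiss <- colSums(is.na(bm))
  if (!any(nmiss > 0)) return(bm)
  full <- colSums(!is.na(bm))
  if (any(full == 0)) {
    abort(paste0("CpG(s) with all values missing: ",
                 paste(head(colnames(bm)[full == 0], 10), collapse = ", ")))
  }
  for (j in which(nmiss > 0)) {
    v <- bm[, j]
    bm[is.na(v), j] <- median(v, na.rm = TRUE)
  }
  bm
}
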