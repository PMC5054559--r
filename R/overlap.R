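as_cpg_ids <- function(x) {
  ids <- if (inherits(x, "clock_model")) {
    names(x$weights)
  } else if (is.data.frame(x) && "cpg_id" %in% names(x)) {
    x$cpg_id
  } else {
    as.character(x)
  }
  unique(ids)
}

#' Exact set arithmetic over two CpG sets
#'
#' @param a,b CpG id vectors; also accepts a `clock_model` (its weighted
#'   CpGs) or any data frame with a `cpg_id` column. Duplicates are removed.
#' @param label_a,label_b Labels carried into the report.
#' @return A one-row tibble: `label_a`, `label_b`, `n_a`, `n_b`,
#'   `n_intersect`, `n_union`, `n_only_a`, `n_only_b`. The identities
#'   `n_union = n_a + n_b - n_intersect`, `n_only_a = n_a - n_intersect` and
#'   `n_only_b = n_b - n_intersect` hold by construction and are asserted.
#' @export
compare_sets <- function(a, b, label_a = "A", label_b = "B") {
  a <- as_cpg_ids(a)
  b <- as_cpg_ids(b)
  n_int <- length(intersect(a, b))
  rep <- tibble(label_a = label_a, label_b = label_b,
                n_a = length(a), n_b = length(b),
                n_intersect = n_int,
                n_union = length(union(a, b)),
                n_only_a = length(setdiff(a, b)),
                n_only_b = length(setdiff(b, a)))
  stopifnot(rep$n_union == rep$n_a + rep$n_b - rep$n_intersect,
            rep$n_only_a == rep$n_a - rep$n_intersect,
            rep$n_only_b == rep$n_b - rep$n_intersect)
  rep
}

#' Map CpG ids to gene symbols
#'
#' Splits the annotation's semicolon-separated gene lists, strips
#' whitespace, deduplicates, and returns the union (case-sensitive
#' comparison; empty annotations contribute nothing). CpGs absent from the
#' annotation are skipped with a message.
#'
#' @param ids CpG ids (or a `clock_model` / data frame, as in
#'   [compare_sets()]).
#' @param ann CpG annotation tibble (see [read_cpg_annotation()]).
#' @return Sorted character vector of unique gene symbols.
#' @export
map_cpgs_to_genes <- function(ids, ann) {
  ids <- as_cpg_ids(ids)
  hit <- match(ids, ann$cpg_id)
  if (anyNA(hit)) {
    message(sprintf("map_cpgs_to_genes: %d id(s) not in annotation, skipped",
                    sum(is.na(hit))))
  }
  genes <- ann$genes[hit[!is.na(hit)]]
  genes <- unlist(strsplit(genes, ";", fixed = TRUE))
  genes <- trimws(genes)
  sort(unique(genes[genes != ""]))
}

#' Read an external CpG list
#'
#' Plain text, one CpG id per line, optional second tab-separated gene
#' column.
#'
#' @param path File path.
#' @return A tibble `cpg_id` (and `gene` when present).
#' @export
read_cpg_list <- function(path) {
  lines <- tryCatch(readLines(path), error = function(e) {
    abort(paste0("cannot read CpG list ", path, ": ", conditionMessage(e)))
  })
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t")
  out <- tibble(cpg_id = vapply(parts, `[`, "", 1))
  if (any(lengths(parts) > 1)) {
    out$gene <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  }
  if (anyDuplicated(out$cpg_id)) out <- out[!duplicated(out$cpg_id), ]
  out
}

#' Compare a clock or CpG set with an external study list
#'
#' Reads the external list and delegates to [compare_sets()]; with an
#' annotation, adds gene-level counts and `n_not_mappable` -- external
#' probes absent from the annotation (e.g. assayed on another platform),
#' reported rather than silently dropped.
#'
#' @param x A `clock_model`, CpG id vector, or data frame with `cpg_id`.
#' @param external_file Path to the external list (see [read_cpg_list()]).
#' @param ann Optional CpG annotation for gene-level counts.
#' @param label Label of `x` in the report.
#' @return A one-row tibble: the [compare_sets()] columns, plus
#'   `n_genes_a`, `n_genes_b`, `n_genes_intersect` and `n_not_mappable`
#'   when an annotation is supplied.
#' @export
compare_with_external_list <- function(x, external_file, ann = NULL,
                                       label = "model") {
  ext <- read_cpg_list(external_file)
  rep <- compare_sets(x, ext$cpg_id, label_a = label,
                      label_b = basename(external_file))
  if (!is.null(ann)) {
    ga <- map_cpgs_to_genes(x, ann)
    gb <- suppressMessages(map_cpgs_to_genes(ext$cpg_id, ann))
    rep$n_genes_a <- length(ga)
    rep$n_genes_b <- length(gb)
    rep$n_genes_intersect <- length(intersect(ga, gb))
    rep$n_not_mappable <- sum(!ext$cpg_id %in% ann$cpg_id)
  }
  rep
}
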