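test_that("overlap identities hold exactly on all subsets of a small universe", {
  universe <- letters[1:6]
  subsets <- lapply(0:63, function(k) universe[bitwAnd(k, 2^(0:5)) > 0])
  for (a in subsets[seq(1, 64, by = 7)]) {
    for (b in subsets) {
      rep <- compare_sets(a, b)
      expect_identical(rep$n_union, rep$n_a + rep$n_b - rep$n_intersect)
      expect_identical(rep$n_only_a, rep$n_a - rep$n_intersect)
      expect_identical(rep$n_only_b, rep$n_b - rep$n_intersect)
      expect_identical(rep$n_intersect, length(intersect(a, b)))
    }
  }
})

test_that("identical sets give full intersection and no uniques", {
  a <- paste0("cg", 1:10)
  rep <- compare_sets(a, a)
  expect_identical(rep$n_intersect, 10L)
  expect_identical(rep$n_union, 10L)
  expect_identical(rep$n_only_a, 0L)
  expect_identical(rep$n_only_b, 0L)
  # duplicates are removed before counting
  expect_identical(compare_sets(c(a, a), a)$n_a, 10L)
})

test_that("gene mapping splits, strips, deduplicates and skips unannotated", {
  ann <- tibble::tibble(cpg_id = c("cg1", "cg2", "cg3"),
                        chromosome = "1", position = 1:3,
                        genes = c("GENEA;GENEB", "GENEB", ""),
                        is_control = 0L)
  expect_identical(map_cpgs_to_genes(c("cg1", "cg2"), ann),
                   c("GENEA", "GENEB"))
  expect_identical(map_cpgs_to_genes("cg3", ann), character(0))
  expect_message(out <- map_cpgs_to_genes(c("cg1", "cg_missing"), ann),
                 "not in annotation")
  expect_identical(out, c("GENEA", "GENEB"))
  # idempotent and order-invariant
  expect_identical(map_cpgs_to_genes(c("cg2", "cg1"), ann),
                   map_cpgs_to_genes(c("cg1", "cg2"), ann))
})

test_that("gene counts are subadditive over random annotated sets", {
  set.seed(1234)
  universe <- sprintf("cg%04d", 1:200)
  gene_pool <- sprintf("GENE%02d", 1:40)
  ann <- tibble::tibble(
    cpg_id = universe, chromosome = "1", position = seq_along(universe),
    genes = vapply(universe, function(x) {
      paste(sample(gene_pool, sample(0:3, 1)), collapse = ";")
    }, ""),
    is_control = 0L)
  for (r in 1:10) {
    a <- id_set(30, universe)
    b <- id_set(40, universe)
    ga <- map_cpgs_to_genes(a, ann)
    gb <- map_cpgs_to_genes(b, ann)
    gu <- map_cpgs_to_genes(union(a, b), ann)
    expect_lte(length(gu), length(ga) + length(gb))
    expect_identical(sort(gu), sort(union(ga, gb)))
  }
})

test_that("external-list comparison reports overlap and unmappable probes", {
  universe <- sprintf("cg%05d", 1:1000)
  set.seed(99)
  model_ids <- universe[1:131]
  shared <- model_ids[1:26]
  external <- c(shared, universe[500:733])  # 26 + 234 = 260 ids
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(external, path)
  rep <- compare_with_external_list(model_ids, path)
  expect_identical(rep$n_a, 131L)
  expect_identical(rep$n_b, 260L)
  expect_identical(rep$n_intersect, 26L)

  # disjoint and identical boundary cases
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(universe[900:950], path2)
  expect_identical(compare_with_external_list(model_ids, path2)$n_intersect, 0L)
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(model_ids, path3)
  expect_identical(compare_with_external_list(model_ids, path3)$n_intersect, 131L)

  # platform mismatch: ids missing from the annotation are counted, not dropped
  ann <- tibble::tibble(cpg_id = universe[1:600], chromosome = "1",
                        position = 1:600, genes = "", is_control = 0L)
  rep2 <- suppressMessages(compare_with_external_list(model_ids, path, ann))
  expect_identical(rep2$n_not_mappable, sum(!external %in% ann$cpg_id))
  suppressWarnings(
    expect_error(compare_with_external_list(model_ids, "no/such/file.txt"),
                 "cannot read"))
})

test_that("clock models and tibbles are accepted as set inputs", {
  model <- structure(list(intercept = 280, weights = c(cg1 = 1, cg2 = -2),
                          alpha = 1, lambda = 1, lambda_rule = "lambda_1se",
                          cv_scheme = "loo", seed = 1999, n_train = 30,
                          n_cpgs_universe = 5, cv = NULL),
                     class = "clock_model")
  rep <- compare_sets(model, c("cg2", "cg3"))
  expect_identical(rep$n_intersect, 1L)
  tib <- tibble::tibble(cpg_id = c("cg1", "cg4"))
  expect_identical(compare_sets(model, tib)$n_intersect, 1L)
})
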