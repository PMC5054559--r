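#' Run the full two-batch clock pipeline on synthetic data
#'
#' Executes the complete study design end to end: simulate a two-batch
#' cohort, estimate cell-type proportions on the training batch, run the
#' robust EWAS for both GA definitions, train clocks on batch 1 (unscreened
#' by default; optionally screened on the Bonferroni-significant CpGs),
#' predict batch 2, evaluate each clock against its own GA definition, and
#' compare the two clocks' CpG sets. All stage outputs are written to
#' `outdir` as tab-delimited text together with a JSON manifest (package
#' version, configuration, seeds, per-file MD5 hashes); reruns with the same
#' configuration are bit-identical, so every artifact is re-derivable from
#' the manifest alone.
#'
#' @param cfg A [simulation_config()]; its `seed` drives every random draw.
#' @param outdir Output directory (created if needed).
#' @param screen Also train Bonferroni-screened clocks (slower; default
#'   `FALSE`).
#' @param ewas_alpha Significance level for screening/selection.
#' @param control [mm_control()] settings shared by all robust fits.
#' @return Invisibly, a list: `cohort`, `proportions`, `ewas` (per GA
#'   definition), `clocks`, `predictions`, `evaluations`, `comparison`,
#'   `overlap`, `manifest_path`.
#' @export
run_pipeline <- function(cfg = simulation_config(), outdir,
                         screen = FALSE, ewas_alpha = 0.05,
                         control = mm_control()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  reference <- step("reference", generate_reference_profiles(
    cfg$n_celltypes, cfg$n_cpgs, seed = cfg$seed))
  cohort <- step("simulate", generate_cohort(cfg, reference))
  write_cohort(cohort, outdir)
  write_reference_profiles(reference, file.path(outdir, "reference_profiles.tsv"))

  b1 <- cohort_batch(cohort, "batch1")
  b2 <- cohort_batch(cohort, "batch2")

  proportions <- step("celltype", estimate_cell_proportions(b1$beta, reference))
  write_cell_proportions(proportions, file.path(outdir, "cell_proportions.tsv"))

  ewas <- list()
  for (ga in c("ga_ultrasound", "ga_lmp")) {
    ewas[[ga]] <- step(paste0("ewas_", ga), suppressMessages(
      run_ewas(b1$beta, b1$sheet, proportions, ga_column = ga,
               alpha = ewas_alpha, control = control)))
    write_ewas_results(ewas[[ga]], file.path(outdir, paste0("ewas_", ga, ".tsv")))
  }

  clocks <- list()
  predictions <- list()
  evaluations <- list()
  beta2 <- median_impute(b2$beta)
  for (ga in c("ga_ultrasound", "ga_lmp")) {
    keep <- !is.na(b1$sheet[[ga]])
    clocks[[ga]] <- step(paste0("train_", ga), train_clock(
      median_impute(b1$beta[keep, , drop = FALSE]),
      b1$sheet[[ga]][keep], seed = cfg$seed))
    write_clock_model(clocks[[ga]], file.path(outdir, paste0("clock_", ga, ".tsv")))
    if (screen) {
      clocks[[paste0(ga, "_screened")]] <- step(paste0("train_screened_", ga),
        screen_then_train(median_impute(b1$beta[keep, , drop = FALSE]),
                          b1$sheet[[ga]][keep], ewas[[ga]],
                          criterion = "p_bonferroni", alpha_level = ewas_alpha,
                          seed = cfg$seed))
      write_clock_model(clocks[[paste0(ga, "_screened")]],
                        file.path(outdir, paste0("clock_", ga, "_screened.tsv")))
    }
    predictions[[ga]] <- step(paste0("predict_", ga),
                              predict_ga(clocks[[ga]], beta2))
    utils::write.table(as.data.frame(predictions[[ga]]),
                       file.path(outdir, paste0("predictions_", ga, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    obs <- b2$sheet[[ga]][match(predictions[[ga]]$sample_id, b2$sheet$sample_id)]
    evaluations[[ga]] <- step(paste0("evaluate_", ga), evaluate_predictions(
      obs, predictions[[ga]]$ga_predicted,
      ga_definition = sub("ga_", "", ga), allow_degenerate = TRUE,
      control = control))
  }
  comparison <- compare_ga_definitions(evaluations$ga_ultrasound,
                                       evaluations$ga_lmp)
  write_evaluation(comparison, file.path(outdir, "evaluation.tsv"))

  overlap <- compare_sets(clocks$ga_ultrasound, clocks$ga_lmp,
                          label_a = "ultrasound_clock", label_b = "lmp_clock")
  utils::write.table(as.data.frame(overlap),
                     file.path(outdir, "clock_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "gestclock",
    version = as.character(utils::packageVersion("gestclock")),
    seed = cfg$seed,
    config = unclass(cfg),
    more_precise = attr(comparison, "more_precise"),
    files = setNames(as.list(unname(tools::md5sum(file.path(outdir, files)))),
                     files))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, proportions = proportions, ewas = ewas,
                 clocks = clocks, predictions = predictions,
                 evaluations = evaluations, comparison = comparison,
                 overlap = overlap, manifest_path = manifest_path))
}
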