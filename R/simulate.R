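# beta <-> M-value maps. M = log2(beta / (1 - beta)); beta = 2^M / (1 + 2^M).

beta_to_m <- function(b) log2(b / (1 - b))
m_to_beta <- function(m) 1 / (1 + 2^(-m))

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic two-batch cohort
#'
#' Defaults emulate a scaled-down two-batch cord-blood 450K study: a training
#' batch and a smaller replication batch, gestational age (GA) around 279.6
#' days (sd 11) by the ultrasound-like definition, an LMP-like definition
#' offset by +2.7 days with 7 days of extra noise, six leukocyte-like cell
#' types mixed per sample from a Dirichlet, and a small set of CpGs whose
#' M-values drift linearly with GA.
#'
#' @param n_samples_batch1,n_samples_batch2 Samples per batch.
#' @param n_cpgs Number of probes simulated.
#' @param n_causal Number of GA-associated probes.
#' @param ga_mean,ga_sd Mean / sd (days) of the latent GA, truncated to
#'   `[210, 300]` days.
#' @param lmp_offset_mean,lmp_noise_sd Mean shift and extra noise (days) of
#'   the LMP-like GA relative to the latent (ultrasound-like) GA.
#' @param effect_sd Scale of the planted per-day slopes (M-value units per
#'   day); slope magnitudes are drawn uniformly from
#'   `[0.8, 1.2] * effect_sd` with random sign, so every causal probe carries
#'   a real effect.
#' @param noise_sd Residual probe noise, M-value units.
#' @param n_celltypes Number of reference cell types.
#' @param dirichlet_concentration Dirichlet concentration of the per-sample
#'   cell mixtures (recycled to `n_celltypes`).
#' @param batch_shift Constant M-value shift applied to batch-2 samples
#'   (default 0: matrices are assumed batch-corrected upstream).
#' @param covariate_effect_sds Named sds (M-value units) of per-probe
#'   covariate coefficients.
#' @param ga_missing_rate_ultrasound,ga_missing_rate_lmp Fractions of samples
#'   with the GA label masked to `NA`.
#' @param seed Global seed; per-sample draws use a hierarchical stream so
#'   enlarging a batch does not reshuffle earlier samples.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples_batch1 = 300,
                              n_samples_batch2 = 150,
                              n_cpgs = 2000,
                              n_causal = 20,
                              ga_mean = 279.6,
                              ga_sd = 11,
                              lmp_offset_mean = 2.7,
                              lmp_noise_sd = 7,
                              effect_sd = 0.01,
                              noise_sd = 0.15,
                              n_celltypes = 6,
                              dirichlet_concentration = c(6, 3, 2, 2, 1, 1),
                              batch_shift = 0,
                              covariate_effect_sds = c(sex = 0.02,
                                                       maternal_smoking = 0.02,
                                                       maternal_age = 0.002,
                                                       caesarean = 0.02,
                                                       design_flag = 0.02),
                              ga_missing_rate_ultrasound = 0.02,
                              ga_missing_rate_lmp = 0.035,
                              seed = 1999) {
  cfg <- list(n_samples_batch1 = n_samples_batch1,
              n_samples_batch2 = n_samples_batch2,
              n_cpgs = n_cpgs, n_causal = n_causal,
              ga_mean = ga_mean, ga_sd = ga_sd,
              lmp_offset_mean = lmp_offset_mean, lmp_noise_sd = lmp_noise_sd,
              effect_sd = effect_sd, noise_sd = noise_sd,
              n_celltypes = n_celltypes,
              dirichlet_concentration =
                rep_len(dirichlet_concentration, n_celltypes),
              batch_shift = batch_shift,
              covariate_effect_sds = covariate_effect_sds,
              ga_missing_rate_ultrasound = ga_missing_rate_ultrasound,
              ga_missing_rate_lmp = ga_missing_rate_lmp,
              seed = seed)
  counts <- c(n_samples_batch1, n_samples_batch2, n_cpgs, n_celltypes)
  if (any(counts < 1)) abort("all counts must be >= 1")
  if (n_causal < 0 || n_causal > n_cpgs) abort("need 0 <= n_causal <= n_cpgs")
  sds <- c(ga_sd, lmp_noise_sd, effect_sd, noise_sd, covariate_effect_sds)
  if (any(sds < 0)) abort("sd parameters must be >= 0")
  if (any(cfg$dirichlet_concentration <= 0)) abort("Dirichlet concentration must be > 0")
  structure(cfg, class = "simulation_config")
}

#' Generate synthetic reference cell-type beta profiles
#'
#' Each cell type receives a disjoint block of `n_markers_per_type` marker
#' CpGs where it is strongly methylated (beta in `[0.82, 0.95]`) while all
#' other types are weakly methylated (`[0.03, 0.18]`), guaranteeing a pairwise
#' between-type difference of at least 0.3 on every marker; the remaining
#' probes share a common baseline with small per-type jitter. All values lie
#' in `[0.02, 0.98]`.
#'
#' @param n_celltypes Number of cell types (>= 2).
#' @param n_cpgs Number of probes; must admit the disjoint marker blocks.
#' @param seed RNG seed (global RNG state is preserved).
#' @param n_markers_per_type Marker CpGs per cell type (default 50).
#' @return A cell types x CpGs matrix with attribute `marker_cpgs`, a named
#'   list of each type's marker ids.
#' @export
generate_reference_profiles <- function(n_celltypes, n_cpgs, seed = 1,
                                        n_markers_per_type = 50) {
  if (n_celltypes < 2) abort("need n_celltypes >= 2")
  if (n_cpgs < n_celltypes * n_markers_per_type) {
    abort(sprintf("n_cpgs too small: need >= %d for %d x %d marker blocks",
                  n_celltypes * n_markers_per_type, n_celltypes, n_markers_per_type))
  }
  with_seed(seed, {
    cpg_ids <- sprintf("cg%08d", seq_len(n_cpgs))
    types <- paste0("celltype", seq_len(n_celltypes))
    baseline <- runif(n_cpgs, 0.15, 0.85)
    ref <- matrix(NA_real_, n_celltypes, n_cpgs, dimnames = list(types, cpg_ids))
    for (t in seq_len(n_celltypes)) {
      ref[t, ] <- pmin(pmax(baseline + rnorm(n_cpgs, 0, 0.02), 0.02), 0.98)
    }
    marker_idx <- matrix(sample.int(n_cpgs, n_celltypes * n_markers_per_type),
                         nrow = n_celltypes)
    markers <- list()
    for (t in seq_len(n_celltypes)) {
      idx <- marker_idx[t, ]
      ref[t, idx] <- runif(n_markers_per_type, 0.82, 0.95)
      ref[-t, idx] <- runif((n_celltypes - 1) * n_markers_per_type, 0.03, 0.18)
      markers[[types[t]]] <- cpg_ids[idx]
    }
    structure(ref, marker_cpgs = markers)
  })
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# 32-bit-safe deterministic per-sample seed derived from the global seed.
sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483629)
}

#' Generate a synthetic two-batch cohort
#'
#' Builds beta values on the M-value scale as: cell-type mixture baseline
#' (the sample's Dirichlet-weighted mixture of the reference profiles,
#' logit2-transformed) + planted slope x (GA - ga_mean) on causal probes +
#' per-probe covariate effects + `batch_shift` for batch-2 samples +
#' Gaussian noise, then mapped back to beta, which keeps every value strictly
#' inside (0, 1) without clipping. Causal probes are drawn outside the
#' reference marker blocks so the GA signal is not confounded with cell
#' composition. Per-sample draws use a hierarchical seed stream: enlarging a
#' batch leaves earlier samples' data bit-identical.
#'
#' @param cfg A [simulation_config()].
#' @param reference Reference profiles from [generate_reference_profiles()];
#'   must have exactly `cfg$n_cpgs` probes and `cfg$n_celltypes` types.
#' @return A list of class `ga_cohort`: `beta` (samples x CpGs matrix),
#'   `sheet` (sample-sheet tibble), and `truth` (list: `causal` tibble of
#'   `cpg_id`/`slope`, `proportions` tibble, `ga_latent` named vector,
#'   `covariate_effects` matrix).
#' @export
generate_cohort <- function(cfg, reference) {
  if (!inherits(cfg, "simulation_config")) abort("cfg must be a simulation_config")
  reference <- as_reference_matrix(reference)
  if (ncol(reference) != cfg$n_cpgs) {
    abort("reference must cover exactly the simulated CpGs (ncol == n_cpgs)")
  }
  if (nrow(reference) != cfg$n_celltypes) {
    abort("reference must have n_celltypes rows")
  }
  cpg_ids <- colnames(reference)
  covs <- names(cfg$covariate_effect_sds)

  # probe-level draws from the global stream
  globals <- with_seed(cfg$seed, {
    markers <- unique(unlist(attr(reference, "marker_cpgs", exact = TRUE)))
    eligible <- setdiff(cpg_ids, markers)
    if (length(eligible) < cfg$n_causal) eligible <- cpg_ids
    causal <- sort(sample(eligible, cfg$n_causal))
    slopes <- runif(cfg$n_causal, 0.8, 1.2) * cfg$effect_sd *
      sample(c(-1, 1), cfg$n_causal, replace = TRUE)
    cov_eff <- matrix(0, length(covs), cfg$n_cpgs,
                      dimnames = list(covs, cpg_ids))
    for (cv in covs) {
      cov_eff[cv, ] <- rnorm(cfg$n_cpgs, 0, cfg$covariate_effect_sds[[cv]])
    }
    list(causal = causal, slopes = slopes, cov_eff = cov_eff)
  })
  slope_full <- setNames(rep(0, cfg$n_cpgs), cpg_ids)
  slope_full[globals$causal] <- globals$slopes

  n <- cfg$n_samples_batch1 + cfg$n_samples_batch2
  batch <- rep(c("batch1", "batch2"),
               c(cfg$n_samples_batch1, cfg$n_samples_batch2))
  sample_ids <- sprintf("%s_s%04d", batch,
                        c(seq_len(cfg$n_samples_batch1),
                          seq_len(cfg$n_samples_batch2)))
  beta <- matrix(NA_real_, n, cfg$n_cpgs, dimnames = list(sample_ids, cpg_ids))
  props <- matrix(NA_real_, n, cfg$n_celltypes,
                  dimnames = list(sample_ids, rownames(reference)))
  sheet <- tibble(sample_id = sample_ids,
                  ga_ultrasound = NA_real_, ga_lmp = NA_real_,
                  sex = NA_real_, maternal_smoking = NA_real_,
                  maternal_age = NA_real_, caesarean = NA_real_,
                  design_flag = NA_real_, batch = batch)
  ga_latent <- setNames(numeric(n), sample_ids)

  for (i in seq_len(n)) {
    with_seed(sample_seed(cfg$seed, i), {
      ga <- rnorm(1, cfg$ga_mean, cfg$ga_sd)
      while (ga < 210 || ga > 300) ga <- rnorm(1, cfg$ga_mean, cfg$ga_sd)
      lmp <- ga + rnorm(1, cfg$lmp_offset_mean, cfg$lmp_noise_sd)
      lmp <- min(max(lmp, 210), 310)
      covv <- c(sex = rbinom(1, 1, 0.532),
                maternal_smoking = rbinom(1, 1, 0.146),
                maternal_age = rnorm(1, 29.9, 4.5),
                caesarean = rbinom(1, 1, 0.115),
                design_flag = rbinom(1, 1, 0.329))
      pi_i <- rdirichlet1(cfg$dirichlet_concentration)
      mix <- drop(pi_i %*% reference)
      m <- beta_to_m(mix) +
        slope_full * (ga - cfg$ga_mean) +
        drop(c(covv["sex"], covv["maternal_smoking"],
               covv["maternal_age"] - 29.9, covv["caesarean"],
               covv["design_flag"]) %*% globals$cov_eff) +
        (if (batch[i] == "batch2") cfg$batch_shift else 0) +
        rnorm(cfg$n_cpgs, 0, cfg$noise_sd)
      miss_us <- runif(1) < cfg$ga_missing_rate_ultrasound
      miss_lmp <- runif(1) < cfg$ga_missing_rate_lmp
      beta[i, ] <- m_to_beta(m)
      props[i, ] <- pi_i
      ga_latent[i] <- ga
      sheet$ga_ultrasound[i] <- if (miss_us) NA_real_ else ga
      sheet$ga_lmp[i] <- if (miss_lmp) NA_real_ else lmp
      sheet$sex[i] <- covv[["sex"]]
      sheet$maternal_smoking[i] <- covv[["maternal_smoking"]]
      sheet$maternal_age[i] <- covv[["maternal_age"]]
      sheet$caesarean[i] <- covv[["caesarean"]]
      sheet$design_flag[i] <- covv[["design_flag"]]
    })
  }

  truth <- list(
    causal = tibble(cpg_id = globals$causal, slope = globals$slopes),
    proportions = tibble(sample_id = sample_ids, as_tibble(props)),
    ga_latent = ga_latent,
    covariate_effects = globals$cov_eff
  )
  structure(list(beta = beta, sheet = sheet, truth = truth),
            class = "ga_cohort")
}

#' Split a cohort by batch
#' @param cohort A `ga_cohort`.
#' @param batch Batch label, e.g. `"batch1"`.
#' @return A list `beta`, `sheet` restricted to the batch.
#' @export
cohort_batch <- function(cohort, batch) {
  keep <- cohort$sheet$batch == batch
  list(beta = cohort$beta[cohort$sheet$sample_id[keep], , drop = FALSE],
       sheet = cohort$sheet[keep, ])
}

#' Write a cohort's standard files
#'
#' Writes the beta matrix, sample sheet, a minimal all-autosome annotation,
#' the truth file (`cpg_id`, `slope`) and the true cell proportions.
#'
#' @param cohort A `ga_cohort`.
#' @param dir Output directory (created if needed).
#' @param digits Beta-matrix precision on disk.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             sheet = file.path(dir, "sample_sheet.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth_slopes.tsv"),
             proportions = file.path(dir, "truth_proportions.tsv"))
  write_beta_matrix(cohort$beta, paths["beta"], digits = digits)
  write_sample_sheet(cohort$sheet, paths["sheet"])
  ann <- tibble(cpg_id = colnames(cohort$beta),
                chromosome = as.character(rep_len(1:22, ncol(cohort$beta))),
                position = seq_len(ncol(cohort$beta)) * 1000L,
                genes = "", is_control = 0L)
  utils::write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth$causal, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$truth$proportions), paths["proportions"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
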