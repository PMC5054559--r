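---
title: "Methods: building and evaluating gestational-age methylation clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating gestational-age methylation clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gestational age (GA) at birth is recorded by two imperfect definitions:
ultrasound dating around pregnancy week 18, and the maternally reported last
menstrual period (LMP). Cord-blood DNA methylation changes systematically
with gestation, so a sparse linear predictor over CpG beta values — a
*gestational-age clock* — can estimate GA directly from a methylation array.
`gestclock` implements the full construction and evaluation cycle for such
clocks: an epigenome-wide association scan (EWAS) with robust regression,
reference-based cell-type deconvolution, penalized-regression clock training
with cross-validated penalty selection, robust evaluation on a held-out
batch, and set arithmetic for comparing clocks between GA definitions and
with external studies. Because the motivating cohort data are not publicly
deposited, the package ships a first-class synthetic-cohort generator with a
recorded ground truth; every statistical property the package claims is
demonstrated on data whose truth is known.

# The synthetic two-batch cohort

`generate_cohort()` emulates a scaled-down two-batch cord-blood 450K study: a
training batch and a smaller replication batch measured on the same probes.
The generative model works on the M-value scale, `M = log2(beta/(1-beta))`,
because additive Gaussian effects on the bounded beta scale would leave the
unit interval; mapping `M` back through the inverse logit keeps every beta
strictly inside (0, 1) without clipping.

Per sample, the M-value of a probe is the sum of:

* a **cell-type mixture baseline**: Dirichlet-weighted mixture of reference
  cell-type beta profiles, logit2-transformed. Reference profiles come from
  `generate_reference_profiles()`, which plants a disjoint block of 50
  marker CpGs per cell type (high beta in the owning type, low in all
  others, pairwise contrast at least 0.3), mimicking the structure of a
  sorted-leukocyte reference panel;
* a **planted GA effect** `slope * (GA - 279.6)` on a small set of causal
  probes. Slope magnitudes are drawn uniformly from
  `[0.8, 1.2] * effect_sd` with random sign rather than from a Gaussian, so
  that in the strong-effect regime every causal probe carries a real,
  detectable effect and recovery statements ("at least 18 of 20 detected")
  do not hinge on lucky draws near zero;
* small **covariate effects** (child's sex, maternal smoking, maternal age,
  caesarean section, a design indicator), each with per-probe coefficients
  so that covariate-adjusted and unadjusted scans differ measurably;
* an optional constant **batch shift** for batch-2 samples (default 0; the
  package consumes matrices assumed already normalized and batch-corrected
  upstream);
* independent Gaussian **probe noise**.

Key defaults and their units: GA is drawn from Normal(279.6, 11) days
truncated to [210, 300]; the mean matches a term cohort and the standard
deviation is back-calculated from a cohort-scale 95% confidence half-width.
The LMP-like label equals the latent GA plus Normal(2.7, 7) days — a small
positive offset with substantial extra noise, which reproduces the
qualitative ordering that ultrasound-referenced evaluation is more precise
than LMP-referenced evaluation. Default sizes are 300 + 150 samples over
2000 probes with 20 causal probes, `effect_sd = 0.01` M-units/day and
`noise_sd = 0.15` M-units; at these settings a causal probe's correlation
with GA is about 0.6, strong but not trivial. A small fraction of GA labels
(2% ultrasound, 3.5% LMP) is masked to exercise missing-data paths.

Randomness is hierarchical: probe-level draws (causal set, slopes, covariate
coefficient matrices) come from the global seed, while each sample has its
own derived seed. Enlarging a batch therefore leaves earlier samples'
data bit-identical, and the whole cohort is reproducible from one integer.

What the generator does **not** emulate: probe-type chemistry, detection
p-values, spatial artefacts, genomic correlation between neighbouring CpGs,
and realistic effect-size distributions (which are unknowable without the
cohort data). Passing tests demonstrate correctness of the machinery under a
known truth, not performance claims about any real cohort.

# The robust EWAS

`run_ewas()` fits one MM-type robust linear regression per probe: the
probe's beta values (not M-values — fidelity to the established analysis
choice for this design) as outcome, GA in days as the exposure, and the
phenotype covariates plus estimated cell-type proportions as adjustments.
One proportion column is dropped to avoid the sum-to-one collinearity with
the intercept.

The MM estimator in `fit_mm_regression()` is authored in the package:

1. an initial high-breakdown **S-estimate**: candidate coefficient vectors
   from random elemental subsets (plus the OLS fit), scored by the bisquare
   M-scale of their residuals with tuning constant `c_s = 1.548` (50%
   breakdown), the best candidate refined by iteratively reweighted least
   squares;
2. an efficient **M-step**: IRLS with the bisquare psi at `c_m = 4.685`
   (95% Gaussian efficiency), holding the S-scale fixed, until the relative
   coefficient change falls below `tol` (default 1e-8, capped at 50
   iterations; non-convergence is flagged, not hidden).

The M-scale equation `mean(rho(r/s)) = 0.5` is solved by Newton iteration
with a fixed-point fallback. A fit whose M-scale is (near) zero — more than
half the points exactly on a hyperplane — is returned through a degenerate
path with `sigma = 0` and undefined p-values.

Standard errors use the asymptotic MM covariance
`sigma^2 * E[psi^2]/E[psi']^2 * (X'X)^-1` with the `n/(n-p)`
degrees-of-freedom and Huber small-sample corrections. P-values are
referred to the **t distribution on n − p degrees of freedom** rather than
the normal limit: at the package's working sample sizes (a few hundred
samples, around ten regressors) the normal reference is measurably
anticonservative for the family-wise error rate, while the t reference —
the convention of the standard robust-regression implementations — restores
calibration. Design subsets are drawn from a private seeded stream, so fits
are deterministic and never touch the global RNG; because the design matrix
is shared by every probe, the subset solvers are factorized once per scan.

Multiple testing: `adjust_pvalues()` offers Bonferroni (`min(1, m p)`) and
Benjamini–Hochberg step-up q-values, with `m` the number of probes actually
tested — constant probes are skipped with undefined p-values and excluded
from `m`. Bonferroni selections are always a subset of BH selections at the
same level. `select_significant()` thresholds strictly below `alpha` and
retains the effect sign so increased/decreased methylation can be reported.

# Cell-type deconvolution

`estimate_cell_proportions()` solves, per sample, the constrained
least-squares projection of the sample's beta values on reference cell-type
profiles: minimize `||W' pi - y||^2` subject to `pi >= 0` and
`sum(pi) <= 1`. The inequality form follows the original
constrained-projection formulation; `1 - sum(pi)` is reported as an
unexplained fraction. The solver is exact two-phase non-negative least
squares: plain NNLS first (if the sum constraint is slack, the KKT
conditions are already met), otherwise the sum constraint is active and the
equality-constrained problem is solved through a heavily weighted sum row.
Tests verify the solution dominates an exhaustive 0.01-step simplex grid.
Deconvolution uses the discriminating CpG subset from
`select_discriminating_cpgs()` (per type, the 50 probes with the largest
contrast between that type and the mean of the others); with only two cell
types the contrast is symmetric between the types, so marker attribution to
a specific type requires at least three.

# Clock training

`train_clock()` wraps cross-validated elastic-net regression: for each
mixing value the full penalty path (100 values, down to 1% of the smallest
all-zero penalty) is cross-validated, the mixing value with the lowest
minimum CV mean-squared error (days²) wins, and the penalty rule is applied.
The default rule is **lambda_1se** — the largest penalty whose CV error is
within one standard error of the minimum — which trades a marginal loss of
accuracy for a much sparser CpG set; `lambda_min` is available. The default
mixing value is 1 (the lasso): sparse clocks of tens of CpGs are the point
of the construction, and a ridge penalty (mixing 0) never sparsifies.
Cross-validation is leave-one-out for n ≤ 200 and 10-fold otherwise, with
fold assignment drawn from the training seed (default 1999); given the seed
and scheme, training is bit-reproducible. Clocks use beta values only by
default; unpenalized covariate columns can be added through a flag.
Predictors must be complete — `median_impute()` implements the per-probe
median imputation used before penalized training — and samples with missing
GA labels are dropped from training rather than having their response
imputed.

`screen_then_train()` optionally restricts the predictor universe to
EWAS-significant probes (Bonferroni or FDR) before training; the unscreened
complete-matrix mode is the headline configuration. `predict_ga()` is plain
linear arithmetic `intercept + sum(weight * beta)` and errors if any clock
CpG is absent from the supplied matrix.

# Evaluation

`evaluate_predictions()` regresses observed GA on predicted GA with the same
MM estimator and reports two numbers per clock and GA definition:

* `r_squared`: squared Pearson correlation between observed and fitted
  values. R² is not uniquely defined for robust fits; this definition is the
  package's documented choice, with a robust-scale alternative
  (`1 - (sigma/sigma_null)^2`) exposed as an option.
* `pi_half_width`: `1.96 * sigma`, the half-width in days of a
  constant-width 95% prediction interval, with `sigma` the robust residual
  scale. A single-number summary implies a constant-width band, so the
  Gaussian-limit form is used rather than leverage-adjusted pointwise
  intervals; empirical coverage of the band is 95% ± 2% on Gaussian
  residuals at n = 2000.

`compare_ga_definitions()` tabulates both definitions side by side and flags
the more precisely predicted one (higher R², smaller interval), with ties
and criterion disagreements flagged as such. Constant predictions (an
all-zero-weight clock on signal-free data) are an error by default or, in
pipeline runs, a flagged degenerate evaluation with `r_squared = 0` so that
end-to-end null runs complete.

# Overlap reports

`compare_sets()` performs exact set arithmetic (sizes, intersection, union,
asymmetric differences, with the identities asserted on every call);
`map_cpgs_to_genes()` resolves semicolon-separated gene annotations with
case-sensitive symbol comparison; `compare_with_external_list()` produces
the study-comparison report, counting externally listed probes absent from
the annotation as "not mappable" rather than silently dropping them —
cross-platform lists legitimately contain such probes.

# The end-to-end pipeline

`run_pipeline()` chains simulate → deconvolve → EWAS (both GA definitions)
→ train (optionally screened) → predict batch 2 → evaluate (both
definitions) → clock-overlap report, writing every artifact as tab-delimited
text plus a JSON manifest of the configuration, seed and per-file MD5
hashes. The manifest contains no timestamps, so a rerun with the same
configuration is bit-identical and every artifact is re-derivable from the
manifest alone. Stage failures abort with the stage name and preserve prior
outputs.

# Numerical and design choices

* Elemental-subset count for the S-stage defaults to 20 plus the OLS
  candidate: the package's simulated data contain response outliers rather
  than high-leverage contamination, and the candidate screen (median
  absolute residual, exact M-scale only for the top three) keeps
  genome-wide scans tractable. The constant is configurable through
  `mm_control()`.
* Tie-breaks in discriminating-CpG selection are by probe order,
  deterministic.
* Degenerate inputs fail loudly: rank-deficient designs, constant GA,
  fully missing probes, clock CpGs absent at prediction time — all are
  errors naming the offender; constant probes in a scan are skipped and
  flagged instead, since one dead probe should not kill a genome-wide scan.
* Problem sizes in the test and acceptance suites are scaled to a desk-run:
  the default cohort (2000 probes, 300 + 150 samples) for recovery
  properties, 20 replicate cohorts for ordering properties, 20 null cohorts
  of 500 probes at n = 200 for family-wise error control, and a 300-probe
  pipeline for bit-level determinism. These sizes are the package's chosen
  demonstration conditions.

# Known limitations

* The synthetic cohort is the only supported data source for end-to-end
  claims; nothing here estimates real-cohort effect sizes.
* The EWAS models probes independently; no genomic-control inflation
  correction or surrogate-variable analysis is included.
* The deconvolution assumes the reference panel spans the sample's cell
  types; unexplained fractions absorb, but do not flag, missing types.
* Clock weights fitted to a real cohort cannot be reproduced without that
  cohort's data; what the package demonstrates is exact set arithmetic at
  study scale and the qualitative ultrasound-versus-LMP precision ordering
  on synthetic data.
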