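#' Train a penalized-regression gestational-age clock
#'
#' Fits elastic-net paths (squared-error loss, predictors standardized
#' internally, coefficients returned on the original beta scale) for each
#' mixing value in `alpha`, cross-validates each path, selects the mixing
#' value with the lowest minimum CV error, and applies the penalty rule:
#' `lambda_1se` (default; the largest penalty whose CV error is within one
#' standard error of the minimum, trading a little accuracy for a much
#' sparser CpG set) or `lambda_min`. Cross-validation is leave-one-out for
#' n <= 200 and 10-fold otherwise; fold assignment and hence the whole fit is
#' deterministic given `seed`.
#'
#' @param bm Beta matrix, samples x CpGs, no missing values (run
#'   [median_impute()] first).
#' @param ga Gestational age response, days, no missing values, same order
#'   as `rownames(bm)`.
#' @param alpha Elastic-net mixing value(s) to try; 1 = lasso (sparse,
#'   the default), 0 = ridge, 0.5 = balanced.
#' @param lambda_rule `"lambda_1se"` or `"lambda_min"`.
#' @param cv_folds Number of CV folds; `NULL` picks leave-one-out for
#'   n <= 200, otherwise 10.
#' @param seed Seed of the fold assignment (default 1999).
#' @param covariates Optional numeric matrix of unpenalized extra columns
#'   (e.g. cell proportions); default none -- the clock uses beta values only.
#' @param lambda_override Optional fixed penalty; skips the rule and extracts
#'   coefficients at this penalty from the CV path (diagnostic use).
#' @return An object of class `clock_model`: `intercept` (days), `weights`
#'   (named vector, days per beta-unit, nonzero entries only), `alpha`,
#'   `lambda`, `lambda_rule`, `cv_scheme`, `seed`, `n_train`,
#'   `n_cpgs_universe` and `cv`, a tibble of the CV curve(s)
#'   (`alpha`, `lambda`, `cvm`, `cvsd`, `lambda_min`, `lambda_1se`).
#' @export
train_clock <- function(bm, ga, alpha = 1,
                        lambda_rule = c("lambda_1se", "lambda_min"),
                        cv_folds = NULL, seed = 1999, covariates = NULL,
                        lambda_override = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  validate_beta_matrix(bm)
  n <- nrow(bm)
  if (length(ga) != n) abort("ga must have one value per sample")
  if (anyNA(bm)) abort("beta matrix has missing values; run median_impute() first")
  if (anyNA(ga)) abort("ga has missing values; drop or impute first")
  if (n < 20) abort("need at least 20 training samples")
  if (sd(ga) == 0) abort("ga is constant; cannot train")

  x <- bm
  pf <- rep(1, ncol(x))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    x <- cbind(x, covariates)
    pf <- c(pf, rep(0, ncol(covariates)))
  }

  if (is.null(cv_folds)) cv_folds <- if (n <= 200) n else 10
  cv_scheme <- if (cv_folds >= n) "loo" else sprintf("%d-fold", cv_folds)
  foldid <- if (cv_folds >= n) {
    seq_len(n)
  } else {
    with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  }

  fits <- list()
  for (a in alpha) {
    fits[[as.character(a)]] <- glmnet::cv.glmnet(
      x, ga, alpha = a, foldid = foldid, family = "gaussian",
      nlambda = 100, lambda.min.ratio = 0.01, standardize = TRUE,
      penalty.factor = pf, grouped = cv_folds < n)
  }
  best_i <- which.min(vapply(fits, function(f) min(f$cvm), numeric(1)))
  best <- fits[[best_i]]
  best_alpha <- alpha[best_i]
  lambda <- if (!is.null(lambda_override)) {
    lambda_override
  } else if (lambda_rule == "lambda_1se") best$lambda.1se else best$lambda.min

  cf <- as.matrix(coef(best, s = lambda))
  intercept <- cf[1, 1]
  w <- cf[-1, 1]
  w <- w[names(w) %in% colnames(bm)]  # covariate columns are not clock weights
  w <- w[w != 0]

  cv <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble(alpha = alpha[i], lambda = f$lambda, cvm = f$cvm, cvsd = f$cvsd,
           lambda_min = f$lambda.min, lambda_1se = f$lambda.1se)
  }))

  structure(list(intercept = intercept, weights = w, alpha = best_alpha,
                 lambda = lambda, lambda_rule = lambda_rule,
                 cv_scheme = cv_scheme, seed = seed, n_train = n,
                 n_cpgs_universe = ncol(bm), cv = cv),
            class = "clock_model")
}

#' Screen CpGs by EWAS significance, then train
#'
#' Restricts the predictor universe to the CpGs passing
#' [select_significant()] before calling [train_clock()]. With
#' `ewas_results = NULL` the unscreened, complete-matrix model is trained
#' instead (the headline configuration).
#'
#' @inheritParams train_clock
#' @param ewas_results An `ewas_results` tibble, or `NULL` for no screening.
#' @param criterion,alpha_level Passed to [select_significant()].
#' @param ... Further arguments to [train_clock()].
#' @return A `clock_model`.
#' @export
screen_then_train <- function(bm, ga, ewas_results = NULL,
                              criterion = c("p_bonferroni", "q_fdr"),
                              alpha_level = 0.05, ...) {
  if (!is.null(ewas_results)) {
    criterion <- match.arg(criterion)
    hits <- select_significant(ewas_results, criterion, alpha_level)
    keep <- intersect(colnames(bm), hits$cpg_id)
    if (!length(keep)) abort("screening left no CpGs; nothing to train on")
    bm <- bm[, keep, drop = FALSE]
  }
  train_clock(bm, ga, ...)
}

#' Predict gestational age from a trained clock
#'
#' `prediction = intercept + sum(weight * beta)` over the clock's CpGs;
#' columns outside the model are ignored.
#'
#' @param model A `clock_model`.
#' @param bm Beta matrix containing every clock CpG (error lists any that are
#'   absent); missing values must be imputed first.
#' @return A tibble `sample_id`, `ga_predicted` (days).
#' @export
predict_ga <- function(model, bm) {
  validate_beta_matrix(bm)
  need <- names(model$weights)
  absent <- setdiff(need, colnames(bm))
  if (length(absent)) {
    abort(paste0("clock CpGs absent from beta matrix: ",
                 paste(head(absent, 10), collapse = ", "),
                 if (length(absent) > 10) sprintf(" (and %d more)", length(absent) - 10) else ""))
  }
  sub <- bm[, need, drop = FALSE]
  if (anyNA(sub)) abort("missing values on clock CpGs; run median_impute() first")
  pred <- model$intercept + drop(sub %*% model$weights)
  tibble(sample_id = rownames(bm), ga_predicted = unname(pred))
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Gestational-age methylation clock\n")
  cat(sprintf("  %d CpGs, intercept %.2f days, alpha = %g, lambda = %.4g (%s)\n",
              length(x$weights), x$intercept, x$alpha, x$lambda, x$lambda_rule))
  cat(sprintf("  trained on n = %d of a %d-CpG universe, CV = %s, seed = %d\n",
              x$n_train, x$n_cpgs_universe, x$cv_scheme, x$seed))
  invisible(x)
}

#' Tidy a clock model
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return A tibble `cpg_id`, `weight` (days per beta-unit), sorted by
#'   decreasing absolute weight.
#' @export
tidy.clock_model <- function(x, ...) {
  out <- tibble(cpg_id = names(x$weights), weight = unname(x$weights))
  out[order(-abs(out$weight)), ]
}

#' One-row summary of a clock model
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return A tibble with the model's headline metadata.
#' @export
glance.clock_model <- function(x, ...) {
  tibble(n_cpgs = length(x$weights), intercept = x$intercept,
         alpha = x$alpha, lambda = x$lambda, lambda_rule = x$lambda_rule,
         cv_scheme = x$cv_scheme, n_train = x$n_train,
         n_cpgs_universe = x$n_cpgs_universe, seed = x$seed)
}

#' Cross-validation curve of a clock model
#' @param object A `clock_model`.
#' @param ... Unused.
#' @return A ggplot: CV mean squared error (+/- 1 SE) against log10 lambda,
#'   with the selected penalty marked.
#' @export
autoplot.clock_model <- function(object, ...) {
  cv <- dplyr::filter(object$cv, .data$alpha == object$alpha)
  ggplot2::ggplot(cv, ggplot2::aes(x = log10(.data$lambda), y = .data$cvm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cvm - .data$cvsd,
                                      ymax = .data$cvm + .data$cvsd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$lambda), linetype = 2) +
    ggplot2::labs(x = expression(log[10](lambda)),
                  y = expression("CV MSE (days"^2*")"),
                  title = sprintf("alpha = %g, rule = %s", object$alpha,
                                  object$lambda_rule)) +
    ggplot2::theme_minimal()
}

#' Serialize / deserialize a clock model
#'
#' Tab-delimited: a `#`-prefixed header block (intercept, alpha, lambda,
#' rule, cv scheme, seed, training sizes) followed by a `cpg_id` / `weight`
#' table. Numeric fields are written with full precision, so the format
#' round-trips exactly.
#'
#' @param model A `clock_model`.
#' @param path File path.
#' @return `write_clock_model`: `path`, invisibly. `read_clock_model`: a
#'   `clock_model` (without the CV curve, which is not serialized).
#' @export
write_clock_model <- function(model, path) {
  hdr <- c(sprintf("#intercept\t%.17g", model$intercept),
           sprintf("#alpha\t%.17g", model$alpha),
           sprintf("#lambda\t%.17g", model$lambda),
           sprintf("#lambda_rule\t%s", model$lambda_rule),
           sprintf("#cv_scheme\t%s", model$cv_scheme),
           sprintf("#seed\t%d", model$seed),
           sprintf("#n_train\t%d", model$n_train),
           sprintf("#n_cpgs_universe\t%d", model$n_cpgs_universe),
           "cpg_id\tweight",
           sprintf("%s\t%.17g", names(model$weights), model$weights))
  writeLines(hdr, path)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "\t")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- body[-1]  # column header
  w <- numeric(0)
  if (length(body)) {
    parts <- strsplit(body, "\t")
    w <- setNames(as.numeric(vapply(parts, `[`, "", 2)),
                  vapply(parts, `[`, "", 1))
  }
  structure(list(intercept = as.numeric(meta[["intercept"]]),
                 weights = w,
                 alpha = as.numeric(meta[["alpha"]]),
                 lambda = as.numeric(meta[["lambda"]]),
                 lambda_rule = meta[["lambda_rule"]],
                 cv_scheme = meta[["cv_scheme"]],
                 seed = as.integer(meta[["seed"]]),
                 n_train = as.integer(meta[["n_train"]]),
                 n_cpgs_universe = as.integer(meta[["n_cpgs_universe"]]),
                 cv = NULL),
            class = "clock_model")
}
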