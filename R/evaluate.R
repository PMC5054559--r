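#' Evaluate gestational-age predictions by robust regression
#'
#' Regresses observed GA on predicted GA with [fit_mm_regression()] and
#' summarises the fit the way clock studies report it: `r_squared` -- the
#' squared Pearson correlation between observed and fitted values (a
#' robust-scale-based alternative is available) -- and `pi_half_width`, the
#' half-width in days of a constant-width 95 percent prediction interval,
#' `1.96 * sigma` with `sigma` the robust residual scale.
#'
#' @param observed Observed GA, days (`NA` pairs dropped).
#' @param predicted Predicted GA, days, same length.
#' @param ga_definition Optional label (`"ultrasound"` / `"lmp"`) carried
#'   into reports.
#' @param r_squared_method `"squared_correlation"` (default) or
#'   `"robust_scale"` (`1 - (sigma / sigma_null)^2`, with `sigma_null` the
#'   robust scale of the intercept-only fit).
#' @param allow_degenerate With the default `FALSE`, constant predictions are
#'   an error; with `TRUE` they yield a flagged intercept-only evaluation
#'   (`r_squared = 0`, interval from the robust scale of the observed values),
#'   which keeps end-to-end runs on signal-free data alive.
#' @param control [mm_control()] settings of the robust fit.
#' @return An object of class `ga_evaluation`: `ga_definition`, `n`,
#'   `n_dropped`, `r_squared`, `pi_half_width`, robust `slope` and
#'   `intercept` of observed-on-predicted, `sigma`, plus the underlying
#'   `fit` and the paired data.
#' @export
evaluate_predictions <- function(observed, predicted, ga_definition = NA_character_,
                                 r_squared_method = c("squared_correlation",
                                                      "robust_scale"),
                                 allow_degenerate = FALSE,
                                 control = mm_control()) {
  r_squared_method <- match.arg(r_squared_method)
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length")
  }
  keep <- !is.na(observed) & !is.na(predicted)
  n_dropped <- sum(!keep)
  obs <- observed[keep]
  pred <- predicted[keep]
  if (length(obs) < 10) abort("need at least 10 paired non-missing values")
  if (sd(pred) == 0) {
    if (!allow_degenerate) abort("predicted values are constant; fit is undefined")
    fit0 <- fit_mm_regression(obs, matrix(1, length(obs), 1,
                                          dimnames = list(NULL, "(Intercept)")),
                              control)
    return(structure(list(ga_definition = ga_definition,
                          n = length(obs), n_dropped = n_dropped,
                          r_squared = 0,
                          pi_half_width = 1.96 * fit0$sigma,
                          slope = NA_real_,
                          intercept = unname(fit0$coefficients[1]),
                          sigma = fit0$sigma, degenerate = TRUE,
                          fit = fit0, observed = obs, predicted = pred),
                     class = "ga_evaluation"))
  }

  fit <- fit_mm_regression(obs, cbind(`(Intercept)` = 1, predicted = pred),
                           control)
  r2 <- if (r_squared_method == "squared_correlation") {
    cor(obs, fit$fitted)^2
  } else {
    s0 <- m_scale(obs - median(obs), control$c_s)
    max(0, min(1, 1 - (fit$sigma / s0)^2))
  }
  structure(list(ga_definition = ga_definition,
                 n = length(obs), n_dropped = n_dropped,
                 r_squared = r2,
                 pi_half_width = 1.96 * fit$sigma,
                 slope = unname(fit$coefficients["predicted"]),
                 intercept = unname(fit$coefficients["(Intercept)"]),
                 sigma = fit$sigma, degenerate = FALSE,
                 fit = fit, observed = obs, predicted = pred),
            class = "ga_evaluation")
}

#' @export
print.ga_evaluation <- function(x, ...) {
  cat(sprintf("GA prediction evaluation%s\n",
              if (is.na(x$ga_definition)) "" else paste0(" (", x$ga_definition, ")")))
  cat(sprintf("  n = %d (%d dropped), R^2 = %.3f, 95%% PI half-width = %.1f days\n",
              x$n, x$n_dropped, x$r_squared, x$pi_half_width))
  invisible(x)
}

#' Tidy a GA evaluation
#' @param x A `ga_evaluation`.
#' @param ... Unused.
#' @return A tibble of the robust observed-on-predicted coefficients.
#' @export
tidy.ga_evaluation <- function(x, ...) tidy(x$fit)

#' One-row summary of a GA evaluation
#' @param x A `ga_evaluation`.
#' @param ... Unused.
#' @return A tibble: `ga_definition`, `n`, `n_dropped`, `r_squared`,
#'   `pi_half_width`, `slope`, `intercept`.
#' @export
glance.ga_evaluation <- function(x, ...) {
  tibble(ga_definition = x$ga_definition, n = x$n, n_dropped = x$n_dropped,
         r_squared = x$r_squared, pi_half_width = x$pi_half_width,
         slope = x$slope, intercept = x$intercept)
}

#' Observed-versus-predicted scatter with the 95 percent band
#' @param object A `ga_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_evaluation <- function(object, ...) {
  df <- tibble(observed = object$observed, predicted = object$predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::geom_abline(intercept = object$intercept + object$pi_half_width,
                         slope = object$slope, linetype = 2) +
    ggplot2::geom_abline(intercept = object$intercept - object$pi_half_width,
                         slope = object$slope, linetype = 2) +
    ggplot2::labs(x = "predicted GA (days)", y = "observed GA (days)",
                  subtitle = sprintf("R² = %.2f, ±%.1f days (95%% PI)",
                                     object$r_squared, object$pi_half_width)) +
    ggplot2::theme_minimal()
}

#' Compare clock accuracy under the two GA definitions
#'
#' Tabulates the two evaluations side by side and flags which definition the
#' clock predicts more precisely (higher R-squared and smaller prediction
#' interval); `"tie"` when identical, `"mixed"` when the two criteria
#' disagree.
#'
#' @param eval_us Evaluation against the ultrasound-based GA.
#' @param eval_lmp Evaluation against the LMP-based GA.
#' @return A tibble of class `ga_comparison` with one row per definition and
#'   attribute `more_precise` (`"ultrasound"`, `"lmp"`, `"tie"` or
#'   `"mixed"`).
#' @export
compare_ga_definitions <- function(eval_us, eval_lmp) {
  tab <- dplyr::bind_rows(
    mutate(glance(eval_us), ga_definition = "ultrasound"),
    mutate(glance(eval_lmp), ga_definition = "lmp"))
  by_r2 <- sign(eval_us$r_squared - eval_lmp$r_squared)
  by_pi <- sign(eval_lmp$pi_half_width - eval_us$pi_half_width)
  more_precise <- if (by_r2 == 0 && by_pi == 0) {
    "tie"
  } else if (by_r2 >= 0 && by_pi >= 0) {
    "ultrasound"
  } else if (by_r2 <= 0 && by_pi <= 0) {
    "lmp"
  } else {
    "mixed"
  }
  structure(tab, class = c("ga_comparison", class(tab)),
            more_precise = more_precise)
}

#' @export
print.ga_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf("more precise definition: %s\n", attr(x, "more_precise")))
  invisible(x)
}

#' Write evaluation rows to a tab-delimited file
#' @param evals A list of `ga_evaluation` objects (or a `ga_comparison`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evals, path) {
  tab <- if (inherits(evals, "ga_comparison")) {
    as.data.frame(evals)
  } else {
    as.data.frame(dplyr::bind_rows(lapply(evals, glance)))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
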