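make_training_data <- function(seed = 1, n = 40, n_noise = 9) {
  set.seed(seed)
  ga <- runif(n, 240, 300)
  causal <- 0.3 + 0.006 * (ga - 270) + rnorm(n, 0, 0.01)
  noise <- matrix(runif(n * n_noise, 0.2, 0.8), n)
  bm <- cbind(causal, noise)
  bm <- pmin(pmax(bm, 0.01), 0.99)
  dimnames(bm) <- list(sprintf("s%02d", 1:n),
                       c("cg_causal", sprintf("cg_noise%02d", 1:n_noise)))
  list(bm = bm, ga = ga)
}

test_that("lasso finds the causal CpG and zeroes most noise probes", {
  d <- make_training_data()
  m <- train_clock(d$bm, d$ga, alpha = 1, lambda_rule = "lambda_min")
  expect_s3_class(m, "clock_model")
  expect_true("cg_causal" %in% names(m$weights))
  expect_identical(names(which.max(abs(m$weights))), "cg_causal")
  expect_gte(sum(!sprintf("cg_noise%02d", 1:9) %in% names(m$weights)), 8)
})

test_that("an over-large penalty yields the null model", {
  d <- make_training_data()
  m <- train_clock(d$bm, d$ga, alpha = 1, lambda_override = 1e6)
  expect_length(m$weights, 0)
  expect_equal(m$intercept, mean(d$ga), tolerance = 1e-6)
  pred <- predict_ga(m, d$bm)
  expect_equal(pred$ga_predicted, rep(m$intercept, nrow(d$bm)))
})

test_that("ridge never sparsifies", {
  set.seed(2)
  n <- 60
  ga <- runif(n, 240, 300)
  bm <- matrix(runif(n * 50, 0.2, 0.8), n,
               dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%02d", 1:50)))
  bm[, 1] <- pmin(pmax(0.3 + 0.005 * (ga - 270) + rnorm(n, 0, 0.02), 0.01), 0.99)
  m <- train_clock(bm, ga, alpha = 0, lambda_rule = "lambda_min")
  expect_equal(sum(coef_count <- length(m$weights)), 50)
})

test_that("the one-SE rule is sparser than the minimum and obeys its bound", {
  fx <- small_cohort(seed = 81, n1 = 120, n2 = 10, n_cpgs = 300, n_causal = 10,
                     effect_sd = 0.02)
  b1 <- cohort_batch(fx$cohort, "batch1")
  keep <- !is.na(b1$sheet$ga_ultrasound)
  bm <- median_impute(b1$beta[keep, ])
  ga <- b1$sheet$ga_ultrasound[keep]
  m1se <- train_clock(bm, ga, lambda_rule = "lambda_1se")
  mmin <- train_clock(bm, ga, lambda_rule = "lambda_min")
  expect_gte(m1se$lambda, mmin$lambda)
  expect_lte(length(m1se$weights), length(mmin$weights))
  cv <- m1se$cv
  err_min <- cv$cvm[which.min(abs(cv$lambda - unique(cv$lambda_min)))]
  sd_min <- cv$cvsd[which.min(abs(cv$lambda - unique(cv$lambda_min)))]
  err_1se <- cv$cvm[which.min(abs(cv$lambda - unique(cv$lambda_1se)))]
  expect_lte(err_1se, err_min + sd_min + 1e-8)
})

test_that("training is bit-reproducible under a fixed seed and scheme", {
  d <- make_training_data(seed = 3, n = 250)  # forces 10-fold CV
  m1 <- train_clock(d$bm, d$ga, seed = 1999)
  m2 <- train_clock(d$bm, d$ga, seed = 1999)
  expect_identical(m1, m2)
  expect_identical(m1$cv_scheme, "10-fold")
  m3 <- train_clock(d$bm[1:50, ], d$ga[1:50], seed = 1999)
  expect_identical(m3$cv_scheme, "loo")
})

test_that("prediction is plain linear arithmetic over model CpGs", {
  model <- structure(list(intercept = 280,
                          weights = c(cg1 = 70),
                          alpha = 1, lambda = 1, lambda_rule = "lambda_1se",
                          cv_scheme = "loo", seed = 1999, n_train = 50,
                          n_cpgs_universe = 10, cv = NULL),
                     class = "clock_model")
  bm <- make_beta(c(0.5, 0.1), c("s1", "s2"), "cg1")
  pred <- predict_ga(model, bm)
  expect_equal(pred$ga_predicted, c(280 + 70 * 0.5, 280 + 70 * 0.1))

  # irrelevant extra columns do not perturb predictions
  bm2 <- cbind(bm, make_beta(c(0.9, 0.9), c("s1", "s2"), "cg_extra"))
  expect_equal(predict_ga(model, bm2)$ga_predicted, pred$ga_predicted)

  # a missing model CpG is a hard error naming the probe
  expect_error(predict_ga(model, make_beta(c(0.1, 0.2), c("s1", "s2"), "cgX")),
               "cg1")
})

test_that("screening restricts the universe and errors when empty", {
  fx <- small_cohort(seed = 91, n1 = 100, n2 = 10, n_cpgs = 250, n_causal = 6,
                     effect_sd = 0.025)
  b1 <- cohort_batch(fx$cohort, "batch1")
  keep <- !is.na(b1$sheet$ga_ultrasound)
  bm <- median_impute(b1$beta[keep, ])
  ga <- b1$sheet$ga_ultrasound[keep]
  props <- estimate_cell_proportions(b1$beta, fx$ref)[keep, ]
  res <- suppressMessages(run_ewas(b1$beta[keep, ], b1$sheet[keep, ], props,
                                   "ga_ultrasound"))
  m_scr <- screen_then_train(bm, ga, res, criterion = "p_bonferroni")
  bonf_hits <- select_significant(res, "p_bonferroni", 0.05)$cpg_id
  expect_true(all(names(m_scr$weights) %in% bonf_hits))
  expect_lte(m_scr$n_cpgs_universe, length(bonf_hits))
  # FDR universe contains the Bonferroni universe
  fdr_hits <- select_significant(res, "q_fdr", 0.05)$cpg_id
  expect_true(all(bonf_hits %in% fdr_hits))
  # unscreened mode trains on the full matrix
  m_all <- screen_then_train(bm, ga, NULL)
  expect_identical(m_all$n_cpgs_universe, ncol(bm))
  # null screening errors out
  null_res <- res
  null_res$p_bonferroni <- 1
  expect_error(screen_then_train(bm, ga, null_res), "no CpGs")
})

test_that("clock models round-trip exactly through the text format", {
  d <- make_training_data(seed = 4)
  m <- train_clock(d$bm, d$ga)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clock_model(m, path)
  back <- read_clock_model(path)
  expect_identical(back$weights, m$weights)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$lambda, m$lambda)
  expect_identical(back$lambda_rule, m$lambda_rule)
  expect_equal(predict_ga(back, d$bm), predict_ga(m, d$bm))
})

test_that("training inputs are validated", {
  d <- make_training_data()
  expect_error(train_clock(d$bm[1:10, ], d$ga[1:10]), "at least 20")
  expect_error(train_clock(d$bm, rep(280, nrow(d$bm))), "constant")
  bad <- d$bm
  bad[1, 1] <- NA
  expect_error(train_clock(bad, d$ga), "missing values")
})

test_that("tidy and glance summarise clock models", {
  d <- make_training_data(seed = 5)
  m <- train_clock(d$bm, d$ga)
  td <- tidy(m)
  expect_named(td, c("cpg_id", "weight"))
  expect_true(all(td$weight != 0))
  gl <- glance(m)
  expect_identical(gl$n_cpgs, length(m$weights))
  expect_identical(gl$lambda_rule, "lambda_1se")
})
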