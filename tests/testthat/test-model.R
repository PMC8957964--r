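test_that("pure-noise methylomes yield sparse, mostly empty supports", {
  # With no probe correlated with BMI, the CV-minimising penalty keeps
  # the support (near-)empty in most replicates. The minimum-MSE rule
  # does overfit a minority of CV curves by design, so the assertion is
  # on the median and majority, not on every seed.
  sizes <- integer(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    b <- matrix(runif(100 * 200), nrow = 200,
                dimnames = list(sprintf("cg%08d", 1:200),
                                sprintf("S%04d", 1:100)))
    bmi <- runif(100, 18, 40)
    fit <- fit_dm_bmi(b, bmi, seed = s)
    sizes[s] <- length(fit$coefficients)
  }
  expect_lte(median(sizes), 2)
  expect_gte(mean(sizes <= 2), 0.5)
  expect_lt(max(sizes), 50)   # never anywhere near the 200 candidates
})

test_that("a noiseless perfectly informative probe is recovered", {
  set.seed(21)
  n <- 120
  bmi <- runif(n, 16, 45)
  fb <- f_bmi(bmi)
  a <- 0.5; bcoef <- 0.25
  signal <- a + bcoef * fb                 # stays inside [0, 1]
  b <- rbind(signal, matrix(runif(20 * n), nrow = 20))
  rownames(b) <- sprintf("cg%08d", 1:21)
  colnames(b) <- sprintf("S%04d", 1:n)
  fit <- fit_dm_bmi(b, bmi, seed = 21)
  expect_true("cg00000001" %in% names(fit$coefficients))

  # hold-out samples from the same noiseless rule
  bmi2 <- runif(50, 16, 45)
  fb2 <- f_bmi(bmi2)
  b2 <- rbind(a + bcoef * fb2, matrix(runif(20 * 50), nrow = 20))
  dimnames(b2) <- list(sprintf("cg%08d", 1:21), sprintf("T%04d", 1:50))
  pred_t <- predict(fit, b2, scale = "transformed")
  expect_lt(max(abs(pred_t - fb2)), 1e-3)
  expect_lt(max(abs(predict(fit, b2) - bmi2)), 0.1)
})

test_that("lasso recovers a causal support on simulated cohorts", {
  cfg <- synth_config(n_samples = 150, n_probes = 500, n_causal = 15,
                      missing_rate = 0, n_batches = 1, seed = 22)
  refs <- simulate_reference_profiles(500, 25, delta = 0.8, seed = 22)
  coh <- simulate_cohort(cfg, refs)
  fit <- fit_dm_bmi(coh$beta, coh$true_bmi, seed = 22)
  recall <- mean(coh$causal_probes %in% names(fit$coefficients))
  expect_gte(recall, 0.5)
})

test_that("an empty model predicts the anchor everywhere", {
  m <- structure(list(intercept = 0,
                      coefficients = setNames(numeric(0), character(0)),
                      lambda_selected = 1, cv_folds = NA_integer_,
                      seed = 1L, healthy_bmi = 25, n_samples = 0,
                      cv = NULL), class = "dmbmi")
  b <- toy_beta(5, 4)
  expect_equal(unname(predict(m, b)), rep(25, 4))
})

test_that("predictions ignore probe order and irrelevant probes", {
  cfg <- synth_config(n_samples = 80, n_probes = 300, n_causal = 8,
                      missing_rate = 0, seed = 23)
  refs <- simulate_reference_profiles(300, 15, delta = 0.8, seed = 23)
  coh <- simulate_cohort(cfg, refs)
  fit <- fit_dm_bmi(coh$beta, coh$true_bmi, seed = 23)
  p0 <- predict(fit, coh$beta)
  set.seed(1)
  perm <- sample(nrow(coh$beta))
  expect_equal(predict(fit, coh$beta[perm, ]), p0)
  extra <- rbind(coh$beta, toy_beta(10, ncol(coh$beta)) * 0 + 0.5)
  rownames(extra)[-seq_len(nrow(coh$beta))] <- sprintf("new%03d", 1:10)
  expect_equal(predict(fit, extra), p0)
})

test_that("an overwhelming penalty empties the support", {
  set.seed(24)
  b <- toy_beta(30, 60)
  bmi <- runif(60, 18, 40)
  fit <- fit_dm_bmi(b, bmi, lambda = 1e6, seed = 24)
  expect_identical(length(fit$coefficients), 0L)
  expect_equal(fit$intercept, mean(f_bmi(bmi)))
  expect_equal(unname(predict(fit, b)),
               rep(inv_f_bmi(mean(f_bmi(bmi))), 60))
})

test_that("fitting is deterministic given data and seed", {
  set.seed(25)
  b <- toy_beta(100, 50)
  bmi <- runif(50, 18, 40)
  expect_identical(fit_dm_bmi(b, bmi, seed = 7), fit_dm_bmi(b, bmi, seed = 7))
})

test_that("fit rejects degenerate inputs and names missing probes", {
  b <- toy_beta(10, 12)
  expect_error(fit_dm_bmi(b, rep(30, 12)), "constant")
  expect_error(fit_dm_bmi(b, runif(12, 20, 30), cv_folds = 20), "cv_folds")
  bna <- b; bna[1, 1] <- NA
  expect_error(fit_dm_bmi(bna, runif(12, 20, 30)), "missing")

  set.seed(26)
  fit <- fit_dm_bmi(toy_beta(50, 40, seed = 26), runif(40, 15, 45),
                    seed = 26)
  if (length(fit$coefficients) > 0) {
    b2 <- toy_beta(50, 5, seed = 27)
    rownames(b2) <- paste0("xx", seq_len(50))
    expect_error(predict(fit, b2), names(fit$coefficients)[1])
  }
})

test_that("model JSON round-trips through serialization", {
  cfg <- synth_config(n_samples = 60, n_probes = 200, n_causal = 6,
                      missing_rate = 0, seed = 28)
  refs <- simulate_reference_profiles(200, 10, delta = 0.8, seed = 28)
  coh <- simulate_cohort(cfg, refs)
  fit <- fit_dm_bmi(coh$beta, coh$true_bmi, seed = 28)
  path <- tempfile(fileext = ".json")
  write_dmbmi(fit, path)
  back <- read_dmbmi(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(predict(back, coh$beta), predict(fit, coh$beta))
})

test_that("prediction evaluation matches closed-form t and Spearman", {
  ev <- evaluate_predictions(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_identical(ev$t, 0)
  expect_identical(ev$df, 4L)
  expect_equal(ev$spearman_r, 1)

  ev2 <- evaluate_predictions(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.na(ev2$t))
  expect_match(ev2$note, "nonzero constant")

  set.seed(30)
  pred <- runif(50, 20, 35)
  truth <- pred + rnorm(50, 0, 2)
  ev3 <- evaluate_predictions(pred, truth)
  oracle <- paired_t_oracle(pred, truth)
  expect_equal(ev3$t, oracle$t, tolerance = 1e-10)
  expect_equal(ev3$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(ev3$spearman_r, spearman_oracle(pred, truth),
               tolerance = 1e-10)
})
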