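#' Fit the DNA-methylation BMI predictor (DM-BMI)
#'
#' Regresses the transformed trait `F(BMI)` (see [f_bmi()]) on probe-level
#' beta values with a lasso penalty (`alpha = 1`). The penalty path holds
#' `nlambda` log-spaced values from the smallest penalty that zeroes every
#' coefficient down to `lambda_min_ratio` times it; the selected penalty
#' minimises the mean squared error of a `cv_folds`-fold cross-validation
#' whose fold assignment is drawn once from `seed` (ties on the CV curve
#' resolve toward the larger, sparser penalty). The model is then refit on
#' the full data at the selected penalty, and only probes with nonzero
#' coefficients are retained. Features are standardized internally during
#' fitting; stored coefficients are on the original beta scale.
#'
#' @param beta Probes x samples numeric matrix in \[0, 1\] with no missing
#'   values and probe/sample dimnames.
#' @param bmi Per-sample BMI (kg/m^2), aligned with columns of `beta`.
#' @param healthy_bmi Anchor of the trait transformation (default 25).
#' @param cv_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param nlambda Length of the penalty grid (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (default 1e-3).
#' @param lambda Optional fixed penalty; when supplied, cross-validation
#'   is skipped and the model is fit once at this value.
#' @return An object of class `dmbmi`: a list with `intercept`,
#'   `coefficients` (named vector over the nonzero-probe support),
#'   `lambda_selected`, `cv_folds`, `seed`, `healthy_bmi`, `n_samples`,
#'   and `cv` (data frame with the penalty grid, mean CV MSE and its
#'   standard error; `NULL` for a fixed-penalty fit).
#' @examples
#' \donttest{
#' cfg <- synth_config(n_samples = 80, n_probes = 300, n_causal = 10,
#'                     missing_rate = 0, seed = 2)
#' refs <- simulate_reference_profiles(300, 30, delta = 0.8, seed = 2)
#' coh <- simulate_cohort(cfg, refs)
#' fit <- fit_dm_bmi(coh$beta, coh$true_bmi, seed = 2)
#' print(fit)
#' }
#' @export
fit_dm_bmi <- function(beta, bmi, healthy_bmi = 25, cv_folds = 10,
                       seed = 1, nlambda = 100, lambda_min_ratio = 1e-3,
                       lambda = NULL) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  if (anyNA(beta))
    stop("`beta` must have no missing values (impute first)", call. = FALSE)
  n <- ncol(beta)
  if (length(bmi) != n)
    stop("`bmi` must have one value per sample", call. = FALSE)
  y <- f_bmi(bmi, healthy_bmi)
  if (stats::var(y) == 0)
    stop("degenerate fit: the (transformed) response is constant",
         call. = FALSE)
  x <- t(beta)

  if (is.null(lambda)) {
    if (n < cv_folds)
      stop(sprintf("n_samples (%d) < cv_folds (%d)", n, cv_folds),
           call. = FALSE)
    # explicit pathwise grid: lambda_max is the smallest penalty zeroing
    # every coefficient (computed on 1/n-standardized features); an
    # explicit grid keeps the full path down to lambda_min_ratio instead
    # of the fitter's early deviance-based truncation
    sdn <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
    ok <- sdn > 0
    if (!any(ok))
      stop("degenerate fit: all probes are constant", call. = FALSE)
    xs <- scale(x[, ok, drop = FALSE], center = TRUE, scale = sdn[ok])
    lmax <- max(abs(crossprod(xs, y - mean(y)))) / n
    grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
    set.seed(as.integer(seed))
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    cvfit <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                               lambda = grid,
                               standardize = TRUE, family = "gaussian")
    lambda_selected <- cvfit$lambda.min
    b <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
    cv <- data.frame(lambda = cvfit$lambda, mean_mse = cvfit$cvm,
                     se_mse = cvfit$cvsd)
  } else {
    stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
    fit <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda,
                          standardize = TRUE, family = "gaussian")
    lambda_selected <- lambda
    b <- as.matrix(stats::coef(fit))
    cv <- NULL
  }
  w <- b[-1, 1]
  w <- w[w != 0]
  structure(list(intercept = unname(b[1, 1]), coefficients = w,
                 lambda_selected = lambda_selected,
                 cv_folds = if (is.null(lambda)) as.integer(cv_folds) else NA_integer_,
                 seed = as.integer(seed), healthy_bmi = healthy_bmi,
                 n_samples = n, cv = cv),
            class = "dmbmi")
}

#' Predict DM-BMI for new samples
#'
#' Applies the sparse linear score `intercept + sum(coef * beta)` on the
#' transformed scale and (by default) maps it back to kg/m^2 through the
#' inverse trait transformation. Predictions depend only on the model's
#' support probes, so they are invariant to probe order and to extra
#' probes in `beta`.
#'
#' @param object A `dmbmi` model.
#' @param beta Probes x samples matrix containing at least the model's
#'   support probes, with no missing values among them.
#' @param scale `"bmi"` (kg/m^2, default) or `"transformed"`.
#' @param ... Unused.
#' @return Named numeric vector of per-sample predictions.
#' @export
predict.dmbmi <- function(object, beta, scale = c("bmi", "transformed"),
                          ...) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  probes <- names(object$coefficients)
  absent <- setdiff(probes, rownames(beta))
  if (length(absent) > 0)
    stop("model probes absent from `beta`: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) ", ..." else "", call. = FALSE)
  if (length(probes) > 0) {
    sub <- beta[probes, , drop = FALSE]
    if (anyNA(sub))
      stop("missing values among model probes", call. = FALSE)
    score <- object$intercept + colSums(sub * object$coefficients)
  } else {
    score <- rep(object$intercept, ncol(beta))
    names(score) <- colnames(beta)
  }
  if (scale == "transformed") score else
    inv_f_bmi(score, object$healthy_bmi)
}

#' @export
coef.dmbmi <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.dmbmi <- function(x, ...) {
  cat("DNA-methylation BMI predictor (lasso on transformed BMI)\n")
  cat(sprintf("  support: %d probes; lambda = %.5g%s\n",
              length(x$coefficients), x$lambda_selected,
              if (!is.na(x$cv_folds))
                sprintf(" (lambda.min, %d-fold CV, seed %d)",
                        x$cv_folds, x$seed) else " (fixed)"))
  cat(sprintf("  anchor healthy BMI: %g kg/m^2; trained on %d samples\n",
              x$healthy_bmi, x$n_samples))
  invisible(x)
}

#' @export
summary.dmbmi <- function(object, ...) {
  co <- object$coefficients
  structure(list(model = object,
                 support_size = length(co),
                 coef_range = if (length(co)) range(co) else c(NA, NA),
                 top = utils::head(co[order(-abs(co))], 10)),
            class = "summary.dmbmi")
}

#' @export
print.summary.dmbmi <- function(x, ...) {
  print(x$model)
  if (x$support_size > 0) {
    cat(sprintf("  coefficient range: [%.4g, %.4g]\n",
                x$coef_range[1], x$coef_range[2]))
    cat("  largest-magnitude coefficients:\n")
    print(round(x$top, 5))
  } else cat("  empty support\n")
  invisible(x)
}

#' Plot the cross-validation curve of a DM-BMI fit
#'
#' @param x A `dmbmi` model fit with cross-validation.
#' @param ... Passed to [plot()].
#' @export
plot.dmbmi <- function(x, ...) {
  if (is.null(x$cv))
    stop("model was fit at a fixed penalty; no CV curve to plot",
         call. = FALSE)
  with(x$cv, {
    plot(log(lambda), mean_mse, type = "l",
         xlab = expression(log(lambda)), ylab = "mean CV MSE", ...)
    graphics::segments(log(lambda), mean_mse - se_mse,
                       log(lambda), mean_mse + se_mse,
                       col = "grey70")
    graphics::abline(v = log(x$lambda_selected), lty = 2)
  })
  invisible(x)
}

#' Serialize / load a DM-BMI model as JSON
#'
#' @param model A `dmbmi` model.
#' @param path Output (or input) JSON path.
#' @return `write_dmbmi` returns `path` invisibly; `read_dmbmi` returns a
#'   `dmbmi` object.
#' @export
write_dmbmi <- function(model, path) {
  stopifnot(inherits(model, "dmbmi"))
  obj <- list(healthy_bmi = model$healthy_bmi,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              lambda_selected = model$lambda_selected,
              cv_folds = model$cv_folds,
              seed = model$seed,
              n_samples = model$n_samples)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dmbmi
#' @export
read_dmbmi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- unlist(obj$coefficients)
  if (is.null(co)) co <- stats::setNames(numeric(0), character(0))
  structure(list(intercept = obj$intercept, coefficients = co,
                 lambda_selected = obj$lambda_selected,
                 cv_folds = obj$cv_folds, seed = obj$seed,
                 healthy_bmi = obj$healthy_bmi,
                 n_samples = obj$n_samples, cv = NULL),
            class = "dmbmi")
}

#' Compare predictions with observed BMI
#'
#' Reports the Spearman correlation (average ranks for ties) between
#' predicted and observed BMI, and a two-sided paired t-test on the
#' per-sample differences (df = n - 1). When all differences are zero the
#' t statistic is 0 with p = 1; when the differences are a nonzero
#' constant the t statistic is undefined (division by a zero standard
#' error) and the report flags it rather than fabricating a value.
#'
#' @param pred Per-sample predicted BMI (kg/m^2).
#' @param truth Per-sample observed BMI, aligned with `pred`.
#' @return An object of class `dmbmi_eval`: list with `n`, `spearman_r`,
#'   `spearman_p`, `t`, `df`, `p_value`, and `note` (`NA` unless a
#'   degenerate case was flagged).
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(is.numeric(pred), is.numeric(truth),
            length(pred) == length(truth))
  n <- length(pred)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  note <- NA_character_

  d <- pred - truth
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) {
      tstat <- 0; pval <- 1
    } else {
      tstat <- NA_real_; pval <- NA_real_
      note <- "differences are a nonzero constant; t undefined (zero variance)"
    }
  } else {
    tstat <- mean(d) / (sd_d / sqrt(n))
    pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }

  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    r <- NA_real_; rp <- NA_real_
    note <- paste(stats::na.omit(c(note,
      "a vector is constant; Spearman undefined")), collapse = "; ")
  } else {
    r <- stats::cor(pred, truth, method = "spearman")
    rp <- suppressWarnings(
      stats::cor.test(pred, truth, method = "spearman",
                      exact = FALSE)$p.value)
    rp <- max(rp, .Machine$double.xmin)
  }
  structure(list(n = n, spearman_r = r, spearman_p = rp,
                 t = tstat, df = n - 1L, p_value = pval, note = note),
            class = "dmbmi_eval")
}

#' @export
print.dmbmi_eval <- function(x, ...) {
  cat(sprintf("Prediction vs truth (n = %d)\n", x$n))
  cat(sprintf("  Spearman r = %.4f (p = %.3g)\n", x$spearman_r,
              x$spearman_p))
  if (is.na(x$t))
    cat("  paired t: undefined\n")
  else
    cat(sprintf("  paired t = %.4f, df = %d, p = %.3g\n", x$t, x$df,
                x$p_value))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
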