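#' Run the DM-BMI analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> fit -> predict -> deconv ->
#' characterize -> scores over a run directory, writing every stage
#' output as TSV/JSON and a manifest recording the parameters actually
#' used (defaults included), per-stage derived seeds, and an MD5 checksum
#' of every output file. Rerunning with an identical configuration and
#' seed reproduces identical checksums. Input files are never modified;
#' all outputs go under `config$out_dir`.
#'
#' `config` is a named list (or a path to a YAML file with the same
#' structure):
#' \describe{
#'   \item{out_dir}{run directory (required).}
#'   \item{seed}{global seed; per-stage seeds are derived from it
#'     (default 1).}
#'   \item{stages}{character subset of
#'     `c("simulate","preprocess","fit","predict","deconv",
#'     "characterize","scores")`; default all.}
#'   \item{synth}{overrides passed to [synth_config()] when simulating.}
#'   \item{params}{stage parameters: `missing_threshold` (0.5), `knn_k`
#'     (10), `cv_folds` (10), `deconv_threshold` (0.7), `flag_threshold`
#'     (0.3), `exome_mb` (38), `healthy_bmi` (25), `bmi_col` ("bmi").}
#'   \item{inputs}{file paths (`beta`, `annotation`, `clinical`,
#'     `expression`, `mutations`, `references`, optionally
#'     `external_scores`) used when `"simulate"` is not among the
#'     stages.}
#' }
#'
#' When simulating, the deconvolution references are the simulator's own
#' (post causal-probe override), so estimated adipose fractions can be
#' compared against the generator's truth.
#'
#' @param config Named list or YAML path as described above.
#' @return The run manifest (a list), invisibly written to
#'   `manifest.json` in the run directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir))
    stop("config$out_dir is required", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  all_stages <- c("simulate", "preprocess", "fit", "predict", "deconv",
                  "characterize", "scores")
  stages <- if (is.null(config$stages)) all_stages else
    match.arg(config$stages, all_stages, several.ok = TRUE)

  defaults <- list(missing_threshold = 0.5, knn_k = 10, cv_folds = 10,
                   deconv_threshold = 0.7, flag_threshold = 0.3,
                   exome_mb = 38, healthy_bmi = 25, bmi_col = "bmi")
  params <- utils::modifyList(defaults,
                              if (is.null(config$params)) list()
                              else config$params)
  # per-stage derived seeds so stages are individually reproducible
  stage_seed <- function(stage)
    as.integer((as.numeric(seed) * 101 + match(stage, all_stages)) %%
                 .Machine$integer.max)

  manifest <- list(seed = seed, stages = stages, params = params,
                   stage = list())
  md5 <- function(paths) as.list(tools::md5sum(unname(paths)))
  record <- function(stage, params, outputs)
    manifest$stage[[stage]] <<- list(seed = stage_seed(stage),
                                     params = params,
                                     outputs = md5(outputs))
  need_input <- function(field) {
    path <- config$inputs[[field]]
    if (is.null(path) || !file.exists(path))
      stop(sprintf("config$inputs$%s: path missing or not found (%s)",
                   field, if (is.null(path)) "unset" else path),
           call. = FALSE)
    path
  }

  ## ---- simulate (or load) ----
  if ("simulate" %in% stages) {
    sargs <- if (is.null(config$synth)) list() else config$synth
    sargs$seed <- stage_seed("simulate")
    cfg <- do.call(synth_config, sargs)
    refs0 <- simulate_reference_profiles(
      cfg$n_probes, n_discriminating = max(20L, cfg$n_probes %/% 50L),
      delta = 0.75, seed = stage_seed("simulate"))
    cohort <- simulate_cohort(cfg, refs0)
    sim_dir <- file.path(out_dir, "simulated")
    files <- write_cohort(cohort, sim_dir)
    record("simulate", cfg[setdiff(names(cfg), "seed")], files)
    beta <- cohort$beta
    ann <- cohort$annotation
    clinical <- cohort$clinical
    expr <- cohort$expression
    mut <- cohort$mutation_counts
    refs <- cohort$refs_used
  } else {
    beta <- read_beta_tsv(need_input("beta"))
    ann <- utils::read.delim(need_input("annotation"),
                             stringsAsFactors = FALSE)
    clinical <- utils::read.delim(need_input("clinical"),
                                  stringsAsFactors = FALSE)
    expr <- if ("characterize" %in% stages || "scores" %in% stages)
      .read_matrix_tsv(need_input("expression")) else NULL
    mut <- if ("scores" %in% stages) {
      md <- utils::read.delim(need_input("mutations"),
                              stringsAsFactors = FALSE)
      stats::setNames(md$n_nonsynonymous, md$sample_id)
    } else NULL
    refs <- if ("deconv" %in% stages)
      read_reference_tsv(need_input("references")) else NULL
    cohort <- NULL
  }

  ## ---- preprocess ----
  if ("preprocess" %in% stages) {
    beta <- filter_probes(beta, ann,
                          missing_threshold = params$missing_threshold)
    beta <- knn_impute(beta, k = params$knn_k)
    batches <- clinical$batch[match(colnames(beta), clinical$sample_id)]
    if (!is.null(batches) && length(unique(batches)) > 1)
      beta <- adjust_batches(beta, batches)
    out <- file.path(out_dir, "beta_clean.tsv")
    write_beta_tsv(beta, out)
    record("preprocess",
           params[c("missing_threshold", "knn_k")], c(beta_clean = out))
  }

  ## ---- fit ----
  model <- NULL
  if ("fit" %in% stages) {
    bmi <- clinical[[params$bmi_col]][match(colnames(beta),
                                            clinical$sample_id)]
    if (anyNA(bmi))
      stop(sprintf("clinical column '%s' missing for some samples",
                   params$bmi_col), call. = FALSE)
    model <- fit_dm_bmi(beta, bmi, healthy_bmi = params$healthy_bmi,
                        cv_folds = params$cv_folds,
                        seed = stage_seed("fit"))
    out <- file.path(out_dir, "model.json")
    write_dmbmi(model, out)
    record("fit", params[c("cv_folds", "healthy_bmi")],
           c(model = out))
  }

  ## ---- predict ----
  dmbmi <- NULL
  if ("predict" %in% stages) {
    if (is.null(model)) stop("predict requires the fit stage",
                             call. = FALSE)
    dmbmi <- predict(model, beta)
    dmbmi_t <- predict(model, beta, scale = "transformed")
    out <- file.path(out_dir, "dmbmi.tsv")
    utils::write.table(
      data.frame(sample_id = names(dmbmi), dm_bmi = unname(dmbmi),
                 dm_bmi_transformed = unname(dmbmi_t)),
      out, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(dmbmi = out)
    bmi <- clinical[[params$bmi_col]][match(names(dmbmi),
                                            clinical$sample_id)]
    if (!anyNA(bmi)) {
      ev <- evaluate_predictions(unname(dmbmi), bmi)
      evf <- file.path(out_dir, "prediction_eval.json")
      jsonlite::write_json(unclass(ev), evf, auto_unbox = TRUE,
                           digits = NA)
      outs <- c(outs, prediction_eval = evf)
    }
    record("predict", list(scale = "bmi"), outs)
  }

  ## ---- deconv ----
  if ("deconv" %in% stages) {
    if (is.null(refs)) stop("deconv requires reference profiles",
                            call. = FALSE)
    basis <- select_discriminating_probes(refs,
                                          params$deconv_threshold)
    basis <- intersect(basis, rownames(beta))
    if (length(basis) == 0)
      stop("no basis probe survived preprocessing", call. = FALSE)
    dec <- estimate_adipose_fraction(beta, refs, basis)
    out <- file.path(out_dir, "adipose_fraction.tsv")
    utils::write.table(
      data.frame(sample_id = names(dec$adipose_fraction),
                 adipose_fraction = unname(dec$adipose_fraction),
                 residual_rmse = unname(dec$residual_rmse)),
      out, sep = "\t", quote = FALSE, row.names = FALSE)
    record("deconv",
           c(params["deconv_threshold"], list(n_basis = length(basis))),
           c(adipose_fraction = out))
  }

  ## ---- characterize ----
  if ("characterize" %in% stages) {
    if (is.null(model)) stop("characterize requires the fit stage",
                             call. = FALSE)
    outs <- character(0)
    dist <- summarize_predictor_distribution(model, ann)
    dist_long <- do.call(rbind, lapply(names(dist), function(ax)
      cbind(axis = ax, dist[[ax]])))
    f1 <- file.path(out_dir, "predictor_distribution.tsv")
    utils::write.table(dist_long, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(outs, predictor_distribution = f1)
    if (!is.null(dmbmi) && length(model$coefficients) > 0) {
      cr <- correlate_features_with_score(
        beta[names(model$coefficients), , drop = FALSE], dmbmi,
        flag_threshold = params$flag_threshold)
      f2 <- file.path(out_dir, "predictor_dmbmi_correlation.tsv")
      utils::write.table(cr, f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, predictor_dmbmi_correlation = f2)
    }
    if (!is.null(expr) && length(model$coefficients) > 0) {
      mp <- names(model$coefficients)
      mapping <- stats::setNames(
        ann$gene[match(mp, ann$probe_id)], mp)
      mapping[is.na(mapping)] <- ""
      mapping[!(mapping %in% rownames(expr))] <- ""
      if (any(nzchar(mapping))) {
        me <- correlate_methylation_expression(beta, expr, mapping)
        f3 <- file.path(out_dir, "methylation_expression.tsv")
        utils::write.table(me, f3, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outs <- c(outs, methylation_expression = f3)
      }
    }
    record("characterize", params["flag_threshold"], outs)
  }

  ## ---- scores ----
  if ("scores" %in% stages) {
    if (is.null(dmbmi)) stop("scores requires the predict stage",
                             call. = FALSE)
    st <- data.frame(sample_id = names(dmbmi))
    if (!is.null(mut))
      st$TMB <- compute_tmb(mut[st$sample_id],
                            exome_mb = params$exome_mb)
    if (!is.null(expr)) {
      sigs <- builtin_signatures()
      for (nm in names(sigs)) {
        sc <- try(score_signature(expr, sigs[[nm]]), silent = TRUE)
        if (!inherits(sc, "try-error"))
          st[[if (nm == "APM") "APS" else nm]] <- sc[st$sample_id]
      }
    }
    if (!is.null(config$inputs$external_scores) &&
        file.exists(config$inputs$external_scores)) {
      ext <- utils::read.delim(config$inputs$external_scores,
                               stringsAsFactors = FALSE)
      st <- merge(st, ext, by = "sample_id", all.x = TRUE, sort = FALSE)
    }
    f1 <- file.path(out_dir, "sample_scores.tsv")
    utils::write.table(st, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(sample_scores = f1)
    if (ncol(st) > 1) {
      assoc <- associate_scores(dmbmi, st,
                                flag_threshold = params$flag_threshold)
      f2 <- file.path(out_dir, "score_associations.tsv")
      utils::write.table(assoc, f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, score_associations = f2)
    }
    record("scores", params[c("exome_mb", "flag_threshold")], outs)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
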