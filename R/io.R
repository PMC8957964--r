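#' Read and write beta-value matrices as TSV
#'
#' The on-disk layout is one row per probe: a `probe_id` column followed
#' by one column per sample; missing values are written as `NA`.
#'
#' @param beta Probes x samples matrix with dimnames.
#' @param path TSV path.
#' @return `write_beta_tsv` returns `path` invisibly; `read_beta_tsv`
#'   returns the matrix.
#' @export
write_beta_tsv <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Read and write reference methylome profiles as TSV
#'
#' Columns: `probe_id`, `beta_epithelial`, `beta_adipose`.
#'
#' @param refs A `reference_profiles` object.
#' @param path TSV path.
#' @return `write_reference_tsv` returns `path` invisibly;
#'   `read_reference_tsv` returns a `reference_profiles` object.
#' @export
write_reference_tsv <- function(refs, path) {
  df <- data.frame(probe_id = refs$probe_ids,
                   beta_epithelial = refs$beta_epithelial,
                   beta_adipose = refs$beta_adipose)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_tsv
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(probe_ids = df$probe_id,
                 beta_epithelial = df$beta_epithelial,
                 beta_adipose = df$beta_adipose,
                 discriminating = NULL),
            class = "reference_profiles")
}

# generic gene x sample (or any labelled) matrix TSV
.write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `beta.tsv`, `annotation.tsv`, `clinical.tsv`, `expression.tsv`,
#' `mutations.tsv` (columns `sample_id`, `n_nonsynonymous`),
#' `references.tsv`, and `truth.json` (causal probes, true adipose
#' fractions, true BMI).
#'
#' @param cohort A `synthetic_cohort` object.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_beta_tsv(cohort$beta, fp("beta.tsv"))
  utils::write.table(cohort$annotation, fp("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, fp("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_matrix_tsv(cohort$expression, fp("expression.tsv"), "gene")
  utils::write.table(
    data.frame(sample_id = names(cohort$mutation_counts),
               n_nonsynonymous = as.integer(cohort$mutation_counts)),
    fp("mutations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_reference_tsv(cohort$refs_used, fp("references.tsv"))
  jsonlite::write_json(
    list(causal_probes = cohort$causal_probes,
         true_bmi = as.list(cohort$true_bmi),
         true_adipose_fraction = as.list(cohort$true_adipose_fraction)),
    fp("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(beta = fp("beta.tsv"), annotation = fp("annotation.tsv"),
             clinical = fp("clinical.tsv"),
             expression = fp("expression.tsv"),
             mutations = fp("mutations.tsv"),
             references = fp("references.tsv"), truth = fp("truth.json"))
  invisible(files)
}
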