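# Spearman r (average ranks) and its p-value for one pair of vectors;
# constant input yields NA with a note rather than an error
.spearman_pair <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_,
                note = "constant input; Spearman undefined"))
  r <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  # the asymptotic p underflows to 0 at |r| = 1; keep it in (0, 1]
  list(r = r, p = max(p, .Machine$double.xmin), note = NA_character_)
}

.canonical_levels <- list(
  region_group = c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body",
                   "3'UTR", "IGR"),
  cgi_relation = c("island", "shore", "shelf", "open_sea"))

#' Genomic-category distribution of predictor CpGs
#'
#' Tallies the probes of a fitted DM-BMI model (or any probe set) across
#' chromosome, gene-region group, and CpG-island relation, reporting
#' counts and proportions. Categories with zero count are reported
#' explicitly so that, e.g., chromosomes carrying no predictor are
#' visible.
#'
#' @param model A `dmbmi` model, or a character vector of probe ids.
#' @param ann Probe annotation data frame (`probe_id`, `chr`,
#'   `region_group`, `cgi_relation`) covering every model probe.
#' @return An object of class `predictor_distribution`: a named list of
#'   data frames (`chromosome`, `region_group`, `cgi_relation`), each with
#'   `category`, `count`, `proportion`.
#' @export
summarize_predictor_distribution <- function(model, ann) {
  probes <- if (inherits(model, "dmbmi")) names(model$coefficients)
            else as.character(model)
  stopifnot(is.data.frame(ann),
            all(c("probe_id", "chr", "region_group", "cgi_relation") %in%
                  names(ann)))
  if (length(probes) == 0) {
    warning("empty predictor set; returning empty distribution")
    empty <- data.frame(category = character(0), count = integer(0),
                        proportion = numeric(0))
    return(structure(list(chromosome = empty, region_group = empty,
                          cgi_relation = empty),
                     class = "predictor_distribution"))
  }
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx))
    stop("unannotated model probes: ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  tab1 <- function(vals, levels) {
    f <- factor(vals, levels = levels)
    ct <- table(f)
    data.frame(category = names(ct), count = as.integer(ct),
               proportion = as.numeric(ct) / length(vals),
               stringsAsFactors = FALSE)
  }
  chr_levels <- unique(c(as.character(1:22), "X", "Y",
                         as.character(ann$chr)))
  structure(list(
    chromosome = tab1(as.character(ann$chr[idx]), chr_levels),
    region_group = tab1(ann$region_group[idx],
                        unique(c(.canonical_levels$region_group,
                                 ann$region_group))),
    cgi_relation = tab1(ann$cgi_relation[idx],
                        unique(c(.canonical_levels$cgi_relation,
                                 ann$cgi_relation)))),
    class = "predictor_distribution")
}

#' @export
print.predictor_distribution <- function(x, ...) {
  for (axis in names(x)) {
    cat(axis, ":\n", sep = "")
    d <- x[[axis]]
    shown <- d[d$count > 0, , drop = FALSE]
    if (nrow(shown) == 0) { cat("  (empty)\n"); next }
    for (i in seq_len(nrow(shown)))
      cat(sprintf("  %-10s %3d (%.1f%%)\n", shown$category[i],
                  shown$count[i], 100 * shown$proportion[i]))
  }
  invisible(x)
}

#' Paired differential methylation between tumor and adjacent tissue
#'
#' For each probe, a two-sided paired t-test on the tumor-minus-adjacent
#' beta differences across sample pairs, with Benjamini-Hochberg
#' adjustment across all tested probes. A probe is called `hyper` (or
#' `hypo`) when its BH q-value is strictly below `alpha` and the mean
#' difference is positive (negative); otherwise `ns`. When a probe's
#' differences have zero variance the t statistic is 0 with p = 1 if the
#' mean difference is also zero, and undefined (NA, noted) otherwise.
#'
#' @param beta_tumor Probes x samples matrix of tumor beta values.
#' @param beta_adjacent Probes x samples matrix for the paired adjacent
#'   tissues; must carry the same probes as `beta_tumor`.
#' @param pairs Data frame with columns `tumor` and `adjacent` naming the
#'   paired sample columns.
#' @param alpha Significance level on the q-value (default 0.05, strict).
#' @return Data frame with `probe_id`, `mean_diff`, `t_stat`, `p_value`,
#'   `q_value`, `direction`.
#' @export
paired_dmp_test <- function(beta_tumor, beta_adjacent, pairs,
                            alpha = 0.05) {
  stopifnot(is.matrix(beta_tumor), is.matrix(beta_adjacent),
            is.data.frame(pairs),
            all(c("tumor", "adjacent") %in% names(pairs)))
  if (nrow(pairs) < 3)
    stop("need at least 3 tumor/adjacent pairs", call. = FALSE)
  miss_t <- setdiff(pairs$tumor, colnames(beta_tumor))
  miss_a <- setdiff(pairs$adjacent, colnames(beta_adjacent))
  if (length(miss_t) || length(miss_a))
    stop("unmatched samples in `pairs`: ",
         paste(utils::head(c(miss_t, miss_a), 5), collapse = ", "),
         call. = FALSE)
  if (!identical(sort(rownames(beta_tumor)), sort(rownames(beta_adjacent))))
    stop("tumor and adjacent matrices must carry the same probes",
         call. = FALSE)
  adj <- beta_adjacent[rownames(beta_tumor), , drop = FALSE]
  D <- beta_tumor[, pairs$tumor, drop = FALSE] -
    adj[, pairs$adjacent, drop = FALSE]
  np <- nrow(pairs)
  m <- rowMeans(D)
  s <- apply(D, 1, stats::sd)
  tstat <- ifelse(s == 0, ifelse(m == 0, 0, NA_real_),
                  m / (s / sqrt(np)))
  pval <- ifelse(is.na(tstat), NA_real_,
                 ifelse(s == 0, 1, 2 * stats::pt(-abs(tstat), df = np - 1)))
  qval <- stats::p.adjust(pval, method = "BH")
  direction <- rep("ns", nrow(D))
  sig <- !is.na(qval) & qval < alpha
  direction[sig & m > 0] <- "hyper"
  direction[sig & m < 0] <- "hypo"
  data.frame(probe_id = rownames(D), mean_diff = m, t_stat = tstat,
             p_value = pval, q_value = qval, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation screen of features against a per-sample score
#'
#' Correlates each feature (row) with the score across samples and flags
#' features with `|r|` strictly greater than `flag_threshold` (default
#' 0.3). Constant features yield an NA correlation with an explanatory
#' note and are never silently dropped.
#'
#' @param features Feature x sample numeric matrix with feature rownames.
#' @param score Per-sample numeric vector aligned with the columns (by
#'   name when both are named, else by position).
#' @param flag_threshold Strict absolute-correlation flag threshold.
#' @return Data frame with `feature_id`, `r`, `p_value`, `flagged`,
#'   `note`.
#' @export
correlate_features_with_score <- function(features, score,
                                          flag_threshold = 0.3) {
  stopifnot(is.matrix(features), is.numeric(score))
  if (!is.null(colnames(features)) && !is.null(names(score))) {
    common <- intersect(colnames(features), names(score))
    if (length(common) < 3)
      stop("fewer than 3 overlapping samples", call. = FALSE)
    features <- features[, common, drop = FALSE]
    score <- score[common]
  } else if (length(score) != ncol(features)) {
    stop("`score` must align with the columns of `features`",
         call. = FALSE)
  }
  if (ncol(features) < 3)
    stop("need at least 3 samples", call. = FALSE)
  res <- lapply(seq_len(nrow(features)), function(i)
    .spearman_pair(features[i, ], score))
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(
    feature_id = if (is.null(rownames(features)))
      as.character(seq_len(nrow(features))) else rownames(features),
    r = r, p_value = p,
    flagged = !is.na(r) & abs(r) > flag_threshold,
    note = vapply(res, `[[`, character(1), "note"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate promoter methylation with gene expression
#'
#' For each probe mapped to a gene, the Spearman correlation between the
#' probe's beta values and the gene's expression across the common
#' samples. A probe is flagged `negative` when r < 0 with p < 0.05 (raw);
#' BH q-values across the tested family are also reported. Probes without
#' a gene mapping are skipped and recorded in the `skipped` attribute.
#'
#' @param beta Probes x samples matrix.
#' @param expr Genes x samples expression matrix.
#' @param mapping Named character vector `probe_id -> gene`, or a data
#'   frame with columns `probe_id` and `gene`. Empty strings and NAs mean
#'   "unmapped".
#' @return Data frame with `probe_id`, `gene`, `r`, `p_value`, `q_value`,
#'   `negative_flag`, `note`; attribute `skipped` lists unmapped probes.
#' @export
correlate_methylation_expression <- function(beta, expr, mapping) {
  stopifnot(is.matrix(beta), is.matrix(expr))
  if (is.data.frame(mapping)) {
    stopifnot(all(c("probe_id", "gene") %in% names(mapping)))
    mapping <- stats::setNames(as.character(mapping$gene),
                               mapping$probe_id)
  }
  mapping <- mapping[names(mapping) %in% rownames(beta)]
  mapped <- !is.na(mapping) & nzchar(mapping)
  skipped <- names(mapping)[!mapped]
  mapping <- mapping[mapped]
  if (length(mapping) == 0)
    stop("no probe maps to a gene; check `mapping`", call. = FALSE)
  absent <- setdiff(unique(mapping), rownames(expr))
  if (length(absent) > 0)
    stop("mapped genes absent from `expr`: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  common <- intersect(colnames(beta), colnames(expr))
  if (length(common) < 3)
    stop("fewer than 3 overlapping samples", call. = FALSE)
  res <- lapply(names(mapping), function(pr)
    .spearman_pair(beta[pr, common], expr[mapping[[pr]], common]))
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- data.frame(probe_id = names(mapping), gene = unname(mapping),
                    r = r, p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    negative_flag = !is.na(r) & r < 0 & !is.na(p) & p < 0.05,
                    note = vapply(res, `[[`, character(1), "note"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
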