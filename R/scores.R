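#' Tumor mutation burden
#'
#' Non-synonymous mutation count divided by the captured exome size in
#' megabases (default 38 Mb), giving mutations/Mb.
#'
#' @param mutations Per-sample non-negative integer counts of
#'   non-synonymous mutations (names preserved).
#' @param exome_mb Exome size in Mb (default 38).
#' @return Per-sample TMB, mutations/Mb.
#' @examples
#' compute_tmb(c(A = 0, B = 38, C = 95))
#' @export
compute_tmb <- function(mutations, exome_mb = 38) {
  stopifnot(is.numeric(mutations), is.numeric(exome_mb),
            length(exome_mb) == 1L, exome_mb > 0)
  if (any(is.na(mutations)) || any(mutations < 0) ||
      any(mutations != floor(mutations)))
    stop("`mutations` must be non-negative integer counts", call. = FALSE)
  mutations / exome_mb
}

#' Built-in immunotherapy-response gene signatures
#'
#' The six-gene interferon-gamma signature (`IFNG`) and the 18-gene
#' antigen processing and presentation machinery set (`APM`, scored as
#' APS). The expanded interferon-gamma hallmark set (`IFNG.GS`) has no
#' fixed built-in membership and must be supplied by the user; see
#' [get_builtin_signature()].
#'
#' @return Named list of signature sets; each is a list with `name` and
#'   `genes`.
#' @export
builtin_signatures <- function() {
  list(
    IFNG = list(name = "IFNG",
                genes = c("IFNG", "STAT1", "IDO1", "CXCL9", "CXCL10",
                          "HLA-DRA")),
    APM = list(name = "APM",
               genes = c("PSMB5", "PSMB6", "PSMB7", "PSMB8", "PSMB9",
                         "PSMB10", "TAP1", "TAP2", "ERAP1", "ERAP2",
                         "CANX", "CALR", "PDIA3", "TAPBP", "B2M",
                         "HLA-A", "HLA-B", "HLA-C")))
}

#' Retrieve a signature set by name
#'
#' @param name One of `"IFNG"`, `"APM"`, `"IFNG.GS"`.
#' @param genes Gene symbols; required for `"IFNG.GS"`, ignored otherwise.
#' @return A signature set (list with `name`, `genes`).
#' @export
get_builtin_signature <- function(name, genes = NULL) {
  sigs <- builtin_signatures()
  if (name %in% names(sigs)) return(sigs[[name]])
  if (name == "IFNG.GS") {
    if (is.null(genes) || length(genes) == 0)
      stop(paste0("IFNG.GS has no built-in membership; supply its gene ",
                  "list via `genes`"), call. = FALSE)
    genes <- unique(as.character(genes))
    return(list(name = "IFNG.GS", genes = genes))
  }
  stop(sprintf("unknown signature '%s'", name), call. = FALSE)
}

#' Score a gene signature as the mean expression of its genes
#'
#' The unweighted per-sample mean over the signature genes present in the
#' expression matrix. Expression is assumed pre-normalized. Signature
#' genes absent from the matrix are recorded in the `missing_genes`
#' attribute; the score is the mean over the present genes.
#'
#' @param expr Genes x samples numeric matrix with gene rownames.
#' @param sig A signature set (list with `name`, `genes`), e.g. from
#'   [builtin_signatures()], or a character vector of gene symbols.
#' @return Named per-sample score vector; attributes `signature`,
#'   `missing_genes`, `n_used`.
#' @export
score_signature <- function(expr, sig) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.character(sig)) sig <- list(name = "custom", genes = sig)
  genes <- unique(sig$genes)
  if (length(genes) == 0) stop("empty signature", call. = FALSE)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0)
    stop(sprintf("no gene of signature '%s' present in `expr`", sig$name),
         call. = FALSE)
  score <- colMeans(expr[present, , drop = FALSE])
  attr(score, "signature") <- sig$name
  attr(score, "missing_genes") <- setdiff(genes, present)
  attr(score, "n_used") <- length(present)
  score
}

#' Associate per-sample scores with DM-BMI
#'
#' Spearman correlation (with p-value) between DM-BMI and each score
#' column over the samples present (non-missing) in both, with the
#' overlap size reported. External-tool scores (immune/stromal estimates,
#' immune-dysfunction scores, cell-type abundances) are ingested as
#' columns of `scores`, never recomputed.
#'
#' @param dmbmi Named per-sample DM-BMI vector (kg/m^2).
#' @param scores Data frame with a `sample_id` column and one numeric
#'   column per score.
#' @param flag_threshold Strict `|r|` flag threshold (default 0.3).
#' @return Data frame with `score`, `n_overlap`, `r`, `p_value`,
#'   `flagged`, `note`.
#' @export
associate_scores <- function(dmbmi, scores, flag_threshold = 0.3) {
  stopifnot(is.numeric(dmbmi), !is.null(names(dmbmi)),
            is.data.frame(scores), "sample_id" %in% names(scores))
  cols <- setdiff(names(scores), "sample_id")
  if (length(cols) == 0) stop("no score columns", call. = FALSE)
  out <- lapply(cols, function(cl) {
    v <- scores[[cl]]
    ok <- !is.na(v) & scores$sample_id %in% names(dmbmi)
    ids <- scores$sample_id[ok]
    if (length(ids) < 3)
      stop(sprintf("score '%s': fewer than 3 overlapping samples", cl),
           call. = FALSE)
    sp <- .spearman_pair(dmbmi[ids], v[ok])
    data.frame(score = cl, n_overlap = length(ids), r = sp$r,
               p_value = sp$p,
               flagged = !is.na(sp$r) && abs(sp$r) > flag_threshold,
               note = sp$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
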