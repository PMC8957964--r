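#' Probe-level quality filter
#'
#' Removes probes that are (i) missing in strictly more than
#' `missing_threshold` of samples, (ii) located on a sex chromosome
#' (X or Y), or (iii) flagged as overlapping a known SNP. The comparison
#' in (i) is strict: a probe missing in exactly half the samples at the
#' default threshold survives. Probe order is preserved, so the filter is
#' idempotent.
#'
#' @param beta Probes x samples numeric matrix in \[0, 1\], `NA` = missing,
#'   with probe/sample dimnames.
#' @param ann Annotation data frame with columns `probe_id`, `chr`,
#'   `snp_flag`, covering every probe of `beta`.
#' @param missing_threshold Missingness fraction above which (strictly) a
#'   probe is removed; default 0.5.
#' @return The filtered beta matrix.
#' @export
filter_probes <- function(beta, ann, missing_threshold = 0.5) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)),
            is.data.frame(ann),
            all(c("probe_id", "chr", "snp_flag") %in% names(ann)),
            missing_threshold >= 0, missing_threshold <= 1)
  idx <- match(rownames(beta), ann$probe_id)
  if (anyNA(idx))
    stop("unannotated probes: ",
         paste(utils::head(rownames(beta)[is.na(idx)], 5), collapse = ", "),
         if (sum(is.na(idx)) > 5) ", ..." else "", call. = FALSE)
  miss_frac <- rowMeans(is.na(beta))
  drop <- miss_frac > missing_threshold |
    as.character(ann$chr[idx]) %in% c("X", "Y") |
    as.logical(ann$snp_flag[idx])
  beta[!drop, , drop = FALSE]
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Fills each missing entry with the mean, at that sample, of the `k`
#' probes nearest to the target probe. Distance between two probes is the
#' Euclidean distance over the samples where both are observed; probes
#' with no co-observed sample, probes unobserved at the target sample, and
#' the target probe itself are excluded as neighbours. Distance ties are
#' broken by probe order. If fewer than `k` eligible neighbours exist, all
#' of them are used; if none exist the probe's own observed mean is used.
#' Observed entries are returned bit-exactly unchanged.
#'
#' @param beta Probes x samples matrix, `NA` = missing; every probe must
#'   have at least one observed value.
#' @param k Number of neighbours (default 10).
#' @return The matrix with no missing entries.
#' @export
knn_impute <- function(beta, k = 10) {
  stopifnot(is.matrix(beta), k >= 1)
  if (!anyNA(beta)) return(beta)
  obs <- !is.na(beta)
  if (any(rowSums(obs) == 0))
    stop("probes with zero observed values cannot be imputed", call. = FALSE)
  if (any(colSums(obs) == 0))
    stop("samples with zero observed probes cannot be imputed",
         call. = FALSE)
  p <- nrow(beta)
  need <- which(rowSums(!obs) > 0)

  # squared distances over co-observed samples, target probes x all probes:
  # sum_s (x_is - x_js)^2 = sum x_is^2 + sum x_js^2 - 2 sum x_is x_js,
  # each sum restricted to samples observed in both rows
  X0 <- beta
  X0[!obs] <- 0
  M <- obs * 1
  Xn <- X0[need, , drop = FALSE]
  Mn <- M[need, , drop = FALSE]
  cross <- Xn %*% t(X0)
  sq_i <- (Xn * Xn) %*% t(M)   # sum of target's squares over co-observed
  sq_j <- Mn %*% t(X0 * X0)    # sum of neighbour's squares over co-observed
  co <- Mn %*% t(M)            # co-observation counts
  d2 <- sq_i + sq_j - 2 * cross
  d2[d2 < 0] <- 0              # numerical noise
  d2[co == 0] <- Inf

  out <- beta
  for (ii in seq_along(need)) {
    i <- need[ii]
    di <- d2[ii, ]
    di[i] <- Inf
    for (s in which(!obs[i, ])) {
      cand <- which(obs[, s] & is.finite(di))
      if (length(cand) == 0) {
        out[i, s] <- mean(beta[i, obs[i, ]])
        next
      }
      ord <- cand[order(di[cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      out[i, s] <- mean(beta[nb, s])
    }
  }
  out
}

#' Simplified batch adjustment by per-batch mean centring
#'
#' For each probe, shifts every batch's mean to the probe's grand mean and
#' clips the result to \[0, 1\]. This removes additive per-batch location
#' shifts exactly; it does not shrink batch-specific variances (no
#' empirical-Bayes step). Each probe's grand mean is preserved whenever
#' clipping is not triggered.
#'
#' @param beta Probes x samples matrix with no missing values.
#' @param batch_labels Per-sample batch factor/vector, aligned with
#'   columns of `beta`.
#' @return The adjusted matrix.
#' @export
adjust_batches <- function(beta, batch_labels) {
  stopifnot(is.matrix(beta))
  if (anyNA(beta))
    stop("`beta` must have no missing values (impute first)", call. = FALSE)
  if (length(batch_labels) != ncol(beta))
    stop("`batch_labels` must have one label per sample", call. = FALSE)
  if (anyNA(batch_labels))
    stop("unlabeled samples: ",
         paste(utils::head(colnames(beta)[is.na(batch_labels)], 5),
               collapse = ", "), call. = FALSE)
  f <- factor(batch_labels)
  if (nlevels(f) == 1) return(beta)
  grand <- rowMeans(beta)
  out <- beta
  for (lev in levels(f)) {
    j <- which(f == lev)
    out[, j] <- beta[, j, drop = FALSE] -
      rowMeans(beta[, j, drop = FALSE]) + grand
  }
  pmin(pmax(out, 0), 1)
}
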